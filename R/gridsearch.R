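# Joint grid search over masking ratio and patch length: every cell
# pre-trains with identical seed and budget, fine-tunes on the labeled
# training set, and reports downstream vGRF correlation on the test set.

#' Masking-ratio x patch-length grid search
#'
#' For each (patch length, masking ratio) cell: pre-train with the
#' self-supervised masking objective, run two-step fine-tuning on the labeled
#' training windows, and record the mean per-participant vGRF correlation on
#' the test windows. All cells share the same seed and step budgets. Cells
#' whose masking ratio rounds to zero masked patches are marked invalid
#' rather than failing the run.
#'
#' @param corpus Normalized pre-training [window_set()].
#' @param labeled_train Normalized labeled training [window_set()].
#' @param labeled_test Normalized labeled test [window_set()] (gold GRF used
#'   for scoring is taken from it, de-normalized with `stats`).
#' @param stats The [fit_normalizer()] statistics of the labeled fold.
#' @param patch_lengths Integer vector of patch lengths.
#' @param mask_ratios Numeric vector of masking ratios.
#' @param base_cfg Architecture defaults for every cell (patch length and
#'   ratio are overridden per cell).
#' @param ssl_cfg [train_config()] for pre-training (shared by all cells).
#' @param ft1,ft2 [train_config()]s for the two fine-tuning steps.
#' @return Tibble of class `grf_grid`: `patch_length`, `masking_ratio`,
#'   `rho`, `valid`.
#' @export
grid_search <- function(corpus, labeled_train, labeled_test, stats,
                        patch_lengths = c(1L, 2L, 4L, 8L),
                        mask_ratios = c(0.0625, 0.125, 0.25, 0.375, 0.5, 0.625),
                        base_cfg = tiny_model_config(),
                        ssl_cfg = train_config(200L),
                        ft1 = train_config(100L, peak_lr = 1e-3),
                        ft2 = train_config(100L, peak_lr = 1e-4)) {
  cells <- tidyr::expand_grid(patch_length = as.integer(patch_lengths),
                              masking_ratio = mask_ratios)
  res <- purrr::pmap_dfr(cells, function(patch_length, masking_ratio) {
    n_patch <- base_cfg$window_length %/% patch_length
    if (round(masking_ratio * n_patch) < 1) {
      return(tibble::tibble(patch_length = patch_length,
                            masking_ratio = masking_ratio,
                            rho = NA_real_, valid = FALSE))
    }
    cfg <- model_config(
      patch_length = patch_length, masking_ratio = masking_ratio,
      embed_dim = base_cfg$embed_dim, n_blocks = base_cfg$n_blocks,
      n_heads = base_cfg$n_heads, ff_dim = base_cfg$ff_dim,
      dropout = base_cfg$dropout, layer_norm_eps = base_cfg$layer_norm_eps,
      n_axes = base_cfg$n_axes, window_length = base_cfg$window_length)
    fit <- pretrain_ssl(corpus, cfg, ssl_cfg)
    ft <- finetune_two_step(fit$state, labeled_train, ft1, ft2)
    rho <- mean_test_vgrf_rho(ft$state, labeled_test, stats)
    tibble::tibble(patch_length = patch_length,
                   masking_ratio = masking_ratio, rho = rho, valid = TRUE)
  })
  class(res) <- c("grf_grid", class(res))
  res
}

# mean per-participant vGRF correlation over stance samples of a labeled,
# normalized test set
mean_test_vgrf_rho <- function(state, labeled_test, stats,
                               present = sensor_names(),
                               cfg_eval = eval_config()) {
  est <- predict_grf_windows(state, labeled_test, stats = stats,
                             present = present)
  gold <- apply_normalizer(labeled_test, stats, invert = TRUE)
  rep <- evaluate_grf(est, gold, cfg_eval)
  mean(rep$per_axis$rho[rep$per_axis$axis == "v"])
}
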