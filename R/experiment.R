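# End-to-end experiment runner: one YAML config drives fixtures ->
# preprocessing -> SSL pre-training -> two-step fine-tuning -> evaluation,
# writing a deterministic artifact directory.

experiment_defaults <- function() {
  list(
    fixtures = list(n_participants = 8L, duration_s = 40, noise_acc = 0.05,
                    noise_gyro = 0.5, stillness_fraction = 0),
    model = list(patch_length = 8L, masking_ratio = 0.125, embed_dim = 64L,
                 n_blocks = 2L, n_heads = 4L, ff_dim = 128L),
    # desk-scale profile: the peak learning rate is scaled up with the
    # 100x shorter schedule relative to full-scale training
    pretrain = list(steps = 500L, peak_lr = 1e-3, batch_size = 64L),
    finetune = list(steps1 = 300L, steps2 = 300L, lr1 = 1e-3, lr2 = 1e-4,
                    batch_size = 64L, labeled_fraction = 1.0,
                    n_test_participants = 2L)
  )
}

validate_run_config <- function(config) {
  required <- c("seed", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("experiment config is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  defaults <- experiment_defaults()
  for (section in names(defaults)) {
    config[[section]] <- utils::modifyList(defaults[[section]],
                                           config[[section]] %||% list())
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full experiment from a config
#'
#' Resolves the config against the package defaults, builds the synthetic
#' corpus, pre-trains with the masking objective, fine-tunes in two steps on
#' the labeled training participants, evaluates on the held-out participants,
#' and writes a deterministic artifact directory: `checkpoints/`, `reports/`,
#' `logs/` and `resolved-config.yaml`.
#'
#' @param config Path to a YAML config, or an equivalent named list. Required
#'   fields: `seed`, `out_dir`; sections `fixtures`, `model`, `pretrain`,
#'   `finetune` override the defaults.
#' @param dry_run If TRUE, validate, print the plan and return it without
#'   computing.
#' @return Invisibly, a list with the resolved config, the evaluation report
#'   and the artifact directory.
#' @export
run_experiment <- function(config, dry_run = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_run_config(config)
  plan <- sprintf(
    paste0("experiment plan: %d participants (%d held out), %g s trials; ",
           "model patch %d width %d x %d blocks; %d SSL steps; ",
           "fine-tune %d + %d steps at %.0f%% labels; out: %s"),
    config$fixtures$n_participants, config$finetune$n_test_participants,
    config$fixtures$duration_s, config$model$patch_length,
    config$model$embed_dim, config$model$n_blocks, config$pretrain$steps,
    config$finetune$steps1, config$finetune$steps2,
    100 * config$finetune$labeled_fraction, config$out_dir)
  if (dry_run) {
    message(plan)
    return(invisible(list(config = config, plan = plan)))
  }
  out_dir <- config$out_dir
  for (d in file.path(out_dir, c("checkpoints", "reports", "logs"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  yaml::write_yaml(config, file.path(out_dir, "resolved-config.yaml"))
  seed <- as.integer(config$seed)

  fx <- do.call(fixture_config,
                c(config$fixtures, list(seed = seed)))
  corpus <- make_corpus(fx, labeled_fraction = 1.0)
  participants <- sort(unique(corpus$labeled$meta$participant_id))
  n_test <- config$finetune$n_test_participants
  test_ids <- utils::tail(participants, n_test)
  train_ids <- setdiff(participants, test_ids)

  pre_train <- subset_windows(
    corpus$pretrain, which(corpus$pretrain$meta$participant_id %in% train_ids))
  stats_pre <- fit_normalizer(pre_train)
  pre_norm <- apply_normalizer(pre_train, stats_pre)
  mcfg <- do.call(model_config, config$model)
  ssl_cfg <- train_config(config$pretrain$steps,
                          peak_lr = config$pretrain$peak_lr,
                          batch_size = config$pretrain$batch_size,
                          seed = seed)
  fit <- pretrain_ssl(pre_norm, mcfg, ssl_cfg)
  save_checkpoint(fit$state, file.path(out_dir, "checkpoints", "ssl.rds"),
                  stats = stats_pre)
  write_jsonl(
    tibble::tibble(step = seq_along(fit$loss_history),
                   lr = vapply(seq_along(fit$loss_history), lr_at,
                               numeric(1), cfg = ssl_cfg),
                   loss = fit$loss_history),
    file.path(out_dir, "logs", "pretrain.jsonl"))

  lab_train <- subset_windows(
    corpus$labeled, which(corpus$labeled$meta$participant_id %in% train_ids))
  lab_test <- subset_windows(
    corpus$labeled, which(corpus$labeled$meta$participant_id %in% test_ids))
  if (config$finetune$labeled_fraction < 1) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed + 3L)
    n <- n_windows(lab_train)
    m <- max(1L, floor(config$finetune$labeled_fraction * n))
    lab_train <- subset_windows(lab_train, sort(sample.int(n, m)))
  }
  stats_ft <- fit_normalizer(lab_train)
  ft <- finetune_two_step(
    fit$state, apply_normalizer(lab_train, stats_ft),
    train_config(config$finetune$steps1, peak_lr = config$finetune$lr1,
                 batch_size = config$finetune$batch_size, seed = seed),
    train_config(config$finetune$steps2, peak_lr = config$finetune$lr2,
                 batch_size = config$finetune$batch_size, seed = seed))
  save_checkpoint(ft$state, file.path(out_dir, "checkpoints", "finetuned.rds"),
                  stats = stats_ft)

  test_norm <- apply_normalizer(lab_test, stats_ft)
  est <- predict_grf_windows(ft$state, test_norm, stats = stats_ft)
  report <- evaluate_grf(est, lab_test)
  report_list <- list(
    per_axis = as.list(dplyr::group_by(report$per_axis, .data$axis) |>
                         dplyr::summarise(rho = mean(.data$rho),
                                          rmse = mean(.data$rmse))),
    peaks = list(rho = mean(report$peaks$rho),
                 rmse = mean(report$peaks$rmse),
                 rrmse = mean(report$peaks$rrmse)),
    n_test_windows = n_windows(lab_test))
  jsonlite::write_json(report_list,
                       file.path(out_dir, "reports", "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(config = config, report = report, out_dir = out_dir))
}

write_jsonl <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}
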