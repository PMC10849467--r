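# Evaluation: stance-phase masking, correlation/RMSE/rRMSE, peak-vGRF
# metrics, FFT spectrum error, subject-wise cross-validation folds, scaling
# curves, and the ANOVA + Bonferroni-paired-t model comparison.

#' Evaluation configuration
#'
#' @param stance_threshold_frac Fraction of body weight below which vertical
#'   GRF samples are excluded (swing/flight).
#' @param g Standard gravity, N/kg; with mass-normalized GRF the stance
#'   threshold is `stance_threshold_frac * g` regardless of body mass.
#' @param k Number of cross-validation folds.
#' @param alpha Significance level.
#' @return An `eval_config` list.
#' @export
eval_config <- function(stance_threshold_frac = 0.02, g = 9.81, k = 5L,
                        alpha = 0.05) {
  stopifnot(k >= 2)
  structure(list(stance_threshold_frac = stance_threshold_frac, g = g,
                 k = as.integer(k), alpha = alpha),
            class = "eval_config")
}

#' Stance-phase inclusion mask
#'
#' TRUE exactly where gold-standard vertical GRF is at or above the
#' body-weight threshold (default 2% of 9.81 N/kg = 0.1962 N/kg); rows beyond
#' `valid_length` are always FALSE.
#'
#' @param vgrf Gold vertical GRF sequence in N/kg.
#' @param threshold_frac Body-weight fraction.
#' @param g Standard gravity in N/kg.
#' @param valid_length Number of valid (non-padded) leading samples.
#' @return Logical vector the length of `vgrf`.
#' @export
phase_mask <- function(vgrf, threshold_frac = 0.02, g = 9.81,
                       valid_length = length(vgrf)) {
  m <- vgrf >= threshold_frac * g
  if (valid_length < length(vgrf)) {
    m[(valid_length + 1L):length(vgrf)] <- FALSE
  }
  m
}

#' Pearson correlation between estimate and gold standard
#'
#' @param a,b Equal-length numeric vectors (length >= 2).
#' @return Correlation coefficient.
#' @export
pearson_r <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: an input has zero variance", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Root mean square error
#' @param a,b Equal-length numeric vectors.
#' @return RMSE.
#' @export
rmse <- function(a, b) {
  stopifnot(length(a) == length(b))
  sqrt(mean((a - b)^2))
}

#' Relative RMSE as a percentage of the gold vGRF range
#'
#' `RMSE / (max(gold) - min(gold)) * 100`, where the range is taken over the
#' participant's gold vertical GRF.
#'
#' @param est,gold Paired numeric vectors entering the RMSE.
#' @param gold_range Optional numeric range values to use as the denominator;
#'   defaults to `gold` itself.
#' @return rRMSE in percent.
#' @export
rrmse <- function(est, gold, gold_range = gold) {
  rng <- max(gold_range) - min(gold_range)
  if (rng <= 0) stop("gold range is zero; rRMSE undefined", call. = FALSE)
  rmse(est, gold) / rng * 100
}

#' Peak-vGRF metrics over windows
#'
#' Takes one peak (maximum of vertical GRF over included samples) per window
#' and computes correlation, RMSE, and rRMSE over the paired peaks. The rRMSE
#' denominator is the range of the participant's gold vGRF over all included
#' samples. Windows whose phase mask is empty are skipped.
#'
#' @param est `n` x `L` matrix (or `n` x `L` x >=1 array slice) of estimated
#'   vGRF per window.
#' @param gold Matching gold vGRF.
#' @param masks `n` x `L` logical matrix of included samples per window.
#' @return Tibble with `rho`, `rmse`, `rrmse`, `n_windows`, `n_skipped`.
#' @export
peak_vgrf_metrics <- function(est, gold, masks) {
  n <- nrow(gold)
  peaks_est <- rep(NA_real_, n); peaks_gold <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    inc <- masks[i, ]
    if (!any(inc)) next
    peaks_est[i] <- max(est[i, inc])
    peaks_gold[i] <- max(gold[i, inc])
  }
  ok <- !is.na(peaks_gold)
  if (sum(ok) < 2) stop("fewer than two windows with stance samples",
                        call. = FALSE)
  gold_all <- as.vector(gold[masks])
  tibble::tibble(
    rho = pearson_r(peaks_est[ok], peaks_gold[ok]),
    rmse = rmse(peaks_est[ok], peaks_gold[ok]),
    rrmse = rmse(peaks_est[ok], peaks_gold[ok]) /
      (max(gold_all) - min(gold_all)) * 100,
    n_windows = sum(ok), n_skipped = sum(!ok))
}

#' Mean spectrum error between estimated and gold GRF
#'
#' Per window, the one-sided FFT magnitude spectrum of the estimate minus
#' that of the gold signal, averaged across windows (signed by default).
#'
#' @param est,gold `n` x `L` matrices of per-window vGRF (or any GRF axis).
#' @param fs Sampling rate in Hz.
#' @param mode `"signed"` (default) or `"absolute"` differences.
#' @return Tibble with `freq_hz` (0 to Nyquist, `L/2 + 1` bins) and `error`.
#' @export
spectrum_error <- function(est, gold, fs = 100, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(all(dim(est) == dim(gold)))
  L <- ncol(est)
  nb <- L %/% 2 + 1L
  diffs <- matrix(0, nrow(est), nb)
  for (i in seq_len(nrow(est))) {
    d <- Mod(stats::fft(est[i, ]))[seq_len(nb)] -
      Mod(stats::fft(gold[i, ]))[seq_len(nb)]
    diffs[i, ] <- if (mode == "signed") d else abs(d)
  }
  tibble::tibble(freq_hz = (seq_len(nb) - 1) * fs / L,
                 error = colMeans(diffs))
}

#' Subject-wise cross-validation folds
#'
#' Randomly partitions participants into `k` folds whose sizes differ by at
#' most one; no participant appears in two folds.
#'
#' @param participant_ids Character vector of (unique) participant ids.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Tibble with `participant_id` and `fold` (1..k).
#' @export
make_folds <- function(participant_ids, k = 5L, seed = 1L) {
  ids <- unique(participant_ids)
  if (length(ids) < k) {
    stop("need at least as many participants as folds", call. = FALSE)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample(ids)
  fold <- rep(seq_len(k), length.out = length(ids))
  tibble::tibble(participant_id = perm, fold = fold) |>
    dplyr::arrange(.data$participant_id)
}

#' Training-fraction grids for scaling curves
#'
#' Linear grid 100% down to 10% in steps of 10 (10 points); exponential grid
#' `10^0` down to `10^-2` in steps of `10^-0.2` (11 points).
#'
#' @param type `"linear"` or `"exponential"`.
#' @return Numeric vector of fractions, sorted descending.
#' @export
fraction_grid <- function(type = c("linear", "exponential")) {
  type <- match.arg(type)
  if (type == "linear") seq(1.0, 0.1, by = -0.1) else 10^seq(0, -2, by = -0.2)
}

#' Data-efficiency scaling curve
#'
#' For each training fraction, draws that share of training windows (seeded
#' and nested: the windows used at a smaller fraction are a subset of those
#' used at any larger one), invokes the train-and-evaluate callback, and
#' records the resulting metric.
#'
#' @param train A [window_set()] of training windows.
#' @param fractions Fractions in (0, 1], sorted descending.
#' @param callback `function(train_subset, fraction)` returning a scalar
#'   metric; must be deterministic given its inputs and `seed`.
#' @param seed Integer seed for the nested subsampling.
#' @return Tibble of class `grf_scaling_curve` with `fraction`, `n_windows`,
#'   `metric`.
#' @export
scaling_curve <- function(train, fractions, callback, seed = 1L) {
  stopifnot(all(diff(fractions) < 0) || length(fractions) == 1L,
            all(fractions > 0), all(fractions <= 1))
  n <- n_windows(train)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(n)
  rows <- lapply(fractions, function(f) {
    m <- floor(f * n + 1e-9)
    if (m < 1) stop("fraction ", f, " yields zero training windows",
                    call. = FALSE)
    sort(perm[seq_len(m)])
  })
  metric <- vapply(seq_along(fractions), function(i) {
    callback(subset_windows(train, rows[[i]]), fractions[i])
  }, numeric(1))
  out <- tibble::tibble(fraction = fractions,
                        n_windows = vapply(rows, length, 1L),
                        metric = metric)
  class(out) <- c("grf_scaling_curve", class(out))
  out
}

#' Compare model settings across participants
#'
#' One-way ANOVA of the per-participant metric across settings; when the
#' ANOVA is significant at `alpha`, all pairwise paired t-tests are run with
#' Bonferroni correction (raw p times the number of comparisons, capped at 1).
#'
#' @param metrics Numeric matrix, participants x settings (complete), or a
#'   data frame coercible to one.
#' @param alpha Significance level gating the pairwise tests.
#' @return List with `anova_p`, `pairwise` (tibble of setting pairs, raw and
#'   corrected p), and `n_comparisons`.
#' @export
compare_models <- function(metrics, alpha = 0.05) {
  metrics <- as.matrix(metrics)
  if (anyNA(metrics)) stop("metric matrix has missing entries", call. = FALSE)
  if (ncol(metrics) < 2 || nrow(metrics) < 3) {
    stop("need at least 2 settings and 3 participants", call. = FALSE)
  }
  if (is.null(colnames(metrics))) {
    colnames(metrics) <- paste0("setting", seq_len(ncol(metrics)))
  }
  df <- data.frame(
    value = as.vector(metrics),
    setting = factor(rep(colnames(metrics), each = nrow(metrics))))
  an <- stats::anova(stats::aov(value ~ setting, data = df))
  anova_p <- an[["Pr(>F)"]][1]
  if (is.na(anova_p)) anova_p <- 1  # zero between- and within-group variance
  pairs <- utils::combn(colnames(metrics), 2)
  n_comp <- ncol(pairs)
  pairwise <- NULL
  if (anova_p < alpha) {
    pairwise <- purrr::map_dfr(seq_len(n_comp), function(j) {
      a <- metrics[, pairs[1, j]]; b <- metrics[, pairs[2, j]]
      p_raw <- stats::t.test(a, b, paired = TRUE)$p.value
      tibble::tibble(setting_a = pairs[1, j], setting_b = pairs[2, j],
                     p_raw = p_raw, p_corrected = min(1, p_raw * n_comp))
    })
  }
  list(anova_p = anova_p, pairwise = pairwise, n_comparisons = n_comp)
}

#' Per-participant GRF evaluation report
#'
#' Concatenates, per participant, every included (stance/landing) sample of
#' the test windows and computes correlation and RMSE per GRF axis, plus
#' peak-vGRF metrics and the spectrum-error curve.
#'
#' @param est `n` x `L` x 3 array of estimated GRF in N/kg.
#' @param ws The labeled test [window_set()] (gold GRF in N/kg).
#' @param cfg An [eval_config()].
#' @return An object of class `grf_eval_report`: list with `per_axis` (tibble
#'   participant x axis: rho, rmse), `peaks` (tibble per participant),
#'   `spectrum` (tibble), and `config`.
#' @export
evaluate_grf <- function(est, ws, cfg = eval_config()) {
  stopifnot(!is.null(ws$grf))
  L <- ws$window_length
  masks <- t(vapply(seq_len(n_windows(ws)), function(i) {
    phase_mask(ws$grf[i, , 3], cfg$stance_threshold_frac, cfg$g,
               ws$meta$valid_length[i])
  }, logical(L)))
  axes <- c("ml", "ap", "v")
  participants <- unique(ws$meta$participant_id)
  per_axis <- purrr::map_dfr(participants, function(p) {
    wi <- which(ws$meta$participant_id == p)
    inc <- masks[wi, , drop = FALSE]
    purrr::map_dfr(seq_len(3), function(a) {
      e <- as.vector(est[wi, , a][inc])
      g <- as.vector(ws$grf[wi, , a][inc])
      tibble::tibble(participant_id = p, axis = axes[a],
                     rho = pearson_r(e, g), rmse = rmse(e, g),
                     n_samples = length(g))
    })
  })
  peaks <- purrr::map_dfr(participants, function(p) {
    wi <- which(ws$meta$participant_id == p)
    dplyr::mutate(
      peak_vgrf_metrics(est[wi, , 3, drop = TRUE],
                        ws$grf[wi, , 3, drop = TRUE],
                        masks[wi, , drop = FALSE]),
      participant_id = p, .before = 1)
  })
  spectrum <- spectrum_error(est[, , 3, drop = TRUE],
                             ws$grf[, , 3, drop = TRUE])
  structure(list(per_axis = per_axis, peaks = peaks, spectrum = spectrum,
                 config = cfg),
            class = "grf_eval_report")
}

#' @export
print.grf_eval_report <- function(x, ...) {
  cat("<grf_eval_report>\n")
  s <- x$per_axis |>
    dplyr::group_by(.data$axis) |>
    dplyr::summarise(rho = mean(.data$rho), rmse = mean(.data$rmse))
  print(s)
  invisible(x)
}
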