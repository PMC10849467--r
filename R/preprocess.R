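# Data pipeline: overlapping window segmentation, stillness and range-outlier
# exclusion filters, gait-window extraction around stance onsets, zero-padding
# of short trials, linear resampling, and per-axis z-score normalization.

#' Windowing configuration
#'
#' @param window_length Window length in samples (128 = 1.28 s at 100 Hz).
#' @param overlap Overlap fraction between successive windows, in `[0, 1)`.
#' @param stillness_threshold Stillness criterion in m/s^2: a window is
#'   removed when the mean over the 24 accelerometer axes of the per-axis
#'   standard deviation falls below this value.
#' @param acc_max Accelerometer range threshold in m/s^2; any sample strictly
#'   beyond it removes the window.
#' @param gyro_max Gyroscope range threshold in deg/s.
#' @param pre_stance_offset Samples before each stance onset at which a gait
#'   window starts.
#' @return A `windowing_config` list.
#' @export
windowing_config <- function(window_length = 128L, overlap = 0.5,
                             stillness_threshold = 0.2, acc_max = 160,
                             gyro_max = 2000, pre_stance_offset = 40L) {
  stopifnot(overlap >= 0, overlap < 1, stillness_threshold > 0,
            acc_max > 0, gyro_max > 0)
  structure(list(window_length = as.integer(window_length), overlap = overlap,
                 stillness_threshold = stillness_threshold, acc_max = acc_max,
                 gyro_max = gyro_max,
                 pre_stance_offset = as.integer(pre_stance_offset)),
            class = "windowing_config")
}

#' Segment a trial into overlapping windows
#'
#' Windows start at 0, stride, 2*stride, ... (0-based), where
#' `stride = window_length * (1 - overlap)`; with the defaults, starts are
#' 0, 64, 128, ... and the count is `floor((n - 128) / 64) + 1` for
#' `n >= 128`, else 0. Remainder samples at the trial end are discarded. GRF
#' is sliced alongside when present.
#'
#' @param trial An [imu_trial()].
#' @param cfg A [windowing_config()].
#' @return A [window_set()] (possibly empty).
#' @export
segment_windows <- function(trial, cfg = windowing_config()) {
  L <- cfg$window_length
  stride <- as.integer(round(L * (1 - cfg$overlap)))
  n <- nrow(trial$data)
  k <- if (n >= L) (n - L) %/% stride + 1L else 0L
  starts <- if (k > 0) (seq_len(k) - 1L) * stride else integer(0)
  data <- array(0, c(k, L, 48))
  grf <- if (!is.null(trial$grf) && k > 0) array(0, c(k, L, 3))
  for (i in seq_len(k)) {
    rows <- starts[i] + seq_len(L)  # 0-based start -> 1-based rows
    data[i, , ] <- trial$data[rows, ]
    if (!is.null(grf)) grf[i, , ] <- trial$grf[rows, ]
  }
  meta <- tibble::tibble(participant_id = rep(trial$participant_id, k),
                         trial_id = rep(trial$trial_id, k),
                         start = starts, valid_length = rep(L, k))
  window_set(data, meta, grf = grf)
}

window_stat_still <- function(ws) {
  # mean over the 24 accelerometer axes of the per-axis (sample) SD, padded
  # rows excluded
  acc <- acc_columns()
  vapply(seq_len(n_windows(ws)), function(i) {
    v <- ws$meta$valid_length[i]
    mean(apply(ws$data[i, seq_len(v), acc, drop = FALSE], 3, stats::sd))
  }, numeric(1))
}

#' Remove still windows
#'
#' Retains windows whose stillness statistic (mean per-axis accelerometer
#' standard deviation) is at or above `threshold`; reports the removed count
#' as attribute `n_removed`.
#'
#' @param ws A [window_set()].
#' @param threshold Stillness threshold in m/s^2.
#' @return Filtered `window_set` with attribute `n_removed`.
#' @export
filter_still <- function(ws, threshold = 0.2) {
  if (n_windows(ws) == 0L) return(ws)
  keep <- window_stat_still(ws) >= threshold
  out <- subset_windows(ws, which(keep))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Remove range-outlier windows
#'
#' Removes any window containing an accelerometer sample with
#' `|acc| > acc_max` or a gyroscope sample with `|gyr| > gyro_max` (strict
#' comparisons: values exactly at the threshold are retained). Thresholds
#' default to the measurement ranges of typical IMUs.
#'
#' @param ws A [window_set()].
#' @param acc_max Accelerometer bound in m/s^2.
#' @param gyro_max Gyroscope bound in deg/s.
#' @return Filtered `window_set` with attribute `n_removed`.
#' @export
filter_outliers <- function(ws, acc_max = 160, gyro_max = 2000) {
  if (n_windows(ws) == 0L) return(ws)
  acc <- acc_columns(); gyr <- gyr_columns()
  keep <- vapply(seq_len(n_windows(ws)), function(i) {
    w <- ws$data[i, , ]
    max(abs(w[, acc])) <= acc_max && max(abs(w[, gyr])) <= gyro_max
  }, logical(1))
  out <- subset_windows(ws, which(keep))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Extract gait windows around stance onsets
#'
#' One window per stance onset `s`, starting at `max(0, s - pre_stance_offset)`
#' (0-based); windows overrunning the trial end are dropped.
#'
#' @param trial An [imu_trial()] with non-empty `stance_onsets`.
#' @param cfg A [windowing_config()].
#' @return A [window_set()].
#' @export
extract_gait_windows <- function(trial, cfg = windowing_config()) {
  if (is.null(trial$stance_onsets) || length(trial$stance_onsets) == 0L) {
    stop("trial has no stance-onset annotations", call. = FALSE)
  }
  L <- cfg$window_length
  n <- nrow(trial$data)
  starts <- pmax(0L, trial$stance_onsets - cfg$pre_stance_offset)
  starts <- starts[starts + L <= n]
  k <- length(starts)
  data <- array(0, c(k, L, 48))
  grf <- if (!is.null(trial$grf) && k > 0) array(0, c(k, L, 3))
  for (i in seq_len(k)) {
    rows <- starts[i] + seq_len(L)
    data[i, , ] <- trial$data[rows, ]
    if (!is.null(grf)) grf[i, , ] <- trial$grf[rows, ]
  }
  meta <- tibble::tibble(participant_id = rep(trial$participant_id, k),
                         trial_id = rep(trial$trial_id, k),
                         start = starts, valid_length = rep(L, k))
  window_set(data, meta, grf = grf)
}

#' Zero-pad a short trial to one window
#'
#' Appends all-zero rows so a trial of at most `target` steps fills one
#' window; `valid_length` records the original step count (e.g. 0.8 s
#' drop-landing trials of 80 steps padded to 128).
#'
#' @param trial An [imu_trial()] with `n_steps <= target`.
#' @param target Window length.
#' @return A single-window [window_set()].
#' @export
pad_trial_to_window <- function(trial, target = 128L) {
  n <- nrow(trial$data)
  if (n > target) {
    stop("trial has ", n, " steps, longer than the window length ", target,
         call. = FALSE)
  }
  data <- array(0, c(1L, target, 48))
  data[1, seq_len(n), ] <- trial$data
  grf <- NULL
  if (!is.null(trial$grf)) {
    grf <- array(0, c(1L, target, 3))
    grf[1, seq_len(n), ] <- trial$grf
  }
  meta <- tibble::tibble(participant_id = trial$participant_id,
                         trial_id = trial$trial_id, start = 0L,
                         valid_length = n)
  window_set(data, meta, grf = grf)
}

#' Linearly resample a trial
#'
#' Linear interpolation of IMU (and GRF) channels onto a uniform grid at
#' `fs_out`; duration is preserved within one output sample. Stance onsets are
#' remapped to the nearest output sample.
#'
#' @param trial An [imu_trial()].
#' @param fs_out Output sampling rate in Hz (at most the input rate).
#' @return An [imu_trial()] at `fs_out`.
#' @export
resample_trial <- function(trial, fs_out = 100) {
  fs_in <- trial$sampling_rate
  stopifnot(fs_out <= fs_in)
  n <- nrow(trial$data)
  if (abs(fs_out - fs_in) < 1e-12) return(trial)
  t_in <- (seq_len(n) - 1) / fs_in
  t_out <- seq(0, floor(t_in[n] * fs_out + 1e-9) / fs_out, by = 1 / fs_out)
  interp <- function(M) apply(M, 2, function(col) {
    stats::approx(t_in, col, xout = t_out)$y
  })
  data <- interp(trial$data)
  colnames(data) <- imu_axis_names()
  grf <- if (!is.null(trial$grf)) {
    g <- interp(trial$grf); colnames(g) <- c("ml", "ap", "v"); g
  }
  onsets <- if (!is.null(trial$stance_onsets)) {
    o <- unique(pmin(length(t_out) - 1L,
                     as.integer(round(trial$stance_onsets / fs_in * fs_out))))
    sort(o)
  }
  imu_trial(data, sampling_rate = fs_out, participant_id = trial$participant_id,
            trial_id = trial$trial_id, grf = grf, stance_onsets = onsets)
}

#' Fit per-axis normalization statistics
#'
#' Mean and standard deviation per IMU axis (and per GRF axis when labels are
#' present), pooled over all valid (non-padded) rows of the training windows.
#' Standard deviations below `eps` are clamped to `eps` so z-scoring stays
#' finite on constant axes.
#'
#' @param train A [window_set()] of training windows.
#' @param eps Standard-deviation clamp.
#' @return A `normalization_stats` list.
#' @export
fit_normalizer <- function(train, eps = 1e-8) {
  stopifnot(n_windows(train) > 0L)
  rows <- valid_row_matrix(train)  # n x L logical
  X <- flatten_valid(train$data, rows)   # (sum valid) x 48
  imu_mean <- colMeans(X)
  imu_sd <- pmax(apply(X, 2, stats::sd), eps)
  grf_mean <- grf_sd <- NULL
  if (!is.null(train$grf)) {
    G <- flatten_valid(train$grf, rows)
    grf_mean <- colMeans(G)
    grf_sd <- pmax(apply(G, 2, stats::sd), eps)
  }
  structure(list(imu_mean = imu_mean, imu_sd = imu_sd,
                 grf_mean = grf_mean, grf_sd = grf_sd, eps = eps),
            class = "normalization_stats")
}

valid_row_matrix <- function(ws) {
  L <- ws$window_length
  outer(ws$meta$valid_length, seq_len(L), function(v, r) r <= v)
}

flatten_valid <- function(arr, rows) {
  d <- dim(arr)
  out <- matrix(0, sum(rows), d[3])
  at <- 0L
  for (i in seq_len(d[1])) {
    v <- sum(rows[i, ])
    out[at + seq_len(v), ] <- arr[i, seq_len(v), ]
    at <- at + v
  }
  out
}

#' Apply (or invert) z-score normalization
#'
#' Transforms each IMU axis (and GRF axis when both labels and GRF statistics
#' are present) to zero mean and unit variance, or inverts the transform.
#' Padded rows beyond `valid_length` are left exactly zero.
#'
#' @param ws A [window_set()].
#' @param stats A [fit_normalizer()] result.
#' @param invert If TRUE, undo the normalization.
#' @return A transformed `window_set`.
#' @export
apply_normalizer <- function(ws, stats, invert = FALSE) {
  L <- ws$window_length
  data <- ws$data
  grf <- ws$grf
  transform_axis <- function(slice, m, s) {
    if (invert) slice * s + m else (slice - m) / s
  }
  for (a in seq_len(48)) {
    data[, , a] <- transform_axis(data[, , a], stats$imu_mean[a], stats$imu_sd[a])
  }
  if (!is.null(grf) && !is.null(stats$grf_mean)) {
    for (a in seq_len(3)) {
      grf[, , a] <- transform_axis(grf[, , a], stats$grf_mean[a], stats$grf_sd[a])
    }
  }
  # keep padded rows exactly zero
  short <- which(ws$meta$valid_length < L)
  for (i in short) {
    pad <- (ws$meta$valid_length[i] + 1L):L
    data[i, pad, ] <- 0
    if (!is.null(grf)) grf[i, pad, ] <- 0
  }
  window_set(data, ws$meta, grf = grf)
}
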