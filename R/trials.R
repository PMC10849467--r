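# Trial and window containers. A trial is a contiguous recording from one
# participant; a window is a fixed-length 128-sample block of the 48-axis IMU
# matrix, optionally with 3-axis GRF labels. Sample indices in window metadata
# are 0-based with half-open spans [start, start + 128), matching the
# windowing arithmetic used throughout.

#' Construct an IMU trial
#'
#' @param data Numeric matrix, `n_steps` x 48, columns in [imu_axis_names()]
#'   order (accelerometer m/s^2, gyroscope deg/s).
#' @param sampling_rate Sampling rate in Hz.
#' @param participant_id Participant identifier.
#' @param trial_id Trial identifier.
#' @param grf Optional `n_steps` x 3 matrix of ground reaction force in N/kg,
#'   columns medial-lateral, anterior-posterior, vertical.
#' @param stance_onsets Optional integer vector of 0-based sample indices of
#'   stance onsets, strictly increasing, within `[0, n_steps)`.
#' @return An object of class `imu_trial`.
#' @export
imu_trial <- function(data, sampling_rate, participant_id,
                      trial_id = "trial", grf = NULL, stance_onsets = NULL) {
  data <- as.matrix(data)
  if (ncol(data) != 48L) {
    stop("IMU data must have exactly 48 columns, got ", ncol(data),
         call. = FALSE)
  }
  if (!is.null(grf)) {
    grf <- as.matrix(grf)
    if (ncol(grf) != 3L) stop("GRF must have 3 columns (ml, ap, v)", call. = FALSE)
    if (nrow(grf) != nrow(data)) {
      stop("GRF must have the same number of steps as the IMU data",
           call. = FALSE)
    }
  }
  if (!is.null(stance_onsets)) {
    stance_onsets <- as.integer(stance_onsets)
    if (length(stance_onsets) &&
        (any(diff(stance_onsets) <= 0L) ||
         any(stance_onsets < 0L) || any(stance_onsets >= nrow(data)))) {
      stop("stance_onsets must be strictly increasing indices in [0, n_steps)",
           call. = FALSE)
    }
  }
  structure(
    list(data = data, grf = grf, stance_onsets = stance_onsets,
         sampling_rate = sampling_rate,
         participant_id = as.character(participant_id),
         trial_id = as.character(trial_id)),
    class = "imu_trial"
  )
}

#' @export
print.imu_trial <- function(x, ...) {
  cat(sprintf("<imu_trial> %s/%s: %d steps @ %g Hz%s%s\n",
              x$participant_id, x$trial_id, nrow(x$data), x$sampling_rate,
              if (!is.null(x$grf)) ", with GRF" else "",
              if (!is.null(x$stance_onsets))
                sprintf(", %d stance onsets", length(x$stance_onsets)) else ""))
  invisible(x)
}

#' Construct a kinematics trial
#'
#' Per-segment global position and orientation over time, the input to
#' synthetic IMU generation.
#'
#' @param positions Named list (one entry per segment) of `n_steps` x 3
#'   matrices of global positions in metres.
#' @param orientations Named list (same segments) of `n_steps` x 4 matrices of
#'   unit quaternions (w, x, y, z) mapping segment-frame vectors to the global
#'   frame.
#' @param sampling_rate Sampling rate in Hz.
#' @param participant_id Participant identifier.
#' @param trial_id Trial identifier.
#' @return An object of class `kinematics_trial`.
#' @export
kinematics_trial <- function(positions, orientations, sampling_rate,
                             participant_id, trial_id = "trial") {
  if (!identical(names(positions), names(orientations))) {
    stop("positions and orientations must cover the same segments",
         call. = FALSE)
  }
  n <- unique(c(vapply(positions, nrow, 1L), vapply(orientations, nrow, 1L)))
  if (length(n) != 1L) {
    stop("all segments must share the same number of steps", call. = FALSE)
  }
  for (seg in names(orientations)) {
    q <- orientations[[seg]]
    if (ncol(q) != 4L) stop("orientations must be n x 4 quaternions", call. = FALSE)
    norms <- sqrt(rowSums(q^2))
    if (any(abs(norms - 1) > 1e-6)) {
      stop("orientations for segment '", seg,
           "' are not unit quaternions (tolerance 1e-6)", call. = FALSE)
    }
  }
  structure(
    list(positions = positions, orientations = orientations,
         sampling_rate = sampling_rate, n_steps = n,
         participant_id = as.character(participant_id),
         trial_id = as.character(trial_id)),
    class = "kinematics_trial"
  )
}

#' @export
print.kinematics_trial <- function(x, ...) {
  cat(sprintf("<kinematics_trial> %s/%s: %d segments, %d steps @ %g Hz\n",
              x$participant_id, x$trial_id, length(x$positions), x$n_steps,
              x$sampling_rate))
  invisible(x)
}

#' Construct a window set
#'
#' Fixed-length windows of the 48-axis IMU matrix with provenance metadata and
#' optional GRF labels. Rows beyond a window's `valid_length` are exactly zero
#' in both data and GRF (zero-padded short trials).
#'
#' @param data 3-D array `n_windows` x `window_length` x 48.
#' @param meta Tibble with one row per window: `participant_id`, `trial_id`,
#'   `start` (0-based sample index in the source trial), `valid_length`.
#' @param grf Optional 3-D array `n_windows` x `window_length` x 3.
#' @return An object of class `window_set`.
#' @export
window_set <- function(data, meta, grf = NULL) {
  stopifnot(length(dim(data)) == 3L, dim(data)[3] == 48L)
  meta <- tibble::as_tibble(meta)
  if (nrow(meta) != dim(data)[1]) {
    stop("meta must have one row per window", call. = FALSE)
  }
  if (!all(c("participant_id", "trial_id", "start", "valid_length") %in%
           names(meta))) {
    stop("meta must have columns participant_id, trial_id, start, valid_length",
         call. = FALSE)
  }
  if (!is.null(grf)) {
    stopifnot(length(dim(grf)) == 3L, dim(grf)[3] == 3L,
              dim(grf)[1] == dim(data)[1], dim(grf)[2] == dim(data)[2])
  }
  structure(list(data = data, grf = grf, meta = meta,
                 window_length = dim(data)[2]),
            class = "window_set")
}

#' Number of windows in a window set
#' @param ws A `window_set`.
#' @return Integer count.
#' @export
n_windows <- function(ws) dim(ws$data)[1]

#' Subset a window set by window index
#'
#' @param ws A `window_set`.
#' @param idx Integer indices of windows to keep.
#' @return A `window_set` with the selected windows.
#' @export
subset_windows <- function(ws, idx) {
  window_set(ws$data[idx, , , drop = FALSE], ws$meta[idx, , drop = FALSE],
             grf = if (!is.null(ws$grf)) ws$grf[idx, , , drop = FALSE])
}

#' Concatenate window sets
#' @param ... `window_set` objects with matching window length and label
#'   presence.
#' @return A combined `window_set`.
#' @export
bind_windows <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L)
  has_grf <- vapply(sets, function(s) !is.null(s$grf), logical(1))
  if (!all(has_grf) && any(has_grf)) {
    stop("cannot bind labeled and unlabeled window sets", call. = FALSE)
  }
  L <- sets[[1]]$window_length
  n <- sum(vapply(sets, n_windows, 1L))
  data <- array(0, c(n, L, 48))
  grf <- if (all(has_grf)) array(0, c(n, L, 3))
  at <- 0L
  for (s in sets) {
    k <- n_windows(s)
    if (k > 0) {
      data[at + seq_len(k), , ] <- s$data
      if (!is.null(grf)) grf[at + seq_len(k), , ] <- s$grf
    }
    at <- at + k
  }
  window_set(data, dplyr::bind_rows(lapply(sets, `[[`, "meta")), grf = grf)
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d x 48%s, %d participants\n",
              n_windows(x), x$window_length,
              if (!is.null(x$grf)) " (labeled)" else "",
              length(unique(x$meta$participant_id))))
  invisible(x)
}

#' Extract one window as a matrix
#' @param ws A `window_set`.
#' @param i Window index (1-based).
#' @return List with `data` (L x 48), `grf` (L x 3 or NULL), and the meta row.
#' @export
get_window <- function(ws, i) {
  list(data = ws$data[i, , ],
       grf = if (!is.null(ws$grf)) ws$grf[i, , ],
       meta = ws$meta[i, ])
}
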