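# File I/O: trial CSVs with YAML sidecars, the window store, and model
# checkpoints. CSV schemas:
#   IMU trial:        time_s, <acc|gyr>_<x|y|z>_<sensor> (48 columns),
#                     optional grf_ml, grf_ap, grf_v, optional stance_onset
#                     (0/1 marker column)
#   kinematics trial: time_s, pos_<x|y|z>_<segment>, quat_<w|x|y|z>_<segment>
# Each trial CSV has a sidecar YAML (<name>.yaml) holding participant_id,
# sampling_rate and optionally body_mass_kg.

read_sidecar <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.csv$", ".yaml", path)
  if (!file.exists(sidecar)) {
    stop("sidecar YAML not found: ", sidecar, call. = FALSE)
  }
  yaml::read_yaml(sidecar)
}

#' Read an IMU trial from CSV
#'
#' Reads a trial CSV (see the package schema) plus its YAML sidecar. Column
#' order in the returned trial always matches [imu_axis_names()], whatever the
#' order in the file.
#'
#' @param path Path to the trial CSV.
#' @param sidecar Optional path to the sidecar YAML; defaults to the CSV path
#'   with extension `.yaml`.
#' @return An [imu_trial()].
#' @export
read_imu_trial <- function(path, sidecar = NULL) {
  side <- read_sidecar(path, sidecar)
  df <- utils::read.csv(path, check.names = FALSE)
  required <- c("time_s", imu_axis_names())
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("trial CSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  allowed <- c(required, "grf_ml", "grf_ap", "grf_v", "stance_onset")
  extra <- setdiff(names(df), allowed)
  if (length(extra)) {
    stop("trial CSV has unrecognized column(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) >= 2 && any(diff(df$time_s) <= 0)) {
    stop("timestamps in time_s must be strictly increasing", call. = FALSE)
  }
  grf_cols <- c("grf_ml", "grf_ap", "grf_v")
  grf <- NULL
  if (any(grf_cols %in% names(df))) {
    if (!all(grf_cols %in% names(df))) {
      stop("GRF columns must be all present or all absent (grf_ml, grf_ap, grf_v)",
           call. = FALSE)
    }
    grf <- as.matrix(df[, grf_cols])
    colnames(grf) <- c("ml", "ap", "v")
  }
  onsets <- NULL
  if ("stance_onset" %in% names(df)) {
    onsets <- which(df$stance_onset != 0) - 1L  # 0-based indices
  }
  data <- as.matrix(df[, imu_axis_names()])
  imu_trial(data, sampling_rate = side$sampling_rate,
            participant_id = side$participant_id,
            trial_id = tools::file_path_sans_ext(basename(path)),
            grf = grf, stance_onsets = onsets)
}

#' Write an IMU trial to CSV with its YAML sidecar
#'
#' @param trial An [imu_trial()].
#' @param path Output CSV path; the sidecar is written next to it.
#' @param body_mass_kg Optional body mass recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_imu_trial <- function(trial, path, body_mass_kg = NULL) {
  n <- nrow(trial$data)
  df <- data.frame(time_s = (seq_len(n) - 1) / trial$sampling_rate)
  imu <- as.data.frame(trial$data)
  names(imu) <- imu_axis_names()
  df <- cbind(df, imu)
  if (!is.null(trial$grf)) {
    df$grf_ml <- trial$grf[, 1]; df$grf_ap <- trial$grf[, 2]
    df$grf_v <- trial$grf[, 3]
  }
  if (!is.null(trial$stance_onsets)) {
    m <- integer(n); m[trial$stance_onsets + 1L] <- 1L
    df$stance_onset <- m
  }
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(participant_id = trial$participant_id,
               sampling_rate = trial$sampling_rate)
  if (!is.null(body_mass_kg)) side$body_mass_kg <- body_mass_kg
  yaml::write_yaml(side, sub("\\.csv$", ".yaml", path))
  invisible(path)
}

#' Read a kinematics trial from CSV
#'
#' @param path Path to the kinematics CSV (`time_s`, `pos_<x|y|z>_<segment>`,
#'   `quat_<w|x|y|z>_<segment>`).
#' @param sidecar Optional sidecar YAML path.
#' @return A [kinematics_trial()].
#' @export
read_kinematics_trial <- function(path, sidecar = NULL) {
  side <- read_sidecar(path, sidecar)
  df <- utils::read.csv(path, check.names = FALSE)
  pos_cols <- grep("^pos_[xyz]_", names(df), value = TRUE)
  segs <- unique(sub("^pos_[xyz]_", "", pos_cols))
  positions <- list(); orientations <- list()
  for (seg in segs) {
    pc <- paste0("pos_", c("x", "y", "z"), "_", seg)
    qc <- paste0("quat_", c("w", "x", "y", "z"), "_", seg)
    if (!all(c(pc, qc) %in% names(df))) {
      stop("kinematics CSV is missing columns for segment '", seg, "'",
           call. = FALSE)
    }
    positions[[seg]] <- as.matrix(df[, pc])
    orientations[[seg]] <- as.matrix(df[, qc])
  }
  kinematics_trial(positions, orientations,
                   sampling_rate = side$sampling_rate,
                   participant_id = side$participant_id,
                   trial_id = tools::file_path_sans_ext(basename(path)))
}

#' Write a kinematics trial to CSV with its YAML sidecar
#'
#' @param trial A [kinematics_trial()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kinematics_trial <- function(trial, path) {
  n <- trial$n_steps
  df <- data.frame(time_s = (seq_len(n) - 1) / trial$sampling_rate)
  for (seg in names(trial$positions)) {
    p <- trial$positions[[seg]]; q <- trial$orientations[[seg]]
    df[paste0("pos_", c("x", "y", "z"), "_", seg)] <- p
    df[paste0("quat_", c("w", "x", "y", "z"), "_", seg)] <- q
  }
  utils::write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(list(participant_id = trial$participant_id,
                        sampling_rate = trial$sampling_rate),
                   sub("\\.csv$", ".yaml", path))
  invisible(path)
}

#' Write / read a window store
#'
#' Single-file container for a [window_set()]; the round trip is bit-exact for
#' all matrices and metadata.
#'
#' @param ws A non-empty `window_set`.
#' @param path Store path (`.rds`).
#' @return `read_window_store()` returns the `window_set`;
#'   `write_window_store()` returns `path` invisibly.
#' @export
write_window_store <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  if (n_windows(ws) == 0L) stop("refusing to write an empty window set",
                                call. = FALSE)
  saveRDS(list(format = "grfimu_window_store", version = 1L, windows = ws),
          path)
  invisible(path)
}

#' @rdname write_window_store
#' @export
read_window_store <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt or unreadable window store: ", path, call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, "grfimu_window_store")) {
    stop("not a grfimu window store: ", path, call. = FALSE)
  }
  obj$windows
}

#' Save / load a model checkpoint
#'
#' A checkpoint bundles the trainable weights, the architecture configuration
#' that produced them, the normalization statistics in force, and a format
#' version tag. Loading verifies the format and, when an expected
#' configuration is supplied, refuses to load on any architecture mismatch.
#'
#' @param state A `model_state` (see [init_model()]).
#' @param path Checkpoint path (`.rds`).
#' @param stats Optional [fit_normalizer()] statistics stored alongside.
#' @param expected_config Optional `model_config`; loading fails if the stored
#'   architecture differs.
#' @return `load_checkpoint()` returns a list with `state` and `stats`.
#' @export
save_checkpoint <- function(state, path, stats = NULL) {
  stopifnot(inherits(state, "model_state"))
  saveRDS(list(format = "grfimu_checkpoint", version = 1L,
               state = state, stats = stats), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, expected_config = NULL) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt or unreadable checkpoint: ", path, call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, "grfimu_checkpoint")) {
    stop("not a grfimu checkpoint: ", path, call. = FALSE)
  }
  if (!is.null(expected_config)) {
    arch <- c("patch_length", "embed_dim", "n_blocks", "n_heads", "ff_dim",
              "n_axes", "window_length")
    got <- obj$state$config[arch]; want <- expected_config[arch]
    if (!identical(got, want)) {
      stop("checkpoint architecture does not match the expected configuration",
           call. = FALSE)
    }
  }
  list(state = obj$state, stats = obj$stats)
}
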