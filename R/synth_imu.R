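# Synthetic IMU generation from segment kinematics: zero-lag Butterworth
# low-pass + resampling of the kinematics, random mounting perturbations, and
# differentiation of positions/orientations into sensor-frame accelerometer
# and gyroscope signals with gravity added.

#' Gravity convention
#'
#' The global-frame gravity vector added to kinematic accelerations before
#' rotation into the sensor frame, so a static upright sensor reads +9.81
#' m/s^2 on its gravity-aligned axis (a real accelerometer at rest measures
#' the reaction to gravity).
#'
#' @param vector Gravity vector in the global frame, m/s^2. Default z-up
#'   convention `(0, 0, 9.81)`.
#' @return An object of class `gravity_convention`.
#' @export
gravity_convention <- function(vector = c(0, 0, 9.81)) {
  if (abs(sqrt(sum(vector^2)) - 9.81) > 1e-6) {
    stop("gravity magnitude must equal 9.81 m/s^2", call. = FALSE)
  }
  structure(list(vector = vector, sign = "reaction_positive"),
            class = "gravity_convention")
}

#' Low-pass filter and resample a kinematics trial
#'
#' Zero-lag (forward-backward) fourth-order Butterworth filtering of segment
#' positions and quaternion components, then linear resampling onto a uniform
#' grid at `fs_out`. Quaternions are re-normalized after filtering and
#' interpolation.
#'
#' @param trial A [kinematics_trial()].
#' @param cutoff Low-pass cutoff in Hz.
#' @param order Butterworth order (the zero-lag pass squares its magnitude
#'   response).
#' @param fs_out Output sampling rate in Hz.
#' @return A [kinematics_trial()] at `fs_out`.
#' @export
lowpass_resample <- function(trial, cutoff = 15, order = 4, fs_out = 100) {
  fs_in <- trial$sampling_rate
  if (fs_in < 2 * cutoff) {
    stop("trial sampling rate must be at least twice the cutoff", call. = FALSE)
  }
  n <- trial$n_steps
  if (n <= 3 * order) {
    stop("trial too short for stable zero-lag filtering (need n > 3 * order)",
         call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (fs_in / 2), type = "low")
  # odd-reflection padding absorbs the filter's startup transient so the
  # forward-backward pass is transient-free at the trial boundaries
  pad <- n - 1L
  filt_cols <- function(M) apply(M, 2, function(col) {
    front <- 2 * col[1] - col[(pad + 1):2]
    back <- 2 * col[n] - col[(n - 1):(n - pad)]
    y <- as.numeric(signal::filtfilt(bf, c(front, col, back)))
    y[(pad + 1):(pad + n)]
  })
  t_in <- (seq_len(n) - 1) / fs_in
  t_out <- seq(0, floor(t_in[n] * fs_out + 1e-9) / fs_out, by = 1 / fs_out)
  interp_cols <- function(M) apply(M, 2, function(col) {
    stats::approx(t_in, col, xout = t_out)$y
  })
  positions <- lapply(trial$positions, function(P) interp_cols(filt_cols(P)))
  orientations <- lapply(trial$orientations, function(Q) {
    Qf <- interp_cols(filt_cols(Q))
    Qf / sqrt(rowSums(Qf^2))
  })
  kinematics_trial(positions, orientations, sampling_rate = fs_out,
                   participant_id = trial$participant_id,
                   trial_id = trial$trial_id)
}

#' Sample random mounting perturbations
#'
#' Draws `n_variants` mounting perturbations, each rotating every sensor by
#' three independent angles uniform in `[-max_deg, +max_deg]` about the sensor
#' x, y and z axes (composed intrinsically x then y then z).
#'
#' @param layout A [sensor_layout()].
#' @param n_variants Number of perturbations to draw.
#' @param max_deg Angle bound in degrees.
#' @param seed Integer seed; draws are reproducible for a fixed seed.
#' @return List of `mounting_perturbation` objects, each a named list of
#'   angle triplets (deg) plus the seed used.
#' @export
sample_perturbations <- function(layout, n_variants = 5, max_deg = 10,
                                 seed = 1L) {
  stopifnot(n_variants >= 1)
  validate_layout(layout)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(n_variants), function(v) {
    angles <- lapply(layout$sensor_names, function(s) {
      stats::runif(3, -max_deg, max_deg)
    })
    names(angles) <- layout$sensor_names
    structure(list(angles = angles, max_deg = max_deg, seed = seed,
                   variant = v),
              class = "mounting_perturbation")
  })
}

#' Identity (zero-angle) perturbation
#' @param layout A [sensor_layout()].
#' @return A `mounting_perturbation` with all angles zero.
#' @export
zero_perturbation <- function(layout) {
  angles <- stats::setNames(
    replicate(8, c(0, 0, 0), simplify = FALSE), layout$sensor_names)
  structure(list(angles = angles, max_deg = 0, seed = NA_integer_, variant = 1L),
            class = "mounting_perturbation")
}

#' Perturbation from explicit rotation matrices
#'
#' Wraps per-sensor rotation matrices as a `mounting_perturbation`, e.g. to
#' compose a perturbation with its inverse.
#'
#' @param rotations Named list of 3x3 rotation matrices, one per sensor.
#' @return A `mounting_perturbation`.
#' @export
matrix_perturbation <- function(rotations) {
  structure(list(rotations = rotations, seed = NA_integer_, variant = 1L),
            class = "mounting_perturbation")
}

#' Per-sensor perturbation rotation matrix
#' @keywords internal
perturbation_rotation <- function(perturbation, sensor) {
  if (!is.null(perturbation$rotations)) {
    perturbation$rotations[[sensor]]
  } else {
    rot_xyz_intrinsic(perturbation$angles[[sensor]])
  }
}

# Save/restore the global RNG state so seeded helpers do not disturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Synthesize IMU signals from segment kinematics
#'
#' Computes, per sensor: angular velocity as the symmetric finite difference
#' of sensor orientation expressed in the sensor frame (via the rotation log
#' map of `R(t-1)' R(t+1)` divided by `2*dt`, converted to deg/s), and
#' acceleration as the central second difference of sensor position plus
#' gravity, rotated into the sensor frame (m/s^2). Endpoint samples copy
#' their nearest interior value.
#'
#' @param trial A [kinematics_trial()] at 100 Hz (or the model sampling rate).
#' @param layout A [sensor_layout()]; segment attachment maps each sensor to a
#'   kinematics segment.
#' @param perturbation A `mounting_perturbation` (default: zero angles).
#' @param gravity A [gravity_convention()]. Pass a zero-magnitude convention
#'   only via `add_gravity = FALSE`.
#' @param add_gravity If FALSE, gravity is omitted (used by equivariance
#'   checks).
#' @return An [imu_trial()] with 48 columns in canonical order.
#' @export
synthesize_imu <- function(trial, layout, perturbation = zero_perturbation(layout),
                           gravity = gravity_convention(), add_gravity = TRUE) {
  validate_layout(layout)
  n <- trial$n_steps
  if (n < 3L) stop("kinematics trial must have at least 3 steps", call. = FALSE)
  dt <- 1 / trial$sampling_rate
  g <- if (add_gravity) gravity$vector else c(0, 0, 0)
  out <- matrix(0, n, 48)
  for (s in layout$sensor_names) {
    seg <- layout$segments[[s]]
    P <- trial$positions[[seg]]
    Q <- trial$orientations[[seg]]
    if (is.null(P)) stop("kinematics trial lacks segment '", seg, "'",
                         call. = FALSE)
    # sensor orientation: segment-to-global composed with (segment->sensor
    # mounting)^-1 and the intrinsic perturbation about sensor axes
    R_mount <- t(layout$mountings[[s]]) %*% perturbation_rotation(perturbation, s)
    Rs <- lapply(seq_len(n), function(t) quat_to_mat(Q[t, ]) %*% R_mount)
    acc <- matrix(0, n, 3); gyr <- matrix(0, n, 3)
    for (t in 2:(n - 1)) {
      a_global <- (P[t + 1, ] - 2 * P[t, ] + P[t - 1, ]) / dt^2 + g
      acc[t, ] <- crossprod(Rs[[t]], a_global)
      R_rel <- crossprod(Rs[[t - 1]], Rs[[t + 1]])
      gyr[t, ] <- rotmat_to_rotvec(R_rel) / (2 * dt) * 180 / pi
    }
    acc[1, ] <- acc[2, ]; acc[n, ] <- acc[n - 1, ]
    gyr[1, ] <- gyr[2, ]; gyr[n, ] <- gyr[n - 1, ]
    out[, sensor_columns(s)] <- cbind(acc, gyr)
  }
  colnames(out) <- imu_axis_names()
  imu_trial(out, sampling_rate = trial$sampling_rate,
            participant_id = trial$participant_id, trial_id = trial$trial_id)
}
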