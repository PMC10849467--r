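# Synthetic fixtures: multi-participant gait-like and drop-landing
# kinematics with ground-truth GRF generated from the same internal phase
# variable, so the IMU-to-GRF mapping is learnable by construction. These
# stand in for large motion-capture corpora and force-plate datasets in
# every test and example; biomechanical fidelity is a non-goal.

#' Fixture generator configuration
#'
#' @param n_participants Number of participants.
#' @param duration_s Trial duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param cadence_range Cadence range in steps/min (both legs); stride
#'   frequency per leg is cadence / 120 Hz.
#' @param amp_variation Relative participant-to-participant variation of
#'   joint-motion and GRF amplitudes.
#' @param stride_var Stride-to-stride variability: depth of the slow
#'   (< 0.3 Hz) modulation of movement amplitude and stride timing within a
#'   trial, shared between kinematics and GRF. Real gait is not perfectly
#'   periodic; without this, every window of a participant is a near-copy
#'   and a handful of labeled windows suffices to learn the whole trial.
#' @param peak_vgrf_factor Target peak vertical GRF in multiples of body
#'   weight (9.81 N/kg).
#' @param noise_acc,noise_gyro Gaussian sensor-noise SD added to synthetic
#'   accelerometer (m/s^2) and gyroscope (deg/s) channels by [make_corpus()].
#' @param stillness_fraction Fraction of the trial held still (split between
#'   the start and end) to exercise the stillness filter.
#' @param n_variants Mounting-perturbation variants per trial.
#' @param seed Mandatory integer seed.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_participants = 6L, duration_s = 60,
                           fs = 100, cadence_range = c(105, 135),
                           amp_variation = 0.15, stride_var = 0.12,
                           peak_vgrf_factor = 1.2,
                           noise_acc = 0.05, noise_gyro = 0.5,
                           stillness_fraction = 0, n_variants = 1L,
                           seed = 1L) {
  stopifnot(!is.null(seed), stillness_fraction >= 0, stillness_fraction < 1)
  structure(list(n_participants = as.integer(n_participants),
                 duration_s = duration_s, fs = fs,
                 cadence_range = cadence_range,
                 amp_variation = amp_variation, stride_var = stride_var,
                 peak_vgrf_factor = peak_vgrf_factor,
                 noise_acc = noise_acc, noise_gyro = noise_gyro,
                 stillness_fraction = stillness_fraction,
                 n_variants = as.integer(n_variants),
                 seed = as.integer(seed)),
            class = "fixture_config")
}

smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

# activity envelope: exactly 0 in the stillness pads, exactly 1 in the
# middle, smooth 0.5 s ramps just inside the active region
activity_envelope <- function(t, duration, stillness_fraction, ramp = 0.5) {
  pad <- stillness_fraction / 2 * duration
  up <- smoothstep((t - pad) / ramp)
  down <- smoothstep((duration - pad - t) / ramp)
  pmin(up, down)
}

quat_about_y <- function(theta) cbind(cos(theta / 2), 0, sin(theta / 2), 0)
quat_about_x <- function(theta) cbind(cos(theta / 2), sin(theta / 2), 0, 0)

# double-peaked stance vGRF profile on stance progress u in [0, 1]
stance_shape <- function(u) sin(pi * u) * (1 + 0.3 * cos(2 * pi * u))
stance_shape_max <- function() max(stance_shape(seq(0, 1, by = 1e-4)))

#' Generate gait-like kinematics trials
#'
#' One trial per participant: an 8-segment rigid-body configuration with
#' periodic, participant-specific joint trajectories (sinusoid mixtures at
#' the stride frequency and its first harmonics, band-limited well below
#' 6 Hz), optional still pads at the trial boundaries, and a recorded
#' internal gait phase from which [generate_grf()] derives ground truth.
#'
#' @param cfg A [fixture_config()].
#' @return List of [kinematics_trial()] objects, each carrying attributes
#'   `gait_phase_r` (right-leg stride phase, radians), `env` (activity
#'   envelope) and `grf_gain` used by the GRF generator.
#' @export
generate_gait_kinematics <- function(cfg) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  segs <- sensor_names()
  base_pos <- list(trunk = c(0, 0, 1.30), pelvis = c(0, 0, 1.00),
                   l_thigh = c(0, 0.10, 0.80), r_thigh = c(0, -0.10, 0.80),
                   l_shank = c(0, 0.10, 0.45), r_shank = c(0, -0.10, 0.45),
                   l_foot = c(0, 0.10, 0.10), r_foot = c(0, -0.10, 0.10))
  trials <- vector("list", cfg$n_participants)
  for (p in seq_len(cfg$n_participants)) {
    cadence <- stats::runif(1, cfg$cadence_range[1], cfg$cadence_range[2])
    f <- cadence / 120                      # stride frequency per leg, Hz
    gain <- 1 + stats::runif(1, -cfg$amp_variation, cfg$amp_variation)
    jit <- stats::runif(4, -0.3, 0.3)       # per-participant phase jitter
    jm <- stats::runif(4, 0, 2 * pi)        # modulation phases
    env0 <- activity_envelope(t, cfg$duration_s, cfg$stillness_fraction)
    # stride-to-stride variability: slow (< 0.3 Hz) modulation of movement
    # amplitude and stride timing, shared with the GRF generator
    amp_mod <- 1 + cfg$stride_var * (0.6 * sin(2 * pi * 0.13 * t + jm[1]) +
                                       0.4 * sin(2 * pi * 0.29 * t + jm[2]))
    wander <- 5 * cfg$stride_var * (0.6 * sin(2 * pi * 0.11 * t + jm[3]) +
                                      0.4 * sin(2 * pi * 0.23 * t + jm[4]))
    phi_r <- 2 * pi * f * t + wander        # right-leg stride phase
    phi_l <- phi_r + pi
    env <- env0 * amp_mod                   # motion amplitude envelope
    ang <- list(
      trunk = 0.06 * gain * sin(2 * phi_r + jit[1]) * env,
      pelvis = 0.05 * gain * sin(2 * phi_r + jit[2]) * env,
      l_thigh = 0.50 * gain * sin(phi_l + jit[3]) * env,
      r_thigh = 0.50 * gain * sin(phi_r + jit[3]) * env,
      l_shank = (0.35 * sin(phi_l - 0.6) + 0.15 * sin(2 * phi_l + 0.5)) *
        gain * env,
      r_shank = (0.35 * sin(phi_r - 0.6) + 0.15 * sin(2 * phi_r + 0.5)) *
        gain * env,
      l_foot = (0.30 * sin(phi_l + 0.3 + jit[4]) + 0.10 * sin(2 * phi_l)) *
        gain * env,
      r_foot = (0.30 * sin(phi_r + 0.3 + jit[4]) + 0.10 * sin(2 * phi_r)) *
        gain * env)
    positions <- list(); orientations <- list()
    for (s in segs) {
      phi <- if (startsWith(s, "l_")) phi_l else phi_r
      fwd <- switch(s, trunk = 0.02, pelvis = 0.02, 0.08) *
        gain * sin(phi) * env
      bob <- switch(s, trunk = 0.03, pelvis = 0.03, 0.015) *
        gain * sin(2 * phi + 0.4) * env
      positions[[s]] <- cbind(base_pos[[s]][1] + fwd,
                              rep(base_pos[[s]][2], n),
                              base_pos[[s]][3] + bob)
      orientations[[s]] <- if (s %in% c("pelvis", "trunk")) {
        quat_about_x(ang[[s]])
      } else {
        quat_about_y(ang[[s]])
      }
    }
    tr <- kinematics_trial(positions, orientations, sampling_rate = cfg$fs,
                           participant_id = sprintf("P%02d", p),
                           trial_id = sprintf("gait_P%02d", p))
    attr(tr, "gait_phase_r") <- phi_r
    attr(tr, "env") <- env0
    attr(tr, "amp_mod") <- amp_mod
    attr(tr, "grf_gain") <- gain
    attr(tr, "kind") <- "gait"
    trials[[p]] <- tr
  }
  trials
}

#' Generate drop-landing kinematics trials
#'
#' Short (0.8 s, 80-step) trials: a free-fall descent followed by a smooth
#' landing deceleration impulse, shared by all segments, with knee/hip
#' flexion during the landing. The vertical acceleration profile that drives
#' the kinematics also defines the GRF impulse.
#'
#' @param cfg A [fixture_config()]; `duration_s` is ignored (fixed 0.8 s).
#' @param n_trials_per_participant Trials per participant.
#' @return List of [kinematics_trial()] objects with attribute `accel_z`
#'   (the shared vertical acceleration) for [generate_grf()].
#' @export
generate_drop_landing_kinematics <- function(cfg, n_trials_per_participant = 5L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 101L)
  n <- 80L
  dt <- 1 / cfg$fs
  t <- (seq_len(n) - 1) * dt
  segs <- sensor_names()
  base_z <- c(trunk = 1.30, pelvis = 1.00, l_thigh = 0.80, r_thigh = 0.80,
              l_shank = 0.45, r_shank = 0.45, l_foot = 0.10, r_foot = 0.10)
  trials <- list()
  for (p in seq_len(cfg$n_participants)) {
    gain <- 1 + stats::runif(1, -cfg$amp_variation, cfg$amp_variation)
    for (k in seq_len(n_trials_per_participant)) {
      t_land <- stats::runif(1, 0.28, 0.36)
      width <- stats::runif(1, 0.045, 0.06)
      # per-unit-mass vertical acceleration: free fall, then a Gaussian
      # landing impulse sized to cancel the accumulated downward velocity
      impulse_area <- 9.81 * t_land * 1.15   # slight rebound
      peak <- impulse_area / (width * sqrt(pi))
      a_z <- -9.81 + peak * exp(-((t - t_land - 1.5 * width) / width)^2)
      v_z <- cumsum(a_z) * dt
      z_off <- cumsum(v_z) * dt
      flex <- 0.6 * gain * smoothstep((t - t_land) / 0.25)
      positions <- list(); orientations <- list()
      for (s in segs) {
        positions[[s]] <- cbind(rep(0, n),
                                rep(if (startsWith(s, "l_")) 0.10
                                    else if (startsWith(s, "r_")) -0.10
                                    else 0, n),
                                base_z[[s]] + z_off)
        amp <- switch(s, trunk = 0.3, pelvis = 0.2, 1.0)
        orientations[[s]] <- quat_about_y(amp * flex *
                                            (if (startsWith(s, "l_")) 1 else 1))
      }
      tr <- kinematics_trial(positions, orientations, sampling_rate = cfg$fs,
                             participant_id = sprintf("P%02d", p),
                             trial_id = sprintf("drop_P%02d_%02d", p, k))
      attr(tr, "accel_z") <- a_z
      attr(tr, "t_land") <- t_land
      attr(tr, "grf_gain") <- gain
      attr(tr, "kind") <- "drop_landing"
      trials[[length(trials) + 1L]] <- tr
    }
  }
  trials
}

#' Ground-truth GRF for a fixture trial
#'
#' Derives right-leg 3-axis GRF (N/kg) deterministically from the trial's
#' internal phase (gait) or shared vertical acceleration (drop landing):
#' vertical GRF follows a double-peaked profile during stance and is exactly
#' zero in swing; medial-lateral and anterior-posterior components are
#' smaller-amplitude functions of the same state. Stance onsets are the
#' stance-phase entry samples.
#'
#' @param trial A trial from [generate_gait_kinematics()] or
#'   [generate_drop_landing_kinematics()].
#' @param cfg The [fixture_config()] used to generate it.
#' @param duty Stance fraction of the stride (gait only).
#' @return List with `grf` (`n` x 3 matrix, columns ml/ap/v) and
#'   `stance_onsets` (0-based indices; empty for drop landing).
#' @export
generate_grf <- function(trial, cfg, duty = 0.6) {
  kind <- attr(trial, "kind")
  gain <- attr(trial, "grf_gain")
  if (is.null(kind)) {
    stop("trial lacks the generator's internal phase attributes", call. = FALSE)
  }
  if (kind == "gait") {
    phi <- attr(trial, "gait_phase_r")
    env <- attr(trial, "env")
    am <- attr(trial, "amp_mod")
    if (is.null(am)) am <- rep(1, length(env))
    s <- (phi / (2 * pi)) %% 1
    in_stance <- s < duty
    u <- s / duty
    A <- cfg$peak_vgrf_factor * 9.81 * gain / stance_shape_max()
    scale <- env^2 * am          # GRF follows the shared amplitude state
    v <- ifelse(in_stance, A * stance_shape(u), 0) * scale
    ap <- ifelse(in_stance, -0.25 * A * sin(2 * pi * u), 0) * scale
    ml <- ifelse(in_stance, 0.08 * A * sin(pi * u), 0) * scale
    onsets <- which(in_stance & !c(FALSE, in_stance[-length(in_stance)]) &
                      env > 0.999) - 1L
    list(grf = cbind(ml, ap, v), stance_onsets = onsets)
  } else {
    a_z <- attr(trial, "accel_z")
    v <- pmax(0, (a_z + 9.81) / 2)          # right leg of a double-leg landing
    # no ground contact before touchdown: flight GRF is exactly zero
    t <- (seq_len(length(a_z)) - 1) / trial$sampling_rate
    v[t < attr(trial, "t_land")] <- 0
    ml <- 0.06 * v * gain
    ap <- -0.12 * v * gain
    list(grf = cbind(ml = ml, ap = ap, v = v), stance_onsets = integer(0))
  }
}

#' Build pre-training and labeled downstream window sets
#'
#' Runs the full synthetic pipeline: gait kinematics, low-pass filtering and
#' resampling, synthetic IMU generation with a random mounting perturbation,
#' optional sensor noise, overlapping-window segmentation with stillness and
#' range-outlier filters (pre-training corpus, unlabeled), and gait-window
#' extraction around stance onsets with ground-truth GRF (labeled set).
#'
#' @param cfg A [fixture_config()].
#' @param labeled_fraction Fraction of labeled windows retained (seeded
#'   subsample).
#' @return List of class `grf_corpus` with `pretrain` and `labeled` window
#'   sets, and exclusion counts `n_removed_still`, `n_removed_outliers`.
#' @export
make_corpus <- function(cfg, labeled_fraction = 1.0) {
  layout <- sensor_layout()
  kin <- generate_gait_kinematics(cfg)
  perts <- sample_perturbations(layout, n_variants = max(1L, cfg$n_variants),
                                max_deg = 10, seed = cfg$seed + 17L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 29L)
  pretrain_sets <- list(); labeled_sets <- list()
  n_still <- 0L; n_out <- 0L
  for (i in seq_along(kin)) {
    tr <- kin[[i]]
    lp <- lowpass_resample(tr, cutoff = 15, order = 4, fs_out = 100)
    for (v in seq_len(max(1L, cfg$n_variants))) {
      imu <- synthesize_imu(lp, layout, perts[[v]])
      if (cfg$noise_acc > 0 || cfg$noise_gyro > 0) {
        na <- nrow(imu$data)
        imu$data[, acc_columns()] <- imu$data[, acc_columns()] +
          stats::rnorm(na * 24, 0, cfg$noise_acc)
        imu$data[, gyr_columns()] <- imu$data[, gyr_columns()] +
          stats::rnorm(na * 24, 0, cfg$noise_gyro)
      }
      ws <- segment_windows(imu, windowing_config())
      ws <- filter_still(ws)
      n_still <- n_still + attr(ws, "n_removed")
      ws <- filter_outliers(ws)
      n_out <- n_out + attr(ws, "n_removed")
      if (n_windows(ws) > 0) pretrain_sets[[length(pretrain_sets) + 1L]] <- ws
      if (v == 1L) {
        gt <- generate_grf(tr, cfg)
        lab_trial <- imu_trial(imu$data, imu$sampling_rate,
                               imu$participant_id, imu$trial_id,
                               grf = gt$grf[seq_len(nrow(imu$data)), ,
                                            drop = FALSE],
                               stance_onsets = gt$stance_onsets[
                                 gt$stance_onsets < nrow(imu$data)])
        lws <- extract_gait_windows(lab_trial, windowing_config())
        if (n_windows(lws) > 0) {
          labeled_sets[[length(labeled_sets) + 1L]] <- lws
        }
      }
    }
  }
  pretrain <- do.call(bind_windows, pretrain_sets)
  labeled <- do.call(bind_windows, labeled_sets)
  if (labeled_fraction < 1) {
    n <- n_windows(labeled)
    m <- max(1L, floor(labeled_fraction * n))
    labeled <- subset_windows(labeled, sort(sample.int(n, m)))
  }
  structure(list(pretrain = pretrain, labeled = labeled,
                 n_removed_still = n_still, n_removed_outliers = n_out,
                 config = cfg),
            class = "grf_corpus")
}
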