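# Shared fixtures and small independent oracles for the test suite.

# kinematics builders ---------------------------------------------------------

const_mat <- function(v, n) matrix(rep(v, each = n), n, length(v))

# all segments static at given position/orientation
static_kinematics <- function(n = 200, fs = 100, quat = c(1, 0, 0, 0)) {
  segs <- sensor_names()
  kinematics_trial(
    positions = stats::setNames(lapply(segs, function(s) const_mat(c(0, 0, 1), n)), segs),
    orientations = stats::setNames(lapply(segs, function(s) const_mat(quat, n)), segs),
    sampling_rate = fs, participant_id = "T1")
}

# all segments share one orientation trajectory (n x 4) / position (n x 3)
uniform_kinematics <- function(quat_traj, pos_traj = NULL, fs = 100) {
  n <- nrow(quat_traj)
  if (is.null(pos_traj)) pos_traj <- const_mat(c(0, 0, 1), n)
  segs <- sensor_names()
  kinematics_trial(
    positions = stats::setNames(lapply(segs, function(s) pos_traj), segs),
    orientations = stats::setNames(lapply(segs, function(s) quat_traj), segs),
    sampling_rate = fs, participant_id = "T1")
}

# quaternion product (independent of package internals)
qmul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

# window-set builders ---------------------------------------------------------

random_trial <- function(n = 300, seed = 1, fs = 100, labeled = FALSE,
                         participant = "P1", onsets = NULL) {
  withr::with_seed(seed, {
    data <- matrix(rnorm(n * 48), n, 48)
    colnames(data) <- imu_axis_names()
    grf <- if (labeled) matrix(abs(rnorm(n * 3)), n, 3)
    imu_trial(data, fs, participant, grf = grf, stance_onsets = onsets)
  })
}

random_window_set <- function(n_win = 6, seed = 1, labeled = FALSE,
                              valid = rep(128L, n_win),
                              participants = rep("P1", n_win)) {
  withr::with_seed(seed, {
    data <- array(rnorm(n_win * 128 * 48), c(n_win, 128, 48))
    grf <- if (labeled) array(rnorm(n_win * 128 * 3), c(n_win, 128, 3))
    for (i in which(valid < 128L)) {
      data[i, (valid[i] + 1):128, ] <- 0
      if (labeled) grf[i, (valid[i] + 1):128, ] <- 0
    }
    window_set(data,
               tibble::tibble(participant_id = participants,
                              trial_id = paste0("t", seq_len(n_win)),
                              start = 0L, valid_length = valid),
               grf = grf)
  })
}

# structured windows: shared sinusoid basis + noise, so reconstruction and
# regression are learnable by a small model
make_learnable_corpus <- function(n_win = 48, seed = 1, labeled = FALSE) {
  withr::with_seed(seed, {
    t <- seq_len(128) / 100
    data <- array(0, c(n_win, 128, 48))
    grf <- array(0, c(n_win, 128, 3))
    for (i in seq_len(n_win)) {
      ph <- runif(1, 0, 2 * pi)
      for (a in seq_len(48)) {
        data[i, , a] <- sin(2 * pi * t + ph + a / 8) + rnorm(128, sd = 0.1)
      }
      for (a in seq_len(3)) {
        grf[i, , a] <- 0.8 * sin(2 * pi * t + ph + a / 3)
      }
    }
    window_set(data,
               tibble::tibble(participant_id = rep(c("A", "B"), n_win / 2),
                              trial_id = "t", start = 0L, valid_length = 128L),
               grf = if (labeled) grf)
  })
}

# small model configs ---------------------------------------------------------

toy_cfg <- function(...) {
  tiny_model_config(embed_dim = 16L, n_blocks = 1L, n_heads = 2L,
                    ff_dim = 24L, dropout = 0, ...)
}

# brute-force masked MSE oracle: per-window encode/reconstruct through the
# public single-window API, error summed over exactly the masked entries
oracle_masked_mse <- function(state, ws, masks) {
  cfg <- state$config
  pl <- cfg$patch_length
  total <- 0; count <- 0
  for (i in seq_len(n_windows(ws))) {
    w <- ws$data[i, , ]
    patches <- slice_patches(w, pl)
    masked <- apply_mask(patches, masks[[i]], state$params$mask_patch)
    recon <- reconstruct(encode(masked, state), state)
    v <- ws$meta$valid_length[i]
    for (p in masks[[i]]) {
      rows <- ((p - 1) * pl + 1):(p * pl)
      rows <- rows[rows <= v]
      total <- total + sum((recon[rows, ] - w[rows, ])^2)
      count <- count + length(rows) * 48
    }
  }
  list(mse = total / count, n_entries = count)
}
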