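# Synthetic IMU generation: filtering/resampling, mounting perturbations,
# differentiation of kinematics into sensor-frame signals.

test_that("low-pass resampling passes DC, preserves tones, fixes the grid", {
  n <- 120
  t_in <- (seq_len(n) - 1) / 120
  # constant trajectory is untouched
  kt <- uniform_kinematics(const_mat(c(1, 0, 0, 0), n),
                           const_mat(c(0.3, -0.2, 1.1), n), fs = 120)
  out <- lowpass_resample(kt, cutoff = 15, order = 4, fs_out = 100)
  expect_lt(max(abs(sweep(out$positions$trunk, 2, c(0.3, -0.2, 1.1)))), 1e-9)
  # 120 samples at 120 Hz -> 100 samples at 100 Hz
  expect_identical(out$n_steps, 100L)

  # 1 Hz tone through the squared 4th-order Butterworth response at 15 Hz:
  # |H|^2 = 1 / (1 + (1/15)^8), i.e. attenuation far below 1%
  n2 <- 600
  t2 <- (seq_len(n2) - 1) / 120
  pos <- cbind(0.05 * sin(2 * pi * 1 * t2), 0, 1)
  kt2 <- uniform_kinematics(const_mat(c(1, 0, 0, 0), n2), pos, fs = 120)
  out2 <- lowpass_resample(kt2, fs_out = 100)
  mid <- 100:400
  ratio <- max(abs(out2$positions$trunk[mid, 1] - 0)) / 0.05
  expect_gt(ratio, 0.99)

  # too short for stable zero-lag filtering
  expect_error(lowpass_resample(static_kinematics(n = 10)), "too short")
  # sampling theorem precondition
  expect_error(lowpass_resample(static_kinematics(n = 50, fs = 20)), "twice")
})

test_that("perturbation sampling is seeded, bounded, and degenerate at 0", {
  lay <- sensor_layout()
  p1 <- sample_perturbations(lay, n_variants = 5, max_deg = 10, seed = 7)
  p2 <- sample_perturbations(lay, n_variants = 5, max_deg = 10, seed = 7)
  expect_identical(p1, p2)
  expect_length(p1, 5L)
  all_angles <- unlist(lapply(p1, function(p) unlist(p$angles)))
  expect_true(all(abs(all_angles) <= 10))
  expect_length(all_angles, 5L * 8L * 3L)

  p0 <- sample_perturbations(lay, n_variants = 2, max_deg = 0, seed = 1)
  expect_true(all(unlist(lapply(p0, function(p) unlist(p$angles))) == 0))
})

test_that("static kinematics give zero gyro and gravity-only accelerometer", {
  lay <- sensor_layout()
  imu <- synthesize_imu(static_kinematics(), lay)
  gyr <- imu$data[, grfimu:::gyr_columns()]
  acc <- imu$data[, grfimu:::acc_columns()]
  expect_lt(max(abs(gyr)), 1e-9)
  # z-up sensor reads +9.81 on z, 0 on x/y, constant over time
  expect_lt(max(abs(imu$data[, "acc_z_trunk"] - 9.81)), 1e-9)
  expect_lt(max(abs(imu$data[, c("acc_x_trunk", "acc_y_trunk")])), 1e-9)
  expect_lt(max(apply(acc, 2, function(x) diff(range(x)))), 1e-9)

  # with a 90 deg mounting about x, gravity appears on the rotated axis
  lay90 <- sensor_layout(mountings = stats::setNames(
    replicate(8, grfimu:::rot_x(90), simplify = FALSE), sensor_names()))
  imu90 <- synthesize_imu(static_kinematics(), lay90)
  g_sens <- imu90$data[5, c("acc_x_trunk", "acc_y_trunk", "acc_z_trunk")]
  expect_equal(sqrt(sum(g_sens^2)), 9.81, tolerance = 1e-9)
  expect_gt(abs(g_sens[2]), 9.0)  # gravity moved onto the y axis
})

test_that("constant-rate rotation recovers the angular velocity", {
  n <- 200
  th <- (seq_len(n) - 1) / 100 * 90 * pi / 180
  q <- cbind(cos(th / 2), 0, 0, sin(th / 2))
  imu <- synthesize_imu(uniform_kinematics(q), sensor_layout())
  mid <- 20:180
  expect_lt(max(abs(imu$data[mid, "gyr_z_trunk"] - 90)), 0.5)
  expect_lt(max(abs(imu$data[mid, c("gyr_x_trunk", "gyr_y_trunk")])), 0.5)
})

test_that("quadratic trajectory recovers its analytic acceleration", {
  n <- 200
  t <- (seq_len(n) - 1) / 100
  pos <- cbind(0.5 * t^2, 0, 1)
  imu <- synthesize_imu(uniform_kinematics(const_mat(c(1, 0, 0, 0), n), pos),
                        sensor_layout())
  mid <- 10:190
  expect_lt(max(abs(imu$data[mid, "acc_x_trunk"] - 1)), 1e-3)
  expect_lt(max(abs(imu$data[mid, "acc_z_trunk"] - 9.81)), 1e-3)
  expect_error(
    synthesize_imu(static_kinematics(n = 2), sensor_layout()), "at least 3")
})

test_that("a global rotation leaves gyro unchanged and only moves gravity", {
  n <- 150
  t <- (seq_len(n) - 1) / 100
  th <- 0.4 * sin(2 * pi * 1.5 * t)
  q <- cbind(cos(th / 2), 0.6 * sin(th / 2), 0.8 * sin(th / 2), 0)
  pos <- cbind(0.05 * sin(2 * pi * t), 0.03 * cos(2 * pi * t), 1)
  kt <- uniform_kinematics(q, pos)

  r0 <- c(cos(pi / 7), 0, 0, sin(pi / 7))   # fixed global rotation about z
  R0 <- grfimu:::quat_to_mat(r0)
  q_rot <- t(apply(q, 1, function(qi) qmul(r0, qi)))
  kt_rot <- uniform_kinematics(q_rot, pos %*% t(R0))

  lay <- sensor_layout()
  a <- synthesize_imu(kt, lay, add_gravity = FALSE)
  b <- synthesize_imu(kt_rot, lay, add_gravity = FALSE)
  expect_lt(max(abs(a$data - b$data)), 1e-9)

  ag <- synthesize_imu(kt, lay)
  bg <- synthesize_imu(kt_rot, lay)
  gyr <- grfimu:::gyr_columns()
  expect_lt(max(abs(ag$data[, gyr] - bg$data[, gyr])), 1e-9)
})

test_that("perturbing by R then R^-1 restores the unperturbed output", {
  n <- 150
  t <- (seq_len(n) - 1) / 100
  th <- 0.5 * sin(2 * pi * t)
  q <- cbind(cos(th / 2), 0, sin(th / 2), 0)
  pos <- cbind(0.04 * sin(2 * pi * 1.2 * t), 0, 1 + 0.02 * cos(2 * pi * t))
  kt <- uniform_kinematics(q, pos)
  lay <- sensor_layout()

  pert <- sample_perturbations(lay, n_variants = 1, max_deg = 10, seed = 3)[[1]]
  Rp <- lapply(sensor_names(), function(s) {
    grfimu:::rot_xyz_intrinsic(pert$angles[[s]])
  })
  names(Rp) <- sensor_names()
  # mounting absorbing R, perturbation R^-1: net identity
  lay_r <- sensor_layout(mountings = lapply(Rp, t))
  undone <- synthesize_imu(kt, lay_r,
                           perturbation = matrix_perturbation(lapply(Rp, t)))
  plain <- synthesize_imu(kt, lay)
  expect_lt(max(abs(undone$data - plain$data)), 1e-9)

  # perturbed output differs from unperturbed
  perturbed <- synthesize_imu(kt, lay, perturbation = pert)
  expect_gt(max(abs(perturbed$data - plain$data)), 0.1)
})

test_that("finite-difference error shrinks when the sampling rate doubles", {
  err_at <- function(fs) {
    n <- 2 * fs
    t <- (seq_len(n) - 1) / fs
    th <- 0.5 * sin(2 * pi * t)
    omega_true <- 0.5 * 2 * pi * cos(2 * pi * t) * 180 / pi
    q <- cbind(cos(th / 2), 0, 0, sin(th / 2))
    kt <- uniform_kinematics(q, const_mat(c(0, 0, 1), n), fs = fs)
    imu <- synthesize_imu(kt, sensor_layout())
    mid <- 10:(n - 10)
    max(abs(imu$data[mid, "gyr_z_trunk"] - omega_true[mid]))
  }
  e100 <- err_at(100); e200 <- err_at(200)
  expect_lt(e200, e100 / 2)
})

test_that("gravity convention enforces magnitude 9.81", {
  expect_error(gravity_convention(c(0, 0, 9.8)), "9.81")
  expect_silent(gravity_convention(c(0, 9.81, 0)))
})
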