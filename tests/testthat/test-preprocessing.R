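# Windowing, exclusion filters, gait-window extraction, padding, resampling,
# normalization.

test_that("overlapping segmentation follows the count formula", {
  expect_identical(n_windows(segment_windows(random_trial(128))), 1L)
  ws <- segment_windows(random_trial(256))
  expect_identical(n_windows(ws), 3L)
  expect_identical(ws$meta$start, c(0L, 64L, 128L))
  expect_identical(n_windows(segment_windows(random_trial(127))), 0L)
  # spans reconstruct the covered region [0, 64*(k-1) + 128)
  tr <- random_trial(500)
  ws5 <- segment_windows(tr)
  k <- n_windows(ws5)
  expect_identical(k, (500L - 128L) %/% 64L + 1L)
  covered <- sort(unique(unlist(lapply(ws5$meta$start, function(s) s + 0:127))))
  expect_identical(covered, 0:(64L * (k - 1L) + 127L))
  # GRF sliced alongside
  trg <- random_trial(256, labeled = TRUE)
  wsg <- segment_windows(trg)
  expect_identical(wsg$grf[3, , ], unname(trg$grf[129:256, ]))
})

test_that("stillness filter removes quiet windows with >= retention at the boundary", {
  base <- array(0, c(3, 128, 48))
  withr::with_seed(1, {
    # window 1: all constant (statistic 0) -> removed
    base[1, , ] <- 5
    # window 2: one accelerometer axis with sd exactly 24 * 0.2 = 4.8,
    # everything else constant -> statistic exactly 0.2, retained
    x <- sin(seq_len(128))
    base[2, , 1] <- x / sd(x) * 4.8
    # window 3: lively on all axes -> retained
    base[3, , ] <- rnorm(128 * 48, sd = 3)
  })
  ws <- window_set(base, tibble::tibble(participant_id = "P", trial_id = "t",
                                        start = 0L, valid_length = 128L)[c(1, 1, 1), ])
  stat <- grfimu:::window_stat_still(ws)
  expect_identical(stat[1], 0)                   # all-constant window
  expect_equal(stat[2], 4.8 / 24, tolerance = 1e-12)
  # >= comparison: a window exactly at the threshold is retained
  kept <- filter_still(ws, threshold = stat[2])
  expect_identical(n_windows(kept), 2L)
  expect_identical(attr(kept, "n_removed"), 1L)
  expect_identical(kept$meta$trial_id, c("t", "t"))
  # nudging the boundary axis just below the threshold removes it
  ws$data[2, , 1] <- ws$data[2, , 1] * 0.999
  kept2 <- filter_still(ws, threshold = stat[2])
  expect_identical(n_windows(kept2), 1L)
})

test_that("range-outlier filter is strict beyond thresholds, inclusive at them", {
  ws <- random_window_set(4, seed = 2)
  ws$data[2, 50, 1] <- 161          # acc spike
  ws$data[3, 10, 5] <- 2500         # gyro spike (column 5 is gyr_y_trunk)
  ws$data[4, , ] <- 0
  ws$data[4, 1, 1] <- 160           # exactly at the acc threshold
  ws$data[4, 1, 4] <- 2000          # exactly at the gyro threshold
  kept <- filter_outliers(ws)
  expect_identical(n_windows(kept), 2L)
  expect_identical(attr(kept, "n_removed"), 2L)
  expect_true(all(kept$meta$trial_id == c("t1", "t4")))
})

test_that("filters commute on disjoint criteria", {
  ws <- random_window_set(6, seed = 3)
  ws$data[1, , ] <- 0                    # still
  ws$data[4, 7, 13] <- 500               # acc outlier
  a <- filter_outliers(filter_still(ws))
  b <- filter_still(filter_outliers(ws))
  expect_identical(a$data, b$data)
  expect_identical(a$meta$trial_id, b$meta$trial_id)
})

test_that("gait windows start 40 samples before stance, clamped and bounded", {
  tr <- random_trial(300, labeled = TRUE, onsets = c(20L, 100L, 250L))
  ws <- extract_gait_windows(tr)
  # onset 250 needs samples [210, 338) -> dropped; onset 20 clamps to 0
  expect_identical(ws$meta$start, c(0L, 60L))
  expect_identical(ws$data[2, , ], unname(tr$data[61:188, ]))
  tr2 <- random_trial(300)
  expect_error(extract_gait_windows(tr2), "stance-onset")
})

test_that("zero-padding records valid_length and keeps padded rows zero", {
  tr <- random_trial(80, labeled = TRUE)
  w <- pad_trial_to_window(tr)
  expect_identical(n_windows(w), 1L)
  expect_identical(w$meta$valid_length, 80L)
  expect_true(all(w$data[1, 81:128, ] == 0))
  expect_true(all(w$grf[1, 81:128, ] == 0))
  expect_identical(w$data[1, 1:80, ], unname(tr$data))

  full <- pad_trial_to_window(random_trial(128))
  expect_identical(full$meta$valid_length, 128L)
  expect_error(pad_trial_to_window(random_trial(129)), "longer")
})

test_that("linear resampling preserves duration, ramps, and is identity at fs", {
  tr <- random_trial(256, labeled = TRUE)
  tr$sampling_rate <- 200
  out <- resample_trial(tr, 100)
  expect_identical(nrow(out$data), 128L)
  expect_equal(out$sampling_rate, 100)

  ramp <- imu_trial(matrix(seq_len(300), 300, 48), 150, "P")
  res <- resample_trial(ramp, 100)
  t_out <- (seq_len(nrow(res$data)) - 1) / 100
  expect_equal(res$data[, 1], t_out * 150 + 1, tolerance = 1e-10)

  same <- resample_trial(random_trial(100), 100)
  expect_identical(same$data, random_trial(100)$data)
})

test_that("z-score normalization matches the two-pass oracle and inverts", {
  ws <- random_window_set(8, seed = 4, labeled = TRUE,
                          valid = c(rep(128L, 7), 60L))
  ws$data[, , 7] <- 3.5                          # constant axis
  ws$data[8, 61:128, ] <- 0                      # keep padded rows zero
  stats <- fit_normalizer(ws)

  # two-pass brute force over valid rows only
  pooled <- do.call(rbind, lapply(seq_len(8), function(i) {
    ws$data[i, seq_len(ws$meta$valid_length[i]), ]
  }))
  expect_lt(max(abs(stats$imu_mean - colMeans(pooled))), 1e-10)
  expect_lt(max(abs(stats$imu_sd[-7] - apply(pooled, 2, sd)[-7])), 1e-10)
  expect_identical(stats$imu_sd[[7]], 1e-8)      # epsilon clamp

  norm <- apply_normalizer(ws, stats)
  # z-scored training set: per-axis mean ~ 0, sd ~ 1 over valid rows
  pooled_n <- do.call(rbind, lapply(seq_len(8), function(i) {
    norm$data[i, seq_len(norm$meta$valid_length[i]), ]
  }))
  expect_lt(max(abs(colMeans(pooled_n)[-7])), 1e-9)
  expect_lt(max(abs(apply(pooled_n, 2, sd)[-7] - 1)), 1e-6)
  expect_true(all(pooled_n[, 7] == 0))           # constant axis -> zeros
  # padded rows stay exactly zero
  expect_true(all(norm$data[8, 61:128, ] == 0))
  expect_true(all(norm$grf[8, 61:128, ] == 0))

  back <- apply_normalizer(norm, stats, invert = TRUE)
  expect_lt(max(abs(back$data - ws$data)), 1e-10)
  expect_lt(max(abs(back$grf - ws$grf)), 1e-10)
})

test_that("windowing config validates its ranges", {
  expect_error(windowing_config(overlap = 1), "overlap")
  expect_error(windowing_config(stillness_threshold = 0))
  expect_s3_class(windowing_config(overlap = 0), "windowing_config")
})
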