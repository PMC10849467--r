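# Metrics, phase masking, folds, scaling curves, spectrum analysis,
# statistical comparison.

test_that("phase mask includes samples at or above 2% body weight", {
  v <- c(0, 0.1, 0.1962, 0.2, 5, 0.19)
  m <- phase_mask(v)
  expect_identical(m, c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  # padded rows always excluded
  m2 <- phase_mask(c(5, 5, 5, 5), valid_length = 2)
  expect_identical(m2, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(sum(phase_mask(rep(0, 10))), 0L)
})

test_that("correlation and RMSE match hand formulas and reject degenerate input", {
  a <- c(0.3, 1.2, 2.4, 0.9)
  expect_equal(pearson_r(a, a), 1)
  expect_equal(rmse(a, a), 0)
  expect_equal(pearson_r(a, -a), -1)
  expect_equal(rmse(c(0, 1, 2), c(0, 1, 4)), sqrt(4 / 3))
  # two-pass oracle within 1e-10
  withr::with_seed(1, {
    x <- rnorm(200); y <- 0.7 * x + rnorm(200, sd = 0.3)
  })
  or <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_lt(abs(pearson_r(x, y) - or), 1e-10)
  expect_lt(abs(rmse(x, y) - sqrt(sum((x - y)^2) / 200)), 1e-10)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
})

test_that("rRMSE normalizes by the gold range and is scale-invariant", {
  est <- c(0.4, 1.1, 1.9); gold <- c(0.5, 1.0, 2.0)
  expect_equal(rrmse(gold, gold), 0)
  expect_equal(rrmse(c(0.1, 1.9), c(0, 2)), 0.1 / 2 * 100)
  r1 <- rrmse(est, gold)
  r2 <- rrmse(3.7 * est, 3.7 * gold)
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_error(rrmse(est, rep(1, 3)), "zero")
})

test_that("peak metrics pair per-window maxima with a global range denominator", {
  est <- rbind(c(rep(0, 60), rep(1.1, 40), rep(0, 28)),
               c(rep(0, 60), rep(1.9, 40), rep(0, 28)))
  gold <- rbind(c(rep(0, 60), rep(1.0, 40), rep(0, 28)),
                c(rep(0, 60), rep(2.0, 40), rep(0, 28)))
  masks <- gold >= 0.1962
  res <- peak_vgrf_metrics(est, gold, masks)
  expect_equal(res$rmse, 0.1, tolerance = 1e-12)
  # gold range over all included samples: [1.0, 2.0]
  expect_equal(res$rrmse, 0.1 / 1.0 * 100, tolerance = 1e-12)
  expect_identical(res$n_windows, 2L)

  ident <- peak_vgrf_metrics(gold, gold, masks)
  expect_equal(ident$rho, 1)
  expect_equal(ident$rmse, 0)
  expect_equal(ident$rrmse, 0)

  # constant offset keeps rho = 1, RMSE = offset
  off <- peak_vgrf_metrics(gold + 0.1, gold, masks)
  expect_equal(off$rho, 1)
  expect_equal(off$rmse, 0.1, tolerance = 1e-12)

  # all-swing window skipped and counted
  gold3 <- rbind(gold, 0)
  est3 <- rbind(est, 0)
  masks3 <- gold3 >= 0.1962
  res3 <- peak_vgrf_metrics(est3, gold3, masks3)
  expect_identical(res3$n_skipped, 1L)
})

test_that("spectrum error is zero on identity and localizes a pure tone", {
  withr::with_seed(2, {
    gold <- matrix(rnorm(6 * 128), 6, 128)
  })
  z <- spectrum_error(gold, gold)
  expect_identical(nrow(z), 65L)  # 128/2 + 1 one-sided bins
  expect_true(all(z$error == 0))
  expect_equal(z$freq_hz[2] - z$freq_hz[1], 100 / 128)

  # bin-aligned tone at bin 7 (0-based 6): 6 * 100/128 = 4.6875 Hz
  t <- (0:127) / 100
  tone <- sin(2 * pi * 4.6875 * t)
  est <- sweep(gold, 2, -tone)  # gold + tone
  s <- spectrum_error(est, gold)
  expect_identical(which.max(abs(s$error)), 7L)
  abs_s <- spectrum_error(est, gold, mode = "absolute")
  expect_true(all(abs_s$error >= 0))
})

test_that("participant folds are balanced, disjoint, and seeded", {
  ids15 <- sprintf("P%02d", 1:15)
  f <- make_folds(ids15, k = 5, seed = 1)
  expect_identical(sort(as.integer(table(f$fold))), rep(3L, 5))
  expect_identical(sort(f$participant_id), ids15)

  ids17 <- sprintf("P%02d", 1:17)
  f17 <- make_folds(ids17, k = 5, seed = 2)
  expect_identical(sort(as.integer(table(f17$fold))), c(3L, 3L, 3L, 4L, 4L))
  expect_identical(anyDuplicated(f17$participant_id), 0L)

  expect_identical(make_folds(ids15, 5, seed = 9), make_folds(ids15, 5, seed = 9))
  expect_error(make_folds(sprintf("P%d", 1:4), k = 5), "at least")
})

test_that("fraction grids have the documented sizes", {
  lin <- fraction_grid("linear")
  expect_length(lin, 10L)
  expect_equal(lin[1], 1.0)
  expect_equal(lin[10], 0.1)
  ex <- fraction_grid("exponential")
  expect_length(ex, 11L)
  expect_equal(ex[1], 1.0)
  expect_equal(ex[11], 0.01, tolerance = 1e-12)
})

test_that("scaling-curve subsampling is nested and seeded", {
  ws <- random_window_set(40, seed = 3)
  seen <- list()
  cb <- function(sub, fraction) {
    seen[[as.character(fraction)]] <<- sub$meta$trial_id
    n_windows(sub)
  }
  curve <- scaling_curve(ws, c(1.0, 0.5, 0.1), cb, seed = 4)
  expect_identical(curve$n_windows, c(40L, 20L, 4L))
  expect_identical(curve$metric, c(40, 20, 4))
  expect_true(all(seen[["0.1"]] %in% seen[["0.5"]]))
  expect_true(all(seen[["0.5"]] %in% seen[["1"]]))
  # full training set at fraction 1
  expect_identical(seen[["1"]], ws$meta$trial_id)
  curve2 <- scaling_curve(ws, c(1.0, 0.5, 0.1), cb, seed = 4)
  expect_identical(curve$n_windows, curve2$n_windows)
  expect_error(scaling_curve(ws, c(0.5, 0.001), cb, seed = 1), "zero")
})

test_that("model comparison runs ANOVA then Bonferroni-paired t-tests", {
  withr::with_seed(5, {
    base <- rnorm(8, sd = 0.01)
    jitter2 <- rnorm(8, sd = 0.05)
    jitter3 <- rnorm(8, sd = 0.05)
    jitter4 <- rnorm(8, sd = 0.05)
  })
  # identical columns: no detectable difference, no pairwise tests
  m_same <- cbind(a = base, b = base, c = base)
  res_same <- compare_models(m_same)
  expect_gte(res_same$anova_p, 0.999)
  expect_null(res_same$pairwise)

  # two settings, large separation: single comparison, correction factor 1
  m2 <- cbind(a = base, b = base + 10 + jitter2)
  res2 <- compare_models(m2)
  expect_lt(res2$anova_p, 0.05)
  expect_identical(res2$n_comparisons, 1L)
  expect_equal(res2$pairwise$p_corrected, pmin(1, res2$pairwise$p_raw * 1))

  # four settings: C(4,2) = 6 comparisons
  m4 <- cbind(a = base, b = base + 5 + jitter2, c = base + 10 + jitter3,
              d = base + 15 + jitter4)
  res4 <- compare_models(m4)
  expect_identical(res4$n_comparisons, 6L)
  expect_identical(nrow(res4$pairwise), 6L)
  expect_true(all(res4$pairwise$p_corrected <= 1))
  expect_true(all(res4$pairwise$p_corrected >= res4$pairwise$p_raw))

  expect_error(compare_models(m2[1:2, ]), "3 participants")
  m_na <- m2; m_na[1, 1] <- NA
  expect_error(compare_models(m_na), "missing")
})

test_that("metrics ignore appended zero-GRF flight samples", {
  withr::with_seed(6, {
    gold <- abs(rnorm(100)) + 0.5
    est <- gold + rnorm(100, sd = 0.1)
  })
  with_flight_gold <- c(gold, rep(0, 40))
  with_flight_est <- c(est, rnorm(40, sd = 0.01))
  m <- phase_mask(with_flight_gold)
  expect_equal(pearson_r(with_flight_est[m], with_flight_gold[m]),
               pearson_r(est, gold))
  expect_equal(rmse(with_flight_est[m], with_flight_gold[m]), rmse(est, gold))
})

test_that("evaluate_grf aggregates per participant and axis", {
  ws <- random_window_set(6, seed = 7, labeled = TRUE,
                          participants = rep(c("P1", "P2"), each = 3))
  # make vGRF mostly positive so stance samples exist
  ws$grf[, , 3] <- abs(ws$grf[, , 3]) + 0.5
  est <- ws$grf
  rep <- evaluate_grf(est, ws)
  expect_s3_class(rep, "grf_eval_report")
  expect_identical(nrow(rep$per_axis), 6L)  # 2 participants x 3 axes
  expect_equal(rep$per_axis$rho, rep(1, 6))
  expect_equal(rep$per_axis$rmse, rep(0, 6))
  expect_equal(rep$peaks$rrmse, rep(0, 2))
  g <- glance(rep)
  expect_identical(nrow(g), 1L)
  expect_equal(g$rho_v, 1)
  expect_identical(nrow(tidy(rep)), 6L)
})
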