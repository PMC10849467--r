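# Patch transformer: slicing, masking, encoding, heads, substitution,
# parameter counting, checkpointing.

test_that("patch slicing is row-major, invertible, and shape-correct", {
  w <- matrix(rnorm(128 * 48), 128, 48)
  p8 <- slice_patches(w, 8L)
  expect_identical(dim(p8), c(16L, 384L))
  p1 <- slice_patches(w, 1L)
  expect_identical(dim(p1), c(128L, 48L))
  # row-major flatten: patch i, entry (r_local-1)*48 + c == window row, col
  expect_identical(p8[3, (5 - 1) * 48 + 7], w[2 * 8 + 5, 7])
  expect_identical(p8[1, 1:48], w[1, ])
  expect_identical(unslice_patches(p8, 8L), w)
  expect_identical(unslice_patches(p1, 1L), w)
  expect_error(slice_patches(w, 7L), "divisible")
})

test_that("mask sampling draws the exact count, seeded", {
  expect_length(sample_mask(16, 0.125, seed = 1), 2L)
  expect_length(sample_mask(128, 0.0625, seed = 1), 8L)
  expect_identical(sample_mask(128, 0.25, seed = 9),
                   sample_mask(128, 0.25, seed = 9))
  m <- sample_mask(64, 0.5, seed = 2)
  expect_identical(anyDuplicated(m), 0L)
  expect_true(all(m >= 1 & m <= 64))
  expect_error(sample_mask(4, 0.1), "zero masked")
})

test_that("mask application is local and saturates", {
  p <- matrix(rnorm(16 * 384), 16, 384)
  mp <- rnorm(384)
  expect_identical(apply_mask(p, integer(0), mp), p)
  all_masked <- apply_mask(p, 1:16, mp)
  expect_true(all(apply(all_masked, 1, function(r) all(r == mp))))
  one <- apply_mask(p, 5L, mp)
  expect_identical(which(rowSums(one != p) > 0), 5L)
  expect_error(apply_mask(p, 17L, mp), "out of range")
})

test_that("encoding is shape-correct and deterministic without dropout", {
  cfg <- model_config(patch_length = 1L, embed_dim = 32L, n_blocks = 2L,
                      n_heads = 4L, ff_dim = 48L)
  st <- init_model(cfg, seed = 1)
  p <- slice_patches(matrix(rnorm(128 * 48), 128, 48), 1L)
  e1 <- encode(p, st)
  expect_identical(dim(e1), c(128L, 32L))
  expect_identical(e1, encode(p, st))
  expect_error(encode(p[1:10, ], st), "expected 128 patches")
})

test_that("a width-4 single-head block matches a hand-composed attention oracle", {
  cfg <- model_config(patch_length = 16L, embed_dim = 4L, n_blocks = 1L,
                      n_heads = 1L, ff_dim = 8L, dropout = 0,
                      window_length = 64L, n_axes = 48L)
  st <- init_model(cfg, seed = 5)
  Tn <- 4L
  X0 <- matrix(rnorm(Tn * 16 * 48), Tn, 16 * 48)
  got <- encode(X0, st)

  # independent dense-math oracle
  p <- st$params
  pe <- positional_encoding(Tn, 4L)
  H <- X0 %*% p$embed_W + matrix(p$embed_b, Tn, 4, byrow = TRUE) + pe
  Q <- H %*% p$b1_Wq + matrix(p$b1_bq, Tn, 4, byrow = TRUE)
  K <- H %*% p$b1_Wk + matrix(p$b1_bk, Tn, 4, byrow = TRUE)
  V <- H %*% p$b1_Wv + matrix(p$b1_bv, Tn, 4, byrow = TRUE)
  S <- Q %*% t(K) / sqrt(4)
  P <- exp(S) / rowSums(exp(S))
  A <- (P %*% V) %*% p$b1_Wo + matrix(p$b1_bo, Tn, 4, byrow = TRUE)
  ln <- function(X, g, b, eps = 1e-5) {
    t(apply(X, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps) * g + b))
  }
  Y1 <- ln(H + A, p$b1_ln1_g, p$b1_ln1_b)
  Z <- Y1 %*% p$b1_W1 + matrix(p$b1_b1, Tn, 8, byrow = TRUE)
  Ff <- pmax(Z, 0) %*% p$b1_W2 + matrix(p$b1_b2, Tn, 4, byrow = TRUE)
  Y2 <- ln(Y1 + Ff, p$b1_ln2_g, p$b1_ln2_b)
  expect_lt(max(abs(got - Y2)), 1e-5)
})

test_that("reconstruction head maps back to the window shape", {
  cfg <- toy_cfg()
  st <- init_model(cfg, seed = 2)
  p <- slice_patches(matrix(rnorm(128 * 48), 128, 48), cfg$patch_length)
  e <- encode(p, st)
  r <- reconstruct(e, st)
  expect_identical(dim(r), c(128L, 48L))
  st0 <- st
  st0$params$recon_W[] <- 0; st0$params$recon_b[] <- 0
  expect_true(all(reconstruct(e, st0) == 0))
  # changing which patch is masked changes the reconstruction
  mp <- st$params$mask_patch
  r1 <- reconstruct(encode(apply_mask(p, 2L, mp), st), st)
  r2 <- reconstruct(encode(apply_mask(p, 9L, mp), st), st)
  expect_gt(max(abs(r1 - r2)), 0)
})

test_that("GRF head emits 128 x 3 with per-patch dimension 3 * patch_length", {
  cfg4 <- tiny_model_config(patch_length = 4L)
  st <- init_model(cfg4, seed = 3, include_grf_head = TRUE)
  expect_identical(ncol(st$params$grf_W), 12L)
  p <- slice_patches(matrix(rnorm(128 * 48), 128, 48), 4L)
  g <- predict_grf(encode(p, st), st)
  expect_identical(dim(g), c(128L, 3L))
  st$params$grf_W[] <- 0; st$params$grf_b[] <- 0
  expect_true(all(predict_grf(encode(p, st), st) == 0))
  st$params$grf_W <- NULL
  expect_error(predict_grf(encode(p, st), st), "no GRF head")
})

test_that("omitted sensors are substituted by tiled trainable patches", {
  cfg <- toy_cfg()
  subst <- setdiff(sensor_names(), "r_foot")
  st <- init_model(cfg, seed = 4, substituted_sensors = subst)
  w <- matrix(rnorm(128 * 48), 128, 48)
  expect_identical(substitute_missing(w, sensor_names(), st), w)

  out <- substitute_missing(w, "r_foot", st)
  rf <- grfimu:::sensor_columns("r_foot")
  expect_identical(out[, rf], w[, rf])
  changed <- which(colSums(out != w) > 0)
  expect_length(changed, 42L)
  # tiling: every patch-length block of a substituted sensor is identical
  tc <- grfimu:::sensor_columns("trunk")
  blk <- out[1:cfg$patch_length, tc]
  for (i in seq_len(128 / cfg$patch_length - 1)) {
    expect_identical(out[i * cfg$patch_length + 1:cfg$patch_length, tc], blk)
  }

  out4 <- substitute_missing(w, c("trunk", "r_thigh", "r_shank", "r_foot"), st)
  expect_length(which(colSums(out4 != w) > 0), 24L)
  expect_error(substitute_missing(w, character(0), st), "at least one")
  st_miss <- init_model(cfg, seed = 4)
  expect_error(substitute_missing(w, "r_foot", st_miss), "substitution patch")
})

test_that("parameter count matches closed-form layer sums", {
  # toy: patch 1, 2 axes, width 4, 1 block, 1 head, ff 8
  cfg <- model_config(patch_length = 1L, embed_dim = 4L, n_blocks = 1L,
                      n_heads = 1L, ff_dim = 8L, n_axes = 2L,
                      window_length = 8L)
  by_hand <- (2 * 4 + 4) +                       # embedding
    (4 * (4 * 4 + 4)) +                          # q/k/v/o projections
    (2 * 4 + 2 * 4) +                            # two layer norms
    (4 * 8 + 8) + (8 * 4 + 4) +                  # feedforward
    (4 * 2 + 2) +                                # reconstruction head
    2                                            # mask patch
  expect_identical(count_parameters(cfg), as.numeric(by_hand))

  # doubling ff_dim adds 2 * embed_dim * increment + increment per block
  cfg_a <- tiny_model_config(ff_dim = 128L)
  cfg_b <- tiny_model_config(ff_dim = 256L)
  inc <- 128L
  expect_identical(count_parameters(cfg_b) - count_parameters(cfg_a),
                   as.numeric(cfg_a$n_blocks * (2 * 64 * inc + inc)))

  # full-scale architecture rounds to 2 million
  expect_identical(round(count_parameters(model_config()) / 1e6), 2)
})

test_that("masked loss equals a brute-force recomputation over masked entries", {
  cfg <- toy_cfg()
  st <- init_model(cfg, seed = 6)
  ws <- random_window_set(5, seed = 7, valid = c(128L, 128L, 80L, 128L, 128L))
  Tn <- 128L / cfg$patch_length
  masks <- lapply(1:5, function(i) sample_mask(Tn, 0.25, seed = i))
  got <- masked_recon_loss(st, ws, masks = masks)
  oracle <- oracle_masked_mse(st, ws, masks)
  expect_lt(abs(got - oracle$mse), 1e-10)
  # entry count: sum of |mask| * patch_length * 48 over full-length windows,
  # reduced by the padded rows of window 3
  full <- 5 * length(masks[[1]]) * cfg$patch_length * 48
  pad_lost <- sum(vapply(masks[[3]], function(p) {
    rows <- ((p - 1) * cfg$patch_length + 1):(p * cfg$patch_length)
    sum(rows > 80) * 48
  }, numeric(1)))
  expect_identical(oracle$n_entries, full - pad_lost)
  # permutation of the mask index set leaves the loss unchanged
  masks_perm <- lapply(masks, rev)
  expect_equal(masked_recon_loss(st, ws, masks = masks_perm), got,
               tolerance = 1e-12)
})

test_that("checkpoints restore bit-exactly and refuse config mismatches", {
  dir <- withr::local_tempdir()
  st <- init_model(toy_cfg(), seed = 8, include_grf_head = TRUE)
  stats <- fit_normalizer(random_window_set(3, seed = 9, labeled = TRUE))
  path <- file.path(dir, "ck.rds")
  save_checkpoint(st, path, stats = stats)
  back <- load_checkpoint(path, expected_config = toy_cfg())
  expect_identical(back$state$params, st$params)
  expect_identical(back$stats, stats)
  expect_error(load_checkpoint(path, expected_config = tiny_model_config()),
               "does not match")
  writeLines("junk", file.path(dir, "bad.rds"))
  expect_error(load_checkpoint(file.path(dir, "bad.rds")), "checkpoint")
})

test_that("model config enforces divisibility", {
  expect_error(model_config(patch_length = 3L), "divisible")
  expect_error(model_config(embed_dim = 100L, n_heads = 8L), "divisible")
})
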