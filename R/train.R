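# Training: warmup-cosine learning-rate schedule, decoupled-weight-decay Adam
# (AdamW), masked-patch self-supervised pre-training, supervised transfer
# pre-training, and the two-step fine-tuning protocol (linear head first,
# then the whole model).

#' Training configuration
#'
#' @param total_steps Number of backpropagation steps.
#' @param peak_lr Peak learning rate of the warmup-cosine schedule.
#' @param weight_decay Decoupled weight decay coefficient.
#' @param batch_size Minibatch size.
#' @param warmup_fraction Fraction of steps spent in linear warmup.
#' @param seed Integer seed controlling weight init, batch shuffling, mask
#'   draws and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(total_steps, peak_lr = 1e-4, weight_decay = 0.01,
                         batch_size = 64L, warmup_fraction = 0.2, seed = 1L) {
  stopifnot(total_steps >= 1, warmup_fraction > 0, warmup_fraction < 1)
  structure(list(total_steps = as.integer(total_steps), peak_lr = peak_lr,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 warmup_fraction = warmup_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given step
#'
#' Linear ramp from `peak_lr / warmup_steps` at step 1 up to `peak_lr` at
#' step `ceiling(warmup_fraction * total_steps)`, then cosine decay to zero
#' at the final step, without restarts.
#'
#' @param step Optimizer step, 1-based, in `[1, total_steps]`.
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @export
lr_at <- function(step, cfg) {
  if (step < 1 || step > cfg$total_steps) {
    stop("step must be in [1, total_steps]", call. = FALSE)
  }
  warmup <- ceiling(cfg$warmup_fraction * cfg$total_steps)
  if (step <= warmup) {
    cfg$peak_lr * step / warmup
  } else {
    prog <- (step - warmup) / (cfg$total_steps - warmup)
    cfg$peak_lr * 0.5 * (1 + cos(pi * prog))
  }
}

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, opt, lr, weight_decay,
                       trainable = names(params),
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in trainable) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           weight_decay * params[[nm]])
  }
  list(params = params, opt = opt)
}

# ---- token assembly ---------------------------------------------------------

# rows of the token matrix belonging to windows idx (token-fastest layout)
cache_rows <- function(idx, Tn) rep((idx - 1L) * Tn, each = Tn) + seq_len(Tn)

# Raw patch tokens for a batch of windows: returns (B*T) x P matrix with rows
# token-fastest, plus a (B*T) x P weight matrix of valid (non-padded) entries.
batch_tokens <- function(arr, valid_length, patch_length, n_axes) {
  d <- dim(arr)
  Tn <- d[2] %/% patch_length
  P <- patch_length * n_axes
  tok <- batch_slice(arr, patch_length)        # B x T x P
  M <- aperm(tok, c(2, 1, 3))
  dim(M) <- c(Tn * d[1], P)
  # entry j of a token covers sample (j-1) %/% n_axes + 1 within the patch
  W <- matrix(1, Tn * d[1], P)
  short <- which(valid_length < d[2])
  for (b in short) {
    v <- valid_length[b]
    rows_tok <- (b - 1L) * Tn + seq_len(Tn)
    sample_of_entry <- rep(seq_len(patch_length), each = n_axes)
    for (t in seq_len(Tn)) {
      abs_sample <- (t - 1L) * patch_length + sample_of_entry
      W[rows_tok[t], ] <- as.numeric(abs_sample <= v)
    }
  }
  list(M = M, W = W, B = d[1], Tn = Tn, P = P)
}

substitute_batch <- function(arr, state, present) {
  omitted <- setdiff(sensor_names(), present)
  if (length(omitted) == 0L) return(arr)
  pl <- state$config$patch_length
  L <- dim(arr)[2]
  n_tiles <- L %/% pl
  for (s in omitted) {
    patch <- state$params[[paste0("subst_", s)]]
    block <- matrix(patch, pl, 6L, byrow = TRUE)
    tile <- block[rep(seq_len(pl), n_tiles), , drop = FALSE]
    cols <- sensor_columns(s)
    for (j in seq_len(6)) {
      arr[, , cols[j]] <- matrix(tile[, j], dim(arr)[1], L, byrow = TRUE)
    }
  }
  arr
}

# ---- SSL objective ----------------------------------------------------------

# Masked-patch reconstruction loss (and gradients) on one batch of cached
# tokens. M0/W: (B*T) x P token and valid-entry-weight matrices; masks: list
# of masked patch index vectors, one per window.
ssl_batch <- function(state, M0, W, B, masks, training = TRUE,
                      compute_grads = TRUE) {
  cfg <- state$config
  Tn <- n_patches_of(cfg)
  P <- patch_dim_of(cfg)
  masked_rows <- rep((seq_len(B) - 1L) * Tn,
                     times = lengths(masks)) + unlist(masks)
  Min <- M0
  Min[masked_rows, ] <- matrix(state$params$mask_patch, length(masked_rows),
                               P, byrow = TRUE)
  Wm <- matrix(0, nrow(M0), P)
  Wm[masked_rows, ] <- W[masked_rows, ]
  fw <- encoder_forward(state$params, cfg, Min, B = B, training = training,
                        keep_cache = compute_grads)
  R <- add_bias(fw$H %*% state$params$recon_W, state$params$recon_b)
  denom <- sum(Wm)
  diff <- R - M0
  loss <- sum(Wm * diff^2) / denom
  if (!compute_grads) return(list(loss = loss))
  dR <- 2 * Wm * diff / denom
  grads <- list(recon_W = crossprod(fw$H, dR), recon_b = colSums(dR))
  bw <- encoder_backward(state$params, cfg, fw$cache,
                         tcrossprod(dR, state$params$recon_W))
  grads <- c(grads, bw$grads)
  grads$mask_patch <- colSums(bw$dX_tok[masked_rows, , drop = FALSE])
  list(loss = loss, grads = grads)
}

#' Masked-reconstruction loss on a window set
#'
#' Evaluates the masked-patch mean squared error of a model on every window,
#' without updating weights: for each window a mask is drawn (seeded),
#' masked patches are replaced by the trainable mask patch, and the MSE
#' between reconstruction and the unmasked input is averaged over exactly the
#' masked-patch entries.
#'
#' @param state A `model_state`.
#' @param ws A normalized [window_set()].
#' @param ratio Masking ratio; defaults to the model configuration's.
#' @param seed Seed for the mask draws.
#' @param masks Optional explicit list of masked patch indices per window
#'   (overrides `ratio`/`seed`).
#' @return Mean loss over windows (scalar).
#' @export
masked_recon_loss <- function(state, ws, ratio = NULL, seed = 1L,
                              masks = NULL) {
  cfg <- state$config
  if (is.null(ratio)) ratio <- cfg$masking_ratio
  Tn <- n_patches_of(cfg)
  n <- n_windows(ws)
  if (is.null(masks)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    masks <- lapply(seq_len(n), function(i) sample_mask(Tn, ratio))
  }
  tc <- batch_tokens(ws$data, ws$meta$valid_length, cfg$patch_length,
                     cfg$n_axes)
  total <- 0; wsum <- 0
  chunk <- 64L
  for (lo in seq(1L, n, by = chunk)) {
    idx <- lo:min(n, lo + chunk - 1L)
    rows <- cache_rows(idx, Tn)
    res <- ssl_batch(state, tc$M[rows, , drop = FALSE],
                     tc$W[rows, , drop = FALSE], length(idx), masks[idx],
                     training = FALSE, compute_grads = FALSE)
    total <- total + res$loss * length(idx)
    wsum <- wsum + length(idx)
  }
  total / wsum
}

next_batch <- function(env, n, batch_size) {
  # shuffled without replacement per epoch, reshuffled each epoch
  if (length(env$queue) < batch_size) {
    env$queue <- c(env$queue, sample.int(n))
  }
  idx <- env$queue[seq_len(min(batch_size, n))]
  env$queue <- env$queue[-seq_len(min(batch_size, n))]
  idx
}

#' Masked-patch self-supervised pre-training
#'
#' Each step samples a minibatch, draws a fresh random mask per window,
#' replaces masked patches with the trainable mask patch, and minimizes the
#' MSE between the reconstruction and the unmasked input over the masked
#' patches only, with AdamW under the warmup-cosine schedule. Padded rows are
#' excluded from the loss.
#'
#' @param corpus A normalized [window_set()] (no labels needed).
#' @param model_cfg A [model_config()].
#' @param cfg A [train_config()].
#' @return A list of class `grf_pretrain_fit` with `state` and
#'   `loss_history` (length `total_steps`).
#' @export
pretrain_ssl <- function(corpus, model_cfg, cfg) {
  n <- n_windows(corpus)
  if (n == 0L) stop("pre-training corpus is empty", call. = FALSE)
  Tn <- n_patches_of(model_cfg)
  k <- round(model_cfg$masking_ratio * Tn)
  if (k < 1) stop("masking ratio rounds to zero patches", call. = FALSE)
  state <- init_model(model_cfg, seed = cfg$seed)
  tc <- batch_tokens(corpus$data, corpus$meta$valid_length,
                     model_cfg$patch_length, model_cfg$n_axes)
  set.seed(cfg$seed)
  opt <- adamw_init(state$params)
  env <- new.env(); env$queue <- integer(0)
  history <- numeric(cfg$total_steps)
  for (step in seq_len(cfg$total_steps)) {
    idx <- next_batch(env, n, cfg$batch_size)
    masks <- lapply(idx, function(i) sample_mask(Tn, model_cfg$masking_ratio))
    rows <- cache_rows(idx, Tn)
    res <- ssl_batch(state, tc$M[rows, , drop = FALSE],
                     tc$W[rows, , drop = FALSE], length(idx), masks,
                     training = TRUE)
    upd <- adamw_step(state$params, res$grads, opt, lr_at(step, cfg),
                      cfg$weight_decay)
    state$params <- upd$params; opt <- upd$opt
    history[step] <- res$loss
  }
  structure(list(state = state, loss_history = history, objective = "ssl"),
            class = "grf_pretrain_fit")
}

# ---- supervised objectives --------------------------------------------------

# token-space entry indices of a sensor's six columns, ordered to match the
# substitution-patch layout (sample-major, axes fastest)
subst_entries <- function(sensor, patch_length, n_axes) {
  cols <- sensor_columns(sensor)
  as.vector(vapply(seq_len(patch_length), function(r) {
    (r - 1L) * n_axes + cols
  }, integer(6)))
}

# overwrite omitted-sensor entries of a token matrix with the (tiled)
# substitution patches
substitute_tokens <- function(M, state, present) {
  omitted <- setdiff(sensor_names(), present)
  cfg <- state$config
  for (s in omitted) {
    e <- subst_entries(s, cfg$patch_length, cfg$n_axes)
    M[, e] <- matrix(state$params[[paste0("subst_", s)]], nrow(M),
                     length(e), byrow = TRUE)
  }
  M
}

# Per-patch regression loss on all (valid) samples; used by supervised
# pre-training and fine-tuning. Min: (B*T) x P input tokens (already
# substituted); Y / WY: target tokens and their valid-entry weights.
supervised_batch <- function(state, Min, Y, WY, B, present = sensor_names(),
                             training = TRUE, compute_grads = TRUE,
                             trainable = names(state$params)) {
  cfg <- state$config
  fw <- encoder_forward(state$params, cfg, Min, B = B,
                        training = training, keep_cache = compute_grads)
  G <- add_bias(fw$H %*% state$params$grf_W, state$params$grf_b)
  denom <- sum(WY)
  diff <- G - Y
  loss <- sum(WY * diff^2) / denom
  if (!compute_grads) return(list(loss = loss))
  dG <- 2 * WY * diff / denom
  grads <- list(grf_W = crossprod(fw$H, dG), grf_b = colSums(dG))
  need_encoder <- !all(trainable %in% c("grf_W", "grf_b"))
  if (need_encoder) {
    bw <- encoder_backward(state$params, cfg, fw$cache,
                           tcrossprod(dG, state$params$grf_W))
    grads <- c(grads, bw$grads)
    omitted <- setdiff(sensor_names(), present)
    for (s in omitted) {
      e <- subst_entries(s, cfg$patch_length, cfg$n_axes)
      grads[[paste0("subst_", s)]] <- colSums(bw$dX_tok)[e]
    }
  }
  list(loss = loss, grads = grads)
}

#' Supervised transfer pre-training
#'
#' Pre-trains the same encoder with a per-patch linear regression head and
#' MSE on all samples (no masking): motion transfer uses real IMU input with
#' 3-axis GRF targets; task transfer uses synthetic IMU input with 3-axis
#' body-centre acceleration targets.
#'
#' @param corpus A normalized [window_set()].
#' @param targets `n` x `window_length` x `head_dim` array of per-sample
#'   targets aligned with the windows; defaults to the corpus GRF labels.
#' @param model_cfg A [model_config()].
#' @param cfg A [train_config()].
#' @param head_dim Output dimension per time step.
#' @return A `grf_pretrain_fit` (state + loss history).
#' @export
pretrain_supervised <- function(corpus, model_cfg, cfg, targets = NULL,
                                head_dim = 3L) {
  n <- n_windows(corpus)
  if (n == 0L) stop("pre-training corpus is empty", call. = FALSE)
  if (is.null(targets)) targets <- corpus$grf
  if (is.null(targets)) stop("no targets supplied and corpus is unlabeled",
                             call. = FALSE)
  if (dim(targets)[1] != n || dim(targets)[2] != corpus$window_length) {
    stop("targets are not aligned with the windows", call. = FALSE)
  }
  state <- init_model(model_cfg, seed = cfg$seed, include_grf_head = TRUE,
                      grf_head_dim = head_dim)
  Tn <- n_patches_of(model_cfg)
  tc <- batch_tokens(corpus$data, corpus$meta$valid_length,
                     model_cfg$patch_length, model_cfg$n_axes)
  ty <- batch_tokens(targets, corpus$meta$valid_length,
                     model_cfg$patch_length, head_dim)
  set.seed(cfg$seed)
  opt <- adamw_init(state$params)
  env <- new.env(); env$queue <- integer(0)
  history <- numeric(cfg$total_steps)
  for (step in seq_len(cfg$total_steps)) {
    idx <- next_batch(env, n, cfg$batch_size)
    rows <- cache_rows(idx, Tn)
    res <- supervised_batch(state, tc$M[rows, , drop = FALSE],
                            ty$M[rows, , drop = FALSE],
                            ty$W[rows, , drop = FALSE], length(idx),
                            training = TRUE)
    upd <- adamw_step(state$params, res$grads, opt, lr_at(step, cfg),
                      cfg$weight_decay)
    state$params <- upd$params; opt <- upd$opt
    history[step] <- res$loss
  }
  structure(list(state = state, loss_history = history,
                 objective = "supervised"),
            class = "grf_pretrain_fit")
}

encoder_param_names <- function(state) {
  nm <- names(state$params)
  nm[!grepl("^(grf_|recon_|subst_)", nm) & nm != "mask_patch"]
}

#' Two-step fine-tuning for GRF estimation
#'
#' Re-initializes the per-patch GRF head, then (step 1) trains only that head
#' with the encoder frozen, and (step 2) fine-tunes the entire model. Both
#' steps use AdamW with the warmup-cosine schedule and MSE on all valid
#' samples; no masking is applied.
#'
#' @param state A `model_state` from pre-training, or a freshly initialized
#'   one for the no-pre-training baseline.
#' @param labeled A normalized [window_set()] carrying GRF labels (statistics
#'   fitted on this training fold).
#' @param cfg1 [train_config()] for the head-only step (default: lr 1e-3,
#'   300 steps).
#' @param cfg2 [train_config()] for the full-model step (default: lr 1e-4,
#'   300 steps).
#' @param present Character vector of present sensors; omitted sensors are
#'   substituted with trainable data patches.
#' @return A list of class `grf_finetune_fit` with `state`, `state_step1`
#'   (the model after the head-only step, for freeze verification),
#'   `loss_history` (both steps concatenated) and `present`.
#' @export
finetune_two_step <- function(state, labeled,
                              cfg1 = train_config(300L, peak_lr = 1e-3),
                              cfg2 = train_config(300L, peak_lr = 1e-4),
                              present = sensor_names()) {
  n <- n_windows(labeled)
  if (n == 0L) stop("no labeled windows", call. = FALSE)
  if (is.null(labeled$grf)) {
    stop("fine-tuning requires GRF labels on every window", call. = FALSE)
  }
  cfg <- state$config
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg1$seed)
  # fresh per-patch GRF head (the SSL reconstruction head has a different
  # output dimension)
  state$params$grf_W <- kaiming_uniform(c(cfg$embed_dim, 3L * cfg$patch_length))
  state$params$grf_b <- rep(0, 3L * cfg$patch_length)
  omitted <- setdiff(sensor_names(), present)
  for (s in omitted) {
    nm <- paste0("subst_", s)
    if (is.null(state$params[[nm]])) {
      state$params[[nm]] <- stats::rnorm(6L * cfg$patch_length, 0, 0.02)
    }
  }
  state$substituted_sensors <- omitted
  Tn <- n_patches_of(cfg)
  tc <- batch_tokens(labeled$data, labeled$meta$valid_length,
                     cfg$patch_length, cfg$n_axes)
  ty <- batch_tokens(labeled$grf, labeled$meta$valid_length,
                     cfg$patch_length, 3L)
  run_step <- function(state, tcfg, trainable) {
    opt <- adamw_init(state$params[trainable])
    env <- new.env(); env$queue <- integer(0)
    history <- numeric(tcfg$total_steps)
    for (step in seq_len(tcfg$total_steps)) {
      idx <- next_batch(env, n, tcfg$batch_size)
      rows <- cache_rows(idx, Tn)
      Min <- substitute_tokens(tc$M[rows, , drop = FALSE], state, present)
      res <- supervised_batch(state, Min, ty$M[rows, , drop = FALSE],
                              ty$W[rows, , drop = FALSE], length(idx),
                              present = present, training = TRUE,
                              trainable = trainable)
      sub <- state$params[trainable]
      upd <- adamw_step(sub, res$grads[trainable], opt, lr_at(step, tcfg),
                        tcfg$weight_decay)
      state$params[trainable] <- upd$params; opt <- upd$opt
      history[step] <- res$loss
    }
    list(state = state, history = history)
  }
  head_names <- c("grf_W", "grf_b")
  s1 <- run_step(state, cfg1, head_names)
  set.seed(cfg2$seed + 1L)
  s2 <- run_step(s1$state, cfg2, names(s1$state$params))
  structure(list(state = s2$state, state_step1 = s1$state,
                 loss_history = c(s1$history, s2$history),
                 n_step1 = cfg1$total_steps, present = present),
            class = "grf_finetune_fit")
}

#' Predict GRF for every window in a set
#'
#' Runs the model in evaluation mode (dropout off) on each window; omitted
#' sensors are substituted with the model's trainable data patches. When
#' normalization statistics are supplied, predictions are returned in N/kg.
#'
#' @param state A fine-tuned `model_state` with a GRF head.
#' @param ws A normalized [window_set()].
#' @param stats Optional [fit_normalizer()] statistics for de-normalization.
#' @param present Present sensors.
#' @return `n` x `window_length` x 3 array of GRF predictions.
#' @export
predict_grf_windows <- function(state, ws, stats = NULL,
                                present = sensor_names()) {
  cfg <- state$config
  n <- n_windows(ws)
  out <- array(0, c(n, cfg$window_length, 3L))
  chunk <- 64L
  for (lo in seq(1L, n, by = chunk)) {
    idx <- lo:min(n, lo + chunk - 1L)
    arr <- substitute_batch(ws$data[idx, , , drop = FALSE], state, present)
    bt <- batch_tokens(arr, ws$meta$valid_length[idx], cfg$patch_length,
                       cfg$n_axes)
    H <- encoder_forward(state$params, cfg, bt$M, B = bt$B,
                         training = FALSE)$H
    G <- add_bias(H %*% state$params$grf_W, state$params$grf_b)
    garr <- G
    dim(garr) <- c(bt$Tn, bt$B, 3L * cfg$patch_length)
    garr <- aperm(garr, c(2, 1, 3))            # B x T x (3*pl)
    out[idx, , ] <- batch_unslice(garr, cfg$patch_length, 3L)
  }
  if (!is.null(stats) && !is.null(stats$grf_mean)) {
    for (a in seq_len(3)) {
      out[, , a] <- out[, , a] * stats$grf_sd[a] + stats$grf_mean[a]
    }
  }
  out
}
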