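# Dense forward and backward passes for the patch transformer, written as
# plain matrix algebra. A batch of B windows with T tokens each is carried as
# a (B*T) x D matrix with rows ordered token-fastest (row = (b-1)*T + t), so
# every position-wise operation is a single matrix product; attention runs
# per window and head on T x T score matrices.

add_bias <- function(M, b) M + rep(b, each = nrow(M))

scale_cols <- function(M, g) M * rep(g, each = nrow(M))

softmax_rows <- function(S) {
  n <- nrow(S)
  rowmax <- S[cbind(seq_len(n), max.col(S, ties.method = "first"))]
  E <- exp(S - rowmax)
  E / rowSums(E)
}

ln_forward <- function(X, g, b, eps) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(Y = add_bias(scale_cols(xhat, g), b), xhat = xhat, inv = inv)
}

ln_backward <- function(dY, cache, g) {
  dg <- colSums(dY * cache$xhat)
  db <- colSums(dY)
  dxhat <- scale_cols(dY, g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- (dxhat - m1 - cache$xhat * m2) * cache$inv
  list(dX = dX, dg = dg, db = db)
}

dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

# Forward pass of the encoder on a batch of raw patch tokens.
# X_tok: (B*T) x P matrix of raw (already masked/substituted) patches.
# Returns the final hidden states and, when keep_cache, everything the
# backward pass needs.
encoder_forward <- function(params, cfg, X_tok, B, training = FALSE,
                            keep_cache = FALSE) {
  Tn <- n_patches_of(cfg)
  D <- cfg$embed_dim
  nh <- cfg$n_heads
  dh <- D %/% nh
  p_drop <- if (training) cfg$dropout else 0
  H0 <- add_bias(X_tok %*% params$embed_W, params$embed_b)
  pe <- positional_encoding(Tn, D)
  H <- H0 + pe[rep(seq_len(Tn), B), , drop = FALSE]
  cache <- if (keep_cache) list(X_tok = X_tok, B = B, blocks = vector("list", cfg$n_blocks))
  X <- H
  scale <- 1 / sqrt(dh)
  for (i in seq_len(cfg$n_blocks)) {
    b <- paste0("b", i, "_")
    Q <- add_bias(X %*% params[[paste0(b, "Wq")]], params[[paste0(b, "bq")]])
    K <- add_bias(X %*% params[[paste0(b, "Wk")]], params[[paste0(b, "bk")]])
    V <- add_bias(X %*% params[[paste0(b, "Wv")]], params[[paste0(b, "bv")]])
    A <- matrix(0, nrow(X), D)
    Plist <- if (keep_cache) vector("list", B * nh)
    for (bb in seq_len(B)) {
      rows <- ((bb - 1L) * Tn + 1L):(bb * Tn)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        S <- tcrossprod(Q[rows, cols, drop = FALSE],
                        K[rows, cols, drop = FALSE]) * scale
        Pm <- softmax_rows(S)
        A[rows, cols] <- Pm %*% V[rows, cols, drop = FALSE]
        if (keep_cache) Plist[[(bb - 1L) * nh + h]] <- Pm
      }
    }
    attn <- add_bias(A %*% params[[paste0(b, "Wo")]], params[[paste0(b, "bo")]])
    d1 <- dropout_mask(nrow(X), D, p_drop)
    r1 <- X + if (is.null(d1)) attn else attn * d1
    l1 <- ln_forward(r1, params[[paste0(b, "ln1_g")]],
                     params[[paste0(b, "ln1_b")]], cfg$layer_norm_eps)
    Z <- add_bias(l1$Y %*% params[[paste0(b, "W1")]], params[[paste0(b, "b1")]])
    Ar <- Z * (Z > 0)
    Ff <- add_bias(Ar %*% params[[paste0(b, "W2")]], params[[paste0(b, "b2")]])
    d2 <- dropout_mask(nrow(X), D, p_drop)
    r2 <- l1$Y + if (is.null(d2)) Ff else Ff * d2
    l2 <- ln_forward(r2, params[[paste0(b, "ln2_g")]],
                     params[[paste0(b, "ln2_b")]], cfg$layer_norm_eps)
    if (keep_cache) {
      cache$blocks[[i]] <- list(X = X, Q = Q, K = K, V = V, A = A,
                                Plist = Plist, d1 = d1,
                                l1 = l1[c("xhat", "inv")], Z = Z, Ar = Ar,
                                d2 = d2, l2 = l2[c("xhat", "inv")],
                                Y1 = l1$Y)
    }
    X <- l2$Y
  }
  list(H = X, cache = cache)
}

# Backward pass. dH: gradient at the encoder output. Returns a named list of
# parameter gradients plus dX_tok, the gradient at the raw patch input.
encoder_backward <- function(params, cfg, cache, dH) {
  Tn <- n_patches_of(cfg)
  D <- cfg$embed_dim
  nh <- cfg$n_heads
  dh <- D %/% nh
  B <- cache$B
  scale <- 1 / sqrt(dh)
  grads <- list()
  dX <- dH
  for (i in rev(seq_len(cfg$n_blocks))) {
    b <- paste0("b", i, "_")
    ck <- cache$blocks[[i]]
    l2 <- ln_backward(dX, ck$l2, params[[paste0(b, "ln2_g")]])
    grads[[paste0(b, "ln2_g")]] <- l2$dg
    grads[[paste0(b, "ln2_b")]] <- l2$db
    dr2 <- l2$dX
    dFf <- if (is.null(ck$d2)) dr2 else dr2 * ck$d2
    dY1 <- dr2
    grads[[paste0(b, "W2")]] <- crossprod(ck$Ar, dFf)
    grads[[paste0(b, "b2")]] <- colSums(dFf)
    dAr <- tcrossprod(dFf, params[[paste0(b, "W2")]])
    dZ <- dAr * (ck$Z > 0)
    grads[[paste0(b, "W1")]] <- crossprod(ck$Y1, dZ)
    grads[[paste0(b, "b1")]] <- colSums(dZ)
    dY1 <- dY1 + tcrossprod(dZ, params[[paste0(b, "W1")]])
    l1 <- ln_backward(dY1, ck$l1, params[[paste0(b, "ln1_g")]])
    grads[[paste0(b, "ln1_g")]] <- l1$dg
    grads[[paste0(b, "ln1_b")]] <- l1$db
    dr1 <- l1$dX
    dAttn <- if (is.null(ck$d1)) dr1 else dr1 * ck$d1
    dXblock <- dr1
    grads[[paste0(b, "Wo")]] <- crossprod(ck$A, dAttn)
    grads[[paste0(b, "bo")]] <- colSums(dAttn)
    dA <- tcrossprod(dAttn, params[[paste0(b, "Wo")]])
    dQ <- matrix(0, nrow(dA), D)
    dK <- matrix(0, nrow(dA), D)
    dV <- matrix(0, nrow(dA), D)
    for (bb in seq_len(B)) {
      rows <- ((bb - 1L) * Tn + 1L):(bb * Tn)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        Pm <- ck$Plist[[(bb - 1L) * nh + h]]
        dO <- dA[rows, cols, drop = FALSE]
        Vh <- ck$V[rows, cols, drop = FALSE]
        dV[rows, cols] <- crossprod(Pm, dO)
        dP <- tcrossprod(dO, Vh)
        dS <- Pm * (dP - rowSums(dP * Pm))
        dQ[rows, cols] <- dS %*% ck$K[rows, cols, drop = FALSE] * scale
        dK[rows, cols] <- crossprod(dS, ck$Q[rows, cols, drop = FALSE]) * scale
      }
    }
    grads[[paste0(b, "Wq")]] <- crossprod(ck$X, dQ)
    grads[[paste0(b, "bq")]] <- colSums(dQ)
    grads[[paste0(b, "Wk")]] <- crossprod(ck$X, dK)
    grads[[paste0(b, "bk")]] <- colSums(dK)
    grads[[paste0(b, "Wv")]] <- crossprod(ck$X, dV)
    grads[[paste0(b, "bv")]] <- colSums(dV)
    dXblock <- dXblock + tcrossprod(dQ, params[[paste0(b, "Wq")]]) +
      tcrossprod(dK, params[[paste0(b, "Wk")]]) +
      tcrossprod(dV, params[[paste0(b, "Wv")]])
    dX <- dXblock
  }
  # positional encoding is additive and fixed: gradient passes straight to
  # the embedding output
  grads$embed_W <- crossprod(cache$X_tok, dX)
  grads$embed_b <- colSums(dX)
  dX_tok <- tcrossprod(dX, params$embed_W)
  list(grads = grads, dX_tok = dX_tok)
}

#' Encode a window's patches
#'
#' Runs the patch tokens through the linear embedding, sinusoidal positional
#' encoding, and the encoder blocks. Deterministic when `training = FALSE`
#' (dropout disabled).
#'
#' @param patches `n_patches` x `patch_dim` matrix of raw (possibly masked)
#'   patches.
#' @param state A `model_state`.
#' @param training If TRUE, dropout is active and draws from the current RNG
#'   stream.
#' @return `n_patches` x `embed_dim` matrix of token embeddings.
#' @export
encode <- function(patches, state, training = FALSE) {
  cfg <- state$config
  if (nrow(patches) != n_patches_of(cfg)) {
    stop("expected ", n_patches_of(cfg), " patches, got ", nrow(patches),
         call. = FALSE)
  }
  if (ncol(patches) != patch_dim_of(cfg)) {
    stop("patch dimension mismatch", call. = FALSE)
  }
  encoder_forward(state$params, cfg, patches, B = 1L, training = training)$H
}

#' Reconstruct a window from token embeddings
#'
#' Per-patch linear map back to raw patch size, unsliced to the window shape.
#'
#' @param embeddings `n_patches` x `embed_dim` matrix from [encode()].
#' @param state A `model_state`.
#' @return `window_length` x `n_axes` reconstruction.
#' @export
reconstruct <- function(embeddings, state) {
  cfg <- state$config
  R <- add_bias(embeddings %*% state$params$recon_W, state$params$recon_b)
  unslice_patches(R, cfg$patch_length, cfg$n_axes)
}

#' Predict normalized GRF from token embeddings
#'
#' Per-patch linear map to `3 * patch_length` values, unsliced to a
#' `window_length` x 3 window of normalized GRF. De-normalization via
#' [apply_normalizer()] statistics is the caller's responsibility.
#'
#' @inheritParams reconstruct
#' @return `window_length` x 3 matrix of normalized GRF.
#' @export
predict_grf <- function(embeddings, state) {
  cfg <- state$config
  if (is.null(state$params$grf_W)) {
    stop("model has no GRF head; initialize with include_grf_head = TRUE",
         call. = FALSE)
  }
  G <- add_bias(embeddings %*% state$params$grf_W, state$params$grf_b)
  unslice_patches(G, cfg$patch_length, n_axes = 3L)
}
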