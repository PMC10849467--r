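# The patch-masked transformer: architecture configuration, weight
# initialization and counting, patch slicing, the trainable mask patch,
# sinusoidal positional encoding, and missing-sensor substitution. The
# forward/backward passes live in nn.R.

#' Transformer architecture configuration
#'
#' Defaults are the full-scale architecture: patch length 1, embedding width
#' 192, six post-norm encoder blocks with 8 attention heads, 512 feedforward
#' units, ReLU activation, 10% dropout and layer-norm epsilon 1e-5, over
#' 128-sample windows of 48 IMU axes.
#'
#' @param patch_length Samples per patch; must divide `window_length`.
#' @param masking_ratio Fraction of patches masked during pre-training.
#' @param embed_dim Token embedding width; must be divisible by `n_heads`.
#' @param n_blocks Number of encoder blocks.
#' @param n_heads Attention heads per block.
#' @param ff_dim Feedforward hidden units per block.
#' @param dropout Dropout probability (training only).
#' @param layer_norm_eps Layer normalization epsilon.
#' @param n_axes Input axes (48 = 8 sensors x 6 axes).
#' @param window_length Window length in samples.
#' @return A `model_config` list.
#' @export
model_config <- function(patch_length = 1L, masking_ratio = 0.125,
                         embed_dim = 192L, n_blocks = 6L, n_heads = 8L,
                         ff_dim = 512L, dropout = 0.10,
                         layer_norm_eps = 1e-5, n_axes = 48L,
                         window_length = 128L) {
  cfg <- list(patch_length = as.integer(patch_length),
              masking_ratio = masking_ratio,
              embed_dim = as.integer(embed_dim),
              n_blocks = as.integer(n_blocks),
              n_heads = as.integer(n_heads),
              ff_dim = as.integer(ff_dim),
              dropout = dropout, layer_norm_eps = layer_norm_eps,
              n_axes = as.integer(n_axes),
              window_length = as.integer(window_length))
  if (cfg$window_length %% cfg$patch_length != 0L) {
    stop("window_length must be divisible by patch_length", call. = FALSE)
  }
  if (cfg$embed_dim %% cfg$n_heads != 0L) {
    stop("embed_dim must be divisible by n_heads", call. = FALSE)
  }
  structure(cfg, class = "model_config")
}

#' Small configuration for desk-scale experiments and tests
#'
#' Two blocks of width 64 with 128 feedforward units and 16-token patching —
#' enough capacity to learn the synthetic fixtures in CPU-minutes.
#'
#' @param ... Overrides passed to [model_config()].
#' @return A `model_config`.
#' @export
tiny_model_config <- function(...) {
  args <- utils::modifyList(
    list(patch_length = 8L, masking_ratio = 0.125, embed_dim = 64L,
         n_blocks = 2L, n_heads = 4L, ff_dim = 128L),
    list(...))
  do.call(model_config, args)
}

n_patches_of <- function(cfg) cfg$window_length %/% cfg$patch_length
patch_dim_of <- function(cfg) cfg$patch_length * cfg$n_axes

# Shapes of every trainable tensor, in a fixed order. Used by both
# initialization and parameter counting.
param_shapes <- function(cfg, include_grf_head = FALSE,
                         substituted_sensors = character(0),
                         grf_head_dim = 3L) {
  P <- patch_dim_of(cfg); D <- cfg$embed_dim; Ff <- cfg$ff_dim
  shapes <- list(embed_W = c(P, D), embed_b = D)
  for (i in seq_len(cfg$n_blocks)) {
    b <- paste0("b", i, "_")
    shapes[[paste0(b, "Wq")]] <- c(D, D); shapes[[paste0(b, "bq")]] <- D
    shapes[[paste0(b, "Wk")]] <- c(D, D); shapes[[paste0(b, "bk")]] <- D
    shapes[[paste0(b, "Wv")]] <- c(D, D); shapes[[paste0(b, "bv")]] <- D
    shapes[[paste0(b, "Wo")]] <- c(D, D); shapes[[paste0(b, "bo")]] <- D
    shapes[[paste0(b, "ln1_g")]] <- D; shapes[[paste0(b, "ln1_b")]] <- D
    shapes[[paste0(b, "W1")]] <- c(D, Ff); shapes[[paste0(b, "b1")]] <- Ff
    shapes[[paste0(b, "W2")]] <- c(Ff, D); shapes[[paste0(b, "b2")]] <- D
    shapes[[paste0(b, "ln2_g")]] <- D; shapes[[paste0(b, "ln2_b")]] <- D
  }
  shapes$recon_W <- c(D, P); shapes$recon_b <- P
  shapes$mask_patch <- P
  if (include_grf_head) {
    shapes$grf_W <- c(D, grf_head_dim * cfg$patch_length)
    shapes$grf_b <- grf_head_dim * cfg$patch_length
  }
  for (s in substituted_sensors) {
    shapes[[paste0("subst_", s)]] <- 6L * cfg$patch_length
  }
  shapes
}

kaiming_uniform <- function(shape) {
  # PyTorch nn.Linear default: kaiming uniform with a = sqrt(5), i.e.
  # U(-1/sqrt(fan_in), 1/sqrt(fan_in))
  fan_in <- shape[1]
  bound <- 1 / sqrt(fan_in)
  matrix(stats::runif(prod(shape), -bound, bound), shape[1], shape[2])
}

xavier_uniform <- function(shape) {
  bound <- sqrt(6 / (shape[1] + shape[2]))
  matrix(stats::runif(prod(shape), -bound, bound), shape[1], shape[2])
}

#' Initialize a model state
#'
#' Linear layer weights are drawn Kaiming-uniform, attention projections
#' Xavier-uniform, biases zero; layer-norm gains start at one; the mask patch
#' and any per-sensor substitution patches are small Gaussian draws.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for the weight draws.
#' @param include_grf_head If TRUE, create the per-patch regression head.
#' @param substituted_sensors Sensors whose data will be replaced by trainable
#'   substitution patches (omitted IMUs).
#' @param grf_head_dim Output dimension per time step of the regression head.
#' @return An object of class `model_state` with elements `params` (named
#'   list of tensors) and `config`.
#' @export
init_model <- function(cfg, seed = 1L, include_grf_head = FALSE,
                       substituted_sensors = character(0),
                       grf_head_dim = 3L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shapes <- param_shapes(cfg, include_grf_head, substituted_sensors,
                         grf_head_dim)
  params <- list()
  for (nm in names(shapes)) {
    sh <- shapes[[nm]]
    params[[nm]] <- if (grepl("_W[qkvo]$", nm)) {
      xavier_uniform(sh)
    } else if (nm %in% c("embed_W", "recon_W", "grf_W") ||
               grepl("_W[12]$", nm)) {
      kaiming_uniform(sh)
    } else if (grepl("ln[12]_g$", nm)) {
      rep(1, sh)
    } else if (nm == "mask_patch" || grepl("^subst_", nm)) {
      stats::rnorm(sh, 0, 0.02)
    } else {
      # biases and layer-norm offsets
      if (length(sh) == 1L) rep(0, sh) else matrix(0, sh[1], sh[2])
    }
  }
  structure(list(params = params, config = cfg,
                 substituted_sensors = substituted_sensors),
            class = "model_state")
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars for a configuration: patch embedding,
#' encoder blocks (attention, layer norms, feedforward), reconstruction head,
#' mask patch, and optionally the GRF head and substitution patches. The
#' positional encoding is fixed and not counted.
#'
#' @inheritParams init_model
#' @return Integer scalar count.
#' @export
count_parameters <- function(cfg, include_grf_head = FALSE,
                             substituted_sensors = character(0),
                             grf_head_dim = 3L) {
  shapes <- param_shapes(cfg, include_grf_head, substituted_sensors,
                         grf_head_dim)
  sum(vapply(shapes, prod, numeric(1)))
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf(
    "<model_state> patch %d, width %d, %d blocks, %d heads, ff %d: %s parameters\n",
    x$config$patch_length, x$config$embed_dim, x$config$n_blocks,
    x$config$n_heads, x$config$ff_dim,
    format(sum(vapply(x$params, length, 1L)), big.mark = ",")))
  invisible(x)
}

#' Slice a window into flattened patches
#'
#' Patch `i` (1-based) holds window rows `[(i-1)*L + 1, i*L]` flattened
#' row-major (sample-major, axes fastest). `unslice_patches()` inverts the
#' operation bit-exactly.
#'
#' @param window Numeric matrix `window_length` x `n_axes`.
#' @param patch_length Samples per patch; must divide the window length.
#' @return `n_patches` x `patch_length * n_axes` matrix.
#' @export
slice_patches <- function(window, patch_length) {
  L <- nrow(window); C <- ncol(window)
  if (L %% patch_length != 0L) {
    stop("window length must be divisible by the patch length", call. = FALSE)
  }
  n_patches <- L %/% patch_length
  # row-major flatten of each patch block
  m <- t(window)                      # C x L, element (c, r)
  dim(m) <- c(C * patch_length, n_patches)
  t(m)
}

#' @rdname slice_patches
#' @param patches `n_patches` x `patch_length * n_axes` matrix.
#' @param n_axes Number of axes in the original window.
#' @return `unslice_patches()`: the `window_length` x `n_axes` window.
#' @export
unslice_patches <- function(patches, patch_length, n_axes = 48L) {
  n_patches <- nrow(patches)
  m <- t(patches)                     # (n_axes * patch_length) x n_patches
  dim(m) <- c(n_axes, patch_length * n_patches)
  t(m)
}

# Batched versions operating on B x L x C arrays <-> B x T x P arrays.
batch_slice <- function(arr, patch_length) {
  d <- dim(arr)  # B, L, C
  Tn <- d[2] %/% patch_length
  m <- aperm(arr, c(3, 2, 1))              # C, L, B
  dim(m) <- c(d[3] * patch_length, Tn, d[1])
  aperm(m, c(3, 2, 1))                     # B, T, P
}

batch_unslice <- function(parr, patch_length, n_axes) {
  d <- dim(parr)  # B, T, P
  m <- aperm(parr, c(3, 2, 1))             # P, T, B
  dim(m) <- c(n_axes, patch_length * d[2], d[1])
  aperm(m, c(3, 2, 1))                     # B, L, C
}

#' Sample a random patch mask
#'
#' Draws exactly `round(ratio * n_patches)` distinct patch indices uniformly
#' without replacement.
#'
#' @param n_patches Number of patches in the window.
#' @param ratio Masking ratio in (0, 1).
#' @param seed Optional integer seed for a reproducible draw; when NULL the
#'   current RNG stream is used (fresh mask per call).
#' @return Sorted integer vector of 1-based masked patch indices.
#' @export
sample_mask <- function(n_patches, ratio, seed = NULL) {
  stopifnot(ratio > 0, ratio < 1)
  k <- round(ratio * n_patches)
  if (k < 1) {
    stop("masking ratio ", ratio, " rounds to zero masked patches for ",
         n_patches, " patches", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  sort(sample.int(n_patches, k))
}

#' Replace masked patches with the trainable mask patch
#'
#' Replacement happens in raw patch space, before the linear embedding; the
#' mask patch is shared across positions.
#'
#' @param patches `n_patches` x `patch_dim` matrix.
#' @param indices 1-based indices of patches to mask.
#' @param mask_patch Numeric vector of length `patch_dim`.
#' @return The masked patch matrix.
#' @export
apply_mask <- function(patches, indices, mask_patch) {
  if (length(indices) == 0L) return(patches)
  if (any(indices < 1L | indices > nrow(patches))) {
    stop("mask index out of range", call. = FALSE)
  }
  patches[indices, ] <- matrix(mask_patch, length(indices),
                               length(mask_patch), byrow = TRUE)
  patches
}

#' Sinusoidal positional encoding
#'
#' The fixed encoding of Vaswani et al.: for 0-based position `pos` and
#' channel pair `2i`, `sin(pos / 10000^(2i/D))` and the matching cosine.
#'
#' @param n_positions Number of token positions.
#' @param dim Embedding width.
#' @return `n_positions` x `dim` matrix.
#' @export
positional_encoding <- function(n_positions, dim) {
  pos <- 0:(n_positions - 1)
  k <- 0:(dim - 1)
  rate <- 10000^(-(2 * (k %/% 2)) / dim)
  angle <- outer(pos, rate)
  pe <- matrix(0, n_positions, dim)
  even <- which(k %% 2 == 0)  # 0-based even channels -> sine
  odd <- which(k %% 2 == 1)
  pe[, even] <- sin(angle[, even])
  pe[, odd] <- cos(angle[, odd])
  pe
}

#' Substitute omitted sensors with trainable data patches
#'
#' Replaces the six columns of every omitted sensor, in each time patch, by
#' that sensor's trainable substitution patch tiled over time. Present-sensor
#' columns are untouched.
#'
#' @param window `window_length` x 48 matrix (normalized space).
#' @param present Character vector of present sensor names (at least one).
#' @param state A `model_state` holding `subst_<sensor>` patches for every
#'   omitted sensor.
#' @return The window with omitted-sensor columns substituted.
#' @export
substitute_missing <- function(window, present, state) {
  nm <- sensor_names()
  if (!all(present %in% nm)) {
    stop("unknown sensor in present set", call. = FALSE)
  }
  if (length(present) == 0L) stop("at least one sensor must be present",
                                  call. = FALSE)
  omitted <- setdiff(nm, present)
  pl <- state$config$patch_length
  n_tiles <- nrow(window) %/% pl
  for (s in omitted) {
    patch <- state$params[[paste0("subst_", s)]]
    if (is.null(patch)) {
      stop("model has no substitution patch for omitted sensor '", s, "'",
           call. = FALSE)
    }
    block <- matrix(patch, pl, 6L, byrow = TRUE)  # row-major: sample-major
    window[, sensor_columns(s)] <-
      block[rep(seq_len(pl), n_tiles), , drop = FALSE]
  }
  window
}
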