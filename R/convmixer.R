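#' ConvMixer for sEMG windows
#'
#' A from-scratch implementation of the ConvMixer architecture applied to
#' 4 x N sEMG windows, treated as a single-plane image. The patch embedding
#' is a 2-D convolution whose kernel spans all electrode channels (height 4)
#' and `patch_size` time samples, with stride equal to the kernel, so the
#' window is tiled into `floor(N / patch_size)` non-overlapping patches of
#' `hidden_dim`-dimensional embeddings. Each mixer block applies a depthwise
#' convolution along the patch axis (groups = hidden_dim, same padding, with
#' a residual connection around the stage) followed by a pointwise (1 x 1)
#' channel-mixing convolution; every convolution is followed by GELU
#' activation and batch normalisation. A global average pool over patch
#' positions feeds a linear classifier, optionally after concatenating the
#' standardised 16-dimensional handcrafted feature vector (late fusion).
#'
#' @name convmixer
NULL

#' ConvMixer model configuration
#'
#' @param n_classes number of output classes K (>= 2).
#' @param hidden_dim embedding width h.
#' @param depth number of mixer blocks.
#' @param kernel_size depthwise kernel extent (odd).
#' @param patch_size patch length p in samples; must leave at least 4
#'   patches, i.e. `floor(n_samples / p) >= 4`.
#' @param fusion_mode `"none"` or `"late_concat"` (concatenate the
#'   handcrafted feature vector with the pooled embedding).
#' @param n_channels,n_samples input window geometry.
#' @param n_features length of the handcrafted feature vector.
#' @param bn_epsilon batch-norm epsilon.
#' @param bn_momentum running-statistics update rate.
#' @param residual keep the residual connection around the depthwise stage.
#' @param epochs,batch_size,learning_rate training schedule (Adam).
#' @param seed integer seed controlling weight init and batch shuffling.
#' @return a `convmixer_config` list.
#' @export
convmixer_config <- function(n_classes,
                             hidden_dim = 64, depth = 4,
                             kernel_size = 9, patch_size = 13,
                             fusion_mode = c("none", "late_concat"),
                             n_channels = 4, n_samples = 481,
                             n_features = 16,
                             bn_epsilon = 1e-5, bn_momentum = 0.1,
                             residual = TRUE,
                             epochs = 50, batch_size = 32,
                             learning_rate = 1e-3, seed = 1L) {
  fusion_mode <- match.arg(fusion_mode)
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  if (kernel_size %% 2 == 0) stop("kernel_size must be odd", call. = FALSE)
  if (min(hidden_dim, depth, patch_size, n_channels, n_samples) < 1) {
    stop("all size parameters must be >= 1", call. = FALSE)
  }
  if (patch_size > n_samples) {
    stop("patch_size (", patch_size, ") exceeds window length (",
         n_samples, ")", call. = FALSE)
  }
  if (n_samples %/% patch_size < 4) {
    stop("patch_size leaves fewer than 4 patches", call. = FALSE)
  }
  if (bn_epsilon <= 0) stop("bn_epsilon must be > 0", call. = FALSE)
  structure(list(n_classes = as.integer(n_classes),
                 hidden_dim = as.integer(hidden_dim),
                 depth = as.integer(depth),
                 kernel_size = as.integer(kernel_size),
                 patch_size = as.integer(patch_size),
                 fusion_mode = fusion_mode,
                 n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 bn_epsilon = bn_epsilon, bn_momentum = bn_momentum,
                 residual = isTRUE(residual),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "convmixer_config")
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

#' Batch normalisation
#'
#' Elementwise per-channel normalisation
#' `(x - mean) / sqrt(var + eps) * gamma + beta`, applied row-wise (rows =
#' channels).
#'
#' @param x numeric matrix, channels x positions.
#' @param mean,var per-channel statistics (length `nrow(x)`); `var >= 0`.
#' @param gamma,beta per-channel scale and shift.
#' @param eps numerical floor added to the variance (> 0).
#' @return normalised matrix, same shape as `x`.
#' @export
batch_normalize <- function(x, mean, var, gamma, beta, eps = 1e-5) {
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  if (any(var < 0)) stop("var must be >= 0", call. = FALSE)
  (x - mean) / sqrt(var + eps) * gamma + beta
}

.bn_new <- function(h) {
  list(gamma = rep(1, h), beta = rep(0, h),
       running_mean = rep(0, h), running_var = rep(1, h))
}

# training-mode batch norm over all columns; returns output + cache
.bn_train <- function(x, bn, eps) {
  m <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  list(y = xhat * bn$gamma + bn$beta, xhat = xhat, inv_sd = inv_sd,
       mu = mu, var = v, m = m)
}

.bn_backward <- function(dy, cache, gamma) {
  m <- cache$m
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * gamma
  dx <- (cache$inv_sd / m) *
    (m * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Initialise ConvMixer weights
#'
#' He-style scaled Gaussian initialisation, deterministic under the config
#' seed.
#'
#' @param config a [convmixer_config()].
#' @return a `convmixer_model` (weights + running batch-norm statistics).
#' @export
init_convmixer <- function(config) {
  h <- config$hidden_dim
  p <- config$patch_size
  k <- config$kernel_size
  fan_patch <- config$n_channels * p
  clf_in <- h + if (config$fusion_mode == "late_concat") config$n_features else 0L
  withr::with_seed(config$seed, {
    w <- list(
      patch_w = matrix(stats::rnorm(h * fan_patch, 0, sqrt(2 / fan_patch)),
                       h, fan_patch),
      patch_b = rep(0, h),
      patch_bn = .bn_new(h),
      blocks = lapply(seq_len(config$depth), function(l) list(
        dw_w = matrix(stats::rnorm(h * k, 0, sqrt(2 / k)), h, k),
        dw_b = rep(0, h),
        dw_bn = .bn_new(h),
        pw_w = matrix(stats::rnorm(h * h, 0, sqrt(2 / h)), h, h),
        pw_b = rep(0, h),
        pw_bn = .bn_new(h)
      )),
      clf_w = matrix(stats::rnorm(config$n_classes * clf_in,
                                  0, sqrt(2 / clf_in)),
                     config$n_classes, clf_in),
      clf_b = rep(0, config$n_classes)
    )
  })
  structure(list(config = config, weights = w, trained = FALSE),
            class = "convmixer_model")
}

#' @export
print.convmixer_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("convmixer_model: h=%d, depth=%d, kernel=%d, patch=%d, K=%d, fusion=%s (%s)\n",
              cfg$hidden_dim, cfg$depth, cfg$kernel_size, cfg$patch_size,
              cfg$n_classes, cfg$fusion_mode,
              if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}

# stack windows [nch x N x B] into the patch matrix [nch*p x (P*B)];
# column index = (b-1)*P + t
.patchify <- function(x, p) {
  d <- dim(x)
  P <- d[2] %/% p
  x <- x[, seq_len(P * p), , drop = FALSE]
  dim(x) <- c(d[1] * p, P * d[3])
  attr(x, "P") <- P
  x
}

#' Patch embedding of a single window
#'
#' The raw linear embedding (2-D convolution with kernel = stride =
#' channels x `p`): the window is cut into `floor(N / p)` non-overlapping
#' patches and each is mapped to a `hidden_dim`-vector. In the network this
#' is followed by GELU activation and batch normalisation.
#'
#' @param window channels x N numeric matrix.
#' @param patch_w embedding kernel, `hidden_dim x (channels * p)`.
#' @param patch_b bias vector of length `hidden_dim`.
#' @param p patch size (stride) in samples; `p <= N`.
#' @return `hidden_dim x floor(N / p)` embedding map.
#' @export
patch_embed <- function(window, patch_w, patch_b, p) {
  if (p > ncol(window)) {
    stop("patch size p (", p, ") exceeds window length (", ncol(window), ")",
         call. = FALSE)
  }
  m <- .patchify(array(window, dim = c(dim(window), 1L)), p)
  patch_w %*% m + patch_b
}

# shift the patch axis by delta within each sample's block of P columns,
# zero-filling at the edges
.shift_cols <- function(x, delta, P) {
  if (delta == 0) return(x)
  nc <- ncol(x)
  tcol <- ((seq_len(nc) - 1L) %% P) + 1L
  valid <- tcol + delta >= 1L & tcol + delta <= P
  out <- matrix(0, nrow(x), nc)
  out[, valid] <- x[, which(valid) + delta]
  out
}

# depthwise conv along the patch axis: groups = hidden_dim, same padding
.dwconv <- function(x, dw_w, dw_b, P) {
  k <- ncol(dw_w)
  pad <- (k - 1L) %/% 2L
  out <- matrix(0, nrow(x), ncol(x))
  for (j in seq_len(k)) {
    out <- out + .shift_cols(x, j - pad - 1L, P) * dw_w[, j]
  }
  out + dw_b
}

.dwconv_backward <- function(dout, x, dw_w, P) {
  k <- ncol(dw_w)
  pad <- (k - 1L) %/% 2L
  dx <- matrix(0, nrow(x), ncol(x))
  dw <- matrix(0, nrow(dw_w), k)
  for (j in seq_len(k)) {
    delta <- j - pad - 1L
    dw[, j] <- rowSums(dout * .shift_cols(x, delta, P))
    dx <- dx + .shift_cols(dout, -delta, P) * dw_w[, j]
  }
  list(dx = dx, dw = dw, db = rowSums(dout))
}

# one mixer block forward; x is [h x (P*B)]; training toggles batch-norm mode
.block_forward <- function(x, blk, P, cfg, training = FALSE) {
  cache <- list(x = x)
  d <- .dwconv(x, blk$dw_w, blk$dw_b, P)
  a1 <- gelu(d)
  if (training) {
    bn1 <- .bn_train(a1, blk$dw_bn, cfg$bn_epsilon)
    y1 <- bn1$y
    cache$bn1 <- bn1
  } else {
    y1 <- batch_normalize(a1, blk$dw_bn$running_mean, blk$dw_bn$running_var,
                          blk$dw_bn$gamma, blk$dw_bn$beta, cfg$bn_epsilon)
  }
  y <- if (cfg$residual) y1 + x else y1
  q <- blk$pw_w %*% y + blk$pw_b
  a2 <- gelu(q)
  if (training) {
    bn2 <- .bn_train(a2, blk$pw_bn, cfg$bn_epsilon)
    out <- bn2$y
    cache$bn2 <- bn2
  } else {
    out <- batch_normalize(a2, blk$pw_bn$running_mean, blk$pw_bn$running_var,
                           blk$pw_bn$gamma, blk$pw_bn$beta, cfg$bn_epsilon)
  }
  cache$d <- d
  cache$a1 <- a1
  cache$y <- y
  cache$q <- q
  cache$a2 <- a2
  list(out = out, cache = cache)
}

#' Apply one mixer block to an embedding map
#'
#' Depthwise convolution (same padding) with a residual connection around
#' the stage, GELU and batch normalisation, then a pointwise (1 x 1)
#' convolution, GELU and batch normalisation. Shape is preserved. Batch
#' normalisation uses the block's running statistics (inference mode).
#'
#' @param e `hidden_dim x P` embedding map (one window).
#' @param block block weight list (`dw_w`, `dw_b`, `dw_bn`, `pw_w`, `pw_b`,
#'   `pw_bn`), e.g. from a `convmixer_model`'s `weights$blocks`.
#' @param config the model's [convmixer_config()].
#' @return transformed embedding map, same shape as `e`.
#' @export
mixer_block <- function(e, block, config) {
  if (length(e) == 0) stop("empty embedding map", call. = FALSE)
  .block_forward(e, block, ncol(e), config, training = FALSE)$out
}

# full network forward over a batch.
# x: [nch x N x B]; feats: [n_features x B] or NULL
.forward_batch <- function(model, x, feats = NULL, training = FALSE) {
  cfg <- model$config
  w <- model$weights
  B <- dim(x)[3]
  m <- .patchify(x, cfg$patch_size)
  P <- attr(m, "P")
  e0 <- w$patch_w %*% m + w$patch_b
  a0 <- gelu(e0)
  caches <- list(m = m, e0 = e0, a0 = a0, P = P, B = B)
  if (training) {
    bn0 <- .bn_train(a0, w$patch_bn, cfg$bn_epsilon)
    z <- bn0$y
    caches$bn0 <- bn0
  } else {
    z <- batch_normalize(a0, w$patch_bn$running_mean, w$patch_bn$running_var,
                         w$patch_bn$gamma, w$patch_bn$beta, cfg$bn_epsilon)
  }
  caches$blocks <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    res <- .block_forward(z, w$blocks[[l]], P, cfg, training)
    caches$blocks[[l]] <- res$cache
    z <- res$out
  }
  caches$z_final <- z
  # global average pool over the P patch positions
  zp <- z
  dim(zp) <- c(cfg$hidden_dim, P, B)
  g <- colSums(aperm(zp, c(2, 1, 3))) / P  # [h x B]
  if (cfg$fusion_mode == "late_concat") {
    if (is.null(feats)) {
      stop("fusion_mode 'late_concat' requires a feature matrix", call. = FALSE)
    }
    if (nrow(feats) != cfg$n_features) {
      stop("feature dimension ", nrow(feats), " does not match config (",
           cfg$n_features, ")", call. = FALSE)
    }
    cat_in <- rbind(g, feats)
  } else {
    cat_in <- g
  }
  logits <- w$clf_w %*% cat_in + w$clf_b
  caches$g <- g
  caches$cat_in <- cat_in
  list(logits = logits, caches = caches)
}

.softmax_cols <- function(logits) {
  z <- exp(sweep(logits, 2, apply(logits, 2, max), "-"))
  sweep(z, 2, colSums(z), "/")
}

#' Forward pass of the ConvMixer on windows
#'
#' @param model a `convmixer_model`.
#' @param windows a `window_set`, or a channels x N matrix (single window),
#'   or a channels x N x B array.
#' @param features standardised feature matrix (windows x 16) or vector;
#'   required when `fusion_mode = "late_concat"`, ignored otherwise.
#' @return matrix of logits, windows x K.
#' @export
forward_convmixer <- function(model, windows, features = NULL) {
  stopifnot(inherits(model, "convmixer_model"))
  x <- .as_window_array(windows)
  feats <- .as_feature_cols(features, dim(x)[3], model$config)
  t(.forward_batch(model, x, feats, training = FALSE)$logits)
}

.as_window_array <- function(windows) {
  if (inherits(windows, "window_set")) return(windows$samples)
  if (is.matrix(windows)) return(array(windows, dim = c(dim(windows), 1L)))
  stopifnot(is.array(windows), length(dim(windows)) == 3)
  windows
}

.as_feature_cols <- function(features, B, cfg) {
  if (cfg$fusion_mode != "late_concat") return(NULL)
  if (is.null(features)) {
    stop("fusion_mode 'late_concat' requires features", call. = FALSE)
  }
  f <- if (is.null(dim(features))) matrix(features, ncol = 1) else t(as.matrix(features))
  if (ncol(f) != B) stop("feature rows must match number of windows", call. = FALSE)
  f
}

#' Predict classes and probabilities
#'
#' @inheritParams forward_convmixer
#' @return list with `class` (integer indices 1..K) and `prob`
#'   (windows x K matrix of softmax probabilities, rows summing to 1).
#' @export
predict_convmixer <- function(model, windows, features = NULL) {
  logits <- forward_convmixer(model, windows, features)
  prob <- t(.softmax_cols(t(logits)))
  list(class = max.col(prob, ties.method = "first"), prob = prob)
}

#' Save a ConvMixer model as a single JSON checkpoint
#'
#' The checkpoint stores the config echo, all weights and the running
#' batch-norm statistics as plain JSON, so checkpoints are portable and
#' diffable. Numeric precision is full double precision.
#'
#' @param model a `convmixer_model`.
#' @param path output file path.
#' @export
save_convmixer <- function(model, path) {
  stopifnot(inherits(model, "convmixer_model"))
  encode <- function(x) {
    if (is.numeric(x)) {
      list(dim = if (is.null(dim(x))) length(x) else dim(x),
           data = as.numeric(x))
    } else {
      lapply(x, encode)
    }
  }
  payload <- list(config = unclass(model$config),
                  weights = encode(model$weights),
                  trained = isTRUE(model$trained))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(model)
}

#' Load a ConvMixer checkpoint written by [save_convmixer()]
#' @param path checkpoint path.
#' @return a `convmixer_model`.
#' @export
load_convmixer <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg_fields <- payload$config[names(payload$config) %in%
                                 names(formals(convmixer_config))]
  cfg <- do.call(convmixer_config, cfg_fields)
  decode <- function(x) {
    if (identical(sort(names(x)), c("data", "dim"))) {
      d <- unlist(x$dim)
      v <- as.numeric(unlist(x$data))
      if (length(d) > 1) dim(v) <- d
      v
    } else {
      lapply(x, decode)
    }
  }
  structure(list(config = cfg, weights = decode(payload$weights),
                 trained = isTRUE(payload$trained)),
            class = "convmixer_model")
}
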