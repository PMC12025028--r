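#' Training the ConvMixer (cross-entropy + Adam)
#'
#' Gradients are derived analytically for every stage (patch embedding,
#' depthwise and pointwise convolutions, GELU, batch normalisation, pooling,
#' fusion and classifier) and checked against finite differences in the test
#' suite. Batch normalisation uses batch statistics during training and
#' exponentially updated running statistics at inference.
#'
#' @name convmixer-training
NULL

# full backward pass; returns gradients in the same structure as weights
.backward_batch <- function(model, caches, dlogits) {
  cfg <- model$config
  w <- model$weights
  P <- caches$P
  B <- caches$B
  h <- cfg$hidden_dim
  g <- list()
  g$clf_w <- dlogits %*% t(caches$cat_in)
  g$clf_b <- rowSums(dlogits)
  dcat <- t(w$clf_w) %*% dlogits
  dg <- dcat[seq_len(h), , drop = FALSE]  # feature rows need no gradient
  # un-pool: every patch position shares dg / P
  dz <- matrix(0, h, P * B)
  dz[, ] <- dg[, rep(seq_len(B), each = P)] / P
  g$blocks <- vector("list", cfg$depth)
  for (l in rev(seq_len(cfg$depth))) {
    blk <- w$blocks[[l]]
    cc <- caches$blocks[[l]]
    gb <- list()
    # pointwise bn -> gelu -> conv
    bb2 <- .bn_backward(dz, cc$bn2, blk$pw_bn$gamma)
    gb$pw_bn_gamma <- bb2$dgamma
    gb$pw_bn_beta <- bb2$dbeta
    dq <- bb2$dx * gelu_grad(cc$q)
    gb$pw_w <- dq %*% t(cc$y)
    gb$pw_b <- rowSums(dq)
    dy <- t(blk$pw_w) %*% dq
    # residual split
    bb1 <- .bn_backward(dy, cc$bn1, blk$dw_bn$gamma)
    gb$dw_bn_gamma <- bb1$dgamma
    gb$dw_bn_beta <- bb1$dbeta
    dd <- bb1$dx * gelu_grad(cc$d)
    dwb <- .dwconv_backward(dd, cc$x, blk$dw_w, P)
    gb$dw_w <- dwb$dw
    gb$dw_b <- dwb$db
    dz <- dwb$dx + if (cfg$residual) dy else 0
    g$blocks[[l]] <- gb
  }
  bb0 <- .bn_backward(dz, caches$bn0, w$patch_bn$gamma)
  g$patch_bn_gamma <- bb0$dgamma
  g$patch_bn_beta <- bb0$dbeta
  de0 <- bb0$dx * gelu_grad(caches$e0)
  g$patch_w <- de0 %*% t(caches$m)
  g$patch_b <- rowSums(de0)
  g
}

# flatten weights/grads to named numeric lists for the optimiser
.trainable_refs <- function(depth) {
  refs <- list(list("patch_w"), list("patch_b"),
               list("patch_bn", "gamma"), list("patch_bn", "beta"),
               list("clf_w"), list("clf_b"))
  for (l in seq_len(depth)) {
    for (nm in c("dw_w", "dw_b", "pw_w", "pw_b")) {
      refs <- c(refs, list(list("blocks", l, nm)))
    }
    for (nm in c("dw_bn", "pw_bn")) {
      refs <- c(refs, list(list("blocks", l, nm, "gamma"),
                           list("blocks", l, nm, "beta")))
    }
  }
  refs
}

.get_ref <- function(x, ref) {
  for (k in ref) x <- x[[k]]
  x
}

.set_ref <- function(x, ref, value) {
  if (length(ref) == 1) {
    x[[ref[[1]]]] <- value
  } else {
    x[[ref[[1]]]] <- .set_ref(x[[ref[[1]]]], ref[-1], value)
  }
  x
}

# gradient structure uses flattened names for bn params
.grad_ref <- function(ref) {
  n <- length(ref)
  if (n >= 2 && ref[[n - 1]] %in% c("patch_bn", "dw_bn", "pw_bn")) {
    c(ref[-c(n - 1, n)], list(paste0(ref[[n - 1]], "_", ref[[n]])))
  } else ref
}

.adam_init <- function(weights, refs) {
  lapply(refs, function(r) {
    w <- .get_ref(weights, r)
    list(m = w * 0, v = w * 0)
  })
}

.adam_step <- function(model, grads, opt, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  refs <- opt$refs
  for (i in seq_along(refs)) {
    r <- refs[[i]]
    gref <- .grad_ref(r)
    gr <- .get_ref(grads, gref)
    st <- opt$state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * gr
    st$v <- beta2 * st$v + (1 - beta2) * gr^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    wcur <- .get_ref(model$weights, r)
    model$weights <- .set_ref(model$weights, r,
                              wcur - lr * mhat / (sqrt(vhat) + eps))
    opt$state[[i]] <- st
  }
  list(model = model, opt = opt)
}

# update running bn stats from the training caches
.update_running <- function(model, caches) {
  mom <- model$config$bn_momentum
  upd <- function(bn, cache) {
    bn$running_mean <- (1 - mom) * bn$running_mean + mom * cache$mu
    bn$running_var <- (1 - mom) * bn$running_var + mom * cache$var
    bn
  }
  model$weights$patch_bn <- upd(model$weights$patch_bn, caches$bn0)
  for (l in seq_along(model$weights$blocks)) {
    model$weights$blocks[[l]]$dw_bn <-
      upd(model$weights$blocks[[l]]$dw_bn, caches$blocks[[l]]$bn1)
    model$weights$blocks[[l]]$pw_bn <-
      upd(model$weights$blocks[[l]]$pw_bn, caches$blocks[[l]]$bn2)
  }
  model
}

.xent_grad <- function(logits, y, K) {
  # logits [K x B]; y integer 1..K; returns mean loss and dlogits
  B <- ncol(logits)
  prob <- .softmax_cols(logits)
  idx <- cbind(y, seq_len(B))
  loss <- -mean(log(pmax(t(prob)[cbind(seq_len(B), y)], 1e-12)))
  onehot <- matrix(0, K, B)
  onehot[cbind(y, seq_len(B))] <- 1
  list(loss = loss, dlogits = (prob - onehot) / B)
}

#' Train a ConvMixer on labelled windows
#'
#' Minimises the softmax cross-entropy with Adam over seeded mini-batches.
#' Requires every class in 1..K to be present in the training labels.
#'
#' @param train_windows a `window_set` (or channels x N x B array) of
#'   training windows.
#' @param train_labels integer class indices 1..K, one per training window.
#' @param config a [convmixer_config()].
#' @param train_features standardised feature matrix (windows x 16);
#'   required when `config$fusion_mode == "late_concat"`.
#' @param val_windows,val_labels,val_features optional validation split
#'   (disjoint from training), used for the per-epoch accuracy trace.
#' @param coarsen_to optional granularity level; when the model is trained
#'   at a finer level, validation accuracy is also reported after
#'   probability coarsening to this level (`from_level` must then be given).
#' @param from_level granularity level of the training labels (needed for
#'   `coarsen_to`).
#' @param verbose print one line per epoch.
#' @return the trained `convmixer_model`, with a `report` element holding
#'   per-epoch loss and validation accuracy, the config echo and the seed.
#' @export
train_convmixer <- function(train_windows, train_labels, config,
                            train_features = NULL,
                            val_windows = NULL, val_labels = NULL,
                            val_features = NULL,
                            coarsen_to = NULL, from_level = NULL,
                            verbose = FALSE) {
  x <- .as_window_array(train_windows)
  y <- as.integer(train_labels)
  K <- config$n_classes
  if (length(y) != dim(x)[3]) stop("labels must match windows", call. = FALSE)
  missing_cls <- setdiff(seq_len(K), unique(y))
  if (length(missing_cls)) {
    stop("class(es) ", paste(missing_cls, collapse = ", "),
         " absent from training set", call. = FALSE)
  }
  feats <- .as_feature_cols(train_features, dim(x)[3], config)
  model <- init_convmixer(config)
  refs <- .trainable_refs(config$depth)
  opt <- list(refs = refs, state = .adam_init(model$weights, refs))
  n <- dim(x)[3]
  losses <- numeric(config$epochs)
  val_acc <- rep(NA_real_, config$epochs)
  val_acc_coarse <- rep(NA_real_, config$epochs)
  step <- 0L
  withr::with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        if (length(idx) < 2L) next  # batch statistics need >= 2 columns
        xb <- x[, , idx, drop = FALSE]
        fb <- if (!is.null(feats)) feats[, idx, drop = FALSE] else NULL
        fwd <- .forward_batch(model, xb, fb, training = TRUE)
        ce <- .xent_grad(fwd$logits, y[idx], K)
        grads <- .backward_batch(model, fwd$caches, ce$dlogits)
        step <- step + 1L
        upd <- .adam_step(model, grads, opt, config$learning_rate, step)
        model <- upd$model
        opt <- upd$opt
        model <- .update_running(model, fwd$caches)
        batch_losses <- c(batch_losses, ce$loss)
      }
      losses[epoch] <- mean(batch_losses)
      if (!is.null(val_windows)) {
        pr <- predict_convmixer(model, val_windows, val_features)
        val_acc[epoch] <- mean(pr$class == val_labels)
        if (!is.null(coarsen_to) && !is.null(from_level)) {
          cp <- coarsen_probabilities(pr$prob, from_level, coarsen_to)
          val_acc_coarse[epoch] <-
            mean(max.col(cp, ties.method = "first") ==
                   coarsen(val_labels, from_level, coarsen_to))
        }
      }
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val_acc %s", epoch,
                        losses[epoch],
                        ifelse(is.na(val_acc[epoch]), "-",
                               sprintf("%.4f", val_acc[epoch]))))
      }
    }
  })
  model$trained <- TRUE
  model$report <- list(loss = losses, val_accuracy = val_acc,
                       val_accuracy_coarse = val_acc_coarse,
                       config = config, seed = config$seed)
  model
}

#' Train a small dense classifier on handcrafted features only
#'
#' A one-hidden-layer (GELU) network on the standardised 16-dimensional
#' feature vector, trained with the same Adam/cross-entropy machinery as the
#' ConvMixer. Used by the "features-only" input mode of
#' [compare_settings()].
#'
#' @param train_features standardised feature matrix (rows = windows).
#' @param train_labels integer class indices 1..K.
#' @param n_classes K.
#' @param hidden hidden-layer width.
#' @param epochs,batch_size,learning_rate,seed training schedule.
#' @return a `dense_head` model with a `predict` usable via
#'   [predict_dense_head()].
#' @export
train_dense_head <- function(train_features, train_labels, n_classes,
                             hidden = 32, epochs = 60, batch_size = 32,
                             learning_rate = 1e-2, seed = 1L) {
  X <- t(as.matrix(train_features))  # [d x n]
  y <- as.integer(train_labels)
  d <- nrow(X)
  n <- ncol(X)
  K <- as.integer(n_classes)
  withr::with_seed(as.integer(seed), {
    W1 <- matrix(stats::rnorm(hidden * d, 0, sqrt(2 / d)), hidden, d)
    b1 <- rep(0, hidden)
    W2 <- matrix(stats::rnorm(K * hidden, 0, sqrt(2 / hidden)), K, hidden)
    b2 <- rep(0, K)
    ms <- lapply(list(W1, b1, W2, b2), function(w) list(m = w * 0, v = w * 0))
    step <- 0L
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      for (s0 in seq(1, n, by = batch_size)) {
        idx <- ord[s0:min(s0 + batch_size - 1L, n)]
        xb <- X[, idx, drop = FALSE]
        h1 <- W1 %*% xb + b1
        a1 <- gelu(h1)
        logits <- W2 %*% a1 + b2
        ce <- .xent_grad(logits, y[idx], K)
        dW2 <- ce$dlogits %*% t(a1)
        db2 <- rowSums(ce$dlogits)
        da1 <- t(W2) %*% ce$dlogits * gelu_grad(h1)
        dW1 <- da1 %*% t(xb)
        db1 <- rowSums(da1)
        step <- step + 1L
        adam1 <- function(wst, g) {
          wst$m <- 0.9 * wst$m + 0.1 * g
          wst$v <- 0.999 * wst$v + 0.001 * g^2
          wst
        }
        upd <- function(w, wst) {
          w - learning_rate * (wst$m / (1 - 0.9^step)) /
            (sqrt(wst$v / (1 - 0.999^step)) + 1e-8)
        }
        ms[[1]] <- adam1(ms[[1]], dW1); W1 <- upd(W1, ms[[1]])
        ms[[2]] <- adam1(ms[[2]], db1); b1 <- upd(b1, ms[[2]])
        ms[[3]] <- adam1(ms[[3]], dW2); W2 <- upd(W2, ms[[3]])
        ms[[4]] <- adam1(ms[[4]], db2); b2 <- upd(b2, ms[[4]])
      }
    }
  })
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, n_classes = K),
            class = "dense_head")
}

#' Predict with a dense feature-only head
#' @param model a [train_dense_head()] model.
#' @param features feature matrix (rows = windows), standardised with the
#'   training scaler.
#' @return list with `class` and `prob` as in [predict_convmixer()].
#' @export
predict_dense_head <- function(model, features) {
  X <- t(as.matrix(features))
  logits <- model$W2 %*% gelu(model$W1 %*% X + model$b1) + model$b2
  prob <- t(.softmax_cols(logits))
  list(class = max.col(prob, ties.method = "first"), prob = prob)
}
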