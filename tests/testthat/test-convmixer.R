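make_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_classes = 3, hidden_dim = 6, depth = 2, kernel_size = 3,
         patch_size = 5, n_channels = 2, n_samples = 20, n_features = 4,
         epochs = 2, batch_size = 4, seed = 2),
    list(...))
  do.call(convmixer_config, args)
}

test_that("config validation enforces the architecture contracts", {
  expect_error(make_cfg(kernel_size = 4), "odd")
  expect_error(make_cfg(patch_size = 21), "exceeds")
  expect_error(make_cfg(patch_size = 10), "fewer than 4 patches")
  expect_error(make_cfg(n_classes = 1), ">= 2")
  expect_error(make_cfg(bn_epsilon = 0), "> 0")
})

test_that("patch embedding tiles the window into floor(N/p) positions", {
  cfg <- convmixer_config(n_classes = 13, n_samples = 481, patch_size = 13)
  m <- init_convmixer(cfg)
  w <- matrix(withr::with_seed(41, rnorm(4 * 481)), 4, 481)
  e <- patch_embed(w, m$weights$patch_w, m$weights$patch_b, 13)
  expect_equal(dim(e), c(64L, 37L))  # floor(481 / 13) = 37
  # constant input with an averaging kernel gives a constant map
  const <- matrix(1, 4, 481)
  e2 <- patch_embed(const, m$weights$patch_w, m$weights$patch_b, 13)
  expect_equal(max(apply(e2, 1, function(r) diff(range(r)))), 0)
  expect_error(patch_embed(matrix(0, 4, 10), m$weights$patch_w,
                           m$weights$patch_b, 13), "exceeds")
})

test_that("shape contracts hold across random valid configs", {
  withr::with_seed(42, {
    for (r in 1:10) {
      n_samp <- sample(40:120, 1)
      p <- sample(2:(n_samp %/% 4), 1)
      cfg <- make_cfg(hidden_dim = sample(3:10, 1), depth = sample(1:3, 1),
                      kernel_size = sample(c(3, 5, 7), 1), patch_size = p,
                      n_samples = n_samp, fusion_mode = "none")
      m <- init_convmixer(cfg)
      x <- array(rnorm(2 * n_samp * 3), c(2, n_samp, 3))
      logits <- forward_convmixer(m, x)
      expect_equal(dim(logits), c(3L, cfg$n_classes))
      # mixer block preserves shape
      e <- matrix(rnorm(cfg$hidden_dim * 8), cfg$hidden_dim, 8)
      expect_equal(dim(mixer_block(e, m$weights$blocks[[1]], cfg)), dim(e))
    }
  })
})

test_that("batch_normalize matches the naive elementwise formula", {
  withr::with_seed(43, {
    for (r in 1:20) {
      h <- sample(2:8, 1)
      x <- matrix(rnorm(h * 30), h, 30)
      mu <- rnorm(h); v <- rexp(h); g <- rnorm(h); b <- rnorm(h)
      expect_equal(batch_normalize(x, mu, v, g, b, 1e-5),
                   naive_bn(x, mu, v, g, b, 1e-5), tolerance = 1e-6)
    }
  })
  x <- matrix(withr::with_seed(44, rnorm(12)), 3, 4)
  # identity parameters pass the input through (up to the epsilon factor)
  expect_equal(batch_normalize(x, rep(0, 3), rep(1, 3), rep(1, 3), rep(0, 3),
                               1e-5), x, tolerance = 1e-4)
  # zero scale collapses to the shift
  expect_equal(batch_normalize(x, rep(0, 3), rep(1, 3), rep(0, 3), rep(2, 3)),
               matrix(2, 3, 4))
  expect_error(batch_normalize(x, rep(0, 3), rep(-1, 3), rep(1, 3), rep(0, 3)),
               ">= 0")
})

test_that("depthwise convolution matches a naive per-channel oracle and is channel-local", {
  withr::with_seed(45, {
    for (r in 1:10) {
      h <- sample(2:6, 1); P <- sample(5:12, 1); B <- sample(1:3, 1)
      k <- sample(c(3, 5), 1)
      x <- matrix(rnorm(h * P * B), h, P * B)
      w <- matrix(rnorm(h * k), h, k)
      b <- rnorm(h)
      expect_equal(emgmixer:::.dwconv(x, w, b, P), naive_dwconv(x, w, b, P),
                   tolerance = 1e-9)
      # perturbing channel j changes only channel j of the output
      j <- sample(h, 1)
      x2 <- x
      x2[j, ] <- x2[j, ] + rnorm(P * B)
      d <- emgmixer:::.dwconv(x2, w, b, P) - emgmixer:::.dwconv(x, w, b, P)
      expect_true(all(d[-j, ] == 0))
      expect_true(any(d[j, ] != 0))
    }
  })
})

test_that("pointwise stage equals a direct 1x1 convolution", {
  cfg <- make_cfg(depth = 1)
  m <- init_convmixer(cfg)
  blk <- m$weights$blocks[[1]]
  y <- matrix(withr::with_seed(46, rnorm(cfg$hidden_dim * 8)),
              cfg$hidden_dim, 8)
  # naive: each output position is W %*% column + b
  naive <- sapply(seq_len(8), function(t) blk$pw_w %*% y[, t] + blk$pw_b)
  expect_equal(blk$pw_w %*% y + blk$pw_b, naive, tolerance = 1e-12)
})

test_that("zeroed depthwise weights with identity norm make the stage a residual identity", {
  cfg <- make_cfg(depth = 1)
  m <- init_convmixer(cfg)
  blk <- m$weights$blocks[[1]]
  blk$dw_w[] <- 0
  blk$dw_b[] <- 0
  # running stats are still (0, 1) and gamma/beta (1, 0): inference BN of
  # gelu(0) = 0 stays 0, so the depthwise stage output equals its input
  x <- matrix(withr::with_seed(47, rnorm(cfg$hidden_dim * 10)),
              cfg$hidden_dim, 10)
  d <- emgmixer:::.dwconv(x, blk$dw_w, blk$dw_b, 10)
  bn <- batch_normalize(gelu_out <- emgmixer:::gelu(d), blk$dw_bn$running_mean,
                        blk$dw_bn$running_var, blk$dw_bn$gamma,
                        blk$dw_bn$beta, cfg$bn_epsilon)
  expect_equal(bn + x, x, tolerance = 1e-12)
})

test_that("forward honours the fusion contract", {
  cfg_none <- make_cfg(fusion_mode = "none")
  m <- init_convmixer(cfg_none)
  x <- array(withr::with_seed(48, rnorm(2 * 20 * 3)), c(2, 20, 3))
  f <- matrix(withr::with_seed(49, rnorm(3 * 4)), 3, 4)
  expect_equal(forward_convmixer(m, x), forward_convmixer(m, x, f))
  cfg_fuse <- make_cfg(fusion_mode = "late_concat")
  mf <- init_convmixer(cfg_fuse)
  expect_error(forward_convmixer(mf, x), "requires features")
  expect_error(forward_convmixer(mf, x, matrix(0, 3, 7)),
               "does not match")
  # zeroing the feature columns of the classifier reproduces the unfused logits
  mf0 <- mf
  h <- cfg_fuse$hidden_dim
  mf0$weights$clf_w[, (h + 1):(h + 4)] <- 0
  m_none <- mf0
  m_none$config <- cfg_none
  m_none$weights$clf_w <- mf0$weights$clf_w[, 1:h, drop = FALSE]
  expect_equal(forward_convmixer(mf0, x, f), forward_convmixer(m_none, x),
               tolerance = 1e-12)
})

test_that("softmax probabilities are normalised and inference is deterministic", {
  cfg <- make_cfg(fusion_mode = "none")
  m <- init_convmixer(cfg)
  x <- array(withr::with_seed(50, rnorm(2 * 20 * 5)), c(2, 20, 5))
  p1 <- predict_convmixer(m, x)
  p2 <- predict_convmixer(m, x)
  expect_identical(p1, p2)
  expect_equal(unname(rowSums(p1$prob)), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p1$class %in% 1:3))
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- make_cfg(fusion_mode = "late_concat", seed = 3)
  m <- init_convmixer(cfg)
  withr::with_seed(51, {
    x <- array(rnorm(2 * 20 * 4), c(2, 20, 4))
    fe <- matrix(rnorm(4 * 4), 4, 4)
    y <- c(1, 2, 3, 1)
  })
  fwd <- emgmixer:::.forward_batch(m, x, t(fe), training = TRUE)
  ce <- emgmixer:::.xent_grad(fwd$logits, y, 3)
  gr <- emgmixer:::.backward_batch(m, fwd$caches, ce$dlogits)
  loss_of <- function(model) {
    f <- emgmixer:::.forward_batch(model, x, t(fe), training = TRUE)
    emgmixer:::.xent_grad(f$logits, y, 3)$loss
  }
  refs <- list(list("patch_w"), list("blocks", 1L, "dw_w"),
               list("blocks", 2L, "pw_w"), list("clf_w"),
               list("patch_bn", "gamma"), list("blocks", 1L, "dw_bn", "beta"))
  eps <- 1e-5
  withr::with_seed(52, {
    for (ref in refs) {
      w <- emgmixer:::.get_ref(m$weights, ref)
      g <- emgmixer:::.get_ref(gr, emgmixer:::.grad_ref(ref))
      for (j in sample(length(w), min(3, length(w)))) {
        w2 <- w
        w2[j] <- w2[j] + eps
        m2 <- m
        m2$weights <- emgmixer:::.set_ref(m2$weights, ref, w2)
        num <- (loss_of(m2) - ce$loss) / eps
        expect_equal(g[j], num, tolerance = 1e-3,
                     info = paste(unlist(ref), collapse = "/"))
      }
    }
  })
})

test_that("training is deterministic and requires every class", {
  withr::with_seed(53, {
    x <- array(rnorm(2 * 20 * 12), c(2, 20, 12))
    y <- rep(1:3, 4)
  })
  cfg <- make_cfg(fusion_mode = "none", epochs = 1)
  m1 <- train_convmixer(x, y, cfg)
  m2 <- train_convmixer(x, y, cfg)
  expect_identical(m1$report$loss, m2$report$loss)
  expect_identical(m1$weights, m2$weights)
  expect_true(all(is.finite(m1$report$loss)))
  expect_error(train_convmixer(x, rep(1:2, 6), cfg), "absent")
})

test_that("a tiny model overfits 20 windows to perfect training accuracy", {
  withr::with_seed(54, {
    x <- array(rnorm(2 * 20 * 20, sd = 0.3), c(2, 20, 20))
    y <- rep(1:2, each = 10)
    x[, , y == 2] <- x[, , y == 2] + 1.5  # amplitude-separable classes
  })
  cfg <- make_cfg(n_classes = 2, fusion_mode = "none", epochs = 40,
                  batch_size = 10, learning_rate = 5e-3)
  m <- train_convmixer(x, y, cfg)
  pr <- predict_convmixer(m, x)
  expect_equal(mean(pr$class == y), 1.0)
  # loss decreases over training on this easy task
  expect_lt(mean(tail(m$report$loss, 5)), mean(head(m$report$loss, 5)))
})

test_that("a separable 2-class problem reaches 95% validation accuracy within 30 epochs", {
  withr::with_seed(55, {
    n <- 60
    x <- array(rnorm(2 * 20 * n, sd = 0.5), c(2, 20, n))
    y <- rep(1:2, n / 2)
    x[, , y == 2] <- x[, , y == 2] * 3  # high vs low amplitude
    val_idx <- sample(n, 20)
  })
  cfg <- make_cfg(n_classes = 2, fusion_mode = "none", epochs = 30,
                  batch_size = 8, learning_rate = 3e-3)
  m <- train_convmixer(x[, , -val_idx, drop = FALSE], y[-val_idx], cfg,
                       val_windows = x[, , val_idx, drop = FALSE],
                       val_labels = y[val_idx])
  expect_gte(max(m$report$val_accuracy, na.rm = TRUE), 0.95)
})

test_that("model checkpoints round-trip through JSON", {
  cfg <- make_cfg(fusion_mode = "none", seed = 8)
  m <- init_convmixer(cfg)
  x <- array(withr::with_seed(56, rnorm(2 * 20 * 3)), c(2, 20, 3))
  path <- withr::local_tempfile(fileext = ".json")
  save_convmixer(m, path)
  m2 <- load_convmixer(path)
  expect_equal(forward_convmixer(m2, x), forward_convmixer(m, x),
               tolerance = 1e-12)
  expect_equal(m2$config$kernel_size, cfg$kernel_size)
})
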