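# Independent naive oracles used to cross-check the vectorized implementations.

naive_rms <- function(x) {
  s <- 0
  for (xi in x) s <- s + xi^2
  sqrt(s / length(x))
}

naive_var <- function(x) {
  s <- 0
  for (xi in x) s <- s + xi^2
  s / (length(x) - 1)
}

naive_zc <- function(x, eps = 0) {
  n <- 0L
  for (i in seq_len(length(x) - 1)) {
    if (-x[i] * x[i + 1] > eps) n <- n + 1L
  }
  n
}

naive_wl <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
  s
}

# naive depthwise convolution (cross-correlation, same zero padding),
# one channel at a time, sample by sample
naive_dwconv <- function(x, w, b, P) {
  k <- ncol(w)
  pad <- (k - 1) %/% 2
  B <- ncol(x) / P
  out <- matrix(0, nrow(x), ncol(x))
  for (ch in seq_len(nrow(x))) {
    for (bi in seq_len(B)) {
      for (t in seq_len(P)) {
        acc <- 0
        for (j in seq_len(k)) {
          src <- t + j - pad - 1
          if (src >= 1 && src <= P) {
            acc <- acc + w[ch, j] * x[ch, (bi - 1) * P + src]
          }
        }
        out[ch, (bi - 1) * P + t] <- acc + b[ch]
      }
    }
  }
  out
}

naive_bn <- function(x, mean, var, gamma, beta, eps) {
  out <- x
  for (ch in seq_len(nrow(x))) {
    out[ch, ] <- (x[ch, ] - mean[ch]) / sqrt(var[ch] + eps) * gamma[ch] + beta[ch]
  }
  out
}

# one-vs-rest metrics, plain loops
naive_metrics <- function(cm) {
  total <- sum(cm)
  K <- nrow(cm)
  sens <- spec <- numeric(0)
  for (i in seq_len(K)) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    if (tp + fn > 0) sens <- c(sens, tp / (tp + fn))
    if (tn + fp > 0) spec <- c(spec, tn / (tn + fp))
  }
  list(accuracy = sum(diag(cm)) / total,
       sensitivity = mean(sens), specificity = mean(spec))
}

# small sinusoid session for filter tests
sine_session <- function(freq, fs = 2000, dur = 2, nch = 4, amplitude = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  sig <- matrix(rep(amplitude * sin(2 * pi * freq * t), nch),
                nrow = nch, byrow = TRUE)
  recording_session(sig, fs)
}

# small labelled random session for segmentation tests
toy_labelled_session <- function(fs = 1000, intervals, seed = 42) {
  dur <- max(intervals$end_s)
  n <- ceiling(fs * dur)
  sig <- withr::with_seed(seed, matrix(rnorm(4 * n), 4, n))
  recording_session(sig, fs, intervals)
}
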