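#' Time-domain sEMG features
#'
#' The handcrafted feature set used throughout the package: root mean square
#' (RMS), sum-of-squares power with an N-1 denominator (VAR), thresholded
#' zero crossings (ZC) and waveform length (WL), computed per channel per
#' window. Note that VAR is deliberately the raw second moment
#' `sum(x^2) / (N - 1)` -- no mean subtraction -- so it behaves like a mean
#' power measure rather than a central variance; the name is kept for
#' continuity with the EMG literature.
#'
#' @name emg-features
NULL

FEATURE_NAMES <- c("rms", "var", "zc", "wl")

#' Root mean square amplitude
#' @param x numeric sample vector (length >= 1).
#' @return `sqrt(mean(x^2))`.
#' @export
emg_rms <- function(x) {
  if (length(x) < 1L) stop("rms needs at least one sample", call. = FALSE)
  sqrt(sum(x^2) / length(x))
}

#' Sum-of-squares power (VAR)
#'
#' `sum(x^2) / (N - 1)` -- a mean-power style statistic, not the variance
#' about the mean.
#'
#' @param x numeric sample vector (length >= 2).
#' @return non-negative scalar.
#' @export
emg_var <- function(x) {
  if (length(x) < 2L) stop("var feature needs at least two samples", call. = FALSE)
  sum(x^2) / (length(x) - 1L)
}

#' Thresholded zero-crossing count
#'
#' Counts adjacent sample pairs whose product is negative and exceeds the
#' deadband `eps` in magnitude: a crossing is scored when `-x[i] * x[i+1] >
#' eps`. With `eps = 0` this is the plain sign-change count.
#'
#' @param x numeric sample vector (length >= 2).
#' @param eps non-negative deadband (default 0).
#' @return integer count in `[0, N - 1]`.
#' @export
emg_zc <- function(x, eps = 0) {
  if (length(x) < 2L) stop("zc needs at least two samples", call. = FALSE)
  if (!is.finite(eps) || eps < 0) stop("eps must be >= 0", call. = FALSE)
  n <- length(x)
  sum(-x[-n] * x[-1] > eps)
}

#' Waveform length
#' @param x numeric sample vector (length >= 2).
#' @return sum of absolute first differences.
#' @export
emg_wl <- function(x) {
  if (length(x) < 2L) stop("wl needs at least two samples", call. = FALSE)
  sum(abs(diff(x)))
}

#' Feature extraction parameters
#'
#' @param zc_eps zero-crossing deadband in mV (default 0.01; a small
#'   deadband suppresses crossings of the noise floor).
#' @param feature_order permutation of `c("rms", "var", "zc", "wl")` fixing
#'   the within-channel feature order.
#' @return a `feature_params` list.
#' @export
feature_params <- function(zc_eps = 0.01, feature_order = FEATURE_NAMES) {
  if (!is.finite(zc_eps) || zc_eps < 0) stop("zc_eps must be >= 0", call. = FALSE)
  if (!setequal(feature_order, FEATURE_NAMES) ||
      length(feature_order) != length(FEATURE_NAMES)) {
    stop("feature_order must be a permutation of ",
         paste(FEATURE_NAMES, collapse = ", "), call. = FALSE)
  }
  structure(list(zc_eps = zc_eps, feature_order = feature_order),
            class = "feature_params")
}

.features_one_channel <- function(x, params) {
  vals <- c(rms = emg_rms(x), var = emg_var(x),
            zc = as.numeric(emg_zc(x, params$zc_eps)), wl = emg_wl(x))
  vals[params$feature_order]
}

#' Extract the handcrafted feature vector of one window
#'
#' @param window numeric matrix, channels x samples.
#' @param params a [feature_params()] object.
#' @return named numeric vector of length `4 * nrow(window)` in
#'   channel-major order (`ch1_rms, ch1_var, ch1_zc, ch1_wl, ch2_rms, ...`
#'   under the default feature order).
#' @export
extract_features <- function(window, params = feature_params()) {
  if (!is.matrix(window) || any(!is.finite(window))) {
    stop("window must be a finite numeric matrix (channels x samples)",
         call. = FALSE)
  }
  out <- unlist(lapply(seq_len(nrow(window)), function(ch) {
    v <- .features_one_channel(window[ch, ], params)
    names(v) <- paste0("ch", ch, "_", names(v))
    v
  }))
  out
}

#' Feature matrix for a window set
#'
#' @param windows a `window_set` (see [segment_windows()]).
#' @param params a [feature_params()] object.
#' @return numeric matrix, one row per window, 16 columns.
#' @export
feature_matrix <- function(windows, params = feature_params()) {
  stopifnot(inherits(windows, "window_set"))
  n <- dim(windows$samples)[3]
  out <- t(vapply(seq_len(n),
                  function(i) extract_features(windows$samples[, , i], params),
                  numeric(nrow(windows$samples) * length(FEATURE_NAMES))))
  rownames(out) <- NULL
  out
}

#' Fit a per-dimension standardiser on training features
#'
#' @param train numeric matrix of training feature vectors (rows =
#'   observations).
#' @param scale_floor minimum allowed scale; near-constant dimensions are
#'   clamped to this floor instead of dividing by ~0.
#' @return a `feature_scaler` with `center` and `scale` vectors.
#' @export
fit_scaler <- function(train, scale_floor = 1e-8) {
  train <- as.matrix(train)
  if (nrow(train) < 1L) stop("training set is empty", call. = FALSE)
  ctr <- colMeans(train)
  sc <- apply(train, 2, stats::sd)
  sc[!is.finite(sc) | sc < scale_floor] <- scale_floor
  structure(list(center = ctr, scale = sc), class = "feature_scaler")
}

#' Apply a fitted standardiser
#' @param scaler a [fit_scaler()] result.
#' @param x feature vector or matrix (rows = observations).
#' @return standardised features with the same shape as `x`.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "feature_scaler"))
  if (is.null(dim(x))) {
    (x - scaler$center) / scaler$scale
  } else {
    sweep(sweep(as.matrix(x), 2, scaler$center, "-"), 2, scaler$scale, "/")
  }
}

#' Write a feature table (windows x features) with labels as CSV
#'
#' @param features feature matrix from [feature_matrix()].
#' @param labels fine label ids, one per row of `features`.
#' @param path output CSV path.
#' @export
write_feature_table <- function(features, labels, path) {
  stopifnot(nrow(features) == length(labels))
  tab <- data.frame(window_id = seq_len(nrow(features)),
                    label = normalize_fine_id(labels), features,
                    check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
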