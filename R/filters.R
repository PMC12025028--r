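#' Preprocessing filter specification
#'
#' Defaults follow standard sEMG practice: a 50 Hz powerline notch (Q = 30)
#' and a 4th-order Butterworth band-pass over the 20--450 Hz sEMG band. Both
#' filters are applied zero-phase (forward-backward) since the analysis is
#' offline and phase distortion would bias the time-domain features.
#'
#' @param notch_freq powerline frequency in Hz.
#' @param notch_q notch quality factor (bandwidth = `notch_freq / notch_q`).
#' @param band_low,band_high Butterworth band edges in Hz.
#' @param butterworth_order filter order (>= 1).
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(notch_freq = 50, notch_q = 30,
                        band_low = 20, band_high = 450,
                        butterworth_order = 4) {
  if (!is.finite(notch_freq) || notch_freq <= 0) stop("notch_freq must be > 0", call. = FALSE)
  if (!is.finite(notch_q) || notch_q <= 0) stop("notch_q must be > 0", call. = FALSE)
  if (!(band_low > 0 && band_low < band_high)) {
    stop("need 0 < band_low < band_high", call. = FALSE)
  }
  if (butterworth_order < 1) stop("butterworth_order must be >= 1", call. = FALSE)
  structure(list(notch_freq = notch_freq, notch_q = notch_q,
                 band_low = band_low, band_high = band_high,
                 butterworth_order = butterworth_order),
            class = "filter_spec")
}

# Zero-phase (forward-backward) IIR filtering with odd-extension padding and
# steady-state initial conditions, so edge transients do not leak into the
# signal (plain forward-backward filtering without padding lets the startup
# transient of narrow filters dominate short recordings).
.one_pass <- function(b, a, x) {
  nb <- length(b)
  na <- length(a)
  g <- sum(b) / sum(a)  # DC gain: exact steady state for a constant input
  init.x <- rep(x[1], nb - 1)
  init.y <- rep(g * x[1], na - 1)
  signal::filter(b, a, x, init.x = init.x, init.y = init.y)
}

.zero_phase <- function(filt, x) {
  b <- filt$b
  a <- filt$a
  n <- length(x)
  padlen <- min(n - 1L, 10L * max(length(a), length(b)) + 100L)
  pre <- 2 * x[1] - x[seq(padlen + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
  ext <- c(pre, x, post)
  y <- .one_pass(b, a, ext)
  y <- rev(.one_pass(b, a, rev(y)))
  y[padlen + seq_len(n)]
}

.filtfilt_rows <- function(filt, signal) {
  out <- signal
  for (ch in seq_len(nrow(signal))) {
    out[ch, ] <- .zero_phase(filt, signal[ch, ])
  }
  out
}

#' Zero-phase powerline notch filter
#'
#' Second-order Butterworth band-stop centred on the powerline frequency
#' with bandwidth `notch_freq / notch_q`, run forward-backward per channel.
#'
#' @param session a [recording_session()].
#' @param spec a [filter_spec()].
#' @return the session with the filtered signal (same shape).
#' @export
notch_filter <- function(session, spec = filter_spec()) {
  stopifnot(inherits(session, "recording_session"))
  nyq <- session$sampling_rate / 2
  if (spec$notch_freq >= nyq) {
    stop("notch_freq (", spec$notch_freq, " Hz) must be below Nyquist (",
         nyq, " Hz)", call. = FALSE)
  }
  bw <- spec$notch_freq / spec$notch_q
  edges <- c(spec$notch_freq - bw / 2, spec$notch_freq + bw / 2) / nyq
  filt <- signal::butter(2, edges, type = "stop")
  session$signal <- .filtfilt_rows(filt, session$signal)
  session
}

#' Zero-phase Butterworth band-pass filter
#'
#' @param session a [recording_session()].
#' @param spec a [filter_spec()].
#' @return the session with the filtered signal (same shape).
#' @export
bandpass_filter <- function(session, spec = filter_spec()) {
  stopifnot(inherits(session, "recording_session"))
  nyq <- session$sampling_rate / 2
  if (spec$band_high >= nyq) {
    stop("band_high (", spec$band_high, " Hz) must be below Nyquist (",
         nyq, " Hz)", call. = FALSE)
  }
  filt <- signal::butter(spec$butterworth_order,
                         c(spec$band_low, spec$band_high) / nyq,
                         type = "pass")
  session$signal <- .filtfilt_rows(filt, session$signal)
  session
}

#' Apply the full preprocessing chain (notch then band-pass)
#'
#' @inheritParams notch_filter
#' @return the filtered session.
#' @export
preprocess_session <- function(session, spec = filter_spec()) {
  bandpass_filter(notch_filter(session, spec), spec)
}
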