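#' Segment a session into overlapping labelled windows
#'
#' Windows of `window_ms` milliseconds are slid in steps of `step_ms` inside
#' each annotated interval; only windows fully contained in a single interval
#' are emitted and they carry that interval's label. The window length in
#' samples is `N = floor(fs * window_ms / 1000)` (truncation, so 250 ms at
#' 1925.9259 Hz gives the canonical 481 samples) and the step is
#' `floor(fs * step_ms / 1000)` samples. With the 250/50 ms defaults,
#' consecutive windows share 80% of their samples. Intervals shorter than
#' one window yield no windows (with a warning).
#'
#' @param session a [recording_session()] with annotations.
#' @param window_ms window length in milliseconds (default 250).
#' @param step_ms step between window starts in milliseconds (default 50;
#'   must be smaller than `window_ms`).
#' @return a `window_set`: list with `samples` (channels x N x n_windows
#'   array), `info` (data frame of `label`, `start_s`, `interval`) and
#'   `sampling_rate`.
#' @export
segment_windows <- function(session, window_ms = 250, step_ms = 50) {
  stopifnot(inherits(session, "recording_session"))
  if (!(window_ms > step_ms && step_ms > 0)) {
    stop("need window_ms > step_ms > 0", call. = FALSE)
  }
  fs <- session$sampling_rate
  n_win <- as.integer(floor(fs * window_ms / 1000))
  step <- as.integer(floor(fs * step_ms / 1000))
  if (step < 1L) stop("step_ms too small for this sampling rate", call. = FALSE)
  nch <- nrow(session$signal)
  starts <- integer(0)   # 1-based sample index of each window start
  labels <- integer(0)
  interval <- integer(0)
  for (i in seq_len(nrow(session$annotations))) {
    a <- session$annotations[i, ]
    # half-open interval [start, end): first sample at ceil(start*fs),
    # last sample strictly before end*fs
    s0 <- as.integer(ceiling(a$start_s * fs - 1e-9)) + 1L
    s1 <- min(as.integer(ceiling(a$end_s * fs - 1e-9)), ncol(session$signal))
    len <- s1 - s0 + 1L
    if (len < n_win) {
      warning(sprintf("interval %d (label %d, %.2f-%.2f s) shorter than one window; skipped",
                      i, a$label, a$start_s, a$end_s), call. = FALSE)
      next
    }
    k <- (len - n_win) %/% step + 1L
    w_starts <- s0 + (seq_len(k) - 1L) * step
    starts <- c(starts, w_starts)
    labels <- c(labels, rep(as.integer(a$label), k))
    interval <- c(interval, rep(i, k))
  }
  samples <- array(0, dim = c(nch, n_win, length(starts)))
  for (w in seq_along(starts)) {
    samples[, , w] <- session$signal[, starts[w]:(starts[w] + n_win - 1L)]
  }
  structure(list(samples = samples,
                 info = data.frame(label = labels,
                                   start_s = (starts - 1L) / fs,
                                   interval = interval),
                 sampling_rate = fs),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("window_set: %d windows of %d channels x %d samples (%d labels)\n",
              d[3], d[1], d[2], length(unique(x$info$label))))
  invisible(x)
}

#' Subset a window set
#' @param windows a `window_set`.
#' @param idx integer or logical index over windows.
#' @return the subsetted `window_set`.
#' @export
subset_windows <- function(windows, idx) {
  stopifnot(inherits(windows, "window_set"))
  structure(list(samples = windows$samples[, , idx, drop = FALSE],
                 info = windows$info[idx, , drop = FALSE],
                 sampling_rate = windows$sampling_rate),
            class = "window_set")
}

#' Persist a window set as plain CSV
#'
#' Samples go to `<path>_samples.csv` (one row per window, channels
#' concatenated channel-major) and labels/offsets to `<path>_info.csv`.
#'
#' @param windows a `window_set`.
#' @param path_prefix path prefix for the two CSV files.
#' @export
write_windows <- function(windows, path_prefix) {
  stopifnot(inherits(windows, "window_set"))
  d <- dim(windows$samples)
  flat <- t(apply(windows$samples, 3, function(m) as.numeric(t(m))))
  utils::write.csv(data.frame(flat), paste0(path_prefix, "_samples.csv"),
                   row.names = FALSE)
  info <- windows$info
  info$n_channels <- d[1]
  info$n_samples <- d[2]
  info$sampling_rate <- windows$sampling_rate
  utils::write.csv(info, paste0(path_prefix, "_info.csv"), row.names = FALSE)
  invisible(windows)
}

#' Read a window set written by [write_windows()]
#' @param path_prefix path prefix used when writing.
#' @return a `window_set`.
#' @export
read_windows <- function(path_prefix) {
  flat <- as.matrix(utils::read.csv(paste0(path_prefix, "_samples.csv")))
  info <- utils::read.csv(paste0(path_prefix, "_info.csv"))
  nch <- info$n_channels[1]
  n <- info$n_samples[1]
  samples <- array(0, dim = c(nch, n, nrow(flat)))
  for (w in seq_len(nrow(flat))) {
    samples[, , w] <- matrix(flat[w, ], nrow = nch, byrow = TRUE)
  }
  structure(list(samples = samples,
                 info = info[, c("label", "start_s", "interval")],
                 sampling_rate = info$sampling_rate[1]),
            class = "window_set")
}
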