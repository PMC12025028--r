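#' Multichannel recording sessions
#'
#' A `recording_session` bundles a channels x samples signal matrix (mV),
#' its sampling rate, and the labelled active intervals. Time is in seconds
#' and intervals are half-open `[start, end)` so boundary samples are never
#' assigned twice.
#'
#' @param signal numeric matrix, channels x samples (default 4 channels).
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param annotations data frame with columns `label` (fine id), `start_s`,
#'   `end_s`; intervals must be non-overlapping and inside the recording.
#' @param subject_id free-text subject identifier.
#' @return a `recording_session` object.
#' @export
recording_session <- function(signal, sampling_rate,
                              annotations = data.frame(label = integer(),
                                                       start_s = numeric(),
                                                       end_s = numeric()),
                              subject_id = "synthetic") {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("signal must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be > 0", call. = FALSE)
  }
  annotations <- as.data.frame(annotations)
  req <- c("label", "start_s", "end_s")
  if (!all(req %in% names(annotations))) {
    stop("annotations need columns label, start_s, end_s", call. = FALSE)
  }
  dur <- ncol(signal) / sampling_rate
  if (nrow(annotations)) {
    annotations$label <- normalize_fine_id(annotations$label)
    annotations <- annotations[order(annotations$start_s), , drop = FALSE]
    rownames(annotations) <- NULL
    if (any(annotations$end_s <= annotations$start_s)) {
      stop("annotation intervals must have end_s > start_s", call. = FALSE)
    }
    if (any(annotations$start_s < 0) || any(annotations$end_s > dur + 1e-9)) {
      stop("annotation interval outside signal duration (", round(dur, 3),
           " s)", call. = FALSE)
    }
    if (nrow(annotations) > 1 &&
        any(annotations$start_s[-1] < annotations$end_s[-nrow(annotations)] - 1e-9)) {
      stop("annotation intervals overlap", call. = FALSE)
    }
  }
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 annotations = annotations, subject_id = subject_id),
            class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("recording_session: %d channels x %d samples (%.1f s @ %.4f Hz), %d annotated intervals, subject '%s'\n",
              nrow(x$signal), ncol(x$signal), ncol(x$signal) / x$sampling_rate,
              x$sampling_rate, nrow(x$annotations), x$subject_id))
  invisible(x)
}

#' Write a session as paired CSV files
#'
#' Signal CSV has header `time_s,ch1,...`; annotation CSV has header
#' `label,start_s,end_s`.
#'
#' @param session a [recording_session()].
#' @param signal_path,annotation_path output CSV paths.
#' @export
write_session <- function(session, signal_path, annotation_path) {
  stopifnot(inherits(session, "recording_session"))
  n <- ncol(session$signal)
  tab <- data.frame(time_s = (seq_len(n) - 1) / session$sampling_rate,
                    t(session$signal))
  names(tab) <- c("time_s", paste0("ch", seq_len(nrow(session$signal))))
  utils::write.csv(tab, signal_path, row.names = FALSE)
  utils::write.csv(session$annotations[, c("label", "start_s", "end_s")],
                   annotation_path, row.names = FALSE)
  invisible(session)
}

#' Read a session from paired CSV files
#'
#' The sampling rate is inferred from the median time step of the `time_s`
#' column; the time axis must be strictly increasing and annotations must
#' lie within the recording.
#'
#' @param signal_path CSV with header `time_s,ch1,ch2,...`.
#' @param annotation_path CSV with header `label,start_s,end_s`.
#' @param subject_id subject identifier to attach.
#' @return a [recording_session()].
#' @export
read_session <- function(signal_path, annotation_path, subject_id = "unknown") {
  for (p in c(signal_path, annotation_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  sig <- utils::read.csv(signal_path)
  if (names(sig)[1] != "time_s" || ncol(sig) < 2) {
    stop(signal_path, ": expected header time_s,ch1,...", call. = FALSE)
  }
  if (any(is.na(sig))) {
    bad <- which(rowSums(is.na(sig)) > 0)[1]
    stop(signal_path, ": missing value at data line ", bad, call. = FALSE)
  }
  dt <- diff(sig$time_s)
  if (any(dt <= 0)) {
    stop(signal_path, ": time_s not strictly increasing at data line ",
         which(dt <= 0)[1] + 1L, call. = FALSE)
  }
  fs <- 1 / stats::median(dt)
  ann <- utils::read.csv(annotation_path)
  if (!all(c("label", "start_s", "end_s") %in% names(ann))) {
    stop(annotation_path, ": expected header label,start_s,end_s", call. = FALSE)
  }
  mat <- t(as.matrix(sig[, -1, drop = FALSE]))
  dimnames(mat) <- NULL
  recording_session(mat, fs, ann, subject_id = subject_id)
}
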