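#' Synthetic pouring-protocol sEMG sessions
#'
#' The generator emulates the data-collection protocol: a seated subject
#' holds a water bottle and pours left, right or front at 22.5, 45, 67.5 or
#' 90 degrees, each posture held for 5 s followed by 5 s of rest, recorded by
#' four forearm sensors at 1925.9259 Hz. Muscle activity is modelled as
#' Gaussian noise band-limited to the 20--450 Hz sEMG band, amplitude-
#' modulated by a direction-dependent channel gain profile and a monotone
#' angle-dependent scaling, with trapezoidal 100 ms onset/offset ramps, a
#' 50 Hz powerline sinusoid and a broadband baseline noise floor. Hold
#' trials use a uniform low-amplitude grip profile (the bottle is gripped,
#' not released, at rest posture).
#'
#' @name synthetic-emg
NULL

#' Build the pouring experiment protocol plan
#'
#' One repetition contains one trial of each of the 12 direction x angle
#' gestures plus two hold trials (the hold class appears twice per round in
#' the original protocol, which is why its fine id has the alias 10), each
#' trial being `active_s` seconds of posture followed by `rest_s` seconds of
#' rest.
#'
#' @param repetitions number of repetitions per gesture (>= 1).
#' @param sampling_rate sampling rate in Hz.
#' @param active_s,rest_s active and rest durations in seconds.
#' @param seed optional seed; when given, trial order is shuffled
#'   deterministically, otherwise trials stay in construction order.
#' @return a `protocol_plan`: data frame of trials (`fine_id`, `direction`,
#'   `angle`, `active_s`, `rest_s`) with attributes `sampling_rate` and
#'   `repetitions`.
#' @export
make_protocol <- function(repetitions, sampling_rate = 1925.9259,
                          active_s = 5, rest_s = 5, seed = NULL) {
  if (!is.finite(repetitions) || repetitions < 1) {
    stop("repetitions must be >= 1", call. = FALSE)
  }
  if (active_s <= 0 || rest_s < 0) {
    stop("need active_s > 0 and rest_s >= 0", call. = FALSE)
  }
  tab <- label_table()
  one_round <- rbind(tab[tab$direction != "hold",
                         c("fine_id", "direction", "angle")],
                     tab[tab$direction == "hold",
                         c("fine_id", "direction", "angle")],
                     tab[tab$direction == "hold",
                         c("fine_id", "direction", "angle")])
  trials <- do.call(rbind, replicate(as.integer(repetitions),
                                     one_round, simplify = FALSE))
  if (!is.null(seed)) {
    ord <- withr::with_seed(as.integer(seed), sample.int(nrow(trials)))
    trials <- trials[ord, , drop = FALSE]
  }
  trials$active_s <- active_s
  trials$rest_s <- rest_s
  rownames(trials) <- NULL
  structure(trials, class = c("protocol_plan", "data.frame"),
            sampling_rate = sampling_rate,
            repetitions = as.integer(repetitions))
}

#' Direction- and angle-dependent channel activation gains
#'
#' Each pouring direction recruits a distinct dominant forearm sensor
#' (front -> ch1, right -> ch2, left -> ch3, with ch4 a shared synergist),
#' and amplitude grows linearly with pouring angle from 0.4 at 22.5 degrees
#' to 1.0 at 90 degrees. Hold returns a uniform low-gain grip profile.
#'
#' @param direction `"left"`, `"right"`, `"front"` or `"hold"`.
#' @param angle pouring angle in degrees; ignored (and must be absent) for
#'   hold.
#' @param params a [synth_params()] object supplying the gain profiles and
#'   angle scaling.
#' @return numeric 4-vector of channel gains.
#' @export
channel_activation_profile <- function(direction, angle = NA_real_,
                                       params = synth_params()) {
  direction <- match.arg(direction, POUR_DIRECTIONS)
  base <- params$channel_gain_profiles[[direction]]
  if (direction == "hold") return(base)
  if (is.na(angle) || !angle %in% POUR_ANGLES) {
    stop("angle must be one of 22.5, 45, 67.5, 90", call. = FALSE)
  }
  base * params$angle_scaling(angle)
}

#' Synthetic-signal parameters
#'
#' @param channel_gain_profiles named list (left/right/front/hold) of
#'   4-vectors of non-negative relative gains; defaults give each direction
#'   a distinct dominant channel and hold a uniform low grip gain.
#' @param angle_scaling strictly increasing function from angle (degrees)
#'   to an amplitude multiplier; default is the linear map 22.5 -> 0.4,
#'   90 -> 1.0, keeping adjacent angles confusable.
#' @param carrier_band low/high band edges (Hz) of the band-limited carrier
#'   noise; must lie inside (0, fs/2).
#' @param powerline_freq powerline frequency in Hz (50, UK mains).
#' @param powerline_amplitude sinusoid amplitude in mV (default 10% of the
#'   maximum active RMS, which is 1 mV at unit gain).
#' @param baseline_noise_sd broadband baseline noise SD in mV.
#' @param ramp_s trapezoidal onset/offset ramp duration in seconds.
#' @param trial_gain_jitter lognormal SD of a per-trial amplitude factor
#'   (models inter-trial variability; 0 disables).
#' @param seed integer seed for the generator.
#' @return a `synth_params` list.
#' @export
synth_params <- function(channel_gain_profiles = list(
                           left  = c(0.30, 0.20, 1.00, 0.45),
                           right = c(0.30, 1.00, 0.20, 0.45),
                           front = c(1.00, 0.30, 0.30, 0.60),
                           hold  = c(0.15, 0.15, 0.15, 0.15)),
                         angle_scaling = function(angle)
                           0.4 + 0.6 * (angle - 22.5) / 67.5,
                         carrier_band = c(20, 450),
                         powerline_freq = 50,
                         powerline_amplitude = 0.1,
                         baseline_noise_sd = 0.02,
                         ramp_s = 0.1,
                         trial_gain_jitter = 0.05,
                         seed = 1L) {
  stopifnot(all(POUR_DIRECTIONS %in% names(channel_gain_profiles)))
  if (any(unlist(channel_gain_profiles) < 0)) {
    stop("channel gains must be >= 0", call. = FALSE)
  }
  sc <- vapply(POUR_ANGLES, angle_scaling, numeric(1))
  if (any(diff(sc) <= 0)) {
    stop("angle_scaling must be strictly increasing in angle", call. = FALSE)
  }
  if (!(carrier_band[1] > 0 && carrier_band[1] < carrier_band[2])) {
    stop("carrier_band must satisfy 0 < low < high", call. = FALSE)
  }
  structure(list(channel_gain_profiles = channel_gain_profiles,
                 angle_scaling = angle_scaling,
                 carrier_band = carrier_band,
                 powerline_freq = powerline_freq,
                 powerline_amplitude = powerline_amplitude,
                 baseline_noise_sd = baseline_noise_sd,
                 ramp_s = ramp_s,
                 trial_gain_jitter = trial_gain_jitter,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# trapezoidal activation envelope over a global time grid, one interval
.trapezoid <- function(time_s, start_s, end_s, ramp_s) {
  up <- pmin(pmax((time_s - start_s) / ramp_s, 0), 1)
  down <- pmin(pmax((end_s - time_s) / ramp_s, 0), 1)
  pmin(up, down)
}

#' Synthesise a recording session from a protocol plan
#'
#' @param plan a [make_protocol()] plan.
#' @param params a [synth_params()] object.
#' @return a [recording_session()] whose annotations mark the active
#'   interval of every trial with its fine label id. Identical plan, params
#'   and seed give bit-identical sessions.
#' @export
synthesize_session <- function(plan, params = synth_params()) {
  stopifnot(inherits(plan, "protocol_plan"))
  fs <- attr(plan, "sampling_rate")
  if (params$carrier_band[2] >= fs / 2) {
    stop("carrier_band upper edge (", params$carrier_band[2],
         " Hz) must be below Nyquist (", fs / 2, " Hz)", call. = FALSE)
  }
  durations <- plan$active_s + plan$rest_s
  ends <- cumsum(durations)
  starts_active <- ends - durations
  total_s <- ends[length(ends)]
  n <- as.integer(round(fs * total_s))
  time_s <- (seq_len(n) - 1) / fs
  nch <- 4L

  withr::with_seed(params$seed, {
    jitter <- if (params$trial_gain_jitter > 0) {
      exp(stats::rnorm(nrow(plan), 0, params$trial_gain_jitter))
    } else rep(1, nrow(plan))
    # band-limited carrier, one independent stream per channel
    bp <- signal::butter(4, params$carrier_band / (fs / 2), type = "pass")
    carrier <- matrix(stats::rnorm(nch * n), nch, n)
    for (ch in seq_len(nch)) {
      x <- .zero_phase(bp, carrier[ch, ])
      carrier[ch, ] <- x / stats::sd(x)  # unit-RMS carrier
    }
    noise <- matrix(stats::rnorm(nch * n, 0, params$baseline_noise_sd), nch, n)
    powerline_phase <- stats::runif(1, 0, 2 * pi)
  })

  envelope <- matrix(0, nch, n)
  for (i in seq_len(nrow(plan))) {
    a0 <- starts_active[i]
    a1 <- a0 + plan$active_s[i]
    gains <- channel_activation_profile(plan$direction[i], plan$angle[i],
                                        params) * jitter[i]
    idx <- which(time_s >= a0 & time_s < a1)
    if (!length(idx)) next
    tz <- .trapezoid(time_s[idx], a0, a1, params$ramp_s)
    envelope[, idx] <- envelope[, idx] + outer(gains, tz)
  }
  powerline <- params$powerline_amplitude *
    sin(2 * pi * params$powerline_freq * time_s + powerline_phase)
  sig <- carrier * envelope + noise +
    matrix(powerline, nch, n, byrow = TRUE)

  ann <- data.frame(label = plan$fine_id,
                    start_s = starts_active,
                    end_s = starts_active + plan$active_s)
  recording_session(sig, fs, ann, subject_id = "synthetic")
}
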