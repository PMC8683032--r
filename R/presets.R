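#' Ready-made simulation designs
#'
#' Two study designs used throughout the package's evaluation:
#'
#' `sim_config_fixation()` emulates a task-free fixation recording:
#' no cognitive response, a constant spontaneous blink rate (0.3 Hz,
#' typical of fixation data), and the canonical BPR kernel. This is
#' the regime for characterizing the kernel and testing parameter
#' recovery.
#'
#' `sim_config_oddball()` emulates an auditory-oddball-like experiment
#' with 2-s trials and three conditions of decreasing probability and
#' increasing event-locked dilation (peak 0.10 / 0.20 / 0.30 mm at
#' 0.9 s). Blinks are suppressed during stimulus presentation and
#' rebound sharply 0.5--1 s after the stimulus (an "implicit
#' breakpoint" around 0.75 s), with a stronger rebound in rarer
#' conditions — so the blink-locked response is coupled to the
#' conditions of interest and suppresses the late portion of the
#' measured response, attenuating the condition effect.
#'
#' @param n_trials Number of trials.
#' @param rate Sampling rate, Hz.
#' @param blink_rate Constant blink rate for the fixation design, Hz.
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
sim_config_fixation <- function(n_trials = 100, rate = 100,
                                blink_rate = 0.3, seed = 1L) {
  sim_config(n_trials = n_trials, trial_length = 3, rate = rate,
             conditions = list(sim_condition("fixation", 1, 0,
                                             blink_rate)),
             pad_rate = blink_rate, seed = seed)
}

#' @rdname sim_config_fixation
#' @param dilation_peaks Named peak amplitudes (mm) of the event-locked
#'   dilation for the frequent / intermediate / rare conditions.
#' @param blink_peaks Named peak blink-rate rebounds (Hz).
#' @export
sim_config_oddball <- function(n_trials = 300, rate = 100,
                               dilation_peaks = c(frequent = 0.10,
                                                  intermediate = 0.20,
                                                  rare = 0.30),
                               blink_peaks = c(frequent = 0.6,
                                               intermediate = 0.9,
                                               rare = 1.2),
                               seed = 1L) {
  probs <- c(frequent = 0.5, intermediate = 0.3, rare = 0.2)
  mk <- function(label) {
    amp <- dilation_peaks[[label]]
    bp <- blink_peaks[[label]]
    sim_condition(
      label, prob = probs[[label]],
      cognitive = function(p) amp * dilation_profile(p),
      blink_rate = function(p) 0.1 + bp * exp(-(p - 0.75)^2 /
                                                (2 * 0.2^2)))
  }
  sim_config(n_trials = n_trials, trial_length = 2, rate = rate,
             conditions = lapply(names(probs), mk), pad_rate = 0.3,
             seed = seed)
}

#' Canonical event-locked dilation shape
#'
#' A gamma-density time course starting 0.3 s after the event and
#' peaking at 0.9 s, normalized to unit peak; scaled by the
#' condition's dilation amplitude in the oddball preset.
#'
#' @param p Trial phase, seconds after event onset.
#' @return Dilation value (unit peak).
#' @export
dilation_profile <- function(p) {
  mode <- 0.6
  peak <- stats::dgamma(mode, shape = 3, scale = 0.3)
  stats::dgamma(p - 0.3, shape = 3, scale = 0.3) / peak
}

#' Standard-coding regressor for the oddball design
#'
#' Conditions ordered frequent to rare are coded -0.5, 0, 0.5.
#' @return Named numeric vector.
#' @export
oddball_coding <- function() {
  c(frequent = -0.5, intermediate = 0, rare = 0.5)
}

#' Run the standard preprocessing chain
#'
#' Convenience wrapper: [detect_blinks()], then
#' [remove_periblink_artifacts()], then [bandpass_filter()].
#'
#' @param trace A raw [pupil_trace()] in mm.
#' @param params A [preprocess_params()].
#' @return A list with `trace` (preprocessed) and `blinks` (with
#'   artifact windows).
#' @export
preprocess_trace <- function(trace, params = preprocess_params()) {
  bl <- detect_blinks(trace, params)
  pp <- remove_periblink_artifacts(trace, bl, params)
  list(trace = bandpass_filter(pp$trace, params), blinks = pp$blinks)
}
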