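#' Dorsal-root stimulation protocol
#'
#' Describes a stimulus train; the standard spasm-evoking protocol is a train of
#' 15 pulses of 50 microseconds at 10 Hz, with strength graded as a multiple
#' of the threshold T for the smallest monosynaptic ventral-root response.
#'
#' @param pulse_times Pulse onset times in seconds, strictly increasing.
#' @param pulse_width_us Pulse width in microseconds (> 0).
#' @param frequency_hz Train frequency in Hz.
#' @param strength_t Stimulus strength as a multiple of threshold T (> 0).
#'
#' @return A list of class `stimulus_protocol`.
#' @export
#' @examples
#' stim <- stimulus_protocol(train_onset = 5)
#' range(stim$pulse_times)
stimulus_protocol <- function(pulse_times = NULL, pulse_width_us = 50,
                              frequency_hz = 10, strength_t = 1,
                              n_pulses = 15, train_onset = 0) {
  if (is.null(pulse_times)) {
    pulse_times <- train_onset + seq(0, by = 1 / frequency_hz, length.out = n_pulses)
  }
  if (length(pulse_times) == 0 || is.unsorted(pulse_times, strictly = TRUE)) {
    abort("`pulse_times` must be non-empty and strictly increasing.",
          class = "spasm_error_config")
  }
  if (pulse_width_us <= 0) abort("`pulse_width_us` must be > 0.", class = "spasm_error_config")
  if (strength_t <= 0) abort("`strength_t` must be > 0.", class = "spasm_error_config")
  structure(
    list(
      pulse_times = as.numeric(pulse_times),
      pulse_width_us = pulse_width_us,
      frequency_hz = frequency_hz,
      strength_t = strength_t
    ),
    class = "stimulus_protocol"
  )
}

#' Train boundaries of a stimulus protocol
#'
#' The stimulation epoch runs from the first pulse to one inter-pulse
#' interval after the last pulse.
#'
#' @param stim A [stimulus_protocol()].
#' @return Named numeric vector `c(on, off)` in seconds.
#' @export
stim_bounds <- function(stim) {
  on <- stim$pulse_times[1]
  off <- stim$pulse_times[length(stim$pulse_times)] + 1 / stim$frequency_hz
  c(on = on, off = off)
}

#' Four-epoch segmentation of a root recording
#'
#' Boundary times defining the canonical epochs of a ventral-root response:
#' stimulation `[t_stim_on, t_stim_off]`, pre-spasm silence
#' `[t_stim_off, t_spasm_on]`, spasm `[t_spasm_on, t_spasm_off]` and
#' post-spasm silence `[t_spasm_off, t_end]`. These four intervals map onto
#' the normalized axis `[-1, 3]` (100 bins each) used for calcium peak times.
#'
#' @param t_stim_on,t_stim_off,t_spasm_on,t_spasm_off,t_end Boundary times in
#'   seconds, satisfying
#'   `t_stim_on < t_stim_off <= t_spasm_on < t_spasm_off <= t_end`.
#' @param spasm_detected Logical; `FALSE` marks a "no spasm" segmentation in
#'   which the spasm boundaries are `NA`.
#' @param silent_zero Logical flag set when the spasm began during (or at the
#'   end of) the stimulus train, i.e. the silent period has zero duration.
#'
#' @return A tibble of class `epoch_segmentation` with one row.
#' @export
#' @examples
#' seg <- epoch_segmentation(5, 6.5, 8.5, 28.5, 48.5)
#' epoch_durations(seg)
epoch_segmentation <- function(t_stim_on, t_stim_off, t_spasm_on, t_spasm_off,
                               t_end, spasm_detected = TRUE, silent_zero = FALSE) {
  if (spasm_detected) {
    b <- c(t_stim_on, t_stim_off, t_spasm_on, t_spasm_off, t_end)
    if (anyNA(b)) abort("Boundary times must not be NA.", class = "spasm_error_config")
    ok <- t_stim_on < t_stim_off && t_stim_off <= t_spasm_on &&
      t_spasm_on < t_spasm_off && t_spasm_off <= t_end
    if (!ok) {
      abort("Epoch boundaries must satisfy stim_on < stim_off <= spasm_on < spasm_off <= end.",
            class = "spasm_error_config")
    }
  } else {
    t_spasm_on <- NA_real_
    t_spasm_off <- NA_real_
  }
  out <- tibble::tibble(
    t_stim_on = t_stim_on, t_stim_off = t_stim_off,
    t_spasm_on = t_spasm_on, t_spasm_off = t_spasm_off, t_end = t_end,
    spasm_detected = spasm_detected, silent_zero = silent_zero
  )
  class(out) <- c("epoch_segmentation", class(out))
  out
}

#' Silent-period and spasm durations of a segmentation
#'
#' @param seg An [epoch_segmentation()].
#' @return A tibble with columns `silent_s` and `spasm_s`. For a "no spasm"
#'   segmentation the silent duration is `NA` and the spasm duration 0.
#' @export
epoch_durations <- function(seg) {
  stopifnot(inherits(seg, "epoch_segmentation"))
  if (!seg$spasm_detected) {
    return(tibble::tibble(silent_s = NA_real_, spasm_s = 0))
  }
  tibble::tibble(
    silent_s = seg$t_spasm_on - seg$t_stim_off,
    spasm_s = seg$t_spasm_off - seg$t_spasm_on
  )
}
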