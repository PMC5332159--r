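#' Integrated area of the rectified signal over a window
#'
#' Trapezoidal integral of `|x(t)|` over `[t0, t1]`, reported in
#' `units x ms` (mV.ms for a millivolt trace) as reflex areas are
#' conventionally quoted.
#'
#' @param trace A [ts_tbl()].
#' @param t0,t1 Window bounds (s), inside the recording, `t1 > t0`.
#' @return The rectified area (mV.ms).
#' @export
#' @examples
#' ts <- ts_tbl(seq(0, 0.01, by = 1e-4), rep(-1, 101))
#' rectified_area(ts, 0, 0.01) # 10 mV.ms
rectified_area <- function(trace, t0, t1) {
  w <- ts_window(trace, t0, t1)
  x <- abs(w$value)
  dt <- diff(w$time_s)
  sum((x[-1] + x[-length(x)]) / 2 * dt) * 1000
}

#' Monosynaptic and long-lasting reflex areas for one stimulus
#'
#' The short-latency (monosynaptic) response is the rectified area over a
#' 10 ms window post stimulus, and the long-lasting response over a
#' 50-4000 ms window, the period reflecting motor-unit activity during
#' spasms. The first `blank_ms` after the pulse are blanked because the
#' short-lasting deflections there are stimulus artifacts.
#'
#' @param trace A [ts_tbl()] root recording.
#' @param stim_time Stimulus time (s); the record must cover
#'   `stim_time + 4` s.
#' @param strength_t Stimulus strength (multiples of threshold T).
#' @param blank_ms Artifact blanking after the pulse (ms).
#' @return A one-row tibble `stimulus_strength`, `mono_area`, `long_area`
#'   (mV.ms).
#' @export
reflex_measures <- function(trace, stim_time, strength_t = 1, blank_ms = 2) {
  if (stim_time + 4 > trace$time_s[nrow(trace)] + 1e-9) {
    abort("Recording too short: needs 4 s after the stimulus.",
          class = "spasm_error_input")
  }
  tibble::tibble(
    stimulus_strength = strength_t,
    mono_area = rectified_area(trace, stim_time + blank_ms / 1000,
                               stim_time + 0.010),
    long_area = rectified_area(trace, stim_time + 0.050, stim_time + 4.0)
  )
}

#' Threshold and rising-phase slope of a stimulus-response curve
#'
#' The threshold T is the lowest stimulus strength whose response exceeds the
#' noise floor (the lowest strength eliciting the monosynaptic response);
#' the slope is the least-squares line over the rising portion, from the
#' first supra-threshold point to the curve maximum.
#'
#' @param measures Tibble with `strength_t` and the chosen area column, as
#'   accumulated from [reflex_measures()] (or [gen_stimulus_response()]).
#' @param component Column to analyze (default `"mono_area"`).
#' @param noise_floor Response floor; defaults to 5% of the curve maximum.
#' @return A one-row tibble `threshold_t`, `slope`, `n_rising`.
#' @export
#' @examples
#' sr <- gen_stimulus_response(slope = 66.25)
#' stimulus_response_curve(sr)$slope
stimulus_response_curve <- function(measures, component = "mono_area",
                                    noise_floor = NULL) {
  if (length(unique(measures$strength_t)) < 4) {
    abort("Need at least 4 distinct stimulus strengths.", class = "spasm_error_input")
  }
  m <- dplyr::arrange(measures, .data$strength_t)
  area <- m[[component]]
  noise_floor <- noise_floor %||% (0.05 * max(area))
  supra <- which(area > noise_floor)
  if (!length(supra)) {
    abort("No supra-threshold response; threshold T undefined.",
          class = "spasm_error_input")
  }
  first <- supra[1]
  imax <- which.max(area)
  if (imax <= first) imax <- min(length(area), first + 1L)
  idx <- first:imax
  fit <- lm(y ~ x, data = data.frame(x = m$strength_t[idx], y = area[idx]))
  tibble::tibble(threshold_t = m$strength_t[first],
                 slope = coef(fit)[[2]], n_rising = length(idx))
}

#' Segment a root recording into the four spasm epochs
#'
#' The envelope is a zero-phase low-pass (default 10 Hz) of the rectified
#' trace. Baseline statistics come from the `baseline_s` seconds preceding
#' the stimulus train; the spasm onset is the first time after the train end
#' that the envelope stays above `median + k_sd x robust SD` for at least
#' `min_dur`, and the offset the start of the first sub-threshold period of
#' at least `min_dur` after it. The post-spasm epoch extends one spasm
#' duration past the offset, capped at the recording end. Without any
#' supra-threshold episode a "no spasm" segmentation is returned rather than
#' an error. A spasm already running at the train end is flagged with
#' `silent_zero`.
#'
#' @param root A [ts_tbl()] root/EMG recording.
#' @param stim A [stimulus_protocol()].
#' @param k_sd Threshold in robust SDs above the baseline median.
#' @param min_dur Minimum supra/sub-threshold episode duration (s).
#' @param lowpass_hz Envelope low-pass corner (Hz).
#' @param baseline_s Baseline window length before the train (s).
#' @return An [epoch_segmentation()].
#' @export
segment_epochs <- function(root, stim, k_sd = 3, min_dur = 0.2,
                           lowpass_hz = 10, baseline_s = 5) {
  fs <- ts_rate(root)
  sb <- stim_bounds(stim)
  t_on <- sb[["on"]]
  t_off <- sb[["off"]]
  if (t_off + 10 > root$time_s[nrow(root)] + 1e-9) {
    abort("Recording must cover the stimulus train plus at least 10 s.",
          class = "spasm_error_input")
  }
  bf <- signal::butter(2, lowpass_hz / (fs / 2), type = "low")
  env <- signal::filtfilt(bf, abs(root$value))

  b0 <- max(root$time_s[1], t_on - baseline_s)
  base <- env[root$time_s >= b0 & root$time_s < t_on]
  thr <- median(base) + k_sd * mad(base)

  idx <- which(root$time_s >= t_off)
  above <- env[idx] > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  min_n <- round(min_dur * fs)

  on_run <- which(runs$values & runs$lengths >= min_n)
  if (!length(on_run)) {
    return(epoch_segmentation(t_on, t_off, NA, NA,
                              t_end = root$time_s[nrow(root)],
                              spasm_detected = FALSE))
  }
  r1 <- on_run[1]
  t_spasm_on <- root$time_s[idx[starts[r1]]]
  silent_zero <- starts[r1] == 1L
  off_run <- which(!runs$values & runs$lengths >= min_n & seq_along(runs$values) > r1)
  t_spasm_off <- if (length(off_run)) {
    root$time_s[idx[starts[off_run[1]]]]
  } else {
    root$time_s[nrow(root)]
  }
  spasm_dur <- t_spasm_off - t_spasm_on
  t_end <- min(root$time_s[nrow(root)], t_spasm_off + spasm_dur)
  epoch_segmentation(t_on, t_off, t_spasm_on, t_spasm_off, t_end,
                     silent_zero = silent_zero)
}
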