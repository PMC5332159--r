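#' Quality control of a motor-neuron recording
#'
#' Inclusion criteria: a stable resting potential below -60 mV and action
#' potentials of at least 70 mV amplitude. Accepts either a `ramp_recording`
#' (fields measured from the object) or explicit values.
#'
#' @param rec A `ramp_recording`, or `NULL` when passing values directly.
#' @param resting_mv Resting potential (mV).
#' @param ap_amplitude_mv Action-potential amplitude (mV); `NA` when no
#'   spikes are present.
#' @return A one-row tibble `pass`, `reason`.
#' @export
#' @examples
#' qc_motor_neuron(resting_mv = -65, ap_amplitude_mv = 75)$pass
qc_motor_neuron <- function(rec = NULL, resting_mv = NULL, ap_amplitude_mv = NULL) {
  if (!is.null(rec)) {
    resting_mv <- resting_mv %||% rec$resting_potential
    ap_amplitude_mv <- ap_amplitude_mv %||% rec$ap_amplitude
  }
  reasons <- character()
  if (is.na(ap_amplitude_mv)) {
    reasons <- c(reasons, "no action potentials: AP amplitude undefined")
  } else if (ap_amplitude_mv < 70) {
    reasons <- c(reasons, sprintf("AP amplitude %.1f mV < 70 mV", ap_amplitude_mv))
  }
  if (!(resting_mv < -60)) {
    reasons <- c(reasons, sprintf("resting potential %.1f mV not below -60 mV",
                                  resting_mv))
  }
  tibble::tibble(pass = length(reasons) == 0,
                 reason = if (length(reasons)) paste(reasons, collapse = "; ") else NA_character_)
}

# Action-potential times: upward crossings of `threshold_mv` with a
# refractory period. The recordings carry no spike-threshold metadata, so
# -20 mV / 2 ms are package conventions.
detect_aps <- function(voltage, threshold_mv = -20, refractory = 0.002) {
  v <- voltage$value
  up <- which(v[-1] > threshold_mv & v[-length(v)] <= threshold_mv) + 1L
  if (!length(up)) return(numeric())
  keep <- c(TRUE, diff(voltage$time_s[up]) > refractory)
  voltage$time_s[up[keep]]
}

#' Recruitment and de-recruitment currents of a ramp recording
#'
#' `i_re` is the command current at the first action potential (ascending
#' limb) and `i_de` the command current at the last one (descending limb);
#' `delta_i = i_de - i_re`. Negative values indicate firing sustained below
#' the recruitment current, the hallmark of a plateau potential. When the
#' cell is still firing as the command returns to zero, `i_de` is censored:
#' `delta_i` is then only a lower-bound flag and should be excluded from
#' population statistics.
#'
#' @param rec A `ramp_recording` from [gen_ramp_recording()] or built from
#'   read traces (a list with `current` and `voltage` [ts_tbl()]s).
#' @param ap_threshold_mv AP detection threshold (mV).
#' @return A one-row tibble: `i_re`, `i_de`, `delta_i`, `i_de_censored`,
#'   `n_spikes`.
#' @export
ramp_thresholds <- function(rec, ap_threshold_mv = -20) {
  spikes <- detect_aps(rec$voltage, ap_threshold_mv)
  if (!length(spikes)) {
    abort("No action potentials in the ramp recording.", class = "spasm_error_input")
  }
  cur <- rec$current
  apex_t <- cur$time_s[which.max(cur$value)]
  if (min(spikes) > apex_t) {
    abort("No spikes on the ascending limb; recruitment current undefined.",
          class = "spasm_error_input")
  }
  i_at <- function(t) approx(cur$time_s, cur$value, xout = t, rule = 2)$y
  i_re <- i_at(min(spikes))
  t_last <- max(spikes)
  i_de <- i_at(t_last)
  censored <- t_last >= max(cur$time_s) - 2 / ts_rate(cur) ||
    i_de <= 0.01 * max(cur$value)
  tibble::tibble(i_re = i_re, i_de = i_de, delta_i = i_de - i_re,
                 i_de_censored = censored, n_spikes = length(spikes))
}

#' f-I hysteresis of a ramp recording
#'
#' Builds the instantaneous frequency-current relation per limb (frequencies
#' attached to inter-spike-interval midpoints, which keeps a linear rate
#' profile unbiased on both limbs), interpolates both branches over their
#' overlapping current range, and reports the signed hysteresis index
#' `mean(f_descending - f_ascending)`. Counter-clockwise (`ccw`, descending
#' branch above the ascending one) indicates a plateau; `cw` the opposite;
#' `linear` when the index is within the noise floor `epsilon` (2 x the SD
#' of within-limb residuals around a linear f-I fit, with a 0.2 Hz floor for
#' noise-free fixtures).
#'
#' @param rec A `ramp_recording`.
#' @param ap_threshold_mv AP detection threshold (mV).
#' @param n_grid Interpolation points across the overlap range.
#' @return A one-row tibble `hysteresis` (`ccw`/`linear`/`cw`), `index_hz`,
#'   `epsilon_hz`, `mean_rate_hz`.
#' @export
fi_hysteresis <- function(rec, ap_threshold_mv = -20, n_grid = 21) {
  spikes <- detect_aps(rec$voltage, ap_threshold_mv)
  cur <- rec$current
  apex_t <- cur$time_s[which.max(cur$value)]
  asc <- spikes[spikes <= apex_t]
  desc <- spikes[spikes > apex_t]
  if (length(asc) < 3 || length(desc) < 3) {
    abort("Need at least 3 spikes on each limb for f-I hysteresis.",
          class = "spasm_error_input")
  }
  i_at <- function(t) approx(cur$time_s, cur$value, xout = t, rule = 2)$y
  branch <- function(t) {
    mid <- (t[-1] + t[-length(t)]) / 2
    tibble::tibble(i = i_at(mid), f = 1 / diff(t))
  }
  a <- branch(asc)
  d <- branch(desc)
  lo <- max(min(a$i), min(d$i))
  hi <- min(max(a$i), max(d$i))
  mean_rate <- mean(c(a$f, d$f))
  if (hi <= lo) {
    warn("No overlapping current range between limbs; reporting linear.")
    return(tibble::tibble(hysteresis = "linear", index_hz = 0,
                          epsilon_hz = NA_real_, mean_rate_hz = mean_rate))
  }
  grid <- seq(lo, hi, length.out = n_grid)
  fa <- approx(a$i, a$f, xout = grid, ties = mean)$y
  fd <- approx(d$i, d$f, xout = grid, ties = mean)$y
  index <- mean(fd - fa, na.rm = TRUE)
  res <- c(stats::resid(lm(f ~ i, data = a)), stats::resid(lm(f ~ i, data = d)))
  eps <- max(2 * sd(res), 0.2)
  hyst <- if (index > eps) "ccw" else if (index < -eps) "cw" else "linear"
  tibble::tibble(hysteresis = hyst, index_hz = index, epsilon_hz = eps,
                 mean_rate_hz = mean_rate)
}

#' Plateau class from delta-I and hysteresis
#'
#' \itemize{
#'   \item \strong{full}: counter-clockwise hysteresis with negative delta-I
#'     (sustained firing below recruitment, self-sustained plateau);
#'   \item \strong{intermediate}: as full, but with slow sustained firing
#'     (mean rate below `rate_boundary_hz`), the published slow-firing
#'     plateau profile;
#'   \item \strong{partial}: negative delta-I with a linear f-I plot
#'     (sub-threshold plateau activation);
#'   \item \strong{none}: non-negative delta-I (linear or clockwise f-I).
#' }
#' A clockwise f-I with negative delta-I is contradictory for a plateau
#' mechanism and is classified by the delta-I sign, i.e. as `partial`.
#'
#' @param delta_i De-recruitment minus recruitment current (nA).
#' @param hysteresis `"ccw"`, `"linear"` or `"cw"`.
#' @param mean_rate_hz Mean firing rate (Hz), used for the intermediate
#'   split; `NA` disables it.
#' @param rate_boundary_hz Slow-firing boundary (Hz).
#' @return The plateau class as a character scalar.
#' @export
#' @examples
#' classify_plateau(-1.5, "ccw")
#' classify_plateau(0.168, "cw")
classify_plateau <- function(delta_i, hysteresis, mean_rate_hz = NA,
                             rate_boundary_hz = 30) {
  stopifnot(hysteresis %in% c("ccw", "linear", "cw"))
  if (delta_i >= 0) return("none")
  if (hysteresis == "ccw") {
    if (!is.na(mean_rate_hz) && mean_rate_hz < rate_boundary_hz) {
      return("intermediate")
    }
    return("full")
  }
  "partial"
}

#' Full plateau assessment of a ramp recording
#'
#' Combines [ramp_thresholds()], [fi_hysteresis()] and [classify_plateau()].
#'
#' @param rec A `ramp_recording`.
#' @param rate_boundary_hz Passed to [classify_plateau()].
#' @return A one-row tibble: thresholds, hysteresis and `plateau_class`.
#' @export
assess_plateau <- function(rec, rate_boundary_hz = 30) {
  th <- ramp_thresholds(rec)
  hy <- fi_hysteresis(rec)
  dplyr::bind_cols(th, hy) |>
    dplyr::mutate(plateau_class = classify_plateau(
      .data$delta_i, .data$hysteresis, .data$mean_rate_hz, rate_boundary_hz
    ))
}

#' Detect synaptic events (EPSPs/IPSPs) around a stimulation
#'
#' Candidate events are derivative-threshold crossings on the median-filtered
#' voltage (threshold `k_sd` robust SDs of the differentiated trace);
#' polarity follows the deflection sign at the holding potential
#' (depolarizing = EPSP, hyperpolarizing = IPSP, meaningful at depolarized
#' holding); amplitude is baseline-to-peak. Events are counted in windows of
#' `window` seconds before and after `stim_time`.
#'
#' @param voltage A [ts_tbl()] of membrane potential (mV).
#' @param stim_time Stimulation time (s).
#' @param window Window length either side of `stim_time` (s, default 20).
#' @param min_amp Minimum event amplitude (mV).
#' @param k_sd Derivative threshold in robust SDs.
#' @param med_s Median-filter length (s).
#' @param peak_s Peak search span after onset (s).
#' @return A tibble `time_s`, `polarity` (`"EPSP"`/`"IPSP"`), `amplitude`,
#'   `window` (`"pre"`/`"post"`); possibly zero rows.
#' @export
detect_synaptic_events <- function(voltage, stim_time, window = 20,
                                   min_amp = 0.5, k_sd = 3, med_s = 0.001,
                                   peak_s = 0.03) {
  t0 <- stim_time - window
  t1 <- stim_time + window
  if (t0 < voltage$time_s[1] - 1e-9 || t1 > voltage$time_s[nrow(voltage)] + 1e-9) {
    abort("Pre/post windows exceed the recording.", class = "spasm_error_input")
  }
  v <- ts_window(voltage, t0, t1)
  fs <- ts_rate(voltage)
  k <- max(3L, 2L * floor(med_s * fs / 2 + 1e-9) + 1L)
  vf <- stats::runmed(v$value, k)
  # Slope over a `med_s` step rather than adjacent samples: a PSP rise spans
  # milliseconds, and the wider step averages the sample-to-sample noise out
  # of the derivative.
  m <- max(1L, round(med_s * fs))
  dv <- (vf[-seq_len(m)] - vf[seq_len(length(vf) - m)]) * fs / m
  # Amplitudes are read from a wider median filter: the event peak spans
  # several ms, and the extra smoothing keeps noise excursions below the
  # `min_amp` gate without eroding real PSP peaks.
  k3 <- max(3L, 2L * floor(3 * med_s * fs / 2 + 1e-9) + 1L)
  va <- stats::runmed(v$value, k3)
  s <- mad(dv)
  if (s == 0) {
    return(tibble::tibble(time_s = numeric(), polarity = character(),
                          amplitude = numeric(), window = character()))
  }
  thr <- k_sd * s
  hot <- which(abs(dv) > thr)
  if (!length(hot)) {
    return(tibble::tibble(time_s = numeric(), polarity = character(),
                          amplitude = numeric(), window = character()))
  }
  gap_n <- max(1L, round(0.005 * fs))
  peak_n <- max(1L, round(peak_s * fs))
  base_n <- max(1L, round(0.01 * fs))
  n <- length(vf)

  sgn <- sign(dv[hot])
  starts <- hot[c(TRUE, diff(hot) > gap_n | sgn[-1] != sgn[-length(sgn)])]
  ev <- purrr::map_dfr(starts, function(i0) {
    pol <- sign(dv[i0])
    # End of the monotone rise: first sign change of the smoothed slope.
    jmax <- min(length(dv), i0 + peak_n)
    run <- which(sign(dv[i0:jmax]) != pol)
    pk <- min(n, i0 + (if (length(run)) run[1] - 1L else peak_n) + m %/% 2)
    base <- median(va[max(1L, i0 - base_n):i0])
    amp <- (va[pk] - base) * pol
    tibble::tibble(time_s = v$time_s[i0],
                   polarity = if (pol > 0) "EPSP" else "IPSP",
                   amplitude = amp, peak_value = va[pk], base_value = base)
  })
  ev <- ev[ev$amplitude >= min_amp, ]
  # Collapse repeated detections of one rise: same polarity within 10 ms.
  if (nrow(ev) > 1) {
    keep <- c(TRUE, !(diff(ev$time_s) < 0.01 &
                        ev$polarity[-1] == ev$polarity[-nrow(ev)]))
    ev <- ev[keep, ]
  }
  # Drop relaxation artifacts: an opposite-polarity deflection shortly after
  # an event that merely returns toward that event's baseline is its decay;
  # a genuine opposite event overshoots the pre-event baseline.
  if (nrow(ev) > 1) {
    drop <- logical(nrow(ev))
    for (k2 in 2:nrow(ev)) {
      left <- which(!drop[seq_len(k2 - 1)])
      if (!length(left)) next
      prev <- max(left)
      if (ev$polarity[k2] != ev$polarity[prev] &&
          ev$time_s[k2] - ev$time_s[prev] < 0.035) {
        pol <- if (ev$polarity[k2] == "EPSP") 1 else -1
        overshoot <- (ev$peak_value[k2] - ev$base_value[prev]) * pol
        if (overshoot < 0.8 * min_amp) drop[k2] <- TRUE
      }
    }
    ev <- ev[!drop, ]
  }
  ev$window <- ifelse(ev$time_s < stim_time, "pre", "post")
  ev[, c("time_s", "polarity", "amplitude", "window")]
}

#' Excitation/inhibition balance from event counts
#'
#' `inhibition = IPSPs / (IPSPs + EPSPs)` and
#' `excitation = EPSPs / (IPSPs + EPSPs)`; the fractions always sum to 1.
#'
#' @param n_ipsp,n_epsp Non-negative event counts.
#' @return A one-row tibble `inhibition`, `excitation`.
#' @export
#' @examples
#' ei_balance(5, 5)
ei_balance <- function(n_ipsp, n_epsp) {
  if (n_ipsp < 0 || n_epsp < 0) {
    abort("Event counts must be >= 0.", class = "spasm_error_input")
  }
  tot <- n_ipsp + n_epsp
  if (tot == 0) {
    abort("No synaptic events: the E/I balance is undefined.",
          class = "spasm_error_input")
  }
  inh <- n_ipsp / tot
  # E/(I+E) = 1 - I/(I+E) exactly on counts; the subtraction keeps the two
  # reported fractions summing to 1 without floating-point residue.
  tibble::tibble(inhibition = inh, excitation = 1 - inh)
}
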