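#' Band-pass filter an extracellular trace
#'
#' Zero-phase Butterworth band-pass (default 100-1000 Hz, the acquisition
#' band of the gross EMG/root recordings).
#'
#' @param trace A [ts_tbl()].
#' @param low_hz,high_hz Band edges (Hz).
#' @param order Filter order.
#' @return A filtered [ts_tbl()].
#' @export
bandpass_filter <- function(trace, low_hz = 100, high_hz = 1000, order = 2) {
  fs <- ts_rate(trace)
  w <- c(low_hz, min(high_hz, 0.45 * fs)) / (fs / 2)
  bf <- signal::butter(order, w, type = "pass")
  ts_tbl(trace$time_s, signal::filtfilt(bf, trace$value),
         units = ts_units(trace), rate_hz = fs)
}

#' Detect spikes by threshold crossing
#'
#' Band-passes the trace, thresholds its absolute value at
#' `median + threshold_sd * robust SD` (MAD), and keeps one spike per
#' refractory window. Spike amplitude is the peak absolute deflection within
#' the refractory window; a short waveform snippet is attached for template
#' matching.
#'
#' @param trace A [ts_tbl()].
#' @param threshold_sd Detection threshold in robust SDs (> 0).
#' @param refractory Minimum spike separation (s).
#' @param band `c(low, high)` band-pass edges in Hz; `NULL` skips filtering.
#' @param snippet_s Length of the attached waveform snippet (s).
#' @return A spike-train tibble: `time_s` (strictly increasing), `amplitude`,
#'   and a `waveform` list column. Detection runs on the filtered trace;
#'   amplitude (peak absolute deflection) and snippets are taken from the
#'   unfiltered trace so they remain comparable with physical templates.
#'   A flat trace yields zero rows with a warning.
#' @export
detect_spikes <- function(trace, threshold_sd = 5, refractory = 0.002,
                          band = c(100, 1000), snippet_s = 0.002) {
  if (!nrow(trace)) abort("Empty trace.", class = "spasm_error_input")
  if (threshold_sd <= 0) abort("`threshold_sd` must be > 0.", class = "spasm_error_input")
  fs <- ts_rate(trace)
  x <- if (is.null(band)) trace$value else bandpass_filter(trace, band[1], band[2])$value
  s <- mad(x)
  if (s == 0) {
    warn("Flat trace (zero robust SD); no spikes detected.")
    return(tibble::tibble(time_s = numeric(), amplitude = numeric(),
                          waveform = list()))
  }
  thr <- median(x) + threshold_sd * s
  above <- which(abs(x) > thr)
  if (!length(above)) {
    return(tibble::tibble(time_s = numeric(), amplitude = numeric(),
                          waveform = list()))
  }
  raw <- trace$value
  ref_n <- max(1L, round(refractory * fs))
  half <- max(1L, round(snippet_s * fs / 2))
  n <- length(x)
  pks <- integer()
  i <- 1L
  while (i <= length(above)) {
    i0 <- above[i]
    seg <- i0:min(n, i0 + ref_n)
    pk <- seg[which.max(abs(raw[seg]))]
    pks <- c(pks, pk)
    i <- findInterval(pk + ref_n, above) + 1L
  }
  tibble::tibble(
    time_s = trace$time_s[pks],
    amplitude = abs(raw[pks]),
    waveform = lapply(pks, function(pk) raw[max(1L, pk - half):min(n, pk + half)])
  )
}

#' Assign detected spikes to motor units by template matching
#'
#' A spike joins a unit iff its amplitude differs from the template amplitude
#' by strictly less than `tolerance` (default 20%, the published criterion;
#' a change of exactly 20% is rejected) and, when waveforms are available,
#' its waveform correlates with the template at or above `cor_floor`.
#' Spikes matching several templates take the closest amplitude; unmatched
#' spikes keep `unit_id = NA`.
#'
#' @param spikes Spike tibble from [detect_spikes()] (columns `time_s`,
#'   `amplitude`, optional `waveform`).
#' @param templates Tibble with `unit_id`, `amplitude` and optional
#'   `waveform` list column, or a bare numeric vector of template amplitudes.
#' @param tolerance Relative amplitude tolerance in (0, 1).
#' @param cor_floor Minimum waveform correlation.
#' @return The spike tibble with a `unit_id` column added.
#' @export
#' @examples
#' sp <- tibble::tibble(time_s = 1:3 / 10, amplitude = c(1.19, 1.25, 0.9))
#' template_match(sp, templates = c(u1 = 1))$unit_id
template_match <- function(spikes, templates, tolerance = 0.20, cor_floor = 0.8) {
  if (tolerance <= 0 || tolerance >= 1) {
    abort("`tolerance` must be in (0, 1).", class = "spasm_error_input")
  }
  if (is.numeric(templates)) {
    templates <- tibble::tibble(
      unit_id = names(templates) %||% sprintf("u%02d", seq_along(templates)),
      amplitude = as.numeric(templates)
    )
  }
  spikes$unit_id <- NA_character_
  if (!nrow(templates) || !nrow(spikes)) return(spikes)
  has_wf <- "waveform" %in% names(spikes) && "waveform" %in% names(templates)

  # Align two waveforms on their absolute peaks; returns the least-squares
  # amplitude of `w` against the template shape and their correlation. The
  # projection estimator averages noise over the whole waveform instead of
  # reading a single (noise-biased) extremum.
  wf_fit <- function(w, tpl, amp) {
    pw <- which.max(abs(w))
    pt <- which.max(abs(tpl))
    lo <- min(pw, pt) - 1L
    hi <- min(length(w) - pw, length(tpl) - pt)
    iw <- (pw - lo):(pw + hi)
    it <- (pt - lo):(pt + hi)
    if (length(iw) < 5) return(c(a = NA_real_, cc = 1))
    s <- tpl[it] / amp
    a <- sum(w[iw] * s) / sum(s^2)
    suppressWarnings(cc <- stats::cor(w[iw], tpl[it]))
    c(a = a, cc = if (is.finite(cc)) cc else -1)
  }

  for (k in seq_len(nrow(spikes))) {
    if (has_wf) {
      fits <- vapply(seq_len(nrow(templates)), function(j) {
        wf_fit(spikes$waveform[[k]], templates$waveform[[j]],
               templates$amplitude[j])
      }, c(a = 0, cc = 0))
      amp_k <- ifelse(is.na(fits["a", ]), spikes$amplitude[k], fits["a", ])
      rel <- abs(amp_k - templates$amplitude) / templates$amplitude
      cand <- which(tolerance - rel > 1e-9 & fits["cc", ] >= cor_floor)
    } else {
      rel <- abs(spikes$amplitude[k] - templates$amplitude) / templates$amplitude
      # strict "<": a change of exactly `tolerance` (up to representation
      # error) is rejected
      cand <- which(tolerance - rel > 1e-9)
    }
    if (length(cand)) {
      spikes$unit_id[k] <- templates$unit_id[cand[which.min(rel[cand])]]
    }
  }
  spikes
}

#' Instantaneous firing frequency of a spike train
#'
#' Reciprocal inter-spike intervals: the value attached to spike `k`
#' (`k >= 2`) is `1 / (t_k - t_{k-1})`, giving `n - 1` samples.
#'
#' @param spikes Spike tibble (column `time_s`) or numeric spike times.
#' @return A tibble `time_s`, `freq_hz`; empty for fewer than two spikes.
#' @export
#' @examples
#' instantaneous_frequency(c(0, 0.1, 0.2))$freq_hz
instantaneous_frequency <- function(spikes) {
  t <- if (is.data.frame(spikes)) spikes$time_s else as.numeric(spikes)
  if (length(t) < 2) {
    return(tibble::tibble(time_s = numeric(), freq_hz = numeric()))
  }
  if (is.unsorted(t, strictly = TRUE)) {
    abort("Spike times must be strictly increasing.", class = "spasm_error_input")
  }
  tibble::tibble(time_s = t[-1], freq_hz = 1 / diff(t))
}

#' Hartigan's dip test of unimodality
#'
#' Computes the dip statistic (the sup-norm distance from the empirical cdf
#' to the closest unimodal cdf) and a bootstrap p-value against the uniform
#' null, the least favourable unimodal distribution.
#'
#' @param x Numeric sample.
#' @param n_boot Bootstrap resamples for the p-value (0 skips it).
#' @return A one-row tibble `statistic`, `p_value`, `n`.
#' @export
#' @examples
#' set.seed(1)
#' dip_test(c(rnorm(100), rnorm(100, 6)))$p_value
dip_test <- function(x, n_boot = 2000) {
  x <- x[is.finite(x)]
  if (length(x) < 4) {
    abort("Need at least 4 observations for the dip test.", class = "spasm_error_input")
  }
  d <- .dip_statistic(x)
  p <- if (n_boot > 0) .dip_pvalue_boot(d, length(x), as.integer(n_boot)) else NA_real_
  tibble::tibble(statistic = d, p_value = p, n = length(x))
}

# Least-squares change point of a frequency sequence: the split minimizing
# pooled within-segment sum of squares. Returns the index of the first
# sample of the second segment.
change_point <- function(v) {
  n <- length(v)
  if (n < 4) return(NA_integer_)
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  k <- 2:(n - 1)
  ss1 <- cs2[k - 1] - cs[k - 1]^2 / (k - 1)
  ss2 <- (cs2[n] - cs2[k - 1]) - (cs[n] - cs[k - 1])^2 / (n - k + 1)
  k[which.min(ss1 + ss2)]
}

#' Classify the firing phenotype of a motor unit
#'
#' Implements the four-way phenotyping of motor-unit firing during spasms:
#' \itemize{
#'   \item \strong{bimodal} if Hartigan's dip test on the instantaneous
#'     frequencies rejects unimodality (`p < dip_alpha`);
#'   \item otherwise \strong{long_lasting} if the frequency declines
#'     significantly over time (least-squares slope < 0 at `trend_alpha`);
#'   \item otherwise \strong{high} or \strong{low} by the mean frequency
#'     against `high_low_hz` (30 Hz, the midpoint of the published class
#'     means 45.55 and 17.87 Hz).
#' }
#' Units with fewer than `min_samples` frequency samples, or from recordings
#' shorter than `min_duration`, are `unclassified`.
#'
#' Sorting artifacts are removed from the frequency series before
#' classification: a missed spike halves one frequency sample and a
#' collision-born double detection inflates one, and such implausible-ISI
#' samples would masquerade as spurious modes. Samples outside
#' `clean_bounds` times the running median frequency (window
#' `clean_window`) are dropped; contiguous firing phases and trends pass
#' through unchanged.
#'
#' @param freq Frequency tibble from [instantaneous_frequency()].
#' @param clean_bounds `c(lo, hi)` plausibility band around the running
#'   median; `NULL` disables cleaning.
#' @param clean_window Odd running-median window for the plausibility band.
#' @param recording_duration Total recording span (s); classification
#'   requires at least `min_duration` (default 300 s, i.e. five minutes).
#' @param min_duration Minimum recording span (s).
#' @param high_low_hz Boundary between high- and low-frequency classes (Hz).
#' @param dip_alpha,trend_alpha Significance levels.
#' @param min_samples Minimum number of frequency samples.
#' @param n_boot Dip-test bootstrap resamples.
#' @return A one-row tibble: `phenotype`, `mean_hz`, `sd_hz`, `dip_p`,
#'   `slope_hz_s`, `slope_p`, `phase1_hz`, `phase2_hz`, `n_samples`.
#'   The phase columns are the segment means either side of the
#'   least-squares change point of the frequency series; they summarize the
#'   two phases of bimodal units (and are reported for every unit).
#' @export
classify_firing_pattern <- function(freq, recording_duration = NULL,
                                    min_duration = 300, high_low_hz = 30,
                                    dip_alpha = 0.05, trend_alpha = 0.05,
                                    min_samples = 20, n_boot = 2000,
                                    clean_bounds = c(0.6, 1.7),
                                    clean_window = 21) {
  base <- tibble::tibble(
    phenotype = "unclassified", mean_hz = NA_real_, sd_hz = NA_real_,
    dip_p = NA_real_, slope_hz_s = NA_real_, slope_p = NA_real_,
    phase1_hz = NA_real_, phase2_hz = NA_real_, n_samples = nrow(freq)
  )
  if (!is.null(recording_duration) && recording_duration < min_duration) {
    return(base)
  }
  if (nrow(freq) < min_samples) return(base)
  if (!is.null(clean_bounds) && nrow(freq) > clean_window) {
    local_med <- stats::runmed(freq$freq_hz, clean_window)
    ratio <- freq$freq_hz / local_med
    freq <- freq[ratio > clean_bounds[1] & ratio < clean_bounds[2], ]
    base$n_samples <- nrow(freq)
    if (nrow(freq) < min_samples) return(base)
  }

  base$mean_hz <- mean(freq$freq_hz)
  base$sd_hz <- sd(freq$freq_hz)
  dp <- dip_test(freq$freq_hz, n_boot = n_boot)
  base$dip_p <- dp$p_value
  fit <- lm(freq_hz ~ time_s, data = freq)
  sm <- summary(fit)$coefficients
  base$slope_hz_s <- sm[2, 1]
  base$slope_p <- sm[2, 4]

  cp <- change_point(freq$freq_hz)
  if (!is.na(cp)) {
    base$phase1_hz <- mean(freq$freq_hz[seq_len(cp - 1)])
    base$phase2_hz <- mean(freq$freq_hz[cp:nrow(freq)])
  }

  if (!is.na(dp$p_value) && dp$p_value < dip_alpha) {
    base$phenotype <- "bimodal"
  } else if (base$slope_hz_s < 0 && base$slope_p < trend_alpha) {
    base$phenotype <- "long_lasting"
  } else {
    base$phenotype <- if (base$mean_hz >= high_low_hz) "high" else "low"
  }
  base
}

#' Detect, sort and phenotype motor units in one call
#'
#' Chains [detect_spikes()], [template_match()], [instantaneous_frequency()]
#' and [classify_firing_pattern()] over an EMG/root trace.
#'
#' @param trace A [ts_tbl()].
#' @param templates Template table (see [template_match()]).
#' @param recording_duration Span passed to the classifier; defaults to the
#'   trace duration.
#' @param ... Passed to [classify_firing_pattern()].
#' @return A list: `units` (one row per unit: classification summary plus
#'   `n_spikes`), `spikes` (assigned spike table).
#' @export
analyze_motor_units <- function(trace, templates, recording_duration = NULL, ...) {
  sp <- detect_spikes(trace)
  sp <- template_match(sp, templates)
  dur <- recording_duration %||% ts_duration(trace)
  assigned <- sp[!is.na(sp$unit_id), ]
  units <- purrr::map_dfr(split(assigned, assigned$unit_id), function(u) {
    fr <- instantaneous_frequency(u)
    cls <- classify_firing_pattern(fr, recording_duration = dur, ...)
    dplyr::bind_cols(tibble::tibble(unit_id = u$unit_id[1],
                                    n_spikes = nrow(u)), cls)
  })
  list(units = units, spikes = sp)
}
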