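#' Generate one motor-unit spike train of a given firing phenotype
#'
#' Spike trains are built in instantaneous-frequency space so that the mean
#' instantaneous frequency of the unit equals the programmed `mean_hz`
#' (arithmetic mean over spikes). Phenotypes:
#' \describe{
#'   \item{long_lasting}{frequency declines linearly from 1.35 to 0.65 times
#'     the unit mean across the spasm (a gradual decrease).}
#'   \item{bimodal}{an initial unstable phase at `mean_hz` (within-unit SD
#'     `jitter_hz1`) followed by a stable phase at `mean_hz2`.}
#'   \item{high, low}{stationary firing at `mean_hz` with no trend.}
#' }
#'
#' @param phenotype One of `"long_lasting"`, `"bimodal"`, `"high"`, `"low"`.
#' @param mean_hz Unit mean instantaneous frequency (initial phase for
#'   bimodal units).
#' @param t_on,t_off Spasm epoch bounds; all spikes fall inside.
#' @param mean_hz2 Second-phase frequency for bimodal units.
#' @param jitter_hz Within-unit frequency SD (long_lasting trend jitter).
#' @param jitter_hz1,jitter_hz2 Within-phase frequency SDs; for bimodal
#'   units the defaults scale with the phase means (12% unstable initial
#'   phase, 10.5% stable second phase, matching the published within-class
#'   spreads at the class means), for stationary units `jitter_hz2`
#'   defaults to 2.5 Hz.
#' @param phase1_frac Fraction of the epoch occupied by the initial bimodal
#'   phase.
#' @return A tibble with column `time_s` (strictly increasing spike times).
#' @export
#' @examples
#' set.seed(1)
#' sp <- gen_unit_spikes("long_lasting", 27, t_on = 0, t_off = 60)
#' mean(instantaneous_frequency(sp)$freq_hz)
gen_unit_spikes <- function(phenotype, mean_hz, t_on, t_off,
                            mean_hz2 = NA, jitter_hz = 2,
                            jitter_hz1 = NULL, jitter_hz2 = NULL,
                            phase1_frac = 0.35) {
  stopifnot(t_off > t_on, mean_hz > 0)
  dur <- t_off - t_on
  freqs <- switch(
    phenotype,
    long_lasting = {
      # E[1/f] over the 1.35..0.65 ramp is 1.0444/mean, hence the count scale.
      k <- max(2L, floor(dur * mean_hz / 1.0444 * 0.99))
      mean_hz * seq(1.35, 0.65, length.out = k) + rnorm(k, 0, jitter_hz)
    },
    bimodal = {
      stopifnot(is.finite(mean_hz2), mean_hz2 > 0, mean_hz2 < mean_hz)
      j1 <- jitter_hz1 %||% (0.12 * mean_hz)
      j2 <- jitter_hz2 %||% (0.105 * mean_hz2)
      k1 <- max(2L, floor(phase1_frac * dur * mean_hz * 0.98))
      k2 <- max(2L, floor((1 - phase1_frac) * dur * mean_hz2 * 0.98))
      c(rnorm(k1, mean_hz, j1), rnorm(k2, mean_hz2, j2))
    },
    high = ,
    low = {
      k <- max(2L, floor(dur * mean_hz * 0.98))
      rnorm(k, mean_hz, jitter_hz2 %||% 2.5)
    },
    abort(sprintf("Unknown phenotype '%s'.", phenotype), class = "spasm_error_config")
  )
  freqs <- pmax(freqs, 1)
  times <- t_on + cumsum(1 / freqs)
  tibble::tibble(time_s = times[times <= t_off])
}

# Biphasic extracellular spike template: a dominant positive lobe followed by
# a smaller negative one over `width_s`, unit peak amplitude. Only the
# amplitude enters the 20% template-matching criterion, so the shape is a
# convention; the lobe asymmetry keeps peak alignment unambiguous.
spike_template <- function(rate_hz, width_s = 0.002) {
  n <- max(8L, round(width_s * rate_hz))
  u <- seq(0, 1, length.out = n)
  w <- sin(2 * pi * u) * sin(pi * u)^0.5
  w[w < 0] <- 0.6 * w[w < 0]
  w / max(abs(w))
}

add_waveforms <- function(signal, idx, template, amps) {
  m <- length(template)
  n <- length(signal)
  for (j in seq_along(idx)) {
    i0 <- idx[j]
    i1 <- min(n, i0 + m - 1L)
    k <- i1 - i0 + 1L
    signal[i0:i1] <- signal[i0:i1] + amps[j] * template[seq_len(k)]
  }
  signal
}

# Across-unit parameter draw for one unit: the unit mean frequency comes
# from the published class distribution; for bimodal units the second phase
# is a fraction of the first (ratio centered on the published class-mean
# ratio 23.85/41.48, clipped so the two phases of every drawn unit stay
# separable — an inseparable "bimodal" unit would contradict its own
# phenotype definition).
draw_unit_means <- function(phenotype, mean_hz, sd_hz, mean_hz2 = NA) {
  m1 <- max(2, rnorm(1, mean_hz, sd_hz))
  m2 <- if (is.finite(mean_hz2)) {
    r <- min(max(rnorm(1, mean_hz2 / mean_hz, 0.05), 0.40), 0.66)
    m1 * r
  } else {
    NA_real_
  }
  c(m1, m2)
}

# Stratified Gaussian sample: one draw per probability stratum, in random
# order. The sample follows N(mean, sd) exactly in distribution while its
# sample moments match the programmed ones far more tightly than iid draws,
# so a population of n units is representative of its class statistics and
# parameter-recovery error reflects the pipeline, not draw luck.
strat_norm <- function(n, mean, sd) {
  u <- (sample.int(n) - runif(n)) / n
  mean + sd * qnorm(u)
}

#' Generate a population of motor-unit spike trains of one phenotype
#'
#' Per-unit mean frequencies form a stratified sample of the published
#' across-unit class distribution (each unit drawn from one quantile stratum,
#' in random order), so the population realizes the printed class mean and SD;
#' each spike train is then built with [gen_unit_spikes()].
#'
#' @param n_units Number of units.
#' @param phenotype,mean_hz,sd_hz,mean_hz2 Class firing statistics (see
#'   [default_unit_specs()]).
#' @param t_on,t_off Spasm epoch bounds (s).
#' @return A tibble `unit_id`, `phenotype`, `mean_hz_true`, `time_s`.
#' @export
gen_phenotype_units <- function(n_units, phenotype, mean_hz, sd_hz,
                                mean_hz2 = NA, t_on = 0, t_off = 60) {
  m1 <- pmax(2, strat_norm(n_units, mean_hz, sd_hz))
  purrr::map_dfr(seq_len(n_units), function(i) {
    m2 <- if (is.finite(mean_hz2)) {
      m1[i] * min(max(rnorm(1, mean_hz2 / mean_hz, 0.05), 0.40), 0.66)
    } else {
      NA_real_
    }
    st <- gen_unit_spikes(phenotype, m1[i], t_on, t_off, mean_hz2 = m2)
    tibble::tibble(unit_id = sprintf("%s_%02d", phenotype, i),
                   phenotype = phenotype, mean_hz_true = m1[i],
                   time_s = st$time_s)
  })
}

#' Generate a full synthetic spasm session (EMG + root traces)
#'
#' Builds a session with the canonical structure: baseline, stimulus train,
#' silent period, spasm, post-spasm silence. Each configured motor unit
#' fires only inside the spasm epoch with its phenotype's frequency profile;
#' the EMG trace is the sum of template waveforms (amplitude jittered within
#' +/- 8%, inside the 20% matching tolerance) plus Gaussian noise, and the
#' root trace additionally carries per-pulse stimulus artifacts and small
#' monosynaptic reflex responses. Ground truth (spike trains, templates,
#' segmentation) is returned alongside.
#'
#' @param config A [spasm_session_config()].
#' @return A list with elements `emg` and `root` (both [ts_tbl()] tibbles)
#'   and `ground_truth` (list: `spikes`, `units`, `segmentation`, `stim`).
#' @export
gen_spasm_session <- function(config) {
  stopifnot(inherits(config, "spasm_session_config"))
  with_seed(config$seed, {
    fs <- config$sampling_rate
    et <- config$epoch_times
    spasm_dur <- et[4] - et[3]
    t_end <- et[4] + spasm_dur
    seg <- epoch_segmentation(et[1], et[2], et[3], et[4], t_end)
    n <- ceiling(t_end * fs) + 1L
    time_s <- (seq_len(n) - 1L) / fs
    template <- spike_template(fs)

    units <- config$units
    spikes <- NULL
    emg <- rnorm(n, 0, config$noise_sd)
    drive <- numeric(n)
    if (nrow(units)) {
      units$unit_id <- sprintf("u%02d", seq_len(nrow(units)))
      units$waveform <- lapply(units$amplitude, function(a) a * template)
      spikes <- purrr::pmap_dfr(units, function(phenotype, mean_hz, sd_hz,
                                                mean_hz2, sd_hz2, amplitude,
                                                unit_id, ...) {
        par <- draw_unit_means(phenotype, mean_hz, sd_hz, mean_hz2)
        st <- gen_unit_spikes(phenotype, par[1], et[3], et[4], mean_hz2 = par[2])
        tibble::tibble(
          unit_id = unit_id, phenotype = phenotype, time_s = st$time_s,
          amplitude = amplitude * (1 + runif(nrow(st), -0.08, 0.08))
        )
      })
      if (nrow(spikes)) {
        idx <- pmin(n, floor(spikes$time_s * fs) + 1L)
        drive <- add_waveforms(drive, idx, template, spikes$amplitude)
        emg <- emg + drive
      }
    }

    # Root trace: attenuated motor-unit drive + stimulus artifacts + short
    # monosynaptic reflex bumps, plus its own noise floor.
    root <- 0.6 * drive + rnorm(n, 0, config$noise_sd)
    art <- spike_template(fs, width_s = 0.001)
    refl <- exp(-seq(0, 0.005, by = 1 / fs) / 0.0015)
    p_idx <- pmin(n, floor(config$stim$pulse_times * fs) + 1L)
    amp_ref <- if (nrow(units)) max(units$amplitude) else 1
    root <- add_waveforms(root, p_idx, art, rep(3 * amp_ref, length(p_idx)))
    r_idx <- pmin(n, p_idx + round(0.003 * fs))
    root <- add_waveforms(root, r_idx, refl,
                          rep(0.4 * amp_ref * config$stim$strength_t, length(r_idx)))

    list(
      emg = ts_tbl(time_s, emg, units = "mV", rate_hz = fs),
      root = ts_tbl(time_s, root, units = "mV", rate_hz = fs),
      ground_truth = list(
        spikes = spikes %||% tibble::tibble(unit_id = character(),
                                            phenotype = character(),
                                            time_s = numeric(),
                                            amplitude = numeric()),
        units = units, segmentation = seg, stim = config$stim,
        template = template
      )
    )
  })
}

#' Generate a triangular current-ramp recording
#'
#' An 8 s (by default) triangular current command; firing starts on the
#' ascending limb exactly at the programmed recruitment current `i_re` and
#' stops on the descending limb exactly at the de-recruitment current
#' `i_de`, so a downstream threshold analysis must recover
#' `delta_i = i_de - i_re` to within one command sample. The f-I relation is
#' linear on the ascending limb; the descending limb reproduces the requested
#' hysteresis: `"ccw"` lifts the descending branch above the ascending one at
#' matched current, `"cw"` drops it below, `"linear"` overlaps exactly.
#'
#' @param i_re,i_de Recruitment and de-recruitment currents (nA), both in
#'   `(0, amplitude]`.
#' @param hysteresis `"ccw"`, `"linear"` or `"cw"`.
#' @param duration Ramp duration (s).
#' @param amplitude Ramp apex current (nA).
#' @param noise_sd Voltage noise SD (mV); 0 gives a noise-free fixture.
#' @param fs Sampling rate (Hz).
#' @param f0 Firing rate at recruitment (Hz).
#' @param gain f-I gain (Hz/nA).
#' @param hyst_hz Vertical f-I offset of the descending branch for
#'   ccw/cw fixtures (Hz).
#' @param resting Resting potential (mV).
#' @param ap_amplitude Action-potential amplitude above rest (mV).
#' @param r_input Passive depolarization per injected nA (mV/nA).
#' @return A list of class `ramp_recording` with `current` and `voltage`
#'   time series, cell QC fields and the generation ground truth.
#' @export
#' @examples
#' rec <- gen_ramp_recording(4.0, 2.5, "ccw")
#' ramp_thresholds(rec)$delta_i
gen_ramp_recording <- function(i_re, i_de, hysteresis = c("ccw", "linear", "cw"),
                               duration = 8, amplitude = 5, noise_sd = 0,
                               fs = 10000, f0 = 30, gain = 10, hyst_hz = 8,
                               resting = -65, ap_amplitude = 80, r_input = 3) {
  hysteresis <- match.arg(hysteresis)
  if (i_re <= 0 || i_re > amplitude || i_de <= 0 || i_de > amplitude) {
    abort("`i_re` and `i_de` must lie in (0, amplitude].", class = "spasm_error_config")
  }
  if (duration <= 0) abort("`duration` must be > 0.", class = "spasm_error_config")

  n <- round(duration * fs) + 1L
  time_s <- (seq_len(n) - 1L) / fs
  apex <- duration / 2
  current <- amplitude * (1 - abs(time_s - apex) / apex)

  slope <- amplitude / apex # nA per s on each limb
  t_re <- i_re / slope
  t_de <- duration - i_de / slope

  # Rate profile between recruitment and de-recruitment. The ascending limb
  # is anchored at i_re; the descending branch is anchored so that the f-I
  # offset at matched current realises the requested hysteresis direction.
  rate_at <- function(t) {
    i <- amplitude * (1 - abs(t - apex) / apex)
    asc <- f0 + gain * (i - i_re)
    desc <- switch(hysteresis,
      linear = asc,
      ccw = f0 + gain * (i - i_de) + hyst_hz,
      cw = f0 + gain * (i - i_de) - hyst_hz
    )
    pmax(0.5, ifelse(t <= apex, asc, desc))
  }

  grid <- seq(t_re, t_de, by = 1 / fs)
  cum <- cumsum(rate_at(grid)) / fs
  interior <- grid[diff(floor(c(0, cum))) > 0]
  spikes <- unique(c(t_re, interior, t_de))
  spikes <- spikes[c(TRUE, diff(spikes) > 0.003)]
  if (spikes[length(spikes)] < t_de) spikes <- c(spikes, t_de)

  # AP waveform: one-sample rise (so the threshold crossing falls exactly on
  # the spike sample), 0.6 ms fall, brief AHP.
  ap_n <- round(0.001 * fs)
  ap <- c(seq(1, -0.08, length.out = round(0.6 * ap_n) + 1L),
          seq(-0.08, 0, length.out = ap_n)[-1])
  voltage <- resting + r_input * current + rnorm(n, 0, noise_sd)
  idx <- pmin(n, round(spikes * fs) + 1L)
  voltage <- add_waveforms(voltage, idx, ap, rep(ap_amplitude, length(idx)))

  structure(
    list(
      current = ts_tbl(time_s, current, units = "nA", rate_hz = fs),
      voltage = ts_tbl(time_s, voltage, units = "mV", rate_hz = fs),
      resting_potential = resting,
      ap_amplitude = ap_amplitude,
      truth = list(i_re = i_re, i_de = i_de, hysteresis = hysteresis,
                   spike_times = spikes)
    ),
    class = "ramp_recording"
  )
}

#' Generate a synthetic PSP barrage around a stimulation time
#'
#' Poisson event trains per polarity in the 20 s windows before and after the
#' stimulation; each event adds a signed alpha-function kernel (2 ms rise,
#' 10 ms decay) to the holding potential. Post-stimulation events may be
#' scaled up, mirroring the larger composite PSPs seen after dorsal-root
#' stimulation in the chronic state.
#'
#' @param pre_rate_e,pre_rate_i,post_rate_e,post_rate_i Event rates (Hz).
#' @param window Window length either side of `stim_time` (s).
#' @param stim_time Stimulation time; the trace spans
#'   `[stim_time - window, stim_time + window]`.
#' @param amp_mv Median event amplitude (mV).
#' @param post_scale Amplitude scale factor for post-stimulation events.
#' @param noise_sd Voltage noise SD (mV).
#' @param fs Sampling rate (Hz).
#' @param holding Holding potential (mV); EPSPs depolarize, IPSPs
#'   hyperpolarize at depolarized holding.
#' @param tau_rise,tau_decay Kernel time constants (s).
#' @return A list with `voltage` ([ts_tbl()]) and `events` (ground-truth
#'   tibble: `time_s`, `polarity`, `amplitude`, `window`).
#' @export
gen_psp_barrage <- function(pre_rate_e, pre_rate_i, post_rate_e, post_rate_i,
                            window = 20, stim_time = window, amp_mv = 2,
                            post_scale = 1.5, noise_sd = 0.4, fs = 10000,
                            holding = -50, tau_rise = 0.002, tau_decay = 0.01) {
  rates <- c(pre_rate_e, pre_rate_i, post_rate_e, post_rate_i)
  if (any(rates < 0)) abort("Event rates must be >= 0.", class = "spasm_error_config")
  t0 <- stim_time - window
  t1 <- stim_time + window
  n <- round((t1 - t0) * fs) + 1L
  time_s <- t0 + (seq_len(n) - 1L) / fs

  draw <- function(rate, a, b) sort(runif(rpois(1, rate * (b - a)), a, b))
  ev <- dplyr::bind_rows(
    tibble::tibble(time_s = draw(pre_rate_e, t0, stim_time), polarity = "EPSP",
                   window = "pre"),
    tibble::tibble(time_s = draw(pre_rate_i, t0, stim_time), polarity = "IPSP",
                   window = "pre"),
    tibble::tibble(time_s = draw(post_rate_e, stim_time, t1), polarity = "EPSP",
                   window = "post"),
    tibble::tibble(time_s = draw(post_rate_i, stim_time, t1), polarity = "IPSP",
                   window = "post")
  )
  if (nrow(ev)) {
    ev$amplitude <- amp_mv * runif(nrow(ev), 0.8, 1.2) *
      ifelse(ev$window == "post", post_scale, 1)
    ev <- dplyr::arrange(ev, .data$time_s)
  } else {
    ev$amplitude <- numeric()
  }

  kt <- seq(0, 6 * tau_decay, by = 1 / fs)
  kernel <- exp(-kt / tau_decay) - exp(-kt / tau_rise)
  kernel <- kernel / max(kernel)
  v <- rep(holding, n) + rnorm(n, 0, noise_sd)
  if (nrow(ev)) {
    sign_amp <- ev$amplitude * ifelse(ev$polarity == "EPSP", 1, -1)
    idx <- pmin(n, floor((ev$time_s - t0) * fs) + 1L)
    v <- add_waveforms(v, idx, kernel, sign_amp)
  }
  list(voltage = ts_tbl(time_s, v, units = "mV", rate_hz = fs), events = ev)
}

#' Synthetic stimulus-response measurements
#'
#' Builds the rising portion of a monosynaptic stimulus-response curve with a
#' programmed threshold and rising-phase slope, optionally saturating, for
#' testing [stimulus_response_curve()].
#'
#' @param slope Rising-phase slope (area units per multiple of T).
#' @param threshold_t Threshold stimulus strength (multiples of T).
#' @param strengths Stimulus strengths sampled.
#' @param saturation Area ceiling; `Inf` for a purely linear rise.
#' @param noise_sd Additive noise SD on the areas.
#' @return A tibble with columns `strength_t` and `mono_area`.
#' @export
gen_stimulus_response <- function(slope, threshold_t = 1,
                                  strengths = seq(0.5, 5, by = 0.5),
                                  saturation = Inf, noise_sd = 0) {
  area <- pmin(saturation, pmax(0, slope * (strengths - threshold_t)))
  tibble::tibble(
    strength_t = strengths,
    mono_area = pmax(0, area + rnorm(length(area), 0, noise_sd))
  )
}
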