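#' Default motor-unit population of a synthetic spasm session
#'
#' One row per unit class with the published across-unit firing statistics:
#' long-lasting 27 +/- 6.3 Hz with a gradual frequency decline; bimodal with
#' an initial unstable 41.48 +/- 13.15 Hz phase followed by a stable
#' 23.85 +/- 8.5 Hz phase; high-only 45.55 +/- 13.64 Hz; low-only
#' 17.87 +/- 2.5 Hz. Template amplitudes are geometrically spaced so that the
#' 20% template-matching criterion separates units unambiguously.
#'
#' @param n_per_class Named integer vector of unit counts per phenotype.
#' @return A tibble with columns `phenotype`, `mean_hz`, `sd_hz`,
#'   `mean_hz2`, `sd_hz2` (bimodal second phase) and `amplitude`.
#' @export
default_unit_specs <- function(n_per_class = c(long_lasting = 2, bimodal = 1,
                                               high = 1, low = 1)) {
  cls <- tibble::tibble(
    phenotype = c("long_lasting", "bimodal", "high", "low"),
    mean_hz = c(27, 41.48, 45.55, 17.87),
    sd_hz = c(6.3, 13.15, 13.64, 2.5),
    mean_hz2 = c(NA, 23.85, NA, NA),
    sd_hz2 = c(NA, 8.5, NA, NA)
  )
  counts <- n_per_class[cls$phenotype]
  counts[is.na(counts)] <- 0
  out <- cls[rep(seq_len(nrow(cls)), counts), ]
  out$amplitude <- 1.5^(seq_len(nrow(out)) - 1)
  out
}

#' Configuration of a synthetic spasm session
#'
#' Bundles every ground-truth parameter from which all modalities of a fake
#' session are generated. Defaults follow the acquisition conditions of the
#' recordings the analysis targets: EMG/root traces sampled at 20 kHz, a
#' train of 15 x 50 us pulses at 10 Hz, and epoch durations of a typical
#' chronic-stage response (2 s silent period, 20 s spasm, post-spasm epoch
#' equal to the spasm duration capped at the recording end).
#'
#' @param seed Integer seed; a fixed seed makes every generated modality
#'   byte-identical across runs.
#' @param condition `"acute"` or `"chronic"`.
#' @param sampling_rate Hz for EMG/root traces.
#' @param stim A [stimulus_protocol()]. Default: 15-pulse 10 Hz train
#'   starting at `t_stim_on`.
#' @param epoch_times Numeric vector
#'   `c(t_stim_on, t_stim_off, t_spasm_on, t_spasm_off)`, strictly increasing.
#' @param units Unit table as from [default_unit_specs()]; zero rows give a
#'   pure-noise session.
#' @param noise_sd Trace noise SD relative to the smallest template amplitude
#'   (default gives spike SNR of about 10).
#' @param strength_t Stimulus strength in multiples of threshold T.
#'
#' @return A list of class `spasm_session_config`.
#' @export
#' @examples
#' cfg <- spasm_session_config(seed = 1)
#' cfg$epoch_times
spasm_session_config <- function(seed = 1,
                                 condition = c("chronic", "acute"),
                                 sampling_rate = 20000,
                                 stim = NULL,
                                 epoch_times = c(5, 6.5, 8.5, 28.5),
                                 units = default_unit_specs(),
                                 noise_sd = NULL,
                                 strength_t = 2) {
  condition <- match.arg(condition)
  if (length(epoch_times) != 4 || is.unsorted(epoch_times, strictly = TRUE)) {
    abort("`epoch_times` must be four strictly increasing boundary times.",
          class = "spasm_error_config")
  }
  if (is.null(stim)) {
    stim <- stimulus_protocol(train_onset = epoch_times[1], strength_t = strength_t)
  }
  if (is.null(noise_sd)) {
    noise_sd <- if (nrow(units)) min(units$amplitude) / 10 else 0.1
  }
  structure(
    list(
      seed = as.integer(seed), condition = condition,
      sampling_rate = sampling_rate, stim = stim,
      epoch_times = epoch_times, units = units, noise_sd = noise_sd,
      strength_t = strength_t
    ),
    class = "spasm_session_config"
  )
}

#' Epoch boundaries modulated by stimulus strength
#'
#' Encodes the direction of stimulus-strength modulation the root analysis
#' must reproduce: stronger stimulation phase-advances the silent period
#' (shorter) and prolongs the spasm.
#'
#' @param strength_t Stimulus strength (multiples of T).
#' @param t_stim_on Train onset (s).
#' @return Numeric `c(t_stim_on, t_stim_off, t_spasm_on, t_spasm_off)`.
#' @export
epochs_for_strength <- function(strength_t, t_stim_on = 5) {
  t_stim_off <- t_stim_on + 1.5
  silent <- max(0.3, 3.2 - 0.55 * strength_t)
  spasm <- 8 + 5 * strength_t
  c(t_stim_on, t_stim_off, t_stim_off + silent, t_stim_off + silent + spasm)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators are reproducible in isolation.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
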