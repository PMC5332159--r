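# Shared fixtures built in code.

fixture_seg <- function() epoch_segmentation(5, 6.5, 8.5, 28.5, 48.5)

# A small two-unit session; amplitudes separated enough for the 20% criterion.
# `dispersion = FALSE` pins every unit at its class-mean frequency, so label
# recovery measures the pipeline rather than the intrinsic class overlap.
fixture_session <- function(seed = 11, phenotypes = c("long_lasting", "bimodal"),
                            dispersion = TRUE) {
  us <- default_unit_specs(stats::setNames(rep(1, length(phenotypes)), phenotypes))
  us$amplitude <- 1.6^(seq_len(nrow(us)) - 1)
  if (!dispersion) us$sd_hz <- 0
  gen_spasm_session(spasm_session_config(seed = seed, units = us))
}

# Classification of ground-truth spike trains of one phenotype class.
classify_population <- function(trains, ...) {
  purrr::map_dfr(split(trains, trains$unit_id), function(u) {
    cls <- classify_firing_pattern(instantaneous_frequency(u),
                                   recording_duration = 300, ...)
    dplyr::bind_cols(
      tibble::tibble(unit_id = u$unit_id[1], true = u$phenotype[1],
                     mean_hz_true = u$mean_hz_true[1]),
      cls
    )
  })
}

# Recall/precision of detected events against ground truth, by polarity.
event_scores <- function(detected, truth, tol = 0.015) {
  purrr::map_dfr(c("EPSP", "IPSP"), function(pol) {
    d <- detected[detected$polarity == pol, ]
    tr <- truth[truth$polarity == pol, ]
    hits <- vapply(tr$time_s, function(t) any(abs(d$time_s - t) < tol), logical(1))
    prec <- vapply(d$time_s, function(t) any(abs(tr$time_s - t) < tol), logical(1))
    tibble::tibble(polarity = pol, recall = mean(hits), precision = mean(prec))
  })
}
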