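test_that("instantaneous frequency is the reciprocal inter-spike interval", {
  expect_equal(instantaneous_frequency(c(0, 0.1, 0.2))$freq_hz, c(10, 10))
  expect_equal(instantaneous_frequency(c(0, 0.05))$freq_hz, 20)
  expect_equal(nrow(instantaneous_frequency(c(1))), 0)
  expect_equal(nrow(instantaneous_frequency(numeric())), 0)
  expect_error(instantaneous_frequency(c(0.2, 0.1)), class = "spasm_error_input")
  fr <- instantaneous_frequency(c(0, 0.1, 0.25))
  expect_equal(fr$time_s, c(0.1, 0.25))
})

test_that("detect_spikes handles noise, injected spikes and degenerate traces", {
  fs <- 20000
  n <- 200000
  set.seed(31)
  noise <- ts_tbl((seq_len(n) - 1) / fs, rnorm(n), rate_hz = fs)
  fp <- detect_spikes(noise, threshold_sd = 5)
  # Gaussian tail oracle: expected crossings n * P(Z > 5) ~ 0.06, so even
  # with band-pass correlation a couple of detections bound the tail.
  expect_lte(nrow(fp), 2)

  tpl <- spasmpipe:::spike_template(fs)
  x <- rnorm(n, 0, 0.1)
  at <- round(seq(0.05, 9.8, length.out = 50) * fs)
  for (i in at) x[i:(i + length(tpl) - 1)] <- x[i:(i + length(tpl) - 1)] + tpl
  sp <- detect_spikes(ts_tbl((seq_len(n) - 1) / fs, x, rate_hz = fs))
  expect_equal(nrow(sp), 50)

  expect_error(detect_spikes(ts_tbl(numeric(0), numeric(0))),
               class = "spasm_error_input")
  flat <- ts_tbl((1:1000) / fs, rep(0, 1000), rate_hz = fs)
  expect_warning(empty <- detect_spikes(flat), "Flat trace")
  expect_equal(nrow(empty), 0)
})

test_that("template matching enforces the strict 20% amplitude criterion", {
  sp <- tibble::tibble(time_s = (1:4) / 10,
                       amplitude = c(1.19, 1.25, 1.20, 0.801))
  got <- template_match(sp, templates = c(u1 = 1))
  expect_equal(got$unit_id, c("u1", NA, NA, "u1"))
  expect_error(template_match(sp, c(u1 = 1), tolerance = 1.2),
               class = "spasm_error_input")
  # empty template list leaves everything unassigned
  expect_true(all(is.na(template_match(sp, numeric())$unit_id)))
})

test_that("each spike is assigned to at most one unit and the closest one", {
  sp <- tibble::tibble(time_s = c(0.1, 0.2), amplitude = c(1.05, 1.55))
  got <- template_match(sp, templates = c(a = 1, b = 1.6))
  expect_equal(got$unit_id, c("a", "b"))
})

test_that("firing phenotypes classify from programmed frequency profiles", {
  set.seed(32)
  mk <- function(phen, m, m2 = NA) {
    sp <- gen_unit_spikes(phen, m, 0, 60, mean_hz2 = m2)
    classify_firing_pattern(instantaneous_frequency(sp),
                            recording_duration = 300)
  }
  expect_equal(mk("bimodal", 41.48, 23.85)$phenotype, "bimodal")
  expect_equal(mk("low", 17.87)$phenotype, "low")
  expect_equal(mk("high", 45.55)$phenotype, "high")
  expect_equal(mk("long_lasting", 27)$phenotype, "long_lasting")
})

test_that("classification preconditions yield unclassified", {
  fr <- tibble::tibble(time_s = (1:10) / 10, freq_hz = rnorm(10, 30))
  expect_equal(classify_firing_pattern(fr)$phenotype, "unclassified")
  fr2 <- tibble::tibble(time_s = (1:100) / 10, freq_hz = rnorm(100, 30))
  expect_equal(classify_firing_pattern(fr2, recording_duration = 100)$phenotype,
               "unclassified")
})

test_that("bimodal phase means come from the change point", {
  set.seed(33)
  fr <- tibble::tibble(
    time_s = seq_len(400) / 10,
    freq_hz = c(rnorm(150, 41.5, 5), rnorm(250, 23.9, 2.5))
  )
  cls <- classify_firing_pattern(fr, recording_duration = 300)
  expect_equal(cls$phenotype, "bimodal")
  expect_lt(abs(cls$phase1_hz - 41.5), 2.5)
  expect_lt(abs(cls$phase2_hz - 23.9), 1.5)
})

test_that("full detect-sort-classify chain recovers phenotypes on sessions", {
  pairs <- list(c("long_lasting", "bimodal"), c("high", "low"),
                c("long_lasting", "high"), c("bimodal", "low"),
                c("long_lasting", "low"))
  res <- purrr::map_dfr(1:10, function(s) {
    ses <- fixture_session(seed = 300 + s, phenotypes = pairs[[(s - 1) %% 5 + 1]],
                           dispersion = FALSE)
    gt <- ses$ground_truth
    set.seed(400 + s)
    out <- analyze_motor_units(ses$emg,
                               gt$units[, c("unit_id", "amplitude", "waveform")],
                               min_duration = 0)
    dplyr::inner_join(out$units[, c("unit_id", "phenotype")],
                      gt$units[, c("unit_id", "phenotype")],
                      by = "unit_id", suffix = c("_called", "_true"))
  })
  expect_gte(nrow(res), 20)
  expect_gte(mean(res$phenotype_called == res$phenotype_true), 0.9)
})
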