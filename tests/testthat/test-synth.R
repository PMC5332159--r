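test_that("identical config and seed give byte-identical sessions", {
  cfg <- spasm_session_config(seed = 21)
  a <- gen_spasm_session(cfg)
  b <- gen_spasm_session(cfg)
  expect_identical(a$emg, b$emg)
  expect_identical(a$root, b$root)
  expect_identical(a$ground_truth$spikes, b$ground_truth$spikes)
})

test_that("a zero-unit session is pure noise and segments to no spasm", {
  cfg <- spasm_session_config(seed = 22, units = default_unit_specs(c(high = 0)))
  ses <- gen_spasm_session(cfg)
  expect_equal(nrow(ses$ground_truth$spikes), 0)
  seg <- segment_epochs(ses$root, cfg$stim)
  expect_false(seg$spasm_detected)
  expect_equal(epoch_durations(seg)$spasm_s, 0)
})

test_that("config validation rejects non-increasing epoch times", {
  expect_error(spasm_session_config(epoch_times = c(5, 6.5, 6.5, 28)),
               class = "spasm_error_config")
  expect_error(stimulus_protocol(pulse_times = c(1, 1)),
               class = "spasm_error_config")
})

test_that("spikes stay inside the spasm epoch with amplitudes in tolerance", {
  cfg <- spasm_session_config(seed = 23)
  gt <- gen_spasm_session(cfg)$ground_truth
  et <- cfg$epoch_times
  expect_true(all(gt$spikes$time_s >= et[3] & gt$spikes$time_s <= et[4]))
  rel <- abs(gt$spikes$amplitude -
               gt$units$amplitude[match(gt$spikes$unit_id, gt$units$unit_id)]) /
    gt$units$amplitude[match(gt$spikes$unit_id, gt$units$unit_id)]
  expect_true(all(rel < 0.2))
})

test_that("a long-lasting unit at 27 Hz recovers its mean frequency", {
  set.seed(24)
  sp <- gen_unit_spikes("long_lasting", 27, t_on = 0, t_off = 60)
  fr <- instantaneous_frequency(sp)
  expect_lt(abs(mean(fr$freq_hz) - 27), 2)
  # gradual decrease: early frequencies exceed late ones
  expect_gt(mean(fr$freq_hz[seq_len(100)]),
            mean(fr$freq_hz[(nrow(fr) - 99):nrow(fr)]))
})

test_that("ramp generator validates thresholds and encodes hysteresis", {
  expect_error(gen_ramp_recording(0, 2, "ccw"), class = "spasm_error_config")
  expect_error(gen_ramp_recording(2, 6, "ccw", amplitude = 5),
               class = "spasm_error_config")
  set.seed(25)
  expect_equal(ramp_thresholds(gen_ramp_recording(2, 2, "linear"))$delta_i, 0,
               tolerance = 2 * 1.25e-4)
})

test_that("PSP barrage matches Poisson counting and degenerate cases", {
  set.seed(26)
  b <- gen_psp_barrage(20, 10, 20, 10, window = 20)
  pre <- b$events[b$events$window == "pre", ]
  # Poisson oracle: counts within 3 * sqrt(lambda) of 400 / 200.
  expect_lt(abs(sum(pre$polarity == "EPSP") - 400), 3 * sqrt(400))
  expect_lt(abs(sum(pre$polarity == "IPSP") - 200), 3 * sqrt(200))

  flat <- gen_psp_barrage(0, 0, 0, 0, noise_sd = 0)
  expect_equal(nrow(flat$events), 0)
  expect_equal(var(flat$voltage$value), 0)
  expect_error(gen_psp_barrage(-1, 0, 0, 0), class = "spasm_error_config")
})

test_that("calcium population conserves cell count and truncates draws", {
  seg <- fixture_seg()
  set.seed(27)
  pop <- gen_calcium_population(chronic_peak_specs(), seg,
                                n_cells = c(eIN = 12, iIN = 9))
  expect_equal(nrow(pop$cells), 21)
  expect_equal(length(unique(pop$traces$cell_id)), 21)
  expect_true(all(pop$cells$t_norm_true >= -1 & pop$cells$t_norm_true <= 3))

  # Force truncation with a component beyond the axis edge.
  spec <- list(components = tibble::tibble(cell_class = "eIN", mean = 3.5,
                                           sd = 0.1, weight = 1))
  expect_warning(
    pop2 <- gen_calcium_population(spec, seg, n_cells = c(eIN = 5)),
    "truncated"
  )
  expect_equal(pop2$n_truncated, 5)
})

test_that("mixture weights must sum to one per class", {
  seg <- fixture_seg()
  spec <- list(components = tibble::tibble(cell_class = "eIN",
                                           mean = c(0, 1), sd = c(0.1, 0.1),
                                           weight = c(0.5, 0.4)))
  expect_error(gen_calcium_population(spec, seg, n_cells = c(eIN = 5)),
               class = "spasm_error_config")
})

test_that("noise-free single-cell peak lands on the programmed time", {
  seg <- fixture_seg()
  set.seed(28)
  spec <- list(components = tibble::tibble(cell_class = "eIN", mean = 1.4,
                                           sd = 0.05, weight = 1))
  pop <- gen_calcium_population(spec, seg, n_cells = c(eIN = 1), noise_dff = 0)
  tr <- pop$traces
  dff <- compute_dff(ts_tbl(tr$time_s, tr$raw_f), c(3, 5))
  pt <- peak_time(dff, c(seg$t_stim_on, seg$t_end))
  expect_lt(abs(pt - pop$cells$t_peak_abs_true), 0.25)
})

test_that("generated traces re-normalize close to the drawn peak times", {
  seg <- fixture_seg()
  set.seed(29)
  pop <- gen_calcium_population(chronic_peak_specs(), seg,
                                n_cells = c(eIN = 25, iIN = 25), noise_dff = 0)
  pk <- suppressWarnings(recover_peak_times(pop$traces, seg))
  m <- dplyr::inner_join(pk, pop$cells, by = "cell_id")
  # Residual error is frame quantization: half a frame scaled by the epoch.
  err <- abs(m$t_norm - m$t_norm_true)
  expect_lt(median(err), 0.01)
  expect_lt(max(err), 0.05 / 2 / 1.5 + 1e-9)
})
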