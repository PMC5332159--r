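test_that("motor-neuron QC enforces the inclusion criteria", {
  expect_true(qc_motor_neuron(resting_mv = -65, ap_amplitude_mv = 75)$pass)
  qc1 <- qc_motor_neuron(resting_mv = -55, ap_amplitude_mv = 80)
  expect_false(qc1$pass)
  expect_match(qc1$reason, "resting")
  qc2 <- qc_motor_neuron(resting_mv = -70, ap_amplitude_mv = 69)
  expect_false(qc2$pass)
  expect_match(qc2$reason, "AP amplitude")
  qc3 <- qc_motor_neuron(resting_mv = -70, ap_amplitude_mv = NA)
  expect_false(qc3$pass)
  expect_match(qc3$reason, "undefined")
  # boundary: exactly -60 mV is not below -60 mV; exactly 70 mV passes
  expect_false(qc_motor_neuron(resting_mv = -60, ap_amplitude_mv = 80)$pass)
  expect_true(qc_motor_neuron(resting_mv = -61, ap_amplitude_mv = 70)$pass)
})

test_that("ramp thresholds recover programmed currents within one sample step", {
  step <- 2 * 5 / 8 / 10000 # amplitude ramp rate over sampling rate
  fixtures <- list(
    list(4.0, 2.5, "ccw", -1.5),
    list(2.6, 2.0, "linear", -0.6),
    list(2.0, 2.168, "cw", 0.168)
  )
  for (f in fixtures) {
    set.seed(35)
    rec <- gen_ramp_recording(f[[1]], f[[2]], f[[3]])
    th <- ramp_thresholds(rec)
    expect_lt(abs(th$i_re - f[[1]]), step + 1e-12)
    expect_lt(abs(th$i_de - f[[2]]), step + 1e-12)
    expect_lt(abs(th$delta_i - f[[4]]), 2 * step + 1e-12)
    expect_false(th$i_de_censored)
    expect_equal(th$delta_i, th$i_de - th$i_re)
  }
})

test_that("firing past the ramp end flags a censored de-recruitment", {
  set.seed(36)
  rec <- gen_ramp_recording(2.0, 0.02, "ccw")
  expect_true(ramp_thresholds(rec)$i_de_censored)
})

test_that("f-I hysteresis direction follows the generator ground truth", {
  set.seed(37)
  expect_equal(fi_hysteresis(gen_ramp_recording(4.0, 2.5, "ccw"))$hysteresis, "ccw")
  expect_gt(fi_hysteresis(gen_ramp_recording(4.0, 2.5, "ccw"))$index_hz, 0)
  expect_equal(fi_hysteresis(gen_ramp_recording(2.0, 2.168, "cw"))$hysteresis, "cw")
  expect_lt(fi_hysteresis(gen_ramp_recording(2.0, 2.168, "cw"))$index_hz, 0)
  lin <- fi_hysteresis(gen_ramp_recording(2.0, 2.0, "linear"))
  expect_equal(lin$hysteresis, "linear")
  expect_lt(abs(lin$index_hz), lin$epsilon_hz)
})

test_that("plateau classification follows delta-I and hysteresis", {
  expect_equal(classify_plateau(-1.5, "ccw"), "full")
  expect_equal(classify_plateau(-0.6, "linear"), "partial")
  expect_equal(classify_plateau(0.168, "cw"), "none")
  expect_equal(classify_plateau(-1.1, "ccw", mean_rate_hz = 10), "intermediate")
  expect_equal(classify_plateau(-1.5, "ccw", mean_rate_hz = 45), "full")
  expect_equal(classify_plateau(0, "linear"), "none")
})

test_that("plateau classification is pure and respects its invariants", {
  grid <- expand.grid(delta_i = seq(-2, 2, by = 0.25),
                      hysteresis = c("ccw", "linear", "cw"),
                      rate = c(NA, 10, 45), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    cls <- classify_plateau(grid$delta_i[i], grid$hysteresis[i], grid$rate[i])
    expect_identical(cls, classify_plateau(grid$delta_i[i], grid$hysteresis[i],
                                           grid$rate[i]))
    if (cls %in% c("full", "intermediate", "partial")) {
      expect_lt(grid$delta_i[i], 0)
    }
    if (cls == "none") expect_gte(grid$delta_i[i], 0)
  }
})

test_that("synthetic plateau fixtures assess end-to-end to the right class", {
  set.seed(38)
  expect_equal(assess_plateau(gen_ramp_recording(4.0, 2.5, "ccw"))$plateau_class,
               "full")
  expect_equal(assess_plateau(gen_ramp_recording(2.6, 2.0, "linear"))$plateau_class,
               "partial")
  expect_equal(assess_plateau(gen_ramp_recording(2.0, 2.168, "cw"))$plateau_class,
               "none")
  slow <- gen_ramp_recording(3.0, 1.9, "ccw", f0 = 8, gain = 2, hyst_hz = 3)
  expect_equal(assess_plateau(slow)$plateau_class, "intermediate")
})

test_that("synaptic event detection meets recall/precision on a seeded barrage", {
  set.seed(1)
  b <- gen_psp_barrage(1.5, 1.5, 1.5, 1.5)
  ev <- detect_synaptic_events(b$voltage, stim_time = 20)
  sc <- event_scores(ev, b$events)
  expect_true(all(sc$recall >= 0.9))
  expect_true(all(sc$precision >= 0.9))
})

test_that("synaptic event detection handles degenerate inputs", {
  flat <- gen_psp_barrage(0, 0, 0, 0, noise_sd = 0)
  expect_equal(nrow(detect_synaptic_events(flat$voltage, 20)), 0)

  set.seed(39)
  post_only <- gen_psp_barrage(0, 0, 3, 3)
  ev <- detect_synaptic_events(post_only$voltage, 20)
  expect_true(all(ev$window == "post"))
  expect_gt(nrow(ev), 0)

  expect_error(detect_synaptic_events(flat$voltage, 20, window = 30),
               class = "spasm_error_input")
})

test_that("E/I balance implements the count-normalization formula exactly", {
  expect_equal(ei_balance(5, 5), tibble::tibble(inhibition = 0.5, excitation = 0.5))
  expect_equal(ei_balance(0, 10), tibble::tibble(inhibition = 0, excitation = 1))
  expect_error(ei_balance(0, 0), class = "spasm_error_input")
  expect_error(ei_balance(-1, 2), class = "spasm_error_input")
  for (i in 0:12) for (e in 0:12) {
    if (i + e == 0) next
    b <- ei_balance(i, e)
    expect_identical(b$inhibition + b$excitation, 1)
    expect_equal(b$inhibition, i / (i + e))
  }
})
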