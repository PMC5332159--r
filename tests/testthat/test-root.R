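test_that("rectified area matches hand integrals", {
  tt <- seq(0, 0.01, by = 1e-4)
  expect_equal(rectified_area(ts_tbl(tt, rep(1, 101)), 0, 0.01), 10)
  expect_equal(rectified_area(ts_tbl(tt, rep(-1, 101)), 0, 0.01), 10)
  expect_equal(rectified_area(ts_tbl(tt, rep(0, 101)), 0, 0.01), 0)
  # triangle |x| from -1 to 1 over 10 ms integrates to 5 mV.ms
  expect_equal(rectified_area(ts_tbl(tt, seq(-1, 1, length.out = 101)), 0, 0.01),
               5, tolerance = 1e-3)
  expect_error(rectified_area(ts_tbl(tt, rep(1, 101)), 0.01, 0),
               class = "spasm_error_input")
})

test_that("reflex windows separate monosynaptic and long-lasting responses", {
  fs <- 5000
  tt <- (0:(5 * fs)) / fs
  x <- numeric(length(tt))
  x[tt > 0.504 & tt < 0.508] <- 2            # monosynaptic response
  mono_only <- ts_tbl(tt, x, rate_hz = fs)
  m1 <- reflex_measures(mono_only, stim_time = 0.5)
  expect_gt(m1$mono_area, 5)
  expect_equal(m1$long_area, 0)

  x2 <- x
  x2[tt > 0.6 & tt < 2.5] <- 1               # spasm-like long response
  m2 <- reflex_measures(ts_tbl(tt, x2, rate_hz = fs), stim_time = 0.5)
  expect_gt(m2$long_area, 10 * m2$mono_area)

  # artifact only, inside the blanking window
  x3 <- numeric(length(tt))
  x3[tt >= 0.5 & tt < 0.5015] <- 50
  m3 <- reflex_measures(ts_tbl(tt, x3, rate_hz = fs), stim_time = 0.5)
  expect_lt(m3$mono_area, 1e-6)

  expect_error(reflex_measures(mono_only, stim_time = 3),
               class = "spasm_error_input")
})

test_that("stimulus-response curve recovers threshold and slope", {
  # hand regression: areas 0,1,2,3 at strengths 1..4 give slope 1
  ramp <- tibble::tibble(strength_t = 1:4, mono_area = c(0, 1, 2, 3))
  fit <- stimulus_response_curve(ramp)
  expect_equal(fit$slope, 1)
  expect_equal(fit$threshold_t, 2)

  sr <- gen_stimulus_response(66.25, threshold_t = 1)
  expect_equal(stimulus_response_curve(sr)$slope, 66.25, tolerance = 1e-9)

  zero <- tibble::tibble(strength_t = 1:5, mono_area = rep(0, 5))
  expect_error(stimulus_response_curve(zero), class = "spasm_error_input")
  expect_error(stimulus_response_curve(ramp[1:3, ]), class = "spasm_error_input")
})

test_that("segmentation recovers programmed boundaries within 100 ms", {
  cfg <- spasm_session_config(seed = 41)
  ses <- gen_spasm_session(cfg)
  seg <- segment_epochs(ses$root, cfg$stim)
  expect_true(seg$spasm_detected)
  expect_lt(abs(seg$t_spasm_on - cfg$epoch_times[3]), 0.1)
  expect_lt(abs(seg$t_spasm_off - cfg$epoch_times[4]), 0.1)
  # idempotence
  expect_identical(seg, segment_epochs(ses$root, cfg$stim))
})

test_that("pure noise yields a no-spasm segmentation, not an error", {
  set.seed(42)
  fs <- 2000
  tt <- (0:(30 * fs)) / fs
  noise <- ts_tbl(tt, rnorm(length(tt), 0, 0.1), rate_hz = fs)
  seg <- segment_epochs(noise, stimulus_protocol(train_onset = 6))
  expect_false(seg$spasm_detected)
  d <- epoch_durations(seg)
  expect_true(is.na(d$silent_s))
  expect_equal(d$spasm_s, 0)
})

test_that("a spasm already running at train end flags silent_zero", {
  cfg <- spasm_session_config(seed = 43, epoch_times = c(5, 6.5, 6.5 + 1e-6, 26.5))
  ses <- gen_spasm_session(cfg)
  seg <- segment_epochs(ses$root, cfg$stim)
  expect_true(seg$silent_zero)
  expect_lt(epoch_durations(seg)$silent_s, 0.05)
})

test_that("epoch durations derive from the boundaries", {
  seg <- epoch_segmentation(1.5, 3.0, 5.0, 65.0, 80)
  d <- epoch_durations(seg)
  expect_equal(d$silent_s, 2.0)
  expect_equal(d$spasm_s, 60.0)
  seg2 <- epoch_segmentation(1.5, 3.0, 3.0, 65.0, 80)
  expect_equal(epoch_durations(seg2)$silent_s, 0)
})

test_that("stimulus strength modulates silent and spasm durations monotonically", {
  durs <- purrr::map_dfr(c(1, 2, 3, 4), function(st) {
    cfg <- spasm_session_config(seed = 50 + st,
                                epoch_times = epochs_for_strength(st),
                                strength_t = st)
    ses <- gen_spasm_session(cfg)
    epoch_durations(segment_epochs(ses$root, cfg$stim))
  })
  expect_true(all(diff(durs$silent_s) < 0))
  expect_true(all(diff(durs$spasm_s) > 0))
})
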