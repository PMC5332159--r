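test_that("dff implements (Ft - Fo)/Fo x 100 against the baseline mean", {
  tt <- seq(0, 10, by = 0.1)
  const <- compute_dff(ts_tbl(tt, rep(100, 101)), c(0, 5))
  expect_true(all(const$value == 0))

  f <- ts_tbl(tt, c(rep(100, 51), rep(150, 50)))
  expect_equal(compute_dff(f, c(0, 5))$value[101], 50)

  expect_error(compute_dff(ts_tbl(tt, rep(0, 101)), c(0, 5)),
               class = "spasm_error_input")
  expect_error(compute_dff(ts_tbl(tt, rep(-3, 101)), c(0, 5)),
               class = "spasm_error_input")
})

test_that("ROI extraction averages pixels and validates bounds", {
  stack <- array(7, dim = c(20, 20, 5))
  rois <- tibble::tibble(cell_id = "c1", x = 10, y = 10, radius = 3)
  tr <- extract_roi_traces(stack, rois, frame_rate = 10)
  expect_equal(tr$raw_f, rep(7, 5))
  expect_equal(tr$time_s, (0:4) / 10)

  out <- tibble::tibble(cell_id = "c2", x = 19.5, y = 10, radius = 3)
  expect_error(extract_roi_traces(stack, out), class = "spasm_error_input")
})

test_that("rendered stacks round-trip through ROI extraction", {
  seg <- fixture_seg()
  set.seed(51)
  pop <- gen_calcium_population(acute_peak_specs(), seg,
                                n_cells = c(eIN = 3, iIN = 2), frame_rate = 10)
  rend <- render_calcium_stack(pop, dim_px = c(40, 40))
  back <- extract_roi_traces(rend$stack, rend$rois, frame_rate = 10)
  for (id in rend$rois$cell_id) {
    expect_equal(back$raw_f[back$cell_id == id],
                 pop$traces$raw_f[pop$traces$cell_id == id])
  }
})

test_that("TIFF rendering writes a readable multi-page stack", {
  skip_if_not_installed("tiff")
  seg <- fixture_seg()
  set.seed(52)
  pop <- gen_calcium_population(acute_peak_specs(), seg,
                                n_cells = c(eIN = 2, iIN = 2), frame_rate = 10)
  path <- withr::local_tempfile(fileext = ".tif")
  rend <- render_calcium_stack(pop, dim_px = c(32, 32), tiff_path = path)
  back <- extract_roi_traces(path, rend$rois, frame_rate = 10)
  orig <- extract_roi_traces(rend$stack, rend$rois, frame_rate = 10)
  expect_equal(back$raw_f * rend$scale, orig$raw_f, tolerance = 1e-4)
})

test_that("peak time is the max of the 500 ms moving average", {
  fs <- 20
  tt <- (0:200) / fs
  x <- numeric(201)
  x[tt >= 3.75 & tt <= 4.25] <- 1 # boxcar centered at 4.0 s
  pt <- peak_time(ts_tbl(tt, x, rate_hz = fs), c(0, 10))
  expect_lt(abs(pt - 4.0), 1 / fs + 1e-9)

  mono <- peak_time(ts_tbl(tt, tt, rate_hz = fs), c(0, 10))
  expect_equal(mono, tt[201 - 5]) # last valid window center

  expect_warning(flat <- peak_time(ts_tbl(tt, rep(1, 201), rate_hz = fs), c(0, 10)),
                 "earliest")
  expect_equal(flat, tt[6]) # earliest valid center
})

test_that("normalization maps boundaries exactly and is piecewise linear", {
  seg <- fixture_seg()
  b <- normalize_peak_time(c(5, 6.5, 8.5, 28.5, 48.5), seg)
  expect_equal(b$t_norm, c(-1, 0, 1, 2, 3))
  expect_equal(b$epoch, c("stim", "silent", "spasm", "post", "post"))
  mid <- normalize_peak_time(18.5, seg) # spasm midpoint
  expect_equal(mid$t_norm, 1.5)
  expect_equal(mid$bin, 50L)
  expect_equal(normalize_peak_time(8.5, seg)$bin, 0L)
  expect_equal(normalize_peak_time(48.5, seg)$bin, 99L)

  expect_error(normalize_peak_time(4.9, seg), class = "spasm_error_input")
  expect_error(normalize_peak_time(49, seg), class = "spasm_error_input")
  degen <- epoch_segmentation(5, 6.5, 8.5, 28.5, 28.5)
  expect_error(normalize_peak_time(10, degen), class = "spasm_error_input")
})

test_that("warp is monotone and inverse-consistent on random sessions", {
  set.seed(53)
  for (i in 1:200) {
    b <- sort(runif(5, 0, 100))
    if (any(diff(b) < 0.05)) next
    seg <- epoch_segmentation(b[1], b[2], b[3], b[4], b[5])
    tn <- sort(runif(8, -1, 3))
    ta <- denormalize_time(tn, seg)
    expect_true(all(diff(ta) > 0))
    back <- normalize_peak_time(ta, seg)
    expect_equal(back$t_norm, tn, tolerance = 0.01)
    expect_true(all(back$bin >= 0 & back$bin <= 99))
    expect_equal(back$epoch,
                 c("stim", "silent", "spasm", "post")[pmin(4, floor(tn) + 2)])
  }
})

test_that("mixture fits recover published component means", {
  set.seed(54)
  # chronic eIN two-component population, printed parameters
  x <- c(rnorm(99, -0.33, 0.07), rnorm(99, 1.17, 0.2))
  fit <- fit_peak_distribution(x, n_components = 2)
  expect_lt(abs(fit$components$mean[2] - 1.17), 2 * 0.2 / sqrt(99))
  expect_lt(abs(fit$components$mean[1] - (-0.33)), 2 * 0.07 / sqrt(99))
  expect_equal(sum(fit$components$weight), 1)

  y <- rnorm(98, 0.06, 0.13)
  fit1 <- fit_peak_distribution(y, n_components = 1)
  expect_lt(abs(fit1$components$mean - 0.06), 2 * 0.13 / sqrt(98))

  expect_error(fit_peak_distribution(rep(1, 30)), class = "spasm_error_input")
  expect_error(fit_peak_distribution(rnorm(10)), class = "spasm_error_input")
})

test_that("BIC model choice separates one- from two-component patterns", {
  set.seed(55)
  two <- fit_peak_distribution(c(rnorm(120, -0.3, 0.1), rnorm(120, 1.2, 0.2)))
  expect_equal(two$n_components, 2)
  one <- fit_peak_distribution(rnorm(150, 0.1, 0.15))
  expect_equal(one$n_components, 1)
})

test_that("tidy and glance summarize peak fits", {
  set.seed(56)
  fit <- fit_peak_distribution(rnorm(60, 0.2, 0.1), n_components = 1,
                               cell_class = "iIN", condition = "acute")
  td <- tidy(fit)
  expect_equal(nrow(td), 1)
  expect_named(td, c("component", "mean", "sd", "weight", "cell_class",
                     "condition"))
  gl <- glance(fit)
  expect_equal(gl$n, 60)
  expect_equal(gl$n_components, 1)
})

test_that("population raster orders by position with 400 bins", {
  seg <- fixture_seg()
  traces <- dplyr::bind_rows(
    tibble::tibble(cell_id = "a", time_s = seq(0, 48.5, by = 0.1),
                   dff = dnorm(seq(0, 48.5, by = 0.1), 18.5, 1)),
    tibble::tibble(cell_id = "b", time_s = seq(0, 48.5, by = 0.1),
                   dff = dnorm(seq(0, 48.5, by = 0.1), 7.5, 0.5))
  )
  cells <- tibble::tibble(cell_id = c("a", "b"), position_um = c(500, 50))
  m <- population_raster(traces, cells, seg)
  expect_equal(dim(m), c(2, 400))
  expect_equal(rownames(m), c("b", "a")) # dorsal (50 um) first
  expect_true(all(apply(m, 1, max) <= 1))
  # per-row argmax lands in the epoch of each cell's peak
  centers <- attr(m, "bin_centers")
  expect_equal(floor(centers[which.max(m["a", ])]) + 2, 3) # spasm epoch
  expect_equal(floor(centers[which.max(m["b", ])]) + 2, 2) # silent epoch

  cells2 <- tibble::tibble(cell_id = c("a", "b"),
                           position_um = c(NA_real_, 50))
  expect_warning(m2 <- population_raster(traces, cells2, seg), "missing")
  expect_equal(rownames(m2), c("b", "a"))
})

test_that("per-row argmax matches each generated cell's normalized bin", {
  seg <- fixture_seg()
  set.seed(57)
  pop <- gen_calcium_population(chronic_peak_specs(), seg,
                                n_cells = c(eIN = 6, iIN = 6), noise_dff = 2)
  dffs <- purrr::map_dfr(split(pop$traces, pop$traces$cell_id), function(tr) {
    d <- compute_dff(ts_tbl(tr$time_s, tr$raw_f), c(3, 5))
    tibble::tibble(cell_id = tr$cell_id[1], time_s = d$time_s, dff = d$value)
  })
  m <- population_raster(dffs, pop$cells[, c("cell_id", "position_um")], seg)
  centers <- attr(m, "bin_centers")
  for (id in rownames(m)) {
    got <- centers[which.max(m[id, ])]
    want <- pop$cells$t_norm_true[pop$cells$cell_id == id]
    expect_lt(abs(got - want), 0.15)
  }
})
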