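#' Published peak-time distributions of spinal interneuron classes
#'
#' Per-class Gaussian components of the normalized calcium peak-time
#' distributions after spinal cord transection. Acute sessions show a
#' single sequential activation: eINs peak during stimulation
#' (-0.22 +/- 0.24) followed by iINs just after its end (0.06 +/- 0.13).
#' Chronic sessions show, per class, an early peak (eIN -0.33 +/- 0.07,
#' iIN 0.17 +/- 0.19) plus a delayed one: excitatory activity at the start
#' of the spasm (1.17 +/- 0.2) and inhibitory activity just before its end
#' (1.855 +/- 0.25). Component weights are not published; the chronic
#' mixtures default to equal weights.
#'
#' @return A list with `components` (tibble `cell_class`, `mean`, `sd`,
#'   `weight`) and `n_cells` (named vector: population sizes of the pooled
#'   datasets, 98/98 acute and 198 eIN / 184 iIN chronic).
#' @export
#' @examples
#' chronic_peak_specs()$components
acute_peak_specs <- function() {
  list(
    condition = "acute",
    components = tibble::tibble(
      cell_class = c("eIN", "iIN"),
      mean = c(-0.22, 0.06),
      sd = c(0.24, 0.13),
      weight = c(1, 1)
    ),
    n_cells = c(eIN = 98, iIN = 98)
  )
}

#' @rdname acute_peak_specs
#' @export
chronic_peak_specs <- function() {
  list(
    condition = "chronic",
    components = tibble::tibble(
      cell_class = rep(c("eIN", "iIN"), each = 2),
      mean = c(-0.33, 1.17, 0.17, 1.855),
      sd = c(0.07, 0.2, 0.19, 0.25),
      weight = rep(0.5, 4)
    ),
    n_cells = c(eIN = 198, iIN = 184)
  )
}

# Double-exponential transient kernel, zero before onset, unit peak.
calcium_kernel <- function(t, tau_rise, tau_decay) {
  k <- ifelse(t < 0, 0, exp(-t / tau_decay) - exp(-t / tau_rise))
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  k / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
}

# Offset (s) from transient onset to the peak reported by the discrete
# moving-average estimator ([peak_time()]) at the session's frame rate,
# averaged over sub-frame placement phases. Placing transients at
# `t - kernel_peak_offset(...)` makes the estimator unbiased for the drawn
# peak times.
kernel_peak_offset <- function(tau_rise, tau_decay, frame_rate, avg_s = 0.5,
                               n_phase = 21) {
  span <- 10 * tau_decay + 2 * avg_s
  nt <- ceiling(span * frame_rate)
  time_s <- (seq_len(nt) - 1L) / frame_rate
  k <- max(1L, 2L * floor(avg_s * frame_rate / 2 + 1e-9) + 1L)
  t0 <- 2 * avg_s
  phases <- seq(0, 1 / frame_rate, length.out = n_phase + 1)[-(n_phase + 1)]
  est <- vapply(phases, function(p) {
    f <- calcium_kernel(time_s - (t0 + p), tau_rise, tau_decay)
    avg <- zoo::rollmean(f, k, fill = NA, align = "center")
    time_s[which.max(avg)] - (t0 + p)
  }, numeric(1))
  mean(est)
}

#' Generate a synthetic calcium-imaging cell population
#'
#' For each cell a normalized peak time is drawn from its class's Gaussian
#' (mixture) distribution, mapped back to absolute time by inverting the
#' four-epoch normalization, and realised as a GCaMP-like double-exponential
#' transient (50 ms rise, 600 ms decay) placed so that the 500 ms
#' moving-average maximum — the peak estimator used downstream — falls at the
#' drawn time. Draws outside `[-1, 3]` are truncated into range and counted.
#' Cells receive uniform dorsoventral positions.
#'
#' @param specs A spec list as from [acute_peak_specs()] /
#'   [chronic_peak_specs()]; `n_cells` there may be overridden.
#' @param seg The session [epoch_segmentation()].
#' @param n_cells Named vector overriding `specs$n_cells`.
#' @param frame_rate Frames per second (10 or 20 in typical acquisitions).
#' @param amp_dff Transient amplitude in dff percent.
#' @param noise_dff Noise SD in dff percent (default amplitude/5).
#' @param f0 Baseline fluorescence (arbitrary units).
#' @param position_range Dorsoventral position range (µm from dorsal surface).
#' @param tau_rise,tau_decay Transient time constants (s).
#' @param avg_s Peak-estimator averaging window the placement compensates for.
#' @return A list: `traces` (long tibble `cell_id`, `time_s`, `raw_f`),
#'   `cells` (ground truth: `cell_id`, `cell_class`, `position_um`,
#'   `t_norm_true`, `t_peak_abs_true`), `n_truncated`.
#' @export
gen_calcium_population <- function(specs, seg, n_cells = specs$n_cells,
                                   frame_rate = 20, amp_dff = 50,
                                   noise_dff = amp_dff / 5, f0 = 100,
                                   position_range = c(50, 800),
                                   tau_rise = 0.05, tau_decay = 0.6,
                                   avg_s = 0.5) {
  stopifnot(inherits(seg, "epoch_segmentation"), all(n_cells > 0))
  comp <- specs$components
  wsum <- tapply(comp$weight, comp$cell_class, sum)
  if (any(abs(wsum - 1) > 1e-8)) {
    abort("Mixture weights must sum to 1 within each cell class.",
          class = "spasm_error_config")
  }

  nt <- floor(seg$t_end * frame_rate) + 1L
  time_s <- (seq_len(nt) - 1L) / frame_rate
  offset <- kernel_peak_offset(tau_rise, tau_decay, frame_rate, avg_s)

  n_trunc <- 0L
  cells <- purrr::imap_dfr(n_cells, function(nc, cls) {
    cc <- comp[comp$cell_class == cls, ]
    if (!nrow(cc)) abort(sprintf("No components for class '%s'.", cls),
                         class = "spasm_error_config")
    # Component counts proportional to the weights, peak times as stratified
    # Gaussian samples within each component: the generated population
    # realizes the programmed mixture rather than an iid draw from it.
    counts <- diff(round(c(0, cumsum(cc$weight)) * nc))
    ci <- sample(rep.int(seq_len(nrow(cc)), counts))
    tn <- numeric(nc)
    for (j in seq_len(nrow(cc))) {
      sel <- ci == j
      if (any(sel)) tn[sel] <- strat_norm(sum(sel), cc$mean[j], cc$sd[j])
    }
    out <- pmin(pmax(tn, -1 + 1e-6), 3 - 1e-6)
    n_trunc <<- n_trunc + sum(out != tn)
    tibble::tibble(
      cell_id = sprintf("%s_%03d", cls, seq_len(nc)),
      cell_class = cls,
      position_um = runif(nc, position_range[1], position_range[2]),
      component = ci,
      t_norm_true = out,
      t_peak_abs_true = denormalize_time(out, seg)
    )
  })

  traces <- purrr::pmap_dfr(
    cells[, c("cell_id", "t_peak_abs_true")],
    function(cell_id, t_peak_abs_true) {
      f <- calcium_kernel(time_s - (t_peak_abs_true - offset), tau_rise, tau_decay)
      raw <- f0 * (1 + (amp_dff * f + rnorm(nt, 0, noise_dff)) / 100)
      tibble::tibble(cell_id = cell_id, time_s = time_s, raw_f = raw)
    }
  )
  if (n_trunc > 0) {
    warn(sprintf("%d normalized draw(s) truncated into [-1, 3].", n_trunc))
  }
  list(traces = traces, cells = cells, n_truncated = n_trunc)
}

#' Recover normalized peak times from a generated population
#'
#' The standard analysis chain for synthetic (or real) ROI traces: dff
#' against a pre-stimulation baseline, 500 ms moving-average peak detection
#' inside `[t_stim_on, t_end]`, then four-epoch normalization.
#'
#' @param traces Long tibble `cell_id`, `time_s`, `raw_f`.
#' @param seg The session [epoch_segmentation()].
#' @param baseline_s Baseline length before `t_stim_on` used for Fo (s).
#' @param avg_s Peak averaging window (s).
#' @return A tibble: one row per cell with `cell_id`, `t_peak_abs`, `t_norm`,
#'   `epoch`, `bin`.
#' @export
recover_peak_times <- function(traces, seg, baseline_s = 2, avg_s = 0.5) {
  purrr::map_dfr(split(traces, traces$cell_id), function(tr) {
    raw <- ts_tbl(tr$time_s, tr$raw_f, units = "au")
    dff <- compute_dff(raw, c(seg$t_stim_on - baseline_s, seg$t_stim_on))
    tp <- peak_time(dff, search_window = c(seg$t_stim_on, seg$t_end),
                    avg_s = avg_s)
    dplyr::bind_cols(tibble::tibble(cell_id = tr$cell_id[1]),
                     normalize_peak_time(tp, seg))
  })
}

#' Render a calcium population as an image stack
#'
#' Draws each cell as a disk of its fluorescence value on a noisy background,
#' one frame per time point; the inverse of [extract_roi_traces()]. Used for
#' round-trip tests and for writing synthetic TIFF stacks.
#'
#' @param population Output of [gen_calcium_population()].
#' @param dim_px `c(rows, cols)` frame size.
#' @param radius_px ROI radius in pixels.
#' @param bg Background intensity; `noise_sd` pixel noise SD.
#' @param tiff_path Optional path; when given (and the tiff package is
#'   available) the stack is also written as a multi-page TIFF, scaled
#'   to `[0, 1]`.
#' @return A list: `stack` (array rows x cols x frames), `rois` (tibble
#'   `cell_id`, `x`, `y`, `radius`, `cell_class`, `position_um`), `scale`
#'   (intensity scale used for TIFF output).
#' @export
render_calcium_stack <- function(population, dim_px = c(48, 48), radius_px = 3,
                                 bg = 10, noise_sd = 0, tiff_path = NULL) {
  cells <- population$cells
  n <- nrow(cells)
  wide <- tidyr::pivot_wider(population$traces, id_cols = "time_s",
                             names_from = "cell_id", values_from = "raw_f")
  nt <- nrow(wide)
  # Cell centers on a grid with margins so disks stay inside the frame.
  ngrid <- ceiling(sqrt(n))
  gx <- seq(radius_px + 2, dim_px[2] - radius_px - 2, length.out = ngrid)
  gy <- seq(radius_px + 2, dim_px[1] - radius_px - 2, length.out = ngrid)
  centers <- expand.grid(x = round(gx), y = round(gy))[seq_len(n), ]

  stack <- array(bg, dim = c(dim_px[1], dim_px[2], nt))
  if (noise_sd > 0) stack <- stack + rnorm(length(stack), 0, noise_sd)
  for (i in seq_len(n)) {
    rows <- which(abs(seq_len(dim_px[1]) - centers$y[i]) <= radius_px)
    cols <- which(abs(seq_len(dim_px[2]) - centers$x[i]) <= radius_px)
    grid <- expand.grid(r = rows, c = cols)
    keep <- (grid$r - centers$y[i])^2 + (grid$c - centers$x[i])^2 <= radius_px^2
    grid <- grid[keep, ]
    vals <- wide[[cells$cell_id[i]]]
    for (j in seq_len(nrow(grid))) {
      stack[grid$r[j], grid$c[j], ] <- vals
    }
  }
  rois <- tibble::tibble(
    cell_id = cells$cell_id, x = centers$x, y = centers$y, radius = radius_px,
    cell_class = cells$cell_class, position_um = cells$position_um
  )
  scale <- max(stack)
  if (!is.null(tiff_path)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("Writing TIFF stacks requires the `tiff` package.",
            class = "spasm_error_input")
    }
    pages <- lapply(seq_len(nt), function(t) stack[, , t] / scale)
    tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32)
  }
  list(stack = stack, rois = rois, scale = scale)
}
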