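#' Convert a raw fluorescence trace to delta-F/F (%)
#'
#' `dff = (Ft - Fo) / Fo * 100`, with the baseline fluorescence `Fo` taken as
#' the mean of the raw trace over `baseline_window` (which must precede the
#' stimulation).
#'
#' @param raw_f A [ts_tbl()] (or tibble with `time_s`, `value`) of raw
#'   fluorescence.
#' @param baseline_window Numeric `c(t0, t1)` in seconds.
#' @return A [ts_tbl()] of dff in percent.
#' @export
#' @examples
#' f <- ts_tbl(seq(0, 10, by = 0.1), rep(c(100, 150), c(51, 50)))
#' tail(compute_dff(f, c(0, 5))$value, 1)
compute_dff <- function(raw_f, baseline_window) {
  base <- ts_window(raw_f, baseline_window[1], baseline_window[2])
  fo <- mean(base$value)
  if (!is.finite(fo) || fo <= 0) {
    abort("Baseline fluorescence Fo <= 0; check ROI/background subtraction.",
          class = "spasm_error_input")
  }
  ts_tbl(raw_f$time_s, (raw_f$value - fo) / fo * 100, units = "%",
         rate_hz = attr(raw_f, "rate_hz"))
}

#' Extract mean-intensity ROI traces from an image stack
#'
#' `raw_f(t)` is the mean pixel intensity inside each disk-shaped ROI mask
#' per frame. The stack may be a numeric array `[rows, cols, frames]` or a
#' path to a multi-page grayscale TIFF (read with the tiff package).
#'
#' @param stack Array `[rows, cols, frames]` or TIFF path.
#' @param rois Tibble with columns `cell_id`, `x`, `y` (center, pixels,
#'   `x` = column), `radius` (pixels) and optional metadata columns
#'   (`cell_class`, `position_um`), which are carried through.
#' @param frame_rate Frames per second used to build the time axis.
#' @return A long tibble `cell_id`, `time_s`, `raw_f` plus ROI metadata.
#' @export
extract_roi_traces <- function(stack, rois, frame_rate = 10) {
  if (is.character(stack)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("Reading TIFF stacks requires the `tiff` package.",
            class = "spasm_error_input")
    }
    pages <- tiff::readTIFF(stack, all = TRUE)
    stack <- array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
  }
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  nr <- dim(stack)[1]
  nc <- dim(stack)[2]
  nt <- dim(stack)[3]
  time_s <- (seq_len(nt) - 1L) / frame_rate

  purrr::pmap_dfr(rois, function(cell_id, x, y, radius, ...) {
    if (x - radius < 1 || x + radius > nc || y - radius < 1 || y + radius > nr) {
      abort(sprintf("ROI '%s' extends outside the frame.", cell_id),
            class = "spasm_error_input")
    }
    cols <- which(abs(seq_len(nc) - x) <= radius)
    rows <- which(abs(seq_len(nr) - y) <= radius)
    grid <- expand.grid(r = rows, c = cols)
    keep <- (grid$r - y)^2 + (grid$c - x)^2 <= radius^2
    grid <- grid[keep, ]
    if (!nrow(grid)) {
      abort(sprintf("ROI '%s' has an empty mask.", cell_id),
            class = "spasm_error_input")
    }
    sub <- stack[rows, cols, , drop = FALSE]
    mask <- matrix(FALSE, length(rows), length(cols))
    mask[cbind(match(grid$r, rows), match(grid$c, cols))] <- TRUE
    raw <- apply(sub, 3, function(fr) mean(fr[mask]))
    tibble::tibble(cell_id = cell_id, time_s = time_s, raw_f = raw, ...)
  })
}

#' Peak time of a calcium trace (500 ms moving-average maximum)
#'
#' The peak is the center time of the moving-average window (default 500 ms)
#' that maximizes averaged dff within the search window. Ties resolve to the
#' earliest center with a warning.
#'
#' @param dff A [ts_tbl()] of dff.
#' @param search_window `c(t0, t1)` restricting the peak search (s).
#' @param avg_s Averaging window length (s), at least 500 ms by convention.
#' @return The peak time in seconds.
#' @export
peak_time <- function(dff, search_window = range(dff$time_s), avg_s = 0.5) {
  fs <- ts_rate(dff)
  k <- max(1L, 2L * floor(avg_s * fs / 2 + 1e-9) + 1L)
  if (k > nrow(dff)) {
    abort("Averaging window exceeds the recording.", class = "spasm_error_input")
  }
  avg <- zoo::rollmean(dff$value, k, fill = NA, align = "center")
  ok <- !is.na(avg) & dff$time_s >= search_window[1] & dff$time_s <= search_window[2]
  if (!any(ok)) {
    abort("No valid averaging-window centers inside the search window.",
          class = "spasm_error_input")
  }
  cand <- avg[ok]
  tt <- dff$time_s[ok]
  mx <- max(cand)
  hits <- which(cand >= mx - 1e-12)
  if (length(hits) > 1) {
    warn("Multiple equal maxima in peak search; returning the earliest.")
  }
  tt[hits[1]]
}

#' Map an absolute peak time onto the canonical four-epoch axis
#'
#' Each epoch (stimulation, silent, spasm, post-spasm) maps linearly onto a
#' unit interval of the normalized axis with offsets -1, 0, 1, 2, so the
#' boundary times land exactly on -1, 0, 1, 2 and the recording end on 3.
#' Each epoch carries 100 bins; `bin = floor(100 * fraction)` clamped to 99
#' at the right edge. The mapping is continuous and strictly increasing.
#'
#' @param t_peak_abs Absolute peak time(s) in seconds, inside
#'   `[t_stim_on, t_end]`.
#' @param seg An [epoch_segmentation()] with a detected spasm.
#' @return A tibble with columns `t_peak_abs`, `t_norm`, `epoch`, `bin`.
#' @export
#' @examples
#' seg <- epoch_segmentation(5, 6.5, 8.5, 28.5, 48.5)
#' normalize_peak_time(c(5, 8.5, 18.5), seg)$t_norm
normalize_peak_time <- function(t_peak_abs, seg) {
  stopifnot(inherits(seg, "epoch_segmentation"))
  if (!seg$spasm_detected) {
    abort("Cannot normalize against a segmentation without a spasm.",
          class = "spasm_error_input")
  }
  lo <- c(seg$t_stim_on, seg$t_stim_off, seg$t_spasm_on, seg$t_spasm_off)
  hi <- c(seg$t_stim_off, seg$t_spasm_on, seg$t_spasm_off, seg$t_end)
  if (any(hi <= lo)) {
    abort("Degenerate epoch (zero duration); cannot normalize.",
          class = "spasm_error_input")
  }
  labels <- c("stim", "silent", "spasm", "post")
  t <- as.numeric(t_peak_abs)
  if (any(t < lo[1] - 1e-9 | t > hi[4] + 1e-9)) {
    abort("Peak time lies outside [t_stim_on, t_end].", class = "spasm_error_input")
  }
  e <- pmax(1L, pmin(4L, findInterval(t, lo)))
  e[t >= hi[4]] <- 4L
  frac <- pmin(pmax((t - lo[e]) / (hi[e] - lo[e]), 0), 1)
  tibble::tibble(
    t_peak_abs = t,
    t_norm = (e - 2L) + frac,
    epoch = labels[e],
    bin = pmin(99L, as.integer(floor(100 * frac)))
  )
}

#' Invert the four-epoch time normalization
#'
#' @param t_norm Normalized time(s) in `[-1, 3]`.
#' @param seg An [epoch_segmentation()].
#' @return Absolute time(s) in seconds.
#' @export
denormalize_time <- function(t_norm, seg) {
  stopifnot(inherits(seg, "epoch_segmentation"))
  if (any(t_norm < -1 - 1e-9 | t_norm > 3 + 1e-9)) {
    abort("`t_norm` must lie in [-1, 3].", class = "spasm_error_input")
  }
  lo <- c(seg$t_stim_on, seg$t_stim_off, seg$t_spasm_on, seg$t_spasm_off)
  hi <- c(seg$t_stim_off, seg$t_spasm_on, seg$t_spasm_off, seg$t_end)
  e <- pmin(4L, pmax(1L, floor(t_norm) + 2L))
  frac <- t_norm - (e - 2L)
  lo[e] + frac * (hi[e] - lo[e])
}

#' Fit a Gaussian (or two-component mixture) to normalized peak times
#'
#' Maximum-likelihood fit via mclust. One component reproduces the acute
#' pattern (a single activity peak); two components the chronic pattern
#' (an early peak plus a delayed one). With `n_components = NULL` the model
#' is chosen by BIC. Components are reported sorted by mean.
#'
#' @param peaks Numeric vector of normalized peak times, or a tibble with a
#'   `t_norm` column (as from [normalize_peak_time()]).
#' @param n_components 1, 2, or `NULL` for BIC selection.
#' @param cell_class,condition Optional labels carried into the result.
#' @return An object of class `peak_fit`; see [tidy.peak_fit()] and
#'   [glance.peak_fit()].
#' @export
fit_peak_distribution <- function(peaks, n_components = NULL,
                                  cell_class = NA_character_,
                                  condition = NA_character_) {
  x <- if (is.data.frame(peaks)) peaks$t_norm else as.numeric(peaks)
  x <- x[is.finite(x)]
  if (length(x) < 20) {
    abort("Need at least 20 peaks to fit a distribution.", class = "spasm_error_input")
  }
  if (sd(x) < 1e-10) {
    abort("All peaks identical; the fitted SD would be degenerate.",
          class = "spasm_error_input")
  }
  g <- n_components %||% 1:2
  fit <- mclust::Mclust(x, G = g, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) {
    abort("Mixture fit failed to converge.", class = "spasm_error_fit")
  }
  mu <- as.numeric(fit$parameters$mean)
  sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sig) == 1) sig <- rep(sig, length(mu))
  w <- as.numeric(fit$parameters$pro)
  ord <- order(mu)
  structure(
    list(
      components = tibble::tibble(component = seq_along(ord), mean = mu[ord],
                                  sd = sig[ord], weight = w[ord]),
      n = length(x), n_components = length(mu),
      loglik = fit$loglik, bic = fit$bic,
      cell_class = cell_class, condition = condition,
      peaks = x
    ),
    class = "peak_fit"
  )
}

#' Sample moments of normalized peak times
#'
#' The simple alternative estimator to the mixture fit: mean and SD of the
#' peaks, optionally restricted to a window of the normalized axis.
#'
#' @param peaks Numeric vector or tibble with `t_norm`.
#' @param window Optional `c(lo, hi)` on the normalized axis.
#' @return A one-row tibble `mean`, `sd`, `n`.
#' @export
peak_moments <- function(peaks, window = NULL) {
  x <- if (is.data.frame(peaks)) peaks$t_norm else as.numeric(peaks)
  if (!is.null(window)) x <- x[x >= window[1] & x <= window[2]]
  tibble::tibble(mean = mean(x), sd = sd(x), n = length(x))
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("Peak-time fit: %d component(s), n = %d, BIC = %.1f\n",
              x$n_components, x$n, x$bic))
  print(x$components)
  invisible(x)
}

#' Population raster of normalized calcium responses
#'
#' Resamples each cell's dff trace onto the 400-bin normalized axis
#' (4 epochs x 100 bins, linear interpolation), orders rows by dorsoventral
#' position (dorsal first) and max-normalizes each row to `[0, 1]`.
#'
#' @param traces Long tibble `cell_id`, `time_s`, `dff`.
#' @param cells Tibble `cell_id`, `position_um` (µm from the dorsal surface).
#' @param seg The session's [epoch_segmentation()].
#' @return A numeric matrix (cells x 400) with `cell_id` rownames and
#'   attributes `bin_centers` (normalized-axis centers) and `position_um`.
#' @export
population_raster <- function(traces, cells, seg) {
  centers <- seq(-1, 3, length.out = 401)
  centers <- (centers[-1] + centers[-401]) / 2
  t_abs <- denormalize_time(centers, seg)

  pos <- cells$position_um[match(unique(traces$cell_id), cells$cell_id)]
  ids <- unique(traces$cell_id)
  if (anyNA(pos)) {
    warn("Cells with missing dorsoventral position are placed last.")
  }
  ord <- order(pos, na.last = TRUE)
  ids <- ids[ord]

  rows <- purrr::map(ids, function(id) {
    tr <- traces[traces$cell_id == id, ]
    v <- approx(tr$time_s, tr$dff, xout = t_abs, rule = 2)$y
    mx <- max(v)
    if (mx > 0) v / mx else v
  })
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  attr(m, "bin_centers") <- centers
  attr(m, "position_um") <- pos[ord]
  m
}
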