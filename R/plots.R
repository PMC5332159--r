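#' Plot the f-I relation of a ramp recording
#'
#' Instantaneous frequency against injected current, colored by limb; the
#' loop direction (counter-clockwise vs clockwise) makes plateau behavior
#' visible at a glance.
#'
#' @param rec A `ramp_recording`.
#' @return A ggplot object.
#' @export
plot_fi_curve <- function(rec) {
  spikes <- detect_aps(rec$voltage)
  cur <- rec$current
  apex_t <- cur$time_s[which.max(cur$value)]
  i_at <- function(t) approx(cur$time_s, cur$value, xout = t, rule = 2)$y
  df <- purrr::map_dfr(
    list(ascending = spikes[spikes <= apex_t],
         descending = spikes[spikes > apex_t]),
    function(t) {
      if (length(t) < 2) return(tibble::tibble(i = numeric(), f = numeric()))
      mid <- (t[-1] + t[-length(t)]) / 2
      tibble::tibble(i = i_at(mid), f = 1 / diff(t))
    },
    .id = "limb"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$f,
                                   color = .data$limb)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Injected current (nA)",
                  y = "Instantaneous frequency (Hz)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a root trace with its epoch segmentation
#'
#' @param root A [ts_tbl()].
#' @param seg An [epoch_segmentation()].
#' @param downsample Keep every n-th sample for plotting speed.
#' @return A ggplot object.
#' @export
plot_segmentation <- function(root, seg, downsample = 20) {
  df <- root[seq(1, nrow(root), by = downsample), ]
  shade <- tibble::tibble(
    epoch = factor(c("stim", "silent", "spasm", "post"),
                   levels = c("stim", "silent", "spasm", "post")),
    xmin = c(seg$t_stim_on, seg$t_stim_off, seg$t_spasm_on, seg$t_spasm_off),
    xmax = c(seg$t_stim_off, seg$t_spasm_on, seg$t_spasm_off, seg$t_end)
  )
  shade <- shade[!is.na(shade$xmin) & !is.na(shade$xmax), ]
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = shade,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$epoch), alpha = 0.15) +
    ggplot2::geom_line(data = df,
                       ggplot2::aes(x = .data$time_s, y = .data$value),
                       linewidth = 0.2) +
    ggplot2::labs(x = "Time (s)", y = "Amplitude", fill = "Epoch") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.epoch_segmentation <- function(object, root, ...) {
  plot_segmentation(root, object, ...)
}

#' Plot a fitted peak-time distribution over its data
#'
#' Histogram of the normalized peak times with the fitted Gaussian
#' (mixture) density overlaid on the canonical `[-1, 3]` axis.
#'
#' @param fit A `peak_fit` from [fit_peak_distribution()].
#' @param binwidth Histogram bin width on the normalized axis.
#' @return A ggplot object.
#' @export
plot_peak_distribution <- function(fit, binwidth = 0.1) {
  df <- tibble::tibble(t_norm = fit$peaks)
  grid <- seq(-1, 3, length.out = 401)
  dens <- rowSums(vapply(seq_len(nrow(fit$components)), function(j) {
    with(fit$components[j, ], weight * stats::dnorm(grid, mean, sd))
  }, numeric(length(grid))))
  dd <- tibble::tibble(t_norm = grid, density = dens)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_norm)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth, fill = "grey75") +
    ggplot2::geom_line(data = dd,
                       ggplot2::aes(x = .data$t_norm, y = .data$density),
                       color = "firebrick") +
    ggplot2::geom_vline(xintercept = c(-1, 0, 1, 2, 3), linetype = 3) +
    ggplot2::labs(x = "Normalized time (epochs: stim, silent, spasm, post)",
                  y = "Density") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.peak_fit <- function(object, ...) plot_peak_distribution(object, ...)

#' Plot a population raster of normalized calcium responses
#'
#' @param raster Matrix from [population_raster()].
#' @return A ggplot object.
#' @export
plot_population_raster <- function(raster) {
  centers <- attr(raster, "bin_centers")
  df <- tidyr::expand_grid(cell = seq_len(nrow(raster)),
                           bin = seq_len(ncol(raster)))
  df$t_norm <- centers[df$bin]
  df$dff <- raster[cbind(df$cell, df$bin)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_norm, y = .data$cell,
                                   fill = .data$dff)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = c(0, 1, 2), color = "white",
                        linetype = 2, linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "Norm. dF/F") +
    ggplot2::labs(x = "Normalized time", y = "Cell (dorsal to ventral)") +
    ggplot2::theme_minimal()
}
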