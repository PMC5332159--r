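#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted peak-time distribution
#'
#' One row per mixture component, sorted by mean on the normalized axis.
#'
#' @param x A `peak_fit` from [fit_peak_distribution()].
#' @param ... Unused.
#' @return A tibble `component`, `mean`, `sd`, `weight` plus the fit labels.
#' @export
tidy.peak_fit <- function(x, ...) {
  dplyr::mutate(x$components, cell_class = x$cell_class,
                condition = x$condition)
}

#' One-row summary of a fitted peak-time distribution
#'
#' @param x A `peak_fit`.
#' @param ... Unused.
#' @return A tibble `n`, `n_components`, `loglik`, `bic`.
#' @export
glance.peak_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_components = x$n_components,
                 loglik = x$loglik, bic = x$bic)
}
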