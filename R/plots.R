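# ggplot2 views of the three result types: drug spectra, jackknife
# membership distributions, and the (K, m) accuracy surface.

#' Plot drug amplitude spectra
#'
#' Line plot of the Fourier amplitude spectrum of one or more drugs. The DC
#' term (k = 0, the digit sum) dominates; the symmetric upper half mirrors
#' the lower.
#'
#' @param spectra Tibble from [drug_spectrum()].
#' @param drugs Optional character vector of drug ids to show (default: up
#'   to the first 4).
#' @return A ggplot object.
#' @export
plot_drug_spectrum <- function(spectra, drugs = NULL) {
  stopifnot(is.data.frame(spectra), "drug_id" %in% names(spectra))
  if (is.null(drugs)) drugs <- utils::head(spectra$drug_id, 4)
  long <- spectra |>
    dplyr::filter(.data$drug_id %in% drugs) |>
    tidyr::pivot_longer(dplyr::starts_with("amp_"),
                        names_to = "k", values_to = "amplitude",
                        names_prefix = "amp_", names_transform = as.integer)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$drug_id)) +
    ggplot2::labs(x = "frequency index k", y = "amplitude |F(k)|") +
    ggplot2::theme_minimal()
}

#' @method autoplot gdip_jackknife
#' @export
autoplot.gdip_jackknife <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$mu_interactive, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.6,
                            boundary = 0) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "interactive membership (leave-one-out)",
                  y = "pairs", fill = "true label") +
    ggplot2::theme_minimal()
}

#' @method autoplot gdip_grid
#' @export
autoplot.gdip_grid <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$k, y = .data$m, fill = .data$acc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object$best, shape = 21, size = 3,
                        fill = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "K (neighbours)", y = "m (fuzzy coefficient)",
                  fill = "jackknife Acc") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
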