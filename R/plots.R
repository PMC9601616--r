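# ggplot2 displays of the two result types: barcoding-gap histograms and
# discrimination-rate sweeps.

#' Plot a barcoding-gap histogram
#'
#' Paired bars of intraspecific (black) and interspecific (grey) pairwise
#' divergences per distance bin; the overlap interval, when present, is
#' shaded.
#'
#' @param x A [divergence_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_divergence_histogram <- function(x, ...) {
  long <- tidyr::pivot_longer(as_tibble(x), c("intra_count", "inter_count"),
                              names_to = "kind", values_to = "count")
  long$kind <- factor(long$kind, c("intra_count", "inter_count"),
                      c("intraspecific", "interspecific"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_low + attr(x, "bin_width") / 2,
                                          y = .data$count, fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge", width = attr(x, "bin_width") * 0.9) +
    ggplot2::scale_fill_manual(values = c(intraspecific = "black",
                                          interspecific = "grey60"),
                               name = NULL) +
    ggplot2::labs(x = "pairwise distance (substitutions/site)",
                  y = "number of pairs") +
    ggplot2::theme_minimal()
  ov <- overlap_range(x)
  if (!is.null(ov)) {
    p <- p + ggplot2::annotate("rect", xmin = ov[1], xmax = ov[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "red")
  }
  p
}

#' @method autoplot divergence_histogram
#' @export
autoplot.divergence_histogram <- function(object, ...) {
  plot_divergence_histogram(object, ...)
}

#' Plot discrimination rates across marker sets
#'
#' Grouped bars of the identification rate per marker set, coloured by
#' method and model, ordered singletons first then growing combinations.
#'
#' @param rates A tibble of discrimination rows (e.g.
#'   `tidy(run_evaluation(...))`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_discrimination_rates <- function(rates, ...) {
  rates <- dplyr::mutate(
    rates,
    marker_set = factor(.data$marker_set, unique(.data$marker_set)),
    which = paste(.data$method, .data$model, sep = " / ")
  )
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$marker_set, y = .data$rate_pct,
                                      fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_grey(start = 0.1, end = 0.7, name = NULL) +
    ggplot2::labs(x = NULL, y = "species discrimination rate (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot barcode_evaluation
#' @export
autoplot.barcode_evaluation <- function(object, ...) {
  plot_discrimination_rates(object$rates, ...)
}
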