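#' Plot the repeat-length distribution of a cohort
#'
#' Histogram of each individual's longer allele, colored by range class
#' (the conventional way these screens are displayed: normal in blue,
#' premutation in yellow/orange, full mutation in red). Range boundaries
#' are drawn as dashed lines.
#'
#' @param genotypes Genotype tibble.
#' @param catalog A [locus_catalog()].
#' @param binwidth Histogram bin width in repeat units.
#' @return A ggplot object.
#' @export
plot_repeat_distribution <- function(genotypes, catalog = locus_catalog(),
                                     binwidth = 1) {
  status <- classify_genotypes(genotypes, catalog)
  status <- status[!is.na(status$longest_allele), ]
  ggplot2::ggplot(status,
                  ggplot2::aes(x = .data$longest_allele,
                               fill = .data$longest_class)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(catalog$normal_max,
                                       catalog$gray_max,
                                       catalog$premutation_max) + 0.5,
                        linetype = "dashed", color = "grey40") +
    ggplot2::scale_fill_manual(
      values = c(normal = "#4477AA", gray = "#BBBBBB",
                 premutation = "#EEBB44", full = "#CC3311"),
      drop = FALSE) +
    ggplot2::labs(x = sprintf("%s repeat length of longer allele (%s units)",
                              catalog$locus_id, catalog$repeat_unit),
                  y = "individuals", fill = "range class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a transmission summary
#'
#' Bar chart of the 20 transmission/de novo category counts of a
#' [summarize_transmissions()] result, faceted by transmitted-allele
#' range.
#'
#' @param object An `fmr_transmission_summary`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fmr_transmission_summary <- function(object, ...) {
  rows <- object$rows |>
    dplyr::mutate(
      label = ifelse(is.na(.data$parent), .data$offspring_role,
                     paste(.data$parent, "→", .data$offspring_role)),
      allele_range = factor(.data$allele_range,
                            levels = c("premutation", "normal", "de_novo"))
    )
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$count, y = .data$label)) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$allele_range),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(
      title = paste0("Transmissions in expanded-carrier families (",
                     object$cohort_id, ")"),
      x = sprintf("offspring (of %d in carrier families)",
                  object$n_offspring_in_carrier_families),
      y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot call-set concordance
#'
#' Scatter of the longer allele in call set A versus call set B with the
#' identity line; points colored by class agreement.
#'
#' @param object An `fmr_concordance` from [callset_concordance()].
#' @param catalog A [locus_catalog()] (for the premutation threshold
#'   guides).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fmr_concordance <- function(object, catalog = locus_catalog(), ...) {
  longest <- function(gt) {
    vapply(strsplit(sub("^Y/", "", gt), "/", fixed = TRUE),
           function(v) max(suppressWarnings(as.numeric(v))), numeric(1))
  }
  s <- object$samples
  s$len_a <- longest(s$genotype_a)
  s$len_b <- longest(s$genotype_b)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$len_a, y = .data$len_b,
                                  color = .data$agree)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_hline(yintercept = catalog$gray_max + 0.5,
                        linetype = "dashed", color = "grey40") +
    ggplot2::geom_vline(xintercept = catalog$gray_max + 0.5,
                        linetype = "dashed", color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#4477AA",
                                           `FALSE` = "#CC3311")) +
    ggplot2::labs(x = "longer allele, call set A (repeat units)",
                  y = "longer allele, call set B (repeat units)",
                  color = "class agreement") +
    ggplot2::theme_minimal()
}
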