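#' Forest plot of effect sizes across phenotype definitions
#'
#' One point per phenotype definition (GRS coefficient, mg/dl per unit
#' score) with its 95% confidence interval, faceted by score mode when
#' both are present. Visual overlap of the intervals is the qualitative
#' consistency check.
#'
#' @param object An `hdl_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hdl_comparison
#' @export
autoplot.hdl_comparison <- function(object, ...) {
  a <- object$associations |>
    dplyr::mutate(phenotype_definition = factor(
      .data$phenotype_definition, levels = rev(phenotype_definitions())))
  p <- ggplot2::ggplot(a, ggplot2::aes(
    x = .data$beta, y = .data$phenotype_definition)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci95_low, xmax = .data$ci95_high),
      height = 0.2) +
    ggplot2::geom_point(shape = 18, size = 3) +
    ggplot2::labs(x = "GRS effect on HDL-C (mg/dl per score unit, 95% CI)",
                  y = "phenotype definition") +
    ggplot2::theme_minimal()
  if (length(unique(a$grs_mode)) > 1) {
    p <- p + ggplot2::facet_wrap(~grs_mode, scales = "free_x")
  }
  p
}

#' Bar chart of the risk-allele count distribution
#'
#' @param grs A GRS tibble with `risk_allele_total` ([grs_table()] output)
#'   or a pre-computed histogram from [risk_allele_histogram()].
#' @return A ggplot object.
#' @export
plot_risk_allele_histogram <- function(grs) {
  h <- if ("n_subjects" %in% names(grs)) grs else risk_allele_histogram(grs)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$risk_allele_total,
                                  y = .data$n_subjects)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "total HDL-C risk alleles", y = "subjects") +
    ggplot2::theme_minimal()
}
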