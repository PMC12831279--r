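#' Plot a build's error-category breakdown
#'
#' @param object a `ba_build_summary`.
#' @param ... unused.
#' @return a ggplot bar chart of genes per category.
#' @export
autoplot.ba_build_summary <- function(object, ...) {
  df <- tidy(object)
  df$category <- factor(df$category, levels = rev(audit_categories))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$category)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percent)),
                       hjust = -0.1, size = 3) +
    ggplot2::labs(
      x = "genes", y = NULL,
      title = sprintf("Build %s: %.1f%% error-free", df$build_id[1],
                      attr(object, "percent_correct"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the seven-region Venn partition as a bar chart
#'
#' @param object a `ba_venn`.
#' @param ... unused.
#' @return a ggplot bar chart of region counts.
#' @export
autoplot.ba_venn <- function(object, ...) {
  df <- tidy(object)
  df$region <- factor(df$region, levels = c("PMH", "PM", "PH", "MH",
                                            "P", "M", "H"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$n)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3, size = 3) +
    ggplot2::labs(x = "Venn region (pig / mouse / human)", y = "genes",
                  title = "Three-species ortholog partition") +
    ggplot2::theme_minimal()
}

#' Plot top enriched terms
#'
#' @param object a `ba_enrichment`.
#' @param top how many terms (by p) to show.
#' @param ... unused.
#' @return a ggplot chart of fold enrichment, coloured by FDR.
#' @export
autoplot.ba_enrichment <- function(object, top = 15L, ...) {
  df <- utils::head(tidy(object), top)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = .data$term,
                                   fill = -log10(.data$q))) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_viridis_c(name = "-log10 FDR") +
    ggplot2::labs(x = "fold enrichment", y = NULL,
                  title = "Over-represented terms") +
    ggplot2::theme_minimal()
}
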