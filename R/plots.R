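## ggplot2 displays for the three result types: class-by-group divergence
## bars, per-class monophyly, and per-character parsimony changes.

#' Plot class-by-group net divergence
#'
#' Bar chart of length-weighted mean dA per chromosome class, faceted by
#' chromosomal group, with bootstrap intervals when present.
#'
#' @param summary A tibble from [class_group_summary()].
#' @return A ggplot object.
#' @export
plot_class_divergence <- function(summary) {
  p <- ggplot2::ggplot(summary,
                       ggplot2::aes(x = .data$class, y = .data$mean_dA,
                                    fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "chromosome class", y = "mean net divergence (dA)") +
    ggplot2::theme_minimal()
  if (all(c("ci_lower", "ci_upper") %in% names(summary))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper), width = 0.2)
  }
  p
}

#' Plot monophyly fractions from a concordance table
#'
#' @param concordance A tibble from [class_concordance_table()].
#' @return A ggplot object.
#' @export
plot_monophyly <- function(concordance) {
  mono <- concordance[concordance$kind == "monophyly" &
                        !is.na(concordance$fraction), ]
  ggplot2::ggplot(mono, ggplot2::aes(x = .data$class, y = .data$fraction,
                                     fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "chromosome class", y = "fraction of monophyletic taxa") +
    ggplot2::theme_minimal()
}

#' @rdname monophyly_fraction
#' @param object A `monophyly_report`.
#' @export
autoplot.monophyly_report <- function(object, ...) {
  ggplot2::ggplot(object$taxa,
                  ggplot2::aes(x = .data$taxon, y = as.integer(.data$monophyletic),
                               fill = .data$trivial)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "monophyletic", x = NULL,
                  title = sprintf("%s: fraction %.2f", object$tree_id,
                                  object$fraction)) +
    ggplot2::theme_minimal()
}

#' @rdname map_events
#' @param object A `karyotype_events` object.
#' @export
autoplot.karyotype_events <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$character, y = .data$min_changes,
                               fill = .data$homoplasious)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "minimum changes (parsimony)", x = NULL) +
    ggplot2::theme_minimal()
}
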