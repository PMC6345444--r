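#' Plot predicted vs simulated concentration ranges
#'
#' Interval plot with one row per metabolite: simulated ranges as one bar,
#' predicted ranges as a second, on a log10 concentration axis.
#'
#' @param object A `comparison_record` from [compare_bounds()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.comparison_record <- function(object, ...) {
  pm <- object$per_metabolite
  df <- bind_rows(
    tibble(metabolite = pm$metabolite, lower = pm$p_lower, upper = pm$p_upper,
           which = "predicted"),
    tibble(metabolite = pm$metabolite, lower = pm$s_lower, upper = pm$s_upper,
           which = "simulated")
  )
  ggplot2::ggplot(df, ggplot2::aes(y = .data$metabolite, xmin = .data$lower,
                                   xmax = .data$upper,
                                   colour = .data$which)) +
    ggplot2::geom_errorbarh(position = ggplot2::position_dodge(width = 0.6),
                            height = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (mmol/gDW)", y = NULL, colour = NULL)
}

#' Plot a robustness experiment
#'
#' Boxplots of a comparison metric across random rate-constant removals, by
#' removal fraction and substitution scheme.
#'
#' @param data Output of [rate_constant_robustness()].
#' @param metric Metric to display (default `"pearson_lower"`).
#' @return A ggplot object.
#' @export
plot_robustness <- function(data, metric = "pearson_lower") {
  df <- filter(data, .data$metric == !!metric)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fraction), y = .data$value,
                                   fill = .data$scheme)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "% relevant rate constants removed", y = metric,
                  fill = "substitution")
}

#' Plot fold-change histograms of a knockout screen
#'
#' Distribution of predicted (and, when available, simulated) fold-change
#' bins over all knockouts and SCC metabolites.
#'
#' @param screen Output of [knockout_screen()].
#' @param edges Bin edges used (log2 scale).
#' @return A ggplot object.
#' @export
plot_fold_change_bins <- function(screen, edges = fold_change_edges()) {
  lab <- function(i) {
    lo <- edges[i]; hi <- edges[i + 1]
    sprintf("(%s,%s]", format(lo, digits = 2), format(hi, digits = 2))
  }
  labs <- vapply(seq_len(length(edges) - 1), lab, character(1))
  df <- bind_rows(
    tibble(bin = screen$bin, which = "predicted"),
    tibble(bin = screen$sim_bin, which = "simulated")
  )
  df <- filter(df, !is.na(.data$bin))
  df$bin_label <- factor(labs[df$bin], levels = labs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_label, fill = .data$which)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "log2 fold change bin", y = "count", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
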