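# ggplot2 views of the main result types. Each returns a ggplot object so
# callers can restyle with +.

#' @rdname per_site_test
#' @param object A `medseq_site_tests` tibble.
#' @param alpha,n_tests Significance level and Bonferroni denominator for
#'   the drawn threshold line (defaults match [call_dmrs()]).
#' @param ... Unused.
#' @method autoplot medseq_site_tests
#' @export
autoplot.medseq_site_tests <- function(object, alpha = 0.05, n_tests = NULL, ...) {
  n_tests <- n_tests %||% sum(object$case_count + object$control_count > 0)
  dat <- mutate(object,
                neglogp = -log10(pmax(.data$p_value, 1e-300)),
                direction = dplyr::coalesce(.data$direction, "none"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos, y = .data$neglogp,
                                    colour = .data$direction)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha / max(n_tests, 1)),
                        linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(hyper = "#c0392b", hypo = "#2980b9",
                                            none = "grey70")) +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10]~p),
                  colour = "direction",
                  title = "Per-site chi-square tests",
                  subtitle = "dashed line: Bonferroni threshold")
}

#' @rdname call_dmrs
#' @param object A `medseq_dmrs` tibble.
#' @param ... Unused.
#' @method autoplot medseq_dmrs
#' @export
autoplot.medseq_dmrs <- function(object, ...) {
  dat <- mutate(as_tibble(object), y = row_number())
  ggplot2::ggplot(dat) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$y, yend = .data$y,
                                       colour = .data$direction),
                          linewidth = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(hyper = "#c0392b", hypo = "#2980b9")) +
    ggplot2::labs(x = "position (bp)", y = "DMR", title = "Called DMRs")
}

#' @rdname evaluate_classifier
#' @method autoplot classifier_eval
#' @export
autoplot.classifier_eval <- function(object, ...) {
  roc <- tidy(object)
  ggplot2::ggplot(roc, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, colour = "#c0392b", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc),
                  subtitle = sprintf("operating point: sens %.1f%% at spec %.1f%%",
                                     100 * object$sensitivity,
                                     100 * object$specificity))
}

#' Positivity heatmap of a qMSP panel
#'
#' Tile map of per-sample, per-marker positivity calls (red = above the
#' control-percentile threshold, white = below), samples in columns grouped
#' by clinical group.
#'
#' @param positivity A [call_positivity()] result with a `group` column.
#' @return A ggplot object.
#' @export
plot_positivity <- function(positivity) {
  assert_columns(positivity, c("sample", "marker", "group", "positive"),
                 "positivity")
  ggplot2::ggplot(positivity,
                  ggplot2::aes(x = .data$sample, y = .data$marker,
                               fill = factor(.data$positive))) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$group), scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "#c0392b"),
                               labels = c(`0` = "below", `1` = "above")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "threshold",
                  title = "qMSP positivity at the control percentile") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Dilution curve of signature performance vs tumor fraction
#'
#' @param dilution Tibble (tumor_fraction, auc), e.g. from [run_demo()].
#' @return A ggplot object.
#' @export
plot_dilution <- function(dilution) {
  assert_columns(dilution, c("tumor_fraction", "auc"), "dilution")
  ggplot2::ggplot(dilution, ggplot2::aes(x = .data$tumor_fraction, y = .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::scale_x_continuous(trans = "sqrt") +
    ggplot2::coord_cartesian(ylim = c(0.4, 1)) +
    ggplot2::labs(x = "tumor fraction of cfDNA", y = "signature AUC",
                  title = "Dilution of the methylation signature in cfDNA")
}
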