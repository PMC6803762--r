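# broom-style tidiers and ggplot2 autoplot methods for the result classes.

#' @rdname se_dm_tidiers
#' @export
tidy.se_dm <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' Tidiers for differential-methylation results
#'
#' `tidy()` returns the per-region table; `glance()` a one-row summary of
#' the scan (regions tested, hyper/hypo counts, threshold).
#'
#' @param x An `se_dm` result.
#' @param ... Unused.
#' @return A tibble.
#' @name se_dm_tidiers
#' @export
glance.se_dm <- function(x, ...) {
  tibble(n_regions = nrow(x),
         n_dm = sum(x$direction != "none"),
         n_hyper = sum(x$direction == "hyper"),
         n_hypo = sum(x$direction == "hypo"),
         n_skipped = attr(x, "n_skipped") %||% 0L,
         alpha = attr(x, "alpha"),
         test = attr(x, "test"),
         n_case = attr(x, "n_case"),
         n_control = attr(x, "n_control"))
}

#' @rdname se_pairs_tidiers
#' @export
tidy.se_pairs <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' Tidiers for SE-gene pair results
#'
#' `tidy()` returns the per-pair table; `glance()` a one-row summary
#' (candidates, passed, FDR scope).
#'
#' @param x An `se_pairs` result.
#' @param ... Unused.
#' @return A tibble.
#' @name se_pairs_tidiers
#' @export
glance.se_pairs <- function(x, ...) {
  tibble(n_pairs = nrow(x),
         n_passed = sum(x$passed),
         n_genes = length(unique(x$gene_id)),
         n_ses = length(unique(x$se_id)),
         alpha = attr(x, "alpha"),
         fdr_scope = attr(x, "fdr_scope"),
         n_samples = attr(x, "n_samples"))
}

#' @export
glance.se_pipeline <- function(x, ...) {
  tidyr::pivot_wider(x$funnel, names_from = "stage", values_from = "n")
}

unclass_result <- function(x) {
  class(x) <- class(tibble())
  attr(x, "alpha") <- NULL
  attr(x, "test") <- NULL
  attr(x, "fdr_scope") <- NULL
  x
}

#' Volcano-style plot of a differential methylation scan
#'
#' Mean case-control methylation difference against -log10 q, coloured by
#' direction.
#'
#' @param object An `se_dm` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.se_dm <- function(object, ...) {
  d <- as_tibble(object)
  d$mlq <- -log10(pmax(d$q_value, 1e-300))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_case - .data$mean_control,
                                  y = .data$mlq, colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(hyper = "#c0392b", hypo = "#2980b9",
                                            none = "grey60")) +
    ggplot2::labs(x = "mean methylation difference (case - control)",
                  y = expression(-log[10] ~ q), colour = NULL)
}

#' Correlation screen plot for SE-gene pairs
#'
#' Kendall tau against -log10 q per candidate pair; passed pairs
#' highlighted. The empty upper-left quadrant shows the positive-correlation
#' artifact filter.
#'
#' @param object An `se_pairs` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.se_pairs <- function(object, ...) {
  d <- as_tibble(object)
  d$mlq <- -log10(pmax(d$q_se, 1e-300))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tau_se, y = .data$mlq,
                                  colour = .data$passed)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#27ae60", `FALSE` = "grey60")) +
    ggplot2::labs(x = expression(Kendall ~ tau[b] ~ "(SE methylation vs expression)"),
                  y = expression(-log[10] ~ q), colour = "passed")
}

#' Filtering funnel of a pipeline run
#'
#' @param object An `se_pipeline` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.se_pipeline <- function(object, ...) {
  f <- filter(object$funnel, !is.na(.data$n))
  f$stage <- factor(f$stage, levels = rev(f$stage))
  ggplot2::ggplot(f, ggplot2::aes(x = .data$n, y = .data$stage)) +
    ggplot2::geom_col(fill = "#34495e") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), hjust = -0.15, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.12))) +
    ggplot2::labs(x = "count", y = NULL)
}
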