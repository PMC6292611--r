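#' Plot a greedy selection trace
#'
#' One panel per requested metric across the selection steps: the per-group
#' sample size, the per-arm event rates, or the composite risk ratio.
#'
#' @param object A `ce_selection` from [greedy_select()].
#' @param metric One or more of `"ssr"`, `"rate"`, `"rr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ce_selection <- function(object, metric = c("ssr", "rate", "rr"),
                                  ...) {
  metric <- match.arg(metric, several.ok = TRUE)
  rec <- object$records
  long <- bind_rows(
    if ("ssr" %in% metric)
      tibble(step = rec$step, panel = "Sample size per group",
             series = "SSR", value = as.numeric(rec$ssr)),
    if ("rate" %in% metric)
      bind_rows(
        tibble(step = rec$step, panel = "Event rate",
               series = "control", value = rec$rate_control),
        tibble(step = rec$step, panel = "Event rate",
               series = "treatment", value = rec$rate_treatment)),
    if ("rr" %in% metric)
      tibble(step = rec$step, panel = "Risk ratio",
             series = "RR", value = rec$rr)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = rec$step) +
    ggplot2::expand_limits(y = 0) +
    ggplot2::labs(x = "Selection step", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a nine-scenario sensitivity sweep
#'
#' Per-group sample size of the selected composite under each association
#' scenario, annotated with the number of components; the dashed line marks
#' the relevant endpoint's own sample size (the 100% reference).
#'
#' @param object A `ce_sensitivity` from [sweep_associations()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ce_sensitivity <- function(object, ...) {
  df <- as_tibble(object)
  df$scenario <- factor(df$scenario, levels = association_scenarios()$scenario)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$ssr)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = attr(object, "ssr_reference"),
                        linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_components),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "Assumed strength of association",
                  y = "Sample size per group",
                  caption = "Labels: number of combined outcomes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}

#' Plot per-candidate sample-size ranges across attainable associations
#'
#' For each candidate outcome, the segment spans the per-group sample size of
#' its two-component composite with the relevant endpoint from minimum to
#' maximum attainable association; the dashed line is the relevant endpoint's
#' own sample size.
#'
#' @param object A `ce_pair_ranges` from [pair_range_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ce_pair_ranges <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ssr_min_association,
                                       xend = .data$ssr_max_association,
                                       yend = .data$label),
                          linewidth = 2, colour = "steelblue", alpha = 0.7) +
    ggplot2::geom_vline(xintercept = attr(object, "ssr_reference"),
                        linetype = "dashed") +
    ggplot2::labs(x = "Sample size per group (min to max association)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
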