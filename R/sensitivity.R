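#' Nine-scenario association sensitivity analysis
#'
#' The true strength of association between candidate outcomes is usually
#' unknown, so the selected composite and its sample size should be examined
#' across the whole qualitative range. For each of the nine association
#' scenarios, every pairwise association in the panel is overwritten with that
#' scenario, the greedy selection is rerun, and the final composite is
#' reported as one row. Rows are ordered from `lowest` to `highest`
#' association; when all outcomes have risk ratios below 1, the sample size
#' column is non-decreasing along that order (stronger positive association
#' erodes the event-rate gain of combining outcomes).
#'
#' @param panel A [ce_panel()].
#' @return A tibble of class `ce_sensitivity` with nine rows: `scenario`,
#'   `components`, `n_components`, `rate_control`, `rate_treatment`, `rr`,
#'   `ssr`, `pct_of_reference` (percent of the relevant endpoint's own sample
#'   size, 2 dp). Attribute `ssr_reference` carries that reference size.
#' @examples
#' panel <- ce_panel(data.frame(
#'   label = c("Death", "Infarction", "Stroke", "CABG"),
#'   control_rate = c(0.023, 0.0115, 0.0029, 0.092),
#'   rr = c(1.33, 0.73, 0.97, 0.85)
#' ))
#' suppressWarnings(sweep_associations(panel))
#' @export
sweep_associations <- function(panel) {
  stopifnot(inherits(panel, "ce_panel"))
  codes <- association_scenarios()$scenario
  rows <- map(codes, function(sc) {
    p <- panel
    p$associations$joint <- NA_real_
    p$associations$scenario <- sc
    sel <- greedy_select(p)
    last <- sel$records[nrow(sel$records), ]
    tibble(scenario = sc,
           components = last$components,
           n_components = last$n_components,
           rate_control = last$rate_control,
           rate_treatment = last$rate_treatment,
           rr = last$rr, ssr = last$ssr,
           pct_of_reference = last$pct_of_reference)
  })
  out <- bind_rows(rows)
  attr(out, "ssr_reference") <- reference_ssr(panel)
  class(out) <- c("ce_sensitivity", class(out))
  out
}

# the relevant endpoint's own per-group sample size (the 100% reference)
reference_ssr <- function(panel) {
  re <- panel$relevant_index
  za <- qnorm(1 - panel$design$alpha / 2)
  zb <- qnorm(panel$design$power)
  n <- ssr_n(panel$outcomes$control_rate[re], panel$outcomes$treatment_rate[re],
             za, zb, panel$design$method)
  as.integer(n)
}

#' Effect-size sensitivity analysis for one outcome
#'
#' Reruns the greedy selection with one outcome's risk ratio replaced by each
#' value of a grid, and reports the final composite per grid point. Useful
#' when an effect estimate is unstable (few events) and the robustness of the
#' selection to it matters. Inadmissible grid values (non-positive, or
#' implying a treatment rate of 1 or more) yield an error message in that row
#' rather than aborting the sweep.
#'
#' @param panel A [ce_panel()].
#' @param outcome_label Label of the outcome whose risk ratio is varied.
#' @param rr_grid Numeric vector of risk ratios to try.
#' @return A tibble with one row per grid value: `rr_assumed`, `components`,
#'   `n_components`, `ssr`, `pct_of_reference`, `error` (NA unless that grid
#'   value was inadmissible).
#' @export
effect_sensitivity <- function(panel, outcome_label, rr_grid) {
  stopifnot(inherits(panel, "ce_panel"))
  i <- match(outcome_label, panel$outcomes$label)
  if (is.na(i)) {
    abort(sprintf("Unknown outcome label '%s'.", outcome_label),
          class = "cesize_validation_error")
  }
  rows <- map(rr_grid, function(rr) {
    res <- tryCatch({
      p <- panel
      p$outcomes$rr[i] <- rr
      p$outcomes$treatment_rate[i] <- rr * p$outcomes$control_rate[i]
      if (rr <= 0 || p$outcomes$treatment_rate[i] >= 1) {
        abort(sprintf("rr = %g is inadmissible for control rate %g.",
                      rr, p$outcomes$control_rate[i]),
              class = "cesize_validation_error")
      }
      p$relevant_index <- select_relevant(p)
      sel <- greedy_select(p)
      last <- sel$records[nrow(sel$records), ]
      tibble(rr_assumed = rr, components = last$components,
             n_components = last$n_components, ssr = last$ssr,
             pct_of_reference = last$pct_of_reference, error = NA_character_)
    }, cesize_validation_error = function(e) {
      tibble(rr_assumed = rr, components = NA_character_,
             n_components = NA_integer_, ssr = NA_integer_,
             pct_of_reference = NA_real_, error = conditionMessage(e))
    })
    res
  })
  bind_rows(rows)
}

#' @export
print.ce_sensitivity <- function(x, ...) {
  cat(sprintf(
    "<ce_sensitivity> nine association scenarios | reference SSR %d\n",
    attr(x, "ssr_reference")))
  NextMethod()
}
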