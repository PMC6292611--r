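#' The nine qualitative association scenarios
#'
#' Association between two binary outcomes is measured by their joint
#' probability, which for fixed marginals \eqn{p_A, p_B} can only lie between
#' the Fréchet bounds \eqn{\max(0, p_A + p_B - 1)} and \eqn{\min(p_A, p_B)}.
#' When the joint probability is unknown, it can be specified qualitatively by
#' one of nine scenarios that interpolate between the independence product
#' \eqn{p_A p_B} and the relevant bound in quarter steps: `none` is
#' independence; `low`/`moderate`/`strong` positive (negative) scenarios move
#' 1/4, 2/4 and 3/4 of the way from independence to the upper (lower) bound;
#' `highest` and `lowest` sit on the bounds themselves.
#'
#' @return A tibble with columns `scenario` (code) and `theta` (signed
#'   interpolation step, -4 to 4; the imputed joint is
#'   `independence + |theta|/4 * (bound - independence)` toward the upper bound
#'   for positive `theta` and toward the lower bound for negative `theta`).
#' @examples
#' association_scenarios()
#' @seealso [impute_joint()], [frechet_bounds()]
#' @export
association_scenarios <- function() {
  tibble(
    scenario = c("lowest", "strong_negative", "moderate_negative",
                 "low_negative", "none", "low_positive", "moderate_positive",
                 "strong_positive", "highest"),
    theta = c(-4L, -3L, -2L, -1L, 0L, 1L, 2L, 3L, 4L)
  )
}

scenario_theta <- function(scenario) {
  tab <- association_scenarios()
  i <- match(scenario, tab$scenario)
  if (anyNA(i)) {
    abort(sprintf("Unknown association scenario(s): %s. Admissible codes: %s.",
                  paste(unique(scenario[is.na(i)]), collapse = ", "),
                  paste(tab$scenario, collapse = ", ")),
          class = "cesize_validation_error")
  }
  tab$theta[i]
}
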