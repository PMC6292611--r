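#' Fréchet bounds for the joint probability of two binary events
#'
#' Two binary events with marginal probabilities `p_a` and `p_b` can co-occur
#' with probability anywhere in
#' \eqn{[\max(0, p_a + p_b - 1),\ \min(p_a, p_b)]} and nowhere outside it.
#'
#' @param p_a,p_b Marginal event probabilities in \[0, 1\]. Vectorised.
#' @return A tibble with columns `lower` and `upper`.
#' @examples
#' frechet_bounds(0.06, 0.10) # joint must lie in [0, 0.06]
#' @export
frechet_bounds <- function(p_a, p_b) {
  check_probability(p_a, "p_a", open = FALSE)
  check_probability(p_b, "p_b", open = FALSE)
  tibble(lower = pmax(0, p_a + p_b - 1), upper = pmin(p_a, p_b))
}

#' Impute a joint probability from a qualitative association scenario
#'
#' Linearly interpolates between the independence product and the relevant
#' Fréchet bound in quarter steps: the imputed joint is the independence
#' product for `none`, moves \eqn{|\theta|/4} of the distance toward the upper
#' bound for positive scenarios (\eqn{\theta} = 1 low, 2 moderate, 3 strong,
#' 4 highest) and toward the lower bound for negative scenarios. The result
#' always lies within the Fréchet bounds.
#'
#' @inheritParams frechet_bounds
#' @param scenario Scenario code(s); see [association_scenarios()].
#' @return Numeric vector of joint probabilities.
#' @examples
#' impute_joint(0.06, 0.10, "none")              # 0.006, the product
#' impute_joint(0.092, 0.0115, "highest")        # 0.0115, the upper bound
#' impute_joint(0.092, 0.0115, "moderate_positive")
#' @export
impute_joint <- function(p_a, p_b, scenario) {
  b <- frechet_bounds(p_a, p_b)
  theta <- scenario_theta(scenario)
  ind <- p_a * p_b
  ifelse(theta >= 0,
         ind + (b$upper - ind) * theta / 4,
         ind - (ind - b$lower) * (-theta) / 4)
}

#' Correct a joint probability that violates the Fréchet bounds
#'
#' A proposed joint probability outside the attainable interval for the given
#' marginals is replaced by the product of the marginals (the independence
#' value), with a warning identifying the offending value. In-bounds values
#' pass through unchanged, so the correction is idempotent.
#'
#' @inheritParams frechet_bounds
#' @param joint Proposed joint probability in \[0, 1\]. Vectorised.
#' @param label Optional label used in the warning to identify the pair.
#' @return Numeric vector of corrected joint probabilities.
#' @examples
#' suppressWarnings(correct_joint(0.06, 0.10, 0.08)) # -> 0.006
#' correct_joint(0.06, 0.10, 0.05)                   # unchanged
#' @export
correct_joint <- function(p_a, p_b, joint, label = NULL) {
  check_probability(joint, "joint", open = FALSE)
  b <- frechet_bounds(p_a, p_b)
  bad <- joint < b$lower | joint > b$upper
  if (any(bad)) {
    who <- if (is.null(label)) "" else paste0(" for pair ", label)
    warn(sprintf(paste0(
      "Joint probability%s outside the Fréchet bounds ",
      "[%s, %s]; replaced by the product of marginals (%s)."),
      who,
      paste(signif(b$lower[bad], 6), collapse = ", "),
      paste(signif(b$upper[bad], 6), collapse = ", "),
      paste(signif((p_a * p_b)[bad], 6), collapse = ", ")),
      class = "cesize_joint_correction")
  }
  ifelse(bad, p_a * p_b, joint)
}

# clamp a recursion-derived joint into the bounds of (composite, candidate);
# returns value + attr telling whether clamping fired
clamp_joint <- function(joint, p_a, p_b) {
  lo <- pmax(0, p_a + p_b - 1)
  up <- pmin(p_a, p_b)
  pmin(pmax(joint, lo), up)
}
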