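#' Per-group sample size for comparing two proportions
#'
#' Computes the number of subjects required per arm (1:1 allocation) to detect
#' a difference between event probabilities `p1` and `p2` with a two-sided
#' type I error `alpha` and target power, under one of five formulas.
#'
#' With \eqn{z_\alpha} the upper \eqn{\alpha/2} normal quantile, \eqn{z_\beta}
#' the upper \eqn{1-\mathrm{power}} quantile and \eqn{\bar p = (p_1+p_2)/2}:
#' \describe{
#'   \item{`normal_mixed` (default)}{pooled variance under the null for the
#'     \eqn{\alpha} term, unpooled under the alternative for the \eqn{\beta}
#'     term:
#'     \eqn{n = \left(z_\alpha\sqrt{2\bar p(1-\bar p)} +
#'     z_\beta\sqrt{p_1(1-p_1)+p_2(1-p_2)}\right)^2 / (p_1-p_2)^2}}
#'   \item{`normal_pooled`}{\eqn{n = (z_\alpha+z_\beta)^2\, 2\bar p(1-\bar p) /
#'     (p_1-p_2)^2}}
#'   \item{`normal_unpooled`}{\eqn{n = (z_\alpha+z_\beta)^2\,
#'     (p_1(1-p_1)+p_2(1-p_2)) / (p_1-p_2)^2}}
#'   \item{`arcsine`}{variance-stabilising transform:
#'     \eqn{n = (z_\alpha+z_\beta)^2 / (2\arcsin\sqrt{p_1} -
#'     2\arcsin\sqrt{p_2})^2}}
#'   \item{`arcsine_corrected`}{as `arcsine` but with the continuity-corrected
#'     transform \eqn{2\arcsin\sqrt{(np+3/8)/(n+3/4)}}, solved to a fixed
#'     point in \eqn{n} (tolerance 1e-9, at most 100 iterations).}
#' }
#' The per-group size is the ceiling of the unrounded solution.
#'
#' @param p1,p2 Event probabilities in (0, 1); must differ. Vectorised.
#' @param alpha Two-sided type I error, in (0, 1).
#' @param power Target power (1 - type II error), in (0, 1).
#' @param method Formula variant, see Details.
#' @return A tibble with one row per input pair and columns `p_control`,
#'   `p_treatment`, `method`, `raw_n` (unrounded) and `n_per_group`.
#' @examples
#' ssr_two_proportions(0.06, 0.0054)                 # 166 per group
#' ssr_two_proportions(0.092, 0.0782)                # 6417 per group
#' ssr_two_proportions(0.06, 0.0054, method = "arcsine")
#' @export
ssr_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.80,
                                method = c("normal_mixed", "normal_pooled",
                                           "normal_unpooled", "arcsine",
                                           "arcsine_corrected")) {
  method <- match.arg(method)
  check_probability(p1, "p1")
  check_probability(p2, "p2")
  check_design(alpha, power)
  if (any(abs(p1 - p2) < .Machine$double.eps * 4)) {
    abort("`p1` and `p2` are equal: zero effect, sample size undefined.",
          class = "cesize_zero_effect")
  }
  n <- length(p1 + p2) # common recycled length
  p1 <- rep_len(p1, n); p2 <- rep_len(p2, n)
  za <- qnorm(1 - alpha / 2)
  zb <- qnorm(power)
  raw <- vapply(seq_len(n), function(i) {
    ssr_raw(p1[i], p2[i], za, zb, method)
  }, numeric(1))
  tibble(p_control = p1, p_treatment = p2, method = method,
         raw_n = raw, n_per_group = as.integer(ceiling(raw)))
}

# scalar kernel shared with the selection engine (za/zb precomputed)
ssr_raw <- function(p1, p2, za, zb, method = "normal_mixed") {
  d2 <- (p1 - p2)^2
  switch(method,
    normal_mixed = {
      pbar <- (p1 + p2) / 2
      (za * sqrt(2 * pbar * (1 - pbar)) +
         zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / d2
    },
    normal_pooled = {
      pbar <- (p1 + p2) / 2
      (za + zb)^2 * 2 * pbar * (1 - pbar) / d2
    },
    normal_unpooled = {
      (za + zb)^2 * (p1 * (1 - p1) + p2 * (1 - p2)) / d2
    },
    arcsine = {
      h <- 2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))
      (za + zb)^2 / h^2
    },
    arcsine_corrected = {
      h0 <- 2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))
      n <- (za + zb)^2 / h0^2
      for (it in seq_len(100)) {
        hc <- 2 * asin(sqrt((n * p1 + 3 / 8) / (n + 3 / 4))) -
          2 * asin(sqrt((n * p2 + 3 / 8) / (n + 3 / 4)))
        n_new <- (za + zb)^2 / hc^2
        if (abs(n_new - n) < 1e-9 * max(1, n)) return(n_new)
        n <- n_new
      }
      abort(sprintf(paste0(
        "Continuity-corrected arcsine iteration did not converge in 100 ",
        "steps (p1 = %g, p2 = %g, last n = %g)."), p1, p2, n),
        class = "cesize_convergence_error")
    },
    abort(sprintf("Unknown sample-size method '%s'.", method),
          class = "cesize_validation_error")
  )
}

# scalar ceiling-rounded SSR; Inf for a degenerate (zero-effect) composite
ssr_n <- function(p1, p2, za, zb, method) {
  if (abs(p1 - p2) < .Machine$double.eps * 4) return(Inf)
  ceiling(ssr_raw(p1, p2, za, zb, method))
}

check_design <- function(alpha, power, method = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single value in (0, 1).",
          class = "cesize_validation_error")
  }
  if (!is.numeric(power) || length(power) != 1 || power <= 0 || power >= 1) {
    abort("`power` must be a single value in (0, 1).",
          class = "cesize_validation_error")
  }
  if (alpha + (1 - power) >= 1) {
    abort("`alpha` + (1 - `power`) must be < 1.",
          class = "cesize_validation_error")
  }
  invisible(NULL)
}
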