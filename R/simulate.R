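#' Sample correlated binary outcome pairs
#'
#' Draws `n` subjects from the exact four-cell distribution of two binary
#' outcomes with marginals `p_a`, `p_b` and joint probability `joint`:
#' both events with probability `joint`, A only with `p_a - joint`, B only
#' with `p_b - joint`, neither with the remainder. The joint must lie within
#' the Fréchet bounds, which makes all four cells non-negative.
#'
#' @inheritParams frechet_bounds
#' @param joint Joint probability, within [frechet_bounds()] of the marginals.
#' @param n Number of subjects (0 allowed).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with `n` rows and integer columns `a` and `b` (0/1).
#' @examples
#' x <- sample_pair(0.092, 0.0115, 0.092 * 0.0115, n = 1e4, seed = 1)
#' mean(x$a | x$b) # close to 0.092 + 0.0115 - 0.092 * 0.0115
#' @export
sample_pair <- function(p_a, p_b, joint, n, seed = NULL) {
  b <- frechet_bounds(p_a, p_b)
  eps <- 1e-12
  if (joint < b$lower - eps || joint > b$upper + eps) {
    abort("`joint` lies outside the Fréchet bounds of the marginals.",
          class = "cesize_validation_error")
  }
  if (n == 0) return(tibble(a = integer(0), b = integer(0)))
  cells <- pmax(c(joint, p_a - joint, p_b - joint, 1 - p_a - p_b + joint), 0)
  counts <- with_seed(seed, as.vector(rmultinom(1, n, cells)))
  tibble(
    a = rep(c(1L, 1L, 0L, 0L), counts),
    b = rep(c(1L, 0L, 1L, 0L), counts)
  )
}

#' Monte-Carlo power of the pooled two-proportion z-test
#'
#' Simulates `reps` two-arm trials with `n_per_group` subjects per arm and
#' event probabilities `p1`, `p2`, tests each with the pooled two-proportion
#' z-test at two-sided level `alpha`, and returns the rejection fraction with
#' a 95% binomial (Clopper-Pearson) confidence interval. Used to validate the
#' closed-form sample sizes: at the size returned by [ssr_two_proportions()]
#' the estimate should bracket the design power.
#'
#' @param p1,p2 Event probabilities per arm.
#' @param n_per_group Subjects per arm.
#' @param alpha Two-sided test level.
#' @param reps Number of simulated trials, at least 1000.
#' @param seed Optional integer seed.
#' @return A one-row tibble: `power`, `conf_low`, `conf_high`, `reps`.
#' @examples
#' empirical_power(0.06, 0.0054, n_per_group = 166, reps = 2000, seed = 1)
#' @export
empirical_power <- function(p1, p2, n_per_group, alpha = 0.05, reps = 10000,
                            seed = NULL) {
  check_probability(p1, "p1")
  check_probability(p2, "p2")
  if (reps < 1000) {
    abort("`reps` must be at least 1000 for a usable estimate.",
          class = "cesize_validation_error")
  }
  n <- n_per_group
  rej <- with_seed(seed, {
    x1 <- rbinom(reps, n, p1)
    x2 <- rbinom(reps, n, p2)
    pbar <- (x1 + x2) / (2 * n)
    se <- sqrt(pbar * (1 - pbar) * 2 / n)
    z <- ifelse(se > 0, (x1 / n - x2 / n) / se, 0)
    sum(abs(z) > qnorm(1 - alpha / 2))
  })
  ci <- binom.test(rej, reps)$conf.int
  tibble(power = rej / reps, conf_low = ci[1], conf_high = ci[2],
         reps = as.integer(reps))
}

#' Generate a random candidate-outcome panel
#'
#' Draws a reproducible random panel: control rates uniform on `rate_range`,
#' risk ratios uniform on `rr_range`, and an independently sampled association
#' scenario for every pair. The defaults span the event rates and effect
#' sizes typical of cardiovascular trial endpoints (rare-to-uncommon events,
#' protective to mildly harmful effects). All panel invariants hold by
#' construction. Intended as a fixture generator for property tests of the
#' selection engine.
#'
#' @param k Number of outcomes, 2 to 10.
#' @param seed Integer seed; the same seed always yields the same panel.
#' @param rate_range Range of control-arm event probabilities.
#' @param rr_range Range of risk ratios.
#' @param alpha,power,method Design parameters passed to [ce_panel()].
#' @return A [ce_panel()].
#' @examples
#' generate_panel(4, seed = 42)
#' @export
generate_panel <- function(k, seed, rate_range = c(0.005, 0.15),
                           rr_range = c(0.1, 1.4), alpha = 0.05,
                           power = 0.80, method = "normal_mixed") {
  if (k < 2 || k > 10) {
    abort("`k` must be between 2 and 10.", class = "cesize_validation_error")
  }
  with_seed(seed, {
    labels <- sprintf("outcome_%02d", seq_len(k))
    rates <- runif(k, rate_range[1], rate_range[2])
    rrs <- runif(k, rr_range[1], rr_range[2])
    # guard the probability constraint for unusual user-supplied ranges
    rrs <- pmin(rrs, (1 - 1e-9) / rates)
    pairs <- expand_pairs(labels)
    pairs$scenario <- sample(association_scenarios()$scenario,
                             nrow(pairs), replace = TRUE)
    ce_panel(tibble(label = labels, control_rate = rates, rr = rrs),
             associations = pairs, alpha = alpha, power = power,
             method = method)
  })
}
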