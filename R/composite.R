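#' Event rate of a two-component composite endpoint
#'
#' The union of two binary events has probability
#' \eqn{p_A + p_B - \pi_{AB}} where \eqn{\pi_{AB}} is their joint probability,
#' which must lie within the Fréchet bounds of the marginals.
#'
#' @inheritParams frechet_bounds
#' @param joint Joint probability of the two events; must lie within
#'   [frechet_bounds()] of the marginals (correct out-of-bounds values first
#'   with [correct_joint()]).
#' @return Numeric vector of union probabilities.
#' @examples
#' combine_pair(0.092, 0.0115, 0.092 * 0.0115) # independent events
#' combine_pair(0.3, 0.2, 0.2)                 # full overlap: union = max
#' @export
combine_pair <- function(p_a, p_b, joint) {
  b <- frechet_bounds(p_a, p_b)
  eps <- 1e-12
  if (any(joint < b$lower - eps | joint > b$upper + eps)) {
    abort("`joint` lies outside the Fréchet bounds of the marginals; correct it first.",
          class = "cesize_validation_error")
  }
  p_a + p_b - joint
}

#' Joint probability between a composite and a further candidate
#'
#' When outcomes A and B are already merged into a composite, the joint
#' probability between the composite and a third outcome C is
#' \eqn{\pi_{AC} + \pi_{BC} - \pi_{ABC}}. The unknown third-order term
#' \eqn{\pi_{ABC}} is imputed as the product \eqn{\pi_{AC}\,\pi_{BC}}, so the
#' returned value is \eqn{\pi_{AC} + \pi_{BC} - \pi_{AC}\pi_{BC}}. The result
#' is an approximation and may drift slightly outside the Fréchet bounds of
#' (composite rate, candidate rate); the selection engine clamps it back and
#' reports how often clamping fired.
#'
#' @param j_ac,j_bc Joint probabilities of the two members with the candidate,
#'   in \[0, 1\]. Vectorised.
#' @return Numeric vector of composite-candidate joint probabilities.
#' @examples
#' composite_candidate_joint(0.5, 0.5) # 0.75
#' @export
composite_candidate_joint <- function(j_ac, j_bc) {
  check_probability(j_ac, "j_ac", open = FALSE)
  check_probability(j_bc, "j_bc", open = FALSE)
  j_ac + j_bc - j_ac * j_bc
}

# ---- selection engine internals ---------------------------------------------

engine_init <- function(panel) {
  jm <- resolve_arm_joints(panel)
  list(pc = panel$outcomes$control_rate,
       pt = panel$outcomes$treatment_rate,
       labels = panel$outcomes$label,
       jc = jm$control, jt = jm$treatment,
       za = qnorm(1 - panel$design$alpha / 2),
       zb = qnorm(panel$design$power),
       method = panel$design$method)
}

# state: members (ordered), composite rates per arm, joints of the composite
# with every remaining outcome per arm, clamp event counter
state_init <- function(en, first) {
  rem <- setdiff(seq_along(en$pc), first)
  list(members = first,
       c1 = en$pc[first], c2 = en$pt[first],
       rem = rem,
       j1 = en$jc[first, rem], j2 = en$jt[first, rem],
       clamps = 0L)
}

# provisional composite rates if the candidate at remaining-position i joined;
# returns c(control, treatment, n_clamps)
state_peek <- function(en, st, i) {
  k <- st$rem[i]
  q1 <- clamp_joint(st$j1[i], st$c1, en$pc[k])
  q2 <- clamp_joint(st$j2[i], st$c2, en$pt[k])
  clamps <- (q1 != st$j1[i]) + (q2 != st$j2[i])
  c(st$c1 + en$pc[k] - q1, st$c2 + en$pt[k] - q2, clamps)
}

# absorb the candidate at remaining-position i; joints with the other
# remaining outcomes are rebuilt by the third-order recursion
state_add <- function(en, st, i) {
  k <- st$rem[i]
  pk <- state_peek(en, st, i)
  rem2 <- st$rem[-i]
  keep <- match(rem2, st$rem)
  st$j1 <- composite_candidate_joint_raw(st$j1[keep], en$jc[k, rem2])
  st$j2 <- composite_candidate_joint_raw(st$j2[keep], en$jt[k, rem2])
  st$members <- c(st$members, k)
  st$c1 <- pk[1]; st$c2 <- pk[2]
  st$clamps <- st$clamps + as.integer(pk[3])
  st$rem <- rem2
  st
}

# unvalidated kernel for internal vectorised use
composite_candidate_joint_raw <- function(j_ac, j_bc) {
  if (!length(j_ac)) return(numeric(0))
  j_ac + j_bc - j_ac * j_bc
}

state_record <- function(en, st, step, added, ref) {
  n <- ssr_n(st$c1, st$c2, en$za, en$zb, en$method)
  tibble(step = step,
         added = en$labels[added],
         components = paste(en$labels[st$members], collapse = " + "),
         n_components = length(st$members),
         rate_control = st$c1, rate_treatment = st$c2,
         rr = st$c2 / st$c1,
         ssr = as.integer(n),
         pct_of_reference = round_half_up(100 * n / ref, 2))
}

warn_clamps <- function(clamps) {
  if (clamps > 0) {
    warn(sprintf(paste0(
      "The composite-candidate joint recursion left the Fréchet bounds %d ",
      "time(s) and was clamped back."), clamps),
      class = "cesize_clamp_warning")
  }
}

# ---- user-facing operations -------------------------------------------------

#' Greedy forward selection of the composite endpoint
#'
#' Starting from the relevant endpoint alone, repeatedly absorbs the remaining
#' candidate outcome whose inclusion gives the lowest per-group sample size,
#' provided that size is strictly below the incumbent's; stops when every
#' candidate is included or none strictly improves. After each absorption the
#' joint probabilities between the enlarged composite and the remaining
#' candidates are rebuilt with [composite_candidate_joint()] (third-order
#' terms imputed as products), so results depend (mildly) on the insertion
#' order, which the greedy path itself defines.
#'
#' @param panel A [ce_panel()].
#' @return An object of class `ce_selection`: a list with `records` (a tibble
#'   with one row per accepted step: `step`, `added`, `components`,
#'   `n_components`, `rate_control`, `rate_treatment`, `rr`, `ssr`,
#'   `pct_of_reference`), `stopped_reason` (`"all_included"` or
#'   `"no_improvement"`) and the number of `clamp_events`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' panel <- ce_panel(data.frame(
#'   label = c("GI bleeding", "Hb drop >= 4", "Hb drop >= 3", "Hematoma",
#'             "Access complication"),
#'   control_rate = c(0.0144, 0.0057, 0.0374, 0.06, 0.0115),
#'   rr = c(0.19, 0.48, 0.22, 0.09, 0.24)
#' ))
#' sel <- greedy_select(panel)
#' tidy(sel)
#' @export
greedy_select <- function(panel) {
  stopifnot(inherits(panel, "ce_panel"))
  en <- engine_init(panel)
  re <- panel$relevant_index
  st <- state_init(en, re)
  ref <- ssr_n(st$c1, st$c2, en$za, en$zb, en$method)
  if (!is.finite(ref)) {
    abort("The relevant endpoint has zero effect; its sample size is undefined.",
          class = "cesize_zero_effect")
  }
  records <- state_record(en, st, 1L, re, ref)
  cur <- ref
  reason <- "all_included"
  while (length(st$rem) > 0) {
    cand <- vapply(seq_along(st$rem), function(i) {
      pk <- state_peek(en, st, i)
      ssr_n(pk[1], pk[2], en$za, en$zb, en$method)
    }, numeric(1))
    best <- which.min(cand)
    if (!is.finite(cand[best]) || cand[best] >= cur) {
      reason <- "no_improvement"
      break
    }
    st <- state_add(en, st, best)
    cur <- cand[best]
    records <- bind_rows(records,
                         state_record(en, st, nrow(records) + 1L,
                                      st$members[length(st$members)], ref))
  }
  warn_clamps(st$clamps)
  structure(list(records = records, stopped_reason = reason,
                 clamp_events = st$clamps, panel = panel),
            class = "ce_selection")
}

#' Evaluate a fixed composite endpoint
#'
#' Builds the composite of the given outcomes in the given order (first
#' element first) with the panel's resolved associations and the same
#' recursion rules as [greedy_select()], and returns its per-arm rates and
#' sample size. Useful for comparing a prespecified composite against the
#' greedy choice.
#'
#' @param panel A [ce_panel()].
#' @param components Character vector of outcome labels (at least one); the
#'   insertion order is the order given.
#' @return A one-row tibble with `components`, `n_components`, `rate_control`,
#'   `rate_treatment`, `rr`, `ssr` (NA if the composite has zero effect) and
#'   `clamp_events`.
#' @export
build_composite <- function(panel, components) {
  stopifnot(inherits(panel, "ce_panel"))
  idx <- match(components, panel$outcomes$label)
  if (anyNA(idx)) {
    abort(sprintf("Unknown outcome label(s): %s.",
                  paste(components[is.na(idx)], collapse = ", ")),
          class = "cesize_validation_error")
  }
  if (anyDuplicated(idx)) {
    abort("`components` must not repeat outcomes.",
          class = "cesize_validation_error")
  }
  en <- engine_init(panel)
  st <- state_init(en, idx[1])
  for (k in idx[-1]) st <- state_add(en, st, match(k, st$rem))
  n <- ssr_n(st$c1, st$c2, en$za, en$zb, en$method)
  warn_clamps(st$clamps)
  tibble(components = paste(en$labels[st$members], collapse = " + "),
         n_components = length(st$members),
         rate_control = st$c1, rate_treatment = st$c2,
         rr = st$c2 / st$c1,
         ssr = if (is.finite(n)) as.integer(n) else NA_integer_,
         clamp_events = st$clamps)
}

#' Exhaustive search over all composites containing the relevant endpoint
#'
#' Enumerates every subset of outcomes that contains the relevant endpoint
#' and, because the third-order recursion makes the composite rate depend on
#' the order in which members are absorbed, every insertion order of each
#' subset. Returns the minimum sample size found. Since the greedy path is one
#' of the enumerated orders, the result is a true lower bound for
#' [greedy_select()] and quantifies how far the local search is from the
#' optimum. Ties are broken toward the smaller subset, then lexicographically
#' by member indices. Cost grows factorially; intended for panels of up to
#' about 7 outcomes (tests use up to 6).
#'
#' @param panel A [ce_panel()].
#' @return A one-row tibble with `components` (in panel order),
#'   `n_components`, `rate_control`, `rate_treatment`, `rr` and `ssr`, with
#'   attribute `n_evaluated` (number of distinct subsets).
#' @export
exhaustive_search <- function(panel) {
  stopifnot(inherits(panel, "ce_panel"))
  en <- engine_init(panel)
  re <- panel$relevant_index
  others <- setdiff(seq_along(en$pc), re)
  best <- NULL
  n_subsets <- 0L
  for (bits in 0:(2^length(others) - 1)) {
    members <- c(re, others[bitwAnd(bits, 2^(seq_along(others) - 1)) > 0])
    n_subsets <- n_subsets + 1L
    for (ord in permutations(members)) {
      st <- state_init(en, ord[1])
      for (k in ord[-1]) st <- state_add(en, st, match(k, st$rem))
      n <- ssr_n(st$c1, st$c2, en$za, en$zb, en$method)
      if (!is.finite(n)) next
      key <- list(ssr = n, size = length(members), idx = sort(members),
                  c1 = st$c1, c2 = st$c2)
      if (is.null(best) || better_subset(key, best)) best <- key
    }
  }
  if (is.null(best)) {
    abort("Every composite in the panel has zero effect.",
          class = "cesize_zero_effect")
  }
  out <- tibble(components = paste(en$labels[best$idx], collapse = " + "),
                n_components = best$size,
                rate_control = best$c1, rate_treatment = best$c2,
                rr = best$c2 / best$c1,
                ssr = as.integer(best$ssr))
  attr(out, "n_evaluated") <- n_subsets
  out
}

better_subset <- function(a, b) {
  if (a$ssr != b$ssr) return(a$ssr < b$ssr)
  if (a$size != b$size) return(a$size < b$size)
  # lexicographic on sorted member indices (shorter never reaches here equal)
  for (i in seq_along(a$idx)) {
    if (a$idx[i] != b$idx[i]) return(a$idx[i] < b$idx[i])
  }
  FALSE
}

permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- vector("list", factorial(length(v)))
  n <- 0L
  for (i in seq_along(v)) {
    for (rest in permutations(v[-i])) {
      n <- n + 1L
      out[[n]] <- c(v[i], rest)
    }
  }
  out
}

#' Sample-size range per candidate across the attainable association range
#'
#' For each candidate outcome, forms the two-component composite with the
#' relevant endpoint twice: with the joint probability at the lower Fréchet
#' bound (minimum association, largest union) and at the upper bound (maximum
#' association, smallest union), per arm, and reports both per-group sample
#' sizes. This brackets the impact any association assumption can have before
#' one is chosen. A degenerate composite (identical rates in the two arms) is
#' reported as NA rather than an error.
#'
#' @param panel A [ce_panel()].
#' @return A tibble of class `ce_pair_ranges` with one row per candidate:
#'   `label`, `control_rate`, `rr`, `ssr_min_association`,
#'   `ssr_max_association`; attribute `ssr_reference` holds the relevant
#'   endpoint's own sample size.
#' @export
pair_range_table <- function(panel) {
  stopifnot(inherits(panel, "ce_panel"))
  en <- engine_init(panel)
  re <- panel$relevant_index
  others <- setdiff(seq_along(en$pc), re)
  ref <- ssr_n(en$pc[re], en$pt[re], en$za, en$zb, en$method)
  rows <- map(others, function(k) {
    b1 <- frechet_bounds(en$pc[re], en$pc[k])
    b2 <- frechet_bounds(en$pt[re], en$pt[k])
    at <- function(j1, j2) {
      p1 <- en$pc[re] + en$pc[k] - j1
      p2 <- en$pt[re] + en$pt[k] - j2
      n <- ssr_n(p1, p2, en$za, en$zb, en$method)
      if (is.finite(n)) as.integer(n) else NA_integer_
    }
    tibble(label = en$labels[k],
           control_rate = en$pc[k], rr = en$pt[k] / en$pc[k],
           ssr_min_association = at(b1$lower, b2$lower),
           ssr_max_association = at(b1$upper, b2$upper))
  })
  out <- bind_rows(rows)
  attr(out, "ssr_reference") <- if (is.finite(ref)) as.integer(ref) else
    NA_integer_
  class(out) <- c("ce_pair_ranges", class(out))
  out
}

# ---- methods ----------------------------------------------------------------

#' @export
print.ce_selection <- function(x, ...) {
  cat(sprintf("<ce_selection> %d step(s); stopped: %s\n",
              nrow(x$records), x$stopped_reason))
  print(x$records, ...)
  invisible(x)
}

#' @export
tidy.ce_selection <- function(x, ...) x$records

#' @export
glance.ce_selection <- function(x, ...) {
  last <- x$records[nrow(x$records), ]
  tibble(n_steps = nrow(x$records),
         components = last$components,
         n_components = last$n_components,
         ssr = last$ssr,
         pct_of_reference = last$pct_of_reference,
         stopped_reason = x$stopped_reason,
         clamp_events = x$clamp_events)
}
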