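#' Build a panel of candidate outcomes for a composite endpoint
#'
#' A panel bundles everything needed to size a two-arm trial on a binary
#' composite endpoint: 2 to 10 candidate binary outcomes (control-arm rate and
#' treatment effect for each), a pairwise association specification, and the
#' design parameters. One outcome acts as the *relevant endpoint* (RE), the
#' outcome assumed to drive the main effect of the therapy; if none is flagged
#' the outcome with the lowest single-outcome sample size is assigned the role.
#'
#' @param outcomes A data frame with one row per candidate outcome and columns:
#'   * `label` (unique, free text),
#'   * `control_rate` (control-arm event probability, in (0, 1)),
#'   * exactly one of `rr` (risk ratio), `or` (odds ratio) or `diff`
#'     (risk difference, treatment minus control, proportion scale),
#'   * optionally `relevant` (logical; at most one `TRUE`).
#' @param associations Optional data frame with columns `a`, `b` (outcome
#'   labels, one row per unordered pair) and either `joint` (exact joint
#'   probability, control scale) or `scenario` (a code from
#'   [association_scenarios()]); exactly one of the two per row, rows may mix.
#'   Pairs not listed default to the `"none"` (independence) scenario. Exact
#'   joints outside the control-arm Fréchet bounds are corrected to the product
#'   of marginals with a warning.
#' @param alpha Two-sided type I error. Default 0.05.
#' @param power Target power. Default 0.80.
#' @param method Sample-size formula, see [ssr_two_proportions()].
#' @param relevant Optional label of the relevant endpoint; alternative to the
#'   `relevant` column.
#' @return An object of class `ce_panel`: a list with tibbles `outcomes`
#'   (canonical columns `label`, `control_rate`, `rr`, `treatment_rate`,
#'   `relevant`) and `associations` (`a`, `b`, `joint`, `scenario`), the
#'   `design` list and the resolved `relevant_index`.
#' @examples
#' panel <- ce_panel(
#'   data.frame(
#'     label = c("Death", "Infarction", "Stroke", "CABG"),
#'     control_rate = c(0.023, 0.0115, 0.0029, 0.092),
#'     rr = c(1.33, 0.73, 0.97, 0.85)
#'   )
#' )
#' panel
#' @seealso [greedy_select()], [sweep_associations()], [pair_range_table()]
#' @export
ce_panel <- function(outcomes, associations = NULL, alpha = 0.05,
                     power = 0.80,
                     method = c("normal_mixed", "normal_pooled",
                                "normal_unpooled", "arcsine",
                                "arcsine_corrected"),
                     relevant = NULL) {
  method <- match.arg(method)
  check_design(alpha, power)
  outcomes <- as_tibble(outcomes)

  if (!all(c("label", "control_rate") %in% names(outcomes))) {
    abort("`outcomes` needs columns `label` and `control_rate`.",
          class = "cesize_validation_error")
  }
  k <- nrow(outcomes)
  if (k < 2 || k > 10) {
    abort(sprintf("A panel takes between 2 and 10 candidate outcomes; got %d.",
                  k), class = "cesize_validation_error")
  }
  outcomes$label <- as.character(outcomes$label)
  if (anyDuplicated(outcomes$label)) {
    abort("Outcome labels must be unique.", class = "cesize_validation_error")
  }
  check_probability(outcomes$control_rate, "control_rate")

  eff <- intersect(c("rr", "or", "diff"), names(outcomes))
  if (length(eff) != 1) {
    abort("`outcomes` needs exactly one effect column among `rr`, `or`, `diff`.",
          class = "cesize_validation_error")
  }
  rr <- switch(eff,
    rr = outcomes$rr,
    or = or_to_rr(outcomes$or, outcomes$control_rate),
    diff = diff_to_rr(outcomes$diff, outcomes$control_rate)
  )
  if (!is.numeric(rr) || anyNA(rr) || any(rr <= 0)) {
    abort("Risk ratios must be positive (label(s): check the effect column).",
          class = "cesize_validation_error")
  }
  bad <- rr * outcomes$control_rate >= 1
  if (any(bad)) {
    abort(sprintf("Treatment rate rr * control_rate must be < 1; violated for: %s.",
                  paste(outcomes$label[bad], collapse = ", ")),
          class = "cesize_validation_error")
  }

  flag <- if ("relevant" %in% names(outcomes)) {
    isTRUE_vec(outcomes$relevant)
  } else {
    rep(FALSE, k)
  }
  if (!is.null(relevant)) {
    i <- match(relevant, outcomes$label)
    if (is.na(i)) {
      abort(sprintf("`relevant` label '%s' is not in the panel.", relevant),
            class = "cesize_validation_error")
    }
    flag <- replace(rep(FALSE, k), i, TRUE)
  }
  if (sum(flag) > 1) {
    abort("At most one outcome may be flagged as the relevant endpoint.",
          class = "cesize_validation_error")
  }

  out <- tibble(
    label = outcomes$label,
    control_rate = as.numeric(outcomes$control_rate),
    rr = as.numeric(rr),
    treatment_rate = as.numeric(rr * outcomes$control_rate),
    relevant = flag
  )

  assoc <- normalise_associations(associations, out)

  panel <- structure(
    list(outcomes = out, associations = assoc,
         design = list(alpha = alpha, power = power, method = method),
         relevant_index = NA_integer_),
    class = "ce_panel"
  )
  panel$relevant_index <- select_relevant(panel)
  panel
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

# canonical association tibble: one row per unordered pair (a < b in panel
# order), columns a, b, joint (NA unless exact), scenario (NA unless coded)
normalise_associations <- function(associations, outcomes) {
  labels <- outcomes$label
  k <- length(labels)
  pairs <- expand_pairs(labels)
  if (is.null(associations) || nrow(as_tibble(associations)) == 0) {
    return(mutate(pairs, joint = NA_real_, scenario = "none"))
  }
  assoc <- as_tibble(associations)
  if (!all(c("a", "b") %in% names(assoc))) {
    abort("`associations` needs label columns `a` and `b`.",
          class = "cesize_validation_error")
  }
  if (!"joint" %in% names(assoc)) assoc$joint <- NA_real_
  if (!"scenario" %in% names(assoc)) assoc$scenario <- NA_character_
  ia <- match(assoc$a, labels)
  ib <- match(assoc$b, labels)
  if (anyNA(ia) || anyNA(ib)) {
    abort("`associations` mentions labels not present in the panel.",
          class = "cesize_validation_error")
  }
  if (any(ia == ib)) {
    abort("An outcome cannot be paired with itself.",
          class = "cesize_validation_error")
  }
  # orient to panel order and check one entry per unordered pair
  swap <- ia > ib
  tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp
  key <- paste(ia, ib)
  if (anyDuplicated(key)) {
    abort("Each outcome pair may appear at most once in `associations`.",
          class = "cesize_validation_error")
  }
  one <- is.na(assoc$joint) + is.na(assoc$scenario)
  if (any(one != 1)) {
    abort("Each association entry needs exactly one of `joint` or `scenario`.",
          class = "cesize_validation_error")
  }
  coded <- assoc$scenario[!is.na(assoc$scenario)]
  scenario_theta(coded) # validates codes

  out <- mutate(pairs, joint = NA_real_, scenario = "none")
  idx <- match(key, paste(match(out$a, labels), match(out$b, labels)))
  out$joint[idx] <- assoc$joint
  out$scenario[idx] <- ifelse(is.na(assoc$scenario), NA, assoc$scenario)

  # exact joints live on the control scale; apply the automatic correction
  ex <- which(!is.na(out$joint))
  for (i in ex) {
    pa <- outcomes$control_rate[match(out$a[i], labels)]
    pb <- outcomes$control_rate[match(out$b[i], labels)]
    out$joint[i] <- correct_joint(pa, pb, out$joint[i],
                                  label = paste0(out$a[i], "/", out$b[i]))
  }
  out
}

expand_pairs <- function(labels) {
  k <- length(labels)
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  tibble(a = labels[idx[, "row"]], b = labels[idx[, "col"]])
}

#' Identify the relevant endpoint of a panel
#'
#' Returns the index of the user-flagged relevant endpoint if one is flagged;
#' otherwise the outcome whose single-outcome sample size requirement is
#' smallest under the panel's design (ties broken by the lowest index).
#'
#' @param panel A [ce_panel()].
#' @return Integer index into `panel$outcomes`.
#' @examples
#' p <- ce_panel(data.frame(label = c("A", "B"),
#'                          control_rate = c(0.05, 0.10),
#'                          rr = c(0.8, 0.8)))
#' select_relevant(p) # B: higher rate, same RR, fewer subjects needed
#' @export
select_relevant <- function(panel) {
  stopifnot(inherits(panel, "ce_panel"))
  flagged <- which(panel$outcomes$relevant)
  if (length(flagged) == 1) return(flagged)
  za <- qnorm(1 - panel$design$alpha / 2)
  zb <- qnorm(panel$design$power)
  n <- vapply(seq_len(nrow(panel$outcomes)), function(i) {
    ssr_n(panel$outcomes$control_rate[i], panel$outcomes$treatment_rate[i],
          za, zb, panel$design$method)
  }, numeric(1))
  which.min(n) # which.min takes the first (lowest-index) minimum
}

# per-arm K x K joint probability matrices; scenario entries are imputed from
# each arm's own marginals, exact entries are applied to both arms and
# corrected per arm against that arm's Fréchet bounds
resolve_arm_joints <- function(panel) {
  out <- panel$outcomes
  k <- nrow(out)
  jc <- jt <- matrix(NA_real_, k, k)
  for (r in seq_len(nrow(panel$associations))) {
    a <- match(panel$associations$a[r], out$label)
    b <- match(panel$associations$b[r], out$label)
    if (!is.na(panel$associations$joint[r])) {
      j <- panel$associations$joint[r]
      vc <- correct_joint(out$control_rate[a], out$control_rate[b], j,
                          label = paste0(out$label[a], "/", out$label[b],
                                         " (control arm)"))
      vt <- correct_joint(out$treatment_rate[a], out$treatment_rate[b], j,
                          label = paste0(out$label[a], "/", out$label[b],
                                         " (treatment arm)"))
    } else {
      sc <- panel$associations$scenario[r]
      vc <- impute_joint(out$control_rate[a], out$control_rate[b], sc)
      vt <- impute_joint(out$treatment_rate[a], out$treatment_rate[b], sc)
    }
    jc[a, b] <- jc[b, a] <- vc
    jt[a, b] <- jt[b, a] <- vt
  }
  list(control = jc, treatment = jt)
}

#' @export
print.ce_panel <- function(x, ...) {
  k <- nrow(x$outcomes)
  cat(sprintf(
    "<ce_panel> %d candidate outcomes | alpha = %g, power = %g, method = %s\n",
    k, x$design$alpha, x$design$power, x$design$method))
  cat(sprintf("Relevant endpoint: %s%s\n",
              x$outcomes$label[x$relevant_index],
              if (any(x$outcomes$relevant)) " (user flagged)"
              else " (lowest single-outcome sample size)"))
  print(x$outcomes, ...)
  n_exact <- sum(!is.na(x$associations$joint))
  n_none <- sum(!is.na(x$associations$scenario) &
                  x$associations$scenario == "none")
  cat(sprintf("Associations: %d pairs (%d exact, %d independence, %d other)\n",
              nrow(x$associations), n_exact, n_none,
              nrow(x$associations) - n_exact - n_none))
  invisible(x)
}

#' @export
tidy.ce_panel <- function(x, ...) x$outcomes

#' @export
glance.ce_panel <- function(x, ...) {
  tibble(k = nrow(x$outcomes),
         relevant = x$outcomes$label[x$relevant_index],
         alpha = x$design$alpha, power = x$design$power,
         method = x$design$method)
}
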