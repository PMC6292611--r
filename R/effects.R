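#' Convert between risk ratio and odds ratio
#'
#' For a binary outcome with control-arm event probability `p_control`, the
#' risk ratio RR (treatment rate / control rate) and odds ratio OR are
#' interchangeable:
#' \deqn{OR = \frac{RR (1 - p)}{1 - RR\,p}, \qquad RR = \frac{OR}{(1 - p) + OR\,p}.}
#'
#' @param rr Risk ratio(s), positive, with `rr * p_control < 1` so the implied
#'   treatment rate is a probability.
#' @param or Odds ratio(s), positive.
#' @param p_control Control-arm event probability in (0, 1).
#' @return A numeric vector of converted effect measures.
#' @examples
#' rr_to_or(1.33, 0.023) # ~1.34
#' or_to_rr(1.34, 0.023) # ~1.33
#' @export
rr_to_or <- function(rr, p_control) {
  check_probability(p_control, "p_control")
  if (!is.numeric(rr) || anyNA(rr) || any(rr <= 0)) {
    abort("`rr` must be a positive number.", class = "cesize_validation_error")
  }
  if (any(rr * p_control >= 1)) {
    abort("`rr * p_control` must be < 1 (treatment rate must be a probability).",
          class = "cesize_validation_error")
  }
  rr * (1 - p_control) / (1 - rr * p_control)
}

#' @rdname rr_to_or
#' @export
or_to_rr <- function(or, p_control) {
  check_probability(p_control, "p_control")
  if (!is.numeric(or) || anyNA(or) || any(or <= 0)) {
    abort("`or` must be a positive number.", class = "cesize_validation_error")
  }
  or / ((1 - p_control) + or * p_control)
}

# risk difference (treatment - control, proportion scale) to risk ratio
diff_to_rr <- function(diff, p_control) {
  (p_control + diff) / p_control
}
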