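#' Read a study configuration file
#'
#' Loads a panel from a JSON study configuration (canonical, schema
#' `"ce-study/1"`) or from an outcomes-only CSV. The JSON layout is:
#'
#' ```json
#' {
#'   "schema": "ce-study/1",
#'   "outcomes": [
#'     {"label": "Hematoma", "control_rate": 6.0, "percent": true,
#'      "rr": 0.09, "relevant": true}
#'   ],
#'   "associations": [
#'     {"pair": ["Hematoma", "GI bleeding"], "scenario": "none"},
#'     {"pair": ["Hematoma", "Hb drop"], "joint": 0.006}
#'   ],
#'   "design": {"alpha": 0.05, "power": 0.8, "method": "normal_mixed"}
#' }
#' ```
#'
#' Every outcome states its rate scale explicitly via `percent` (no silent
#' heuristics) and carries exactly one of `rr`, `or` or `diff`; `or` and
#' `diff` are converted to risk ratios on load. Association entries give
#' either an exact `joint` probability (proportion scale unless the entry
#' sets `"percent": true`) or a `scenario` code; unlisted pairs default to
#' `"none"`. Out-of-bounds joints are corrected to the product of marginals
#' with a warning. Unknown keys are rejected. A CSV file needs columns
#' `label`, `control_rate`, `percent`, one of `rr`/`or`/`diff` and optionally
#' `relevant`; all associations then default to `"none"`.
#'
#' @param path Path to a `.json` or `.csv` configuration.
#' @param alpha,power,method Optional overrides of the file's design block.
#' @return A [ce_panel()].
#' @seealso [write_study_config()]
#' @export
read_study_config <- function(path, alpha = NULL, power = NULL,
                              method = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Configuration file '%s' does not exist.", path),
          class = "cesize_io_error")
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    cfg <- config_from_csv(path)
  } else {
    cfg <- config_from_json(path)
  }
  design <- cfg$design
  design$alpha <- alpha %||% design$alpha %||% 0.05
  design$power <- power %||% design$power %||% 0.80
  design$method <- method %||% design$method %||% "normal_mixed"
  ce_panel(cfg$outcomes, associations = cfg$associations,
           alpha = design$alpha, power = design$power,
           method = design$method, relevant = cfg$relevant)
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    abort(sprintf("Unknown key(s) in %s: %s.", where,
                  paste(extra, collapse = ", ")),
          class = "cesize_io_error")
  }
}

config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  check_keys(raw, c("schema", "outcomes", "associations", "design",
                    "relevant"), "configuration")
  if (!is.null(raw$schema) && !identical(raw$schema, "ce-study/1")) {
    abort(sprintf("Unsupported schema '%s' (expected 'ce-study/1').",
                  raw$schema), class = "cesize_io_error")
  }
  if (is.null(raw$outcomes) || !length(raw$outcomes)) {
    abort("Configuration has no `outcomes`.", class = "cesize_io_error")
  }
  outcomes <- bind_rows(map(raw$outcomes, parse_outcome))
  associations <- if (length(raw$associations)) {
    bind_rows(map(raw$associations, parse_association))
  }
  design <- raw$design %||% list()
  check_keys(design, c("alpha", "power", "method"), "`design`")
  list(outcomes = outcomes, associations = associations,
       design = design, relevant = raw$relevant)
}

parse_outcome <- function(o) {
  check_keys(o, c("label", "control_rate", "percent", "rr", "or", "diff",
                  "relevant"), "an outcome entry")
  if (is.null(o$label) || is.null(o$control_rate) || is.null(o$percent)) {
    abort("Each outcome needs `label`, `control_rate` and an explicit `percent` flag.",
          class = "cesize_io_error")
  }
  eff <- intersect(c("rr", "or", "diff"), names(o))
  if (length(eff) != 1) {
    abort(sprintf("Outcome '%s' needs exactly one of `rr`, `or`, `diff`.",
                  o$label), class = "cesize_io_error")
  }
  scale <- if (isTRUE(o$percent)) 100 else 1
  row <- tibble(label = as.character(o$label),
                control_rate = as.numeric(o$control_rate) / scale,
                relevant = isTRUE(o$relevant))
  # diff shares the rate scale; rr and or are scale-free
  row[[eff]] <- as.numeric(o[[eff]]) / if (eff == "diff") scale else 1
  row
}

parse_association <- function(a) {
  check_keys(a, c("pair", "joint", "scenario", "percent"),
             "an association entry")
  if (is.null(a$pair) || length(a$pair) != 2) {
    abort("Each association entry needs a `pair` of two labels.",
          class = "cesize_io_error")
  }
  has_joint <- !is.null(a$joint)
  has_scenario <- !is.null(a$scenario)
  if (has_joint == has_scenario) {
    abort(sprintf("Association for pair [%s, %s] needs exactly one of `joint` or `scenario`.",
                  a$pair[[1]], a$pair[[2]]), class = "cesize_io_error")
  }
  scale <- if (isTRUE(a$percent)) 100 else 1
  lab_a <- as.character(a$pair[[1]])
  lab_b <- as.character(a$pair[[2]])
  joint <- if (has_joint) as.numeric(a$joint) / scale else NA_real_
  scenario <- if (has_scenario) as.character(a$scenario) else NA_character_
  tibble(a = lab_a, b = lab_b, joint = joint, scenario = scenario)
}

config_from_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("label", "control_rate", "percent")
  if (!all(need %in% names(df))) {
    abort("CSV configuration needs columns `label`, `control_rate`, `percent`.",
          class = "cesize_io_error")
  }
  eff <- intersect(c("rr", "or", "diff"), names(df))
  if (length(eff) != 1) {
    abort("CSV configuration needs exactly one effect column among `rr`, `or`, `diff`.",
          class = "cesize_io_error")
  }
  scale <- ifelse(isTRUE_vec(df$percent), 100, 1)
  out <- tibble(label = as.character(df$label),
                control_rate = df$control_rate / scale)
  out[[eff]] <- df[[eff]] / if (eff == "diff") scale else 1
  if ("relevant" %in% names(df)) out$relevant <- isTRUE_vec(df$relevant)
  list(outcomes = out, associations = NULL, design = list(), relevant = NULL)
}

#' Write a panel as a canonical JSON study configuration
#'
#' Serialises a panel to the `"ce-study/1"` JSON dialect (proportion scale,
#' risk-ratio effects). Reading the file back with [read_study_config()]
#' reconstructs an identical panel.
#'
#' @param panel A [ce_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(panel, path) {
  stopifnot(inherits(panel, "ce_panel"))
  outcomes <- map(seq_len(nrow(panel$outcomes)), function(i) {
    o <- panel$outcomes[i, ]
    x <- list(label = o$label, control_rate = o$control_rate,
              percent = FALSE, rr = o$rr)
    if (o$relevant) x$relevant <- TRUE
    x
  })
  associations <- map(seq_len(nrow(panel$associations)), function(i) {
    a <- panel$associations[i, ]
    x <- list(pair = c(a$a, a$b))
    if (!is.na(a$joint)) x$joint <- a$joint else x$scenario <- a$scenario
    x
  })
  cfg <- list(schema = "ce-study/1",
              outcomes = outcomes,
              associations = associations,
              design = panel$design)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
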