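# Worked-example panels: bleeding and ischemic outcome sets of the
# STEMI-RADIAL trial (control-arm rates and risk ratios as used throughout
# the documentation). All associations default to independence.

bleeding_outcomes <- function() {
  data.frame(
    label = c("GI bleeding", "Hb drop >= 4", "Hb drop >= 3",
              "Hematoma > 15 cm", "Access complication"),
    control_rate = c(0.0144, 0.0057, 0.0374, 0.06, 0.0115),
    rr = c(0.19, 0.48, 0.22, 0.09, 0.24)
  )
}

bleeding_panel <- function(...) ce_panel(bleeding_outcomes(), ...)

ischemic_outcomes <- function() {
  data.frame(
    label = c("Death", "Infarction", "Stroke", "CABG"),
    control_rate = c(0.023, 0.0115, 0.0029, 0.092),
    rr = c(1.33, 0.73, 0.97, 0.85)
  )
}

ischemic_panel <- function(...) ce_panel(ischemic_outcomes(), ...)

# overwrite every pairwise association of a panel with one scenario code
all_scenario <- function(outcomes, scenario, ...) {
  labels <- outcomes$label
  idx <- which(upper.tri(diag(length(labels))), arr.ind = TRUE)
  ce_panel(outcomes,
           associations = data.frame(a = labels[idx[, "row"]],
                                     b = labels[idx[, "col"]],
                                     scenario = scenario),
           ...)
}
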