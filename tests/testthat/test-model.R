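test_that("risk ratio and odds ratio interconvert as published", {
  # Table-1 style conversions at 2 dp
  expect_equal(round(rr_to_or(1.33, 0.023), 2), 1.34)
  expect_equal(round(rr_to_or(0.85, 0.092), 2), 0.84)
  expect_equal(rr_to_or(0.85, 0.092), 0.8373, tolerance = 1e-4)
  expect_equal(round(or_to_rr(1.34, 0.023), 2), 1.33)
  # a null effect is invariant under conversion
  expect_equal(rr_to_or(1, 0.3), 1)
  expect_equal(or_to_rr(1, 0.5), 1)
})

test_that("rr_to_or and or_to_rr are mutual inverses over an admissible grid", {
  grid <- expand.grid(rr = seq(0.1, 1.4, by = 0.1),
                      p = seq(0.01, 0.5, by = 0.05))
  or <- rr_to_or(grid$rr, grid$p)
  expect_equal(or_to_rr(or, grid$p), grid$rr, tolerance = 1e-12)
  rr <- or_to_rr(grid$rr, grid$p) # reuse grid values as odds ratios
  expect_equal(rr_to_or(rr, grid$p), grid$rr, tolerance = 1e-12)
})

test_that("effect conversions reject out-of-range inputs by name", {
  expect_error(rr_to_or(-1, 0.1), "rr", class = "cesize_validation_error")
  expect_error(rr_to_or(2, 0.6), "rr \\* p_control",
               class = "cesize_validation_error")
  expect_error(or_to_rr(1.2, 1.2), "p_control",
               class = "cesize_validation_error")
})

test_that("Fréchet bounds match direct evaluation", {
  expect_equal(frechet_bounds(0.06, 0.10), tibble::tibble(lower = 0, upper = 0.06))
  expect_equal(frechet_bounds(0.6, 0.7), tibble::tibble(lower = 0.3, upper = 0.6))
  expect_equal(frechet_bounds(0.092, 0.0115),
               tibble::tibble(lower = 0, upper = 0.0115))
  # lower <= upper always, including at the edges of [0, 1]
  g <- expand.grid(a = seq(0, 1, by = 0.1), b = seq(0, 1, by = 0.1))
  b <- frechet_bounds(g$a, g$b)
  expect_true(all(b$lower <= b$upper + 1e-15))
})

test_that("scenario imputation interpolates in quarters and stays in bounds", {
  # anchors from the worked examples
  expect_equal(impute_joint(0.06, 0.10, "none"), 0.006)
  expect_equal(impute_joint(0.092, 0.0115, "highest"), 0.0115)
  # back-solved from the published moderate-positive composite rate:
  # independence + half the distance to the upper bound
  expect_equal(impute_joint(0.092, 0.0115, "moderate_positive"),
               0.001058 + (0.0115 - 0.001058) / 2, tolerance = 1e-12)
  expect_equal(impute_joint(0.092, 0.0115, "moderate_positive"), 0.006279,
               tolerance = 1e-6)
  # lower bound is 0 here, so strong negative keeps a quarter of independence
  expect_equal(impute_joint(0.092, 0.0115, "strong_negative"),
               0.001058 * (1 - 3 / 4), tolerance = 1e-12)
  expect_error(impute_joint(0.1, 0.2, "very_positive"),
               class = "cesize_validation_error")
})

test_that("imputed joints respect bounds and are monotone in theta", {
  scen <- association_scenarios()
  grid <- expand.grid(a = c(0.01, 0.05, 0.12, 0.3, 0.55, 0.8, 0.95),
                      b = c(0.02, 0.09, 0.25, 0.5, 0.7, 0.9))
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; b <- grid$b[i]
    bounds <- frechet_bounds(a, b)
    j <- impute_joint(rep(a, 9), rep(b, 9), scen$scenario)
    expect_true(all(j >= bounds$lower - 1e-15 & j <= bounds$upper + 1e-15))
    # theta = 0 is exact independence; ordering follows theta
    expect_identical(j[scen$theta == 0], a * b)
    expect_true(all(diff(j[order(scen$theta)]) >= -1e-15))
    expect_equal(j[scen$scenario == "lowest"], bounds$lower)
    expect_equal(j[scen$scenario == "highest"], bounds$upper)
  }
})

test_that("out-of-bounds joints are corrected to independence, idempotently", {
  expect_warning(j <- correct_joint(0.06, 0.10, 0.08),
                 class = "cesize_joint_correction")
  expect_equal(j, 0.006)
  expect_silent(expect_equal(correct_joint(0.06, 0.10, 0.05), 0.05))
  expect_warning(j2 <- correct_joint(0.6, 0.7, 0.1),
                 class = "cesize_joint_correction")
  expect_equal(j2, 0.42)
  # idempotence: a corrected value passes through untouched
  expect_silent(expect_equal(correct_joint(0.06, 0.10, j), j))
  expect_silent(expect_equal(correct_joint(0.6, 0.7, j2), j2))
})

test_that("panel construction validates its invariants", {
  out <- data.frame(label = c("A", "B"), control_rate = c(0.1, 0.2),
                    rr = c(0.5, 0.8))
  expect_s3_class(ce_panel(out), "ce_panel")
  expect_error(ce_panel(out[1, ]), "between 2 and 10",
               class = "cesize_validation_error")
  eleven <- data.frame(label = letters[1:11], control_rate = 0.05, rr = 0.5)
  expect_error(ce_panel(eleven), "between 2 and 10",
               class = "cesize_validation_error")
  expect_error(ce_panel(transform(out, label = c("A", "A"))), "unique",
               class = "cesize_validation_error")
  expect_error(ce_panel(transform(out, rr = c(0.5, 6))), "< 1",
               class = "cesize_validation_error")
  expect_error(ce_panel(transform(out, control_rate = c(0, 0.2))),
               class = "cesize_validation_error")
  expect_error(ce_panel(out, relevant = "C"), "not in the panel",
               class = "cesize_validation_error")
  both <- transform(out, relevant = c(TRUE, TRUE))
  expect_error(ce_panel(both), "At most one",
               class = "cesize_validation_error")
  # effect measures are interchangeable at construction
  via_or <- ce_panel(data.frame(label = c("A", "B"),
                                control_rate = c(0.1, 0.2),
                                or = rr_to_or(c(0.5, 0.8), c(0.1, 0.2))))
  expect_equal(via_or$outcomes$rr, c(0.5, 0.8), tolerance = 1e-12)
  via_diff <- ce_panel(data.frame(label = c("A", "B"),
                                  control_rate = c(0.1, 0.2),
                                  diff = c(-0.05, -0.04)))
  expect_equal(via_diff$outcomes$rr, c(0.5, 0.8), tolerance = 1e-12)
})

test_that("the relevant endpoint defaults to the lowest single-outcome size", {
  # CABG needs the fewest subjects among the ischemic outcomes
  p <- ischemic_panel()
  expect_equal(select_relevant(p), 4L)
  expect_equal(p$outcomes$label[p$relevant_index], "CABG")
  # a user flag always wins
  flagged <- ce_panel(bleeding_outcomes(), relevant = "Hb drop >= 3")
  expect_equal(flagged$outcomes$label[flagged$relevant_index], "Hb drop >= 3")
  # ties break toward the lowest index
  twin <- ce_panel(data.frame(label = c("A", "B"),
                              control_rate = c(0.1, 0.1), rr = c(0.5, 0.5)))
  expect_equal(select_relevant(twin), 1L)
})
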