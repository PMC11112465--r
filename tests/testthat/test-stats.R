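fake_params <- function(values, participants, grades, foot = "left") {
  n <- length(values)
  tibble::tibble(
    participant_id = participants, foot = foot, grade = grades,
    step_id = seq_len(n), duration_ms = 700,
    fz2 = values * 1.2, fz3 = values * 0.9, fz4 = values * 1.1,
    fmean_stance = values, fmean_load = values, fmean_mid = values,
    fmean_unload = values, loading_slope = values * 7,
    unloading_slope = values * -7)
}

test_that("grade summaries aggregate with the selected pooling mode", {
  p <- fake_params(c(1, 1), c("A", "A"), c(0, 0))
  sm <- summarize_by_grade(p)
  expect_true(all(sm$sd[sm$parameter == "fmean_stance"] == 0 |
                    is.na(sm$sd[sm$parameter == "fmean_stance"])))
  expect_equal(sm$mean[sm$parameter == "fmean_stance"], 1)

  # participant-first pooling weighs participants equally regardless of steps
  p2 <- fake_params(c(1, 1, 1, 1.4), c("A", "A", "A", "B"), rep(0, 4))
  sm2 <- summarize_by_grade(p2, pooling = "participant")
  expect_equal(sm2$mean[sm2$parameter == "fmean_stance"], 1.2)
  sm3 <- summarize_by_grade(p2, pooling = "step")
  expect_equal(sm3$mean[sm3$parameter == "fmean_stance"], 1.1)
  expect_equal(sm2$n_steps, sm3$n_steps)
})

test_that("summaries are invariant to record order", {
  set.seed(2)
  p <- fake_params(runif(30, 0.8, 1.2),
                   sample(c("A", "B", "C"), 30, TRUE),
                   sample(c(-5, 0, 5), 30, TRUE))
  a <- summarize_by_grade(p)
  b <- summarize_by_grade(p[sample.int(30), ])
  expect_equal(a, b)
})

test_that("percent-of-horizontal normalization anchors every parameter at 100", {
  norm <- normalize_to_horizontal(grade_reference_summary())
  at0 <- norm$pct_of_horizontal[norm$grade == 0]
  expect_equal(at0, rep(100, 9))
  # division oracle on the published means
  fz2 <- norm[norm$parameter == "fz2", ]
  expect_equal(fz2$pct_of_horizontal[fz2$grade == -20], 125.0,
               tolerance = 1e-10)
  expect_equal(fz2$pct_of_horizontal[fz2$grade == -15],
               100 * 1.48 / 1.20, tolerance = 1e-10)
  expect_equal(fz2$pct_of_horizontal[fz2$grade == 20],
               92.5, tolerance = 1e-10)
  un <- norm[norm$parameter == "unloading_slope", ]
  expect_equal(un$pct_of_horizontal[un$grade == -20],
               100 * (-5.30) / (-7.31), tolerance = 1e-10)
  expect_equal(un$pct_of_horizontal[un$grade == -20], 72.5, tolerance = 0.05)
  # a more negative value maps above 100%
  expect_gt(un$pct_of_horizontal[un$grade == 20], 100)
})

test_that("normalization requires a usable horizontal reference", {
  sm <- grade_reference_summary()
  expect_error(normalize_to_horizontal(sm[sm$grade != 0, ]), "0%")
  zero <- sm
  zero$mean[zero$grade == 0] <- 0
  expect_error(normalize_to_horizontal(zero), "zero")
})

test_that("trend regression recovers exact linear series and flags degenerate input", {
  sm <- tibble::tibble(grade = rep(seq(-20, 20, 5), 2),
                       parameter = rep(c("fz2", "fz3"), each = 9),
                       mean = c(100 - 2 * seq(-20, 20, 5),
                                100 + 0.5 * seq(-20, 20, 5)))
  sm$pct_of_horizontal <- sm$mean
  fit <- regress_normalized(sm)
  td <- suppressWarnings(tidy(fit)) # summary.lm cautions on exact fits
  expect_equal(td$slope[td$parameter == "fz2"], -2, tolerance = 1e-10)
  expect_equal(td$slope[td$parameter == "fz3"], 0.5, tolerance = 1e-10)
  expect_equal(td$r_squared, c(1, 1), tolerance = 1e-10)
  expect_error(regress_normalized(sm[sm$grade == 0, ]), "grades")

  gl <- glance(fit)
  expect_equal(gl$n_parameters, 2)
  expect_equal(gl$n_grades, 9)
})

test_that("zero-variance responses report an R-squared of zero", {
  sm <- tibble::tibble(grade = seq(-20, 20, 5), parameter = "fz2",
                       mean = 100, pct_of_horizontal = 100)
  td <- suppressWarnings(tidy(regress_normalized(sm)))
  expect_equal(td$r_squared, 0)
  expect_true(is.na(td$p_value))
})

test_that("per-step trend ANOVA needs at least two grades", {
  p <- fake_params(runif(10), rep("A", 10), rep(0, 10))
  expect_error(anova_per_parameter(p), "grades")
})

test_that("permuted grade labels are rarely significant", {
  set.seed(77)
  hits <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    p <- fake_params(rnorm(90, 1, 0.1), rep(c("A", "B", "C"), 30),
                     sample(rep(seq(-20, 20, 5), each = 10)))
    td <- tidy(anova_per_parameter(p))
    hits <- hits + (td$p_value[td$parameter == "fmean_stance"] < 0.05)
  }
  expect_lt(hits / n_rep, 0.15)
})

test_that("autoplot produces a faceted ggplot", {
  fit <- grade_reference_summary() |> normalize_to_horizontal() |>
    regress_normalized()
  gg <- ggplot2::autoplot(fit)
  expect_s3_class(gg, "ggplot")
})
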