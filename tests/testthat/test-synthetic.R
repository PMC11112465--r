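test_that("session specification enforces its invariants", {
  expect_error(session_spec(dropout_prob = 0.5), "dropout_prob")
  expect_error(session_spec(dropout_prob = 0.05), "dropout_prob")
  expect_error(session_spec(stance_duration_range = c(200, 700)), "300")
  expect_error(session_spec(stance_duration_range = c(700, 2500)), "2000")
  expect_error(session_spec(n_participants = 0))
  expect_s3_class(session_spec(dropout_prob = 0), "session_spec")
})

test_that("generation is reproducible and refuses an empty grade list", {
  spec <- session_spec(n_participants = 2, steps_per_grade = 4, feet = "left",
                       seed = 99)
  s1 <- generate_session(spec, grades = c(-10, 10))
  s2 <- generate_session(spec, grades = c(-10, 10))
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$ground_truth, s2$ground_truth)
  expect_identical(s1$participants, s2$participants)
  expect_error(generate_session(spec, grades = numeric(0)), "non-empty")
  expect_error(generate_session(spec, grades = 3), "grade")
})

test_that("swing-phase samples always stay below the contact threshold", {
  spec <- session_spec(n_participants = 2, steps_per_grade = 8, feet = "left",
                       noise_sd = 0.02, seed = 5)
  s <- generate_session(spec, grades = c(-20, 20))
  sw <- s$samples
  tr <- s$ground_truth
  for (g in c(-20, 20)) {
    for (p in unique(sw$participant_id)) {
      sam <- sw[sw$grade == g & sw$participant_id == p, ]
      tru <- tr[tr$grade == g & tr$participant_id == p, ]
      in_stance <- rep(FALSE, nrow(sam))
      for (k in seq_len(nrow(tru))) {
        in_stance <- in_stance | (sam$timestamp_ms >= tru$start_ms[k] &
                                    sam$timestamp_ms <= tru$end_ms[k])
      }
      expect_true(all(sam$force_n[!in_stance] < 30))
    }
  }
})

test_that("noise-free generation yields exactly the requested stance count", {
  spec <- session_spec(n_participants = 1, steps_per_grade = 50,
                       feet = "left", noise_sd = 0, dropout_prob = 0,
                       seed = 21)
  s <- generate_session(spec, grades = c(-5, 5))
  ev <- detect_stances(s)
  counts <- table(ev$grade)
  expect_equal(unname(counts[["-5"]]), 50)
  expect_equal(unname(counts[["5"]]), 50)
  expect_equal(nrow(stance_exclusions(ev)), 0)
})

test_that("noise-free closed loop recovers every drawn parameter per step", {
  spec <- session_spec(n_participants = 2, steps_per_grade = 20,
                       feet = "left", noise_sd = 0, dropout_prob = 0,
                       seed = 31)
  s <- generate_session(spec, grades = c(-20, 0, 20))
  p <- extract_parameters(s)
  expect_equal(nrow(p), nrow(s$ground_truth)) # nothing rejected
  m <- merge(p, s$ground_truth,
             by = c("participant_id", "foot", "grade", "step_id"))
  for (nm in c("fz2", "fz3", "fz4")) {
    rel <- abs(m[[paste0(nm, ".x")]] - m[[paste0(nm, ".y")]]) /
      m[[paste0(nm, ".y")]]
    expect_lt(max(rel), 0.02)
  }
  for (nm in c("fmean_load", "fmean_mid", "fmean_unload")) {
    rel <- abs(m[[paste0(nm, ".x")]] - m[[paste0(nm, ".y")]]) /
      m[[paste0(nm, ".y")]]
    expect_lt(max(rel), 0.03)
  }
  # per-grade means agree within 2% for all parameters, slopes included
  for (g in c(-20, 0, 20)) {
    mg <- m[m$grade == g, ]
    for (nm in c("fz2", "fz3", "fz4", "fmean_load", "fmean_mid",
                 "fmean_unload", "loading_slope", "unloading_slope")) {
      rel <- abs(mean(mg[[paste0(nm, ".x")]]) - mean(mg[[paste0(nm, ".y")]])) /
        abs(mean(mg[[paste0(nm, ".y")]]))
      expect_lt(rel, 0.02)
    }
  }
})

test_that("noisy closed loop keeps extremum means within a standard error", {
  spec <- session_spec(n_participants = 4, steps_per_grade = 50,
                       feet = "left", noise_sd = 0.02, dropout_prob = 0,
                       seed = 41)
  s <- generate_session(spec, grades = 0)
  p <- extract_parameters(s)
  m <- merge(p, s$ground_truth,
             by = c("participant_id", "foot", "grade", "step_id"))
  gp <- default_grade_parameters()[5, ]
  n <- nrow(m)
  for (nm in c("fz2", "fz3", "fz4")) {
    bound <- gp[[paste0(nm, "_sd")]] / sqrt(n)
    expect_lt(abs(mean(m[[paste0(nm, ".x")]]) - mean(m[[paste0(nm, ".y")]])),
              bound)
  }
})

test_that("dropped samples are absent rows that the spline bridges", {
  spec <- session_spec(n_participants = 1, steps_per_grade = 20,
                       feet = "left", noise_sd = 0.01, dropout_prob = 0.01,
                       seed = 51)
  s <- generate_session(spec, grades = 0)
  dts <- diff(s$samples$timestamp_ms)
  expect_true(any(dts > 10)) # gaps exist
  expect_true(all(s$samples$timestamp_ms %% 10 == 0)) # grid positions only
  p <- extract_parameters(s)
  expect_gt(nrow(p), 0.9 * nrow(s$ground_truth))
})
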