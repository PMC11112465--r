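# A clean two-bump curve with known extremum locations.
m_curve <- function(i2 = 25, i3 = 50, i4 = 75) {
  x <- 0:99
  1 - 0.3 * cos(2 * pi * (x - i3) / (2 * (i4 - i3))) * exp(-((x - i3) / 60)^2)
}

test_that("candidate enumeration finds the strict local extrema", {
  tpl <- make_stance_template(1.2, 0.88, 1.16, loading_slope = 7.1,
                              unloading_slope = -7.3)
  v <- gaussian_smooth(tpl$f((0:99) / 99))
  cands <- find_extremum_candidates(v)
  expect_equal(sum(cands$polarity == "max"), 2)
  expect_equal(sum(cands$polarity == "min"), 1)

  expect_equal(nrow(find_extremum_candidates(seq(0, 1, length.out = 100))), 0)
  expect_equal(nrow(find_extremum_candidates(seq(1, 0, length.out = 100))), 0)
})

test_that("plateaus yield no strict candidate", {
  v <- c(seq(0, 1, length.out = 40), rep(1, 10), seq(1, 0, length.out = 50))
  cands <- find_extremum_candidates(v)
  expect_equal(nrow(cands), 0)
})

test_that("monotony distance counts strict runs and is capped by span and boundary", {
  # triangle peak at 0-based index 6 with 6 rising and 6 falling neighbours
  v <- c(seq(0, 6), seq(5, 0), rep(0.5, 3), 0.4, 0.5, rep(0, 82))
  cands <- find_extremum_candidates(v)
  peak <- cands[cands$index == 6, ]
  expect_equal(peak$monotony_distance, 5L) # capped at the span
  # a peak 2 steps from the boundary is capped at 2
  v2 <- c(0, 0.5, 1, seq(0.9, 0, length.out = 97))
  c2 <- find_extremum_candidates(v2)
  expect_equal(c2$monotony_distance[c2$index == 2], 2L)
})

test_that("pool filtering keeps the strongest candidate, earlier index on ties", {
  cands <- cand_tbl(c(40, 43, 60, 75), c("max", "max", "min", "max"),
                    c(1.18, 1.21, 0.8, 1.1), c(5, 5, 5, 5))
  out <- apply_candidate_cascade(cands)
  expect_setequal(out$index[out$polarity == "max"], c(43, 75))
  expect_true("pool_filtering" %in% attr(out, "strategies"))

  tie <- cand_tbl(c(40, 43, 60, 75), c("max", "max", "min", "max"),
                  c(1.21, 1.21, 0.8, 1.1), c(5, 5, 5, 5))
  out2 <- apply_candidate_cascade(tie)
  expect_setequal(out2$index[out2$polarity == "max"], c(40, 75))
})

test_that("time plausibility removes candidates in the first or last ten indices", {
  cands <- cand_tbl(c(5, 30, 55, 80, 95), c("max", "max", "min", "max", "max"),
                    c(2, 1.2, 0.8, 1.1, 2), rep(5, 5))
  out <- apply_candidate_cascade(cands)
  expect_setequal(out$index, c(30, 55, 80))
  expect_true("time_plausibility" %in% attr(out, "strategies"))
  # boundary cases: index 9 and 90 are eliminated, 10 and 89 survive
  edge <- cand_tbl(c(9, 10, 55, 89, 90), c("max", "max", "min", "max", "max"),
                   c(1, 1.2, 0.8, 1.1, 1), rep(5, 5))
  out2 <- apply_candidate_cascade(edge)
  expect_setequal(out2$index, c(10, 55, 89))
})

test_that("monotony check eliminates weak candidates and grace reinstates them", {
  # three maxima far apart: monotony 5, 3, 4 -> check leaves one, grace
  # brings back the distance-4 casualty to reach two maxima
  cands <- cand_tbl(c(25, 50, 60, 80), c("max", "min", "max", "max"),
                    c(1.2, 0.8, 1.0, 1.1), c(5, 5, 3, 4))
  out <- apply_candidate_cascade(cands)
  expect_setequal(out$index[out$polarity == "max"], c(25, 80))
  expect_true(all(c("monotony_check", "monotony_grace") %in%
                    attr(out, "strategies")))
  # grace tie on monotony distance prefers the earlier index
  tie <- cand_tbl(c(25, 50, 60, 80), c("max", "min", "max", "max"),
                  c(1.2, 0.8, 1.0, 1.1), c(5, 5, 4, 4))
  out2 <- apply_candidate_cascade(tie)
  expect_setequal(out2$index[out2$polarity == "max"], c(25, 60))
})

test_that("the cascade is skipped entirely for unambiguous candidates", {
  cands <- cand_tbl(c(25, 50, 75), c("max", "min", "max"),
                    c(1.2, 0.8, 1.1), c(1, 1, 1)) # weak monotony, but no need
  out <- apply_candidate_cascade(cands)
  expect_identical(attr(out, "strategies"), character(0))
  expect_equal(out$index, c(25, 50, 75))
})

test_that("finalize accepts 2 maxima + 1 minimum in order and re-reads raw values", {
  normalized <- seq(0.5, 1.5, length.out = 100)
  cands <- cand_tbl(c(25, 52, 76), c("max", "min", "max"),
                    c(1.2, 0.8, 1.1), rep(5, 3))
  out <- finalize_extrema(cands, normalized)
  expect_equal(out$status, "accepted")
  expect_equal(out$fz2_idx, 25L)
  expect_equal(out$fz4_idx, 76L)
  expect_equal(out$fz2, normalized[26]) # unfiltered value at the index
  expect_equal(out$fz3, normalized[53])

  too_many <- cand_tbl(c(20, 40, 52, 76), c("max", "max", "min", "max"),
                       c(1, 1, 0.8, 1), rep(5, 4))
  expect_equal(finalize_extrema(too_many, normalized)$reject_reason,
               "candidate_count")

  misordered <- cand_tbl(c(25, 40, 70), c("max", "max", "min"),
                         c(1.2, 1.1, 0.8), rep(5, 3))
  expect_equal(finalize_extrema(misordered, normalized)$reject_reason,
               "ordering")
  expect_equal(finalize_extrema(misordered, normalized,
                                require_ordering = FALSE)$status, "accepted")
})

test_that("cascade and finalization are deterministic", {
  set.seed(3)
  v <- gaussian_smooth(m_curve() + rnorm(100, 0, 0.05))
  c1 <- apply_candidate_cascade(find_extremum_candidates(v))
  c2 <- apply_candidate_cascade(find_extremum_candidates(v))
  expect_identical(c1, c2)
})

test_that("noise-free synthetic curves need no cascade and hit the anchors", {
  spec <- session_spec(n_participants = 1, steps_per_grade = 20,
                       feet = "left", noise_sd = 0, dropout_prob = 0,
                       seed = 61)
  s <- generate_session(spec, grades = 0)
  ev <- detect_stances(s)
  cur <- normalize_stances(ev, s$participants)
  ex <- locate_extrema(cur)
  expect_true(all(ex$status == "accepted"))
  expect_true(all(ex$cascade_strategies == ""))
  m <- merge(ex, s$ground_truth,
             by = c("participant_id", "foot", "grade", "step_id"))
  expect_true(all(abs(m$fz2_idx - round(99 * m$t_fz2.y)) <= 2))
  expect_true(all(abs(m$fz4_idx - round(99 * m$t_fz4.y)) <= 4))
})

test_that("rejection rate stays moderate under realistic sensor noise", {
  spec <- session_spec(n_participants = 3, steps_per_grade = 20,
                       feet = "left", noise_sd = 0.02, dropout_prob = 0,
                       seed = 71)
  s <- generate_session(spec, grades = c(-20, 0, 20))
  ev <- detect_stances(s)
  ex <- locate_extrema(normalize_stances(ev, s$participants))
  expect_lt(mean(ex$status == "rejected"), 0.20)
})
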