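# Independent oracles used by unit and acceptance tests. These deliberately
# re-derive results with different algorithms than the package.

# Brute-force run segmentation: scan a boolean mask, growing an event while
# the run of consecutive FALSE entries stays within the tolerance. Returns a
# matrix of 1-based (start, end) mask positions, both on TRUE entries.
oracle_detect_runs <- function(above, gap_tol = 3) {
  runs <- NULL
  start <- NA_integer_
  last_true <- NA_integer_
  gap <- 0L
  for (i in seq_along(above)) {
    if (above[i]) {
      if (is.na(start)) start <- i
      last_true <- i
      gap <- 0L
    } else if (!is.na(start)) {
      gap <- gap + 1L
      if (gap > gap_tol) {
        runs <- rbind(runs, c(start, last_true))
        start <- NA_integer_
        gap <- 0L
      }
    }
  }
  if (!is.na(start)) runs <- rbind(runs, c(start, last_true))
  runs
}

# Textbook natural cubic spline: solve the tridiagonal second-derivative
# system directly, then evaluate the piecewise cubic.
oracle_natural_spline <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  A[1, 1] <- 1
  A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    rhs[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  m <- solve(A, rhs) # second derivatives at the knots
  vapply(xout, function(xx) {
    i <- max(1, min(n - 1, findInterval(xx, x)))
    a <- (x[i + 1] - xx) / h[i]
    b <- (xx - x[i]) / h[i]
    a * y[i] + b * y[i + 1] +
      ((a^3 - a) * m[i] + (b^3 - b) * m[i + 1]) * h[i]^2 / 6
  }, numeric(1))
}

# Wrap a single force series into the samples-table contract.
as_samples_tbl <- function(timestamp_ms, force_n, participant_id = "P001",
                           foot = "left", grade = 0) {
  tibble::tibble(participant_id = participant_id, foot = foot, grade = grade,
                 timestamp_ms = as.integer(timestamp_ms), force_n = force_n)
}

participants_tbl <- function(id = "P001", weight = 80) {
  tibble::tibble(participant_id = id, body_weight_kg = weight)
}

# Candidate tibble shorthand for cascade fixtures.
cand_tbl <- function(index, polarity, value, mono) {
  tibble::tibble(index = as.integer(index), polarity = polarity,
                 value = value, monotony_distance = as.integer(mono))
}
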