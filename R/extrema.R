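# Extremum localization on the smoothed curve, value re-reading on the raw
# normalized curve, and the deterministic disambiguation cascade.
#
# Hot-path note: candidate sets are tiny (usually 3 entries) but are built
# for every stance of a session, so the internal representation is a plain
# list of parallel vectors; the exported functions wrap it in a tibble.

candidates_core <- function(f, span = 5) {
  n <- length(f)
  if (n < 3) {
    return(list(index = integer(0), polarity = character(0),
                value = numeric(0), monotony_distance = integer(0)))
  }
  left <- f[1:(n - 2)]; mid <- f[2:(n - 1)]; right <- f[3:n]
  is_max <- mid > left & mid > right
  is_min <- mid < left & mid < right
  idx0 <- c(which(is_max), which(is_min)) # 0-based candidate index
  pol <- c(rep("max", sum(is_max)), rep("min", sum(is_min)))
  ord <- order(idx0)
  idx0 <- idx0[ord]; pol <- pol[ord]
  mono <- integer(length(idx0))
  for (k in seq_along(idx0)) {
    i <- idx0[k] + 1L # 1-based position in f
    s <- if (pol[k] == "max") 1 else -1
    dl <- 0L
    while (dl < span && i - dl - 1L >= 1L &&
           s * f[i - dl - 1L] < s * f[i - dl]) dl <- dl + 1L
    dr <- 0L
    while (dr < span && i + dr + 1L <= n &&
           s * f[i + dr + 1L] < s * f[i + dr]) dr <- dr + 1L
    mono[k] <- min(dl, dr)
  }
  list(index = idx0, polarity = pol, value = f[idx0 + 1L],
       monotony_distance = mono)
}

cc_subset <- function(cc, keep) {
  list(index = cc$index[keep], polarity = cc$polarity[keep],
       value = cc$value[keep], monotony_distance = cc$monotony_distance[keep])
}

n_of <- function(cc, pol) sum(cc$polarity == pol)
is_unambiguous <- function(cc) {
  n_of(cc, "max") == 2L && n_of(cc, "min") == 1L
}

# single-linkage chaining of same-polarity candidates with gaps <= pool_gap;
# keep the extreme-value candidate per pool, ties broken by earlier index
pool_core <- function(cc, pool_gap) {
  keep <- logical(length(cc$index))
  for (pol in c("max", "min")) {
    rows <- which(cc$polarity == pol) # already index-ordered
    if (length(rows) == 0) next
    pool <- cumsum(c(1L, as.integer(diff(cc$index[rows]) > pool_gap)))
    for (pl in unique(pool)) {
      prows <- rows[pool == pl]
      vals <- cc$value[prows]
      best <- if (pol == "max") which.max(vals) else which.min(vals)
      keep[prows[best]] <- TRUE # which.max/min take the earlier index on ties
    }
  }
  cc_subset(cc, keep)
}

cascade_core <- function(cc, edge_margin = 10, pool_gap = 5,
                         monotony_span = 5, n_index = 100) {
  applied <- character(0)
  if (!is_unambiguous(cc)) {
    applied <- c(applied, "time_plausibility")
    cc <- cc_subset(cc, cc$index >= edge_margin &
                      cc$index <= (n_index - 1L - edge_margin))
  }
  if (!is_unambiguous(cc)) {
    applied <- c(applied, "pool_filtering")
    cc <- pool_core(cc, pool_gap)
  }
  casualties <- cc_subset(cc, FALSE)
  if (!is_unambiguous(cc)) {
    applied <- c(applied, "monotony_check")
    ok <- cc$monotony_distance >= monotony_span
    casualties <- cc_subset(cc, !ok)
    cc <- cc_subset(cc, ok)
  }
  if (n_of(cc, "max") < 2L || n_of(cc, "min") < 1L) {
    applied <- c(applied, "monotony_grace")
    for (pol in c("max", "min")) {
      target <- if (pol == "max") 2L else 1L
      need <- target - n_of(cc, pol)
      if (need <= 0) next
      pool <- which(casualties$polarity == pol)
      pool <- pool[order(-casualties$monotony_distance[pool],
                         casualties$index[pool])]
      take <- utils::head(pool, need)
      if (length(take)) {
        back <- cc_subset(casualties, take)
        cc <- list(index = c(cc$index, back$index),
                   polarity = c(cc$polarity, back$polarity),
                   value = c(cc$value, back$value),
                   monotony_distance = c(cc$monotony_distance,
                                         back$monotony_distance))
      }
    }
  }
  ord <- order(cc$index)
  cc <- cc_subset(cc, ord)
  attr(cc, "strategies") <- applied
  cc
}

finalize_core <- function(cc, normalized, require_ordering = TRUE) {
  na_row <- function(reason) list(
    status = "rejected", reject_reason = reason,
    fz2_idx = NA_integer_, fz3_idx = NA_integer_, fz4_idx = NA_integer_,
    fz2 = NA_real_, fz3 = NA_real_, fz4 = NA_real_)
  if (!is_unambiguous(cc)) return(na_row("candidate_count"))
  maxima <- sort(cc$index[cc$polarity == "max"])
  minimum <- cc$index[cc$polarity == "min"]
  if (require_ordering && !(maxima[1] < minimum && minimum < maxima[2])) {
    return(na_row("ordering"))
  }
  list(
    status = "accepted", reject_reason = NA_character_,
    fz2_idx = as.integer(maxima[1]), fz3_idx = as.integer(minimum),
    fz4_idx = as.integer(maxima[2]),
    fz2 = normalized[maxima[1] + 1L], fz3 = normalized[minimum + 1L],
    fz4 = normalized[maxima[2] + 1L])
}

#' Enumerate strict local extremum candidates
#'
#' A 0-based index `i` in `[1, n-2]` is a maximum candidate iff
#' `f[i] > f[i-1]` and `f[i] > f[i+1]`, and a minimum candidate with the
#' inequalities reversed. Plateaus (equal neighbours) yield no candidate.
#' Each candidate carries its monotony distance: the largest `d <= span`
#' such that the curve is strictly monotone away from the candidate over
#' both `i-d..i` and `i..i+d` (falling on both flanks of a maximum, rising
#' for a minimum); runs truncated by the curve boundary cap the distance at
#' the available length.
#'
#' @param f Numeric vector, typically a smoothed normalized curve.
#' @param span Maximum monotony distance tracked.
#' @return Tibble with columns `index` (0-based), `polarity` (`"max"` /
#'   `"min"`), `value` (of `f`), `monotony_distance`.
#' @export
#' @examples
#' f <- gaussian_smooth(sin(seq(0, 3 * pi, length.out = 100)) + 1)
#' find_extremum_candidates(f)
find_extremum_candidates <- function(f, span = 5) {
  tibble::as_tibble(candidates_core(f, span))
}

#' Disambiguate extremum candidates
#'
#' Applies up to four strategies, in order, each only while the candidate
#' set is still ambiguous (not exactly two maxima and one minimum):
#'
#' 1. *Time plausibility*: candidates within the first or last
#'    `edge_margin` indices (first/last 10% of the stance) are eliminated.
#' 2. *Pool filtering*: same-polarity candidates chained by pairwise index
#'    gaps of at most `pool_gap` form a pool; only the highest-force
#'    maximum / lowest-force minimum of each pool survives (ties broken by
#'    the earlier index).
#' 3. *Monotony check*: candidates whose monotony distance is below
#'    `monotony_span` are eliminated.
#' 4. *Monotony grace*: if the check left fewer than two maxima or fewer
#'    than one minimum, its casualties are reinstated in descending order of
#'    monotony distance (ties: earlier index) until the target counts are
#'    reached.
#'
#' The cascade is fully deterministic and is a no-op when the initial
#' candidate set is already unambiguous.
#'
#' @param cands Candidates from [find_extremum_candidates()].
#' @param edge_margin,pool_gap,monotony_span Strategy constants.
#' @param n_index Curve length the indices refer to.
#' @return The surviving candidates, ordered by index, with the applied
#'   strategy names in the `"strategies"` attribute.
#' @export
apply_candidate_cascade <- function(cands, edge_margin = 10, pool_gap = 5,
                                    monotony_span = 5, n_index = 100) {
  cc <- cascade_core(as.list(cands), edge_margin = edge_margin,
                     pool_gap = pool_gap, monotony_span = monotony_span,
                     n_index = n_index)
  out <- tibble::as_tibble(cc[c("index", "polarity", "value",
                                "monotony_distance")])
  attr(out, "strategies") <- attr(cc, "strategies")
  out
}

#' Accept or reject a stance from its surviving candidates
#'
#' A stance is accepted iff exactly two maximum candidates and one minimum
#' candidate survive the cascade and (optionally) the minimum lies strictly
#' between the two maxima. Fz2 is the earlier maximum, Fz4 the later one;
#' their values are re-read from the unfiltered normalized curve at the
#' surviving indices, so the reported forces stay close to the raw signal.
#'
#' @param cands Surviving candidates from [apply_candidate_cascade()].
#' @param normalized The unfiltered normalized curve (length 100).
#' @param require_ordering Reject stances whose minimum does not lie between
#'   the maxima (reason `"ordering"`). The ordering requirement is a
#'   documented convention; disable to accept any 2-max/1-min combination.
#' @return One-row tibble: `status` (`"accepted"`/`"rejected"`),
#'   `reject_reason` (`NA`, `"candidate_count"` or `"ordering"`),
#'   `fz2_idx`, `fz3_idx`, `fz4_idx` (0-based indices) and `fz2`, `fz3`,
#'   `fz4` (body-weight fractions from the unfiltered curve).
#' @export
finalize_extrema <- function(cands, normalized, require_ordering = TRUE) {
  tibble::as_tibble(finalize_core(as.list(cands), normalized,
                                  require_ordering))
}

#' Locate the M-curve extrema for every normalized stance
#'
#' Runs the candidate detection on each smoothed curve, the disambiguation
#' cascade where needed, and the final acceptance check against the
#' unfiltered curve.
#'
#' @param curves Result of [normalize_stances()].
#' @param edge_margin,pool_gap,monotony_span Cascade constants, see
#'   [apply_candidate_cascade()].
#' @param require_ordering See [finalize_extrema()].
#' @return `curves` with the columns of [finalize_extrema()] plus
#'   `cascade_strategies` (comma-separated strategies applied; empty when
#'   the candidates were unambiguous from the start).
#' @export
locate_extrema <- function(curves, edge_margin = 10, pool_gap = 5,
                           monotony_span = 5, require_ordering = TRUE) {
  n <- nrow(curves)
  status <- character(n); reason <- rep(NA_character_, n)
  strategies <- character(n)
  ids <- matrix(NA_integer_, n, 3)
  vals <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    filt <- curves$filtered[[i]]
    cc <- candidates_core(filt, span = monotony_span)
    cc <- cascade_core(cc, edge_margin = edge_margin, pool_gap = pool_gap,
                       monotony_span = monotony_span, n_index = length(filt))
    fin <- finalize_core(cc, curves$curve[[i]],
                         require_ordering = require_ordering)
    status[i] <- fin$status; reason[i] <- fin$reject_reason
    ids[i, ] <- c(fin$fz2_idx, fin$fz3_idx, fin$fz4_idx)
    vals[i, ] <- c(fin$fz2, fin$fz3, fin$fz4)
    strategies[i] <- paste(attr(cc, "strategies"), collapse = ",")
  }
  dplyr::bind_cols(curves, tibble::tibble(
    status = status, reject_reason = reason,
    fz2_idx = ids[, 1], fz3_idx = ids[, 2], fz4_idx = ids[, 3],
    fz2 = vals[, 1], fz3 = vals[, 2], fz4 = vals[, 3],
    cascade_strategies = strategies))
}
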