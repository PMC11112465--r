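#' Segment stance events from raw force series
#'
#' Identifies stance phases as maximal runs of samples with force strictly
#' above the contact threshold (default 30 N) on the nominal sampling grid.
#' Runs of up to `gap_tolerance` consecutive missing or sub-threshold samples
#' inside an event are tolerated (bridged); a longer run terminates the
#' event. Candidates are trimmed to start and end on an above-threshold
#' sample and then filtered by duration: events shorter than
#' `min_duration_ms` or longer than `max_duration_ms` (first to last sample,
#' bounds inclusive) are discarded and logged.
#'
#' @param x An `insole_session` or a samples tibble with columns
#'   `participant_id`, `foot`, `grade`, `timestamp_ms`, `force_n`.
#' @param threshold_n Contact threshold in Newtons; "above" is strict, a
#'   reading exactly at the threshold counts as below.
#' @param gap_tolerance Maximum tolerated run of missing/sub-threshold
#'   samples inside an event.
#' @param min_duration_ms,max_duration_ms Inclusive admissible duration band.
#' @param nominal_rate_hz Nominal sampling rate used to place samples on a
#'   regular grid when counting missing samples.
#'
#' @return A tibble with one row per retained stance event: identifiers,
#'   `step_id`, `start_ms`, `end_ms`, `duration_ms`, `n_samples` and a
#'   `samples` list-column of `(timestamp_ms, force_n)` tibbles (tolerated
#'   sub-threshold samples retained, missing ones absent). Discarded
#'   candidates are attached as a tibble in the `"exclusions"` attribute,
#'   see [stance_exclusions()].
#' @export
#' @examples
#' s <- generate_session(session_spec(n_participants = 1, steps_per_grade = 3,
#'                                    feet = "left", seed = 1), grades = 0)
#' ev <- detect_stances(s)
#' ev[, c("step_id", "start_ms", "duration_ms", "n_samples")]
detect_stances <- function(x,
                           threshold_n = 30,
                           gap_tolerance = 3,
                           min_duration_ms = 300,
                           max_duration_ms = 2000,
                           nominal_rate_hz = 100) {
  samples <- if (inherits(x, "insole_session")) x$samples else x
  req <- c("participant_id", "foot", "grade", "timestamp_ms", "force_n")
  if (!all(req %in% names(samples))) {
    stop("samples must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(samples) == 0) {
    empty <- empty_events()
    attr(empty, "exclusions") <- empty_exclusions()
    return(empty)
  }
  dt <- 1000 / nominal_rate_hz
  groups <- samples |>
    dplyr::group_by(.data$participant_id, .data$foot, .data$grade) |>
    dplyr::group_split()
  ev_list <- list(); ex_list <- list()
  for (gdat in groups) {
    res <- detect_series(gdat$timestamp_ms, gdat$force_n, dt, threshold_n,
                         gap_tolerance, min_duration_ms, max_duration_ms)
    key <- gdat[1, c("participant_id", "foot", "grade")]
    if (nrow(res$events) > 0) {
      ev_list[[length(ev_list) + 1L]] <-
        dplyr::bind_cols(key[rep(1, nrow(res$events)), ], res$events)
    }
    if (nrow(res$exclusions) > 0) {
      ex_list[[length(ex_list) + 1L]] <-
        dplyr::bind_cols(key[rep(1, nrow(res$exclusions)), ], res$exclusions)
    }
  }
  events <- if (length(ev_list)) dplyr::bind_rows(ev_list) else empty_events()
  attr(events, "exclusions") <-
    if (length(ex_list)) dplyr::bind_rows(ex_list) else empty_exclusions()
  class(events) <- c("stance_events", class(events))
  events
}

#' Exclusion log of a stance-event table
#'
#' @param events The result of [detect_stances()].
#' @return Tibble of discarded stance candidates with their bounds, duration
#'   and reason (`too_short` or `too_long`).
#' @export
stance_exclusions <- function(events) {
  ex <- attr(events, "exclusions")
  if (is.null(ex)) empty_exclusions() else ex
}

empty_events <- function() {
  tibble::tibble(participant_id = character(), foot = character(),
                 grade = numeric(), step_id = integer(),
                 start_ms = numeric(), end_ms = numeric(),
                 duration_ms = numeric(), n_samples = integer(),
                 samples = list())
}

empty_exclusions <- function() {
  tibble::tibble(participant_id = character(), foot = character(),
                 grade = numeric(), start_ms = numeric(), end_ms = numeric(),
                 duration_ms = numeric(), reason = character())
}

# Core run-length segmentation of one series on the nominal sample grid.
detect_series <- function(ts, force, dt, threshold, gap_tol, min_dur, max_dur) {
  ord <- order(ts)
  ts <- ts[ord]; force <- force[ord]
  slot <- as.integer(round((ts - ts[1]) / dt))
  n_slot <- slot[length(slot)] + 1L
  above <- rep(FALSE, n_slot)          # absent slots stay FALSE
  above[slot + 1L] <- force > threshold

  r <- rle(above)
  nr <- length(r$values)
  if (nr > 1) {
    bridge <- !r$values & r$lengths <= gap_tol &
      seq_len(nr) != 1L & seq_len(nr) != nr
    r$values[bridge] <- TRUE
  }
  mask <- inverse.rle(r)
  r2 <- rle(mask)
  ends_slot <- cumsum(r2$lengths)
  starts_slot <- ends_slot - r2$lengths + 1L

  cand <- which(r2$values)
  sample_slot <- slot + 1L # sorted; binary-searchable
  # candidates span slots [a, b]; endpoints are above-threshold by
  # construction (only interior gaps were bridged)
  lo <- findInterval(starts_slot[cand] - 0.5, sample_slot) + 1L
  hi <- findInterval(ends_slot[cand] + 0.5, sample_slot)
  t0 <- ts[lo]; t1 <- ts[hi]
  dur <- t1 - t0
  keep <- dur >= min_dur & dur <= max_dur
  ev_lo <- lo[keep]; ev_hi <- hi[keep]
  events <- tibble::tibble(
    step_id = seq_len(sum(keep)),
    start_ms = t0[keep], end_ms = t1[keep], duration_ms = dur[keep],
    n_samples = ev_hi - ev_lo + 1L,
    samples = purrr::map2(ev_lo, ev_hi, function(a, b) {
      tibble::new_tibble(list(timestamp_ms = ts[a:b], force_n = force[a:b]),
                         nrow = b - a + 1L)
    }))
  exclusions <- tibble::tibble(
    start_ms = t0[!keep], end_ms = t1[!keep], duration_ms = dur[!keep],
    reason = ifelse(dur[!keep] < min_dur, "too_short", "too_long"))
  list(events = events, exclusions = exclusions)
}
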