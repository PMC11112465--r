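#' Time- and body-weight-normalize one stance event
#'
#' Fits a natural cubic spline (zero second derivative at both ends) to the
#' event's raw `(timestamp, force)` samples after scaling force to a
#' fraction of body weight, and evaluates it at 100 equidistant times
#' spanning the event inclusively -- one interpolated sample per percent of
#' stance duration. Sample index `j` (0-based) corresponds to stance
#' fraction `j/99`. Spline undershoots are clamped at zero.
#'
#' The spline is fitted to the true timestamps, so non-uniform spacing from
#' dropped samples is bridged naturally; tolerated sub-threshold samples
#' inside the event act as ordinary knots.
#'
#' @param timestamp_ms,force_n Raw samples of one stance event.
#' @param body_weight_kg Participant body weight; the normalization constant
#'   is `body_weight_kg * 9.81` Newtons.
#' @param n_out Number of equidistant output samples.
#' @return Numeric vector of length `n_out` (body-weight fractions), or
#'   `NULL` when fewer than 4 samples are available (a cubic spline is not
#'   defined; the event is rejected, not an error).
#' @export
#' @examples
#' normalize_curve(seq(0, 500, 10), rep(400, 51), body_weight_kg = 81.55)[1:5]
normalize_curve <- function(timestamp_ms, force_n, body_weight_kg,
                            n_out = 100) {
  if (length(timestamp_ms) < 4) return(NULL)
  y <- force_n / (body_weight_kg * GRAVITY)
  xout <- seq(timestamp_ms[1], timestamp_ms[length(timestamp_ms)],
              length.out = n_out)
  s <- stats::spline(timestamp_ms, y, xout = xout, method = "natural")
  pmax(s$y, 0)
}

#' Gaussian-smooth a normalized curve
#'
#' Discrete convolution with a sampled Gaussian kernel (`sigma = 3`, kernel
#' size 7 by default), weights proportional to `exp(-k^2 / (2 sigma^2))` for
#' `k` in `-3..3` and normalized to sum 1. At the curve boundaries the
#' kernel is truncated to valid indices and renormalized, so constants are
#' preserved everywhere. The smoothed copy is used only to localize
#' extremum candidates; parameter values are always read from the
#' unsmoothed curve.
#'
#' @param x Numeric vector (a normalized stance curve).
#' @param sigma Gaussian standard deviation in index units.
#' @param size Odd kernel size.
#' @return Numeric vector, same length as `x`.
#' @export
#' @examples
#' gaussian_smooth(c(rep(0, 5), 1, rep(0, 5)))[6] # central weight
gaussian_smooth <- function(x, sigma = 3, size = 7) {
  stopifnot(size %% 2 == 1, sigma > 0)
  half <- (size - 1) / 2
  n <- length(x)
  w <- exp(-((-half):half)^2 / (2 * sigma^2))
  w <- w / sum(w)
  if (n <= size) {
    return(vapply(seq_len(n), function(i) {
      k <- max(1, i - half):min(n, i + half)
      wk <- w[k - i + half + 1]
      sum(x[k] * wk) / sum(wk)
    }, numeric(1)))
  }
  out <- as.numeric(stats::filter(x, w, sides = 2))
  for (i in seq_len(half)) {
    kl <- 1:(i + half)
    wl <- w[(half + 2 - i):size]
    out[i] <- sum(x[kl] * wl) / sum(wl)
    kr <- (n - i - half + 1):n
    wr <- w[1:(size - half + i - 1)]
    out[n - i + 1] <- sum(x[kr] * wr) / sum(wr)
  }
  out
}

#' Normalize all stance events of a session
#'
#' Applies [normalize_curve()] to every detected stance event and attaches
#' the Gaussian-smoothed copy used for extremum localization. Events with
#' fewer than 4 samples are dropped and logged in the `"rejections"`
#' attribute.
#'
#' @param events Stance events from [detect_stances()].
#' @param participants Tibble with `participant_id` and `body_weight_kg`.
#' @param filter_sigma,filter_size Gaussian filter settings, see
#'   [gaussian_smooth()].
#' @return The events tibble with list-columns `curve` (100 body-weight
#'   fraction samples) and `filtered` (smoothed copy), `body_weight_kg`, and
#'   without the raw `samples` column.
#' @export
normalize_stances <- function(events, participants,
                              filter_sigma = 3, filter_size = 7) {
  stopifnot(all(c("participant_id", "body_weight_kg") %in% names(participants)))
  if (any(is.na(participants$body_weight_kg)) ||
      any(participants$body_weight_kg <= 0)) {
    stop("all participants need a positive body weight", call. = FALSE)
  }
  missing <- setdiff(unique(events$participant_id),
                     participants$participant_id)
  if (length(missing)) {
    stop("no body weight for participant(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::left_join(
    events, participants[, c("participant_id", "body_weight_kg")],
    by = "participant_id")
  curves <- purrr::map2(out$samples, out$body_weight_kg,
                        ~ normalize_curve(.x$timestamp_ms, .x$force_n, .y))
  ok <- !purrr::map_lgl(curves, is.null)
  rejections <- out[!ok, c("participant_id", "foot", "grade", "step_id",
                           "start_ms", "end_ms")]
  rejections$reason <- if (nrow(rejections)) "too_few_samples" else character(0)
  out <- out[ok, ]
  out$curve <- curves[ok]
  out$filtered <- purrr::map(out$curve, gaussian_smooth,
                             sigma = filter_sigma, size = filter_size)
  out$samples <- NULL
  attr(out, "rejections") <- rejections
  class(out) <- c("stance_curves", setdiff(class(out), "stance_events"))
  out
}
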