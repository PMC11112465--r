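# The nine scalar stance-curve parameters of one accepted stance.

#' Window means of a normalized stance curve
#'
#' `fmean_stance` is the mean of all 100 samples; `fmean_load` the mean from
#' the start of loading to Fz2, `fmean_mid` from Fz2 to Fz4, `fmean_unload`
#' from Fz4 to the end of the stance. All windows are inclusive of both
#' endpoint indices.
#'
#' @param curve Normalized curve (length 100, body-weight fractions).
#' @param fz2_idx,fz4_idx 0-based indices of the two maxima.
#' @return Named list with the four means.
#' @export
#' @examples
#' stance_window_means(rep(1, 100), 25, 75)
stance_window_means <- function(curve, fz2_idx, fz4_idx) {
  n <- length(curve)
  list(
    fmean_stance = mean(curve),
    fmean_load   = mean(curve[1:(fz2_idx + 1L)]),
    fmean_mid    = mean(curve[(fz2_idx + 1L):(fz4_idx + 1L)]),
    fmean_unload = mean(curve[(fz4_idx + 1L):n])
  )
}

#' Loading slope of a normalized stance curve
#'
#' Slope of the line from the start of the loading phase (index 0) to the
#' first sample with force at or above `crossing_fraction` (default 80%) of
#' Fz2, in percent body weight per percent stance duration (force enters
#' the slope scaled by 100). Undefined -- and returned as `NA` with a flag
#' downstream -- when the very first sample already reaches the crossing
#' level.
#'
#' @param curve Normalized curve.
#' @param fz2 First-maximum value (body-weight fraction).
#' @param crossing_fraction Crossing level as a fraction of Fz2.
#' @return Slope, or `NA_real_` when undefined.
#' @export
#' @examples
#' stance_loading_slope(c(seq(0, 1.2, length.out = 21), rep(1, 79)), fz2 = 1.2)
stance_loading_slope <- function(curve, fz2, crossing_fraction = 0.8) {
  i80 <- which(curve >= crossing_fraction * fz2)[1] - 1L # 0-based
  if (is.na(i80) || i80 == 0L) return(NA_real_)
  (curve[i80 + 1L] - curve[1L]) * 100 / i80
}

#' Unloading slope of a normalized stance curve
#'
#' Slope of the line from the first sample after Fz4 with force below
#' `crossing_fraction` of Fz4 to the end of the stance (index 99), in
#' percent body weight per percent stance duration. Undefined when no such
#' sample exists or when the crossing happens only at the final sample.
#'
#' @param curve Normalized curve.
#' @param fz4 Second-maximum value.
#' @param fz4_idx 0-based index of Fz4.
#' @param crossing_fraction Crossing level as a fraction of Fz4.
#' @return Slope (negative for physiological curves), or `NA_real_`.
#' @export
stance_unloading_slope <- function(curve, fz4, fz4_idx,
                                   crossing_fraction = 0.8) {
  n <- length(curve)
  tail_idx <- which(curve < crossing_fraction * fz4)
  tail_idx <- tail_idx[tail_idx > fz4_idx + 1L] # 1-based, strictly after fz4
  iu <- tail_idx[1] - 1L # 0-based
  if (is.na(iu) || iu >= n - 1L) return(NA_real_)
  (curve[n] - curve[iu + 1L]) * 100 / (n - 1L - iu)
}

#' Compute the nine stance-curve parameters per accepted stance
#'
#' For every stance accepted by [locate_extrema()] this computes, from the
#' unfiltered normalized curve: the three extremum forces (Fz2, Fz3, Fz4),
#' the four window means and the loading/unloading slopes. Stances with an
#' undefined slope keep their remaining parameters; the undefined slope is
#' `NA` and the stance is listed in the `"flags"` attribute.
#'
#' @param extrema Result of [locate_extrema()].
#' @param crossing_fraction Crossing level for the slope definitions.
#' @return Tibble with identifiers, `duration_ms` and the nine parameters;
#'   rejected stances are omitted. Attribute `"flags"` lists stances with
#'   undefined slopes.
#' @export
compute_stance_parameters <- function(extrema, crossing_fraction = 0.8) {
  acc <- extrema[extrema$status == "accepted", ]
  n <- nrow(acc)
  pm <- matrix(NA_real_, n, 6)
  for (i in seq_len(n)) {
    curve <- acc$curve[[i]]
    wm <- stance_window_means(curve, acc$fz2_idx[i], acc$fz4_idx[i])
    pm[i, ] <- c(wm$fmean_stance, wm$fmean_load, wm$fmean_mid,
                 wm$fmean_unload,
                 stance_loading_slope(curve, acc$fz2[i], crossing_fraction),
                 stance_unloading_slope(curve, acc$fz4[i], acc$fz4_idx[i],
                                        crossing_fraction))
  }
  out <- dplyr::bind_cols(
    acc[, c("participant_id", "foot", "grade", "step_id", "duration_ms",
            "fz2", "fz3", "fz4")],
    tibble::tibble(
      fmean_stance = pm[, 1], fmean_load = pm[, 2], fmean_mid = pm[, 3],
      fmean_unload = pm[, 4], loading_slope = pm[, 5],
      unloading_slope = pm[, 6]))
  bad <- is.na(out$loading_slope) | is.na(out$unloading_slope)
  flags <- out[bad, c("participant_id", "foot", "grade", "step_id")]
  flags$flag <- vapply(which(bad), function(i) {
    paste(c("loading_undefined", "unloading_undefined")[
      c(is.na(out$loading_slope[i]), is.na(out$unloading_slope[i]))],
      collapse = ";")
  }, character(1))
  attr(out, "flags") <- flags
  out
}
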