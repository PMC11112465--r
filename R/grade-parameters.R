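#' Per-grade stance-curve parameter targets
#'
#' Reference means and standard deviations of the nine stance-curve
#' parameters for treadmill grades from -20% to +20% in 5% steps, as
#' established for healthy adults walking at 4 km/h. Forces are fractions of
#' body weight (1.0 = body weight); slopes are percent body weight per
#' percent stance duration. These values parameterize the synthetic-gait
#' generator and serve as the reference series for the trend statistics.
#'
#' The three `t_fz*` columns are the nominal positions of the first maximum
#' (Fz2), midstance minimum (Fz3) and second maximum (Fz4) as fractions of
#' stance duration. Extremum timing is not part of the reference tables, so
#' these are package conventions around the canonical M-curve: the first
#' peak near 25% and the valley at 54% of stance, the second peak at
#' 79--83%. Within the narrow admissible bands the per-grade values are set
#' so that the whole-stance mean implied by the window means, extrema and
#' timings reproduces the flat grade profile of the reference table's
#' `fmean_stance` row; the second peak sits late because the 80%-of-Fz4
#' unloading crossing implied by the slope table lies near 88% of stance
#' and the fall from the peak must fit before it. The generator jitters all
#' three positions per step.
#'
#' @return A tibble with one row per grade and columns `grade`,
#'   `<parameter>_mean` / `<parameter>_sd` for the nine parameters, and
#'   `t_fz2`, `t_fz3`, `t_fz4`.
#' @seealso [grade_reference_summary()] for the same means in long format,
#'   [generate_session()].
#' @export
#' @examples
#' default_grade_parameters()[, c("grade", "fz2_mean", "fz3_mean", "fz4_mean")]
default_grade_parameters <- function() {
  out <- tibble::tibble(
    grade = seq(-20, 20, by = 5),
    fmean_stance_mean = c(0.88, 0.90, 0.90, 0.91, 0.90, 0.90, 0.90, 0.89, 0.89),
    fmean_stance_sd   = c(0.21, 0.21, 0.21, 0.21, 0.21, 0.21, 0.21, 0.20, 0.20),
    fmean_load_mean   = c(1.06, 1.04, 0.98, 0.91, 0.86, 0.81, 0.80, 0.78, 0.77),
    fmean_load_sd     = c(0.30, 0.28, 0.26, 0.23, 0.21, 0.20, 0.20, 0.19, 0.18),
    fmean_mid_mean    = c(0.97, 0.99, 0.99, 1.01, 1.03, 1.04, 1.03, 1.02, 1.01),
    fmean_mid_sd      = c(0.24, 0.23, 0.23, 0.23, 0.25, 0.25, 0.25, 0.25, 0.24),
    fmean_unload_mean = c(0.55, 0.61, 0.65, 0.71, 0.72, 0.76, 0.77, 0.78, 0.79),
    fmean_unload_sd   = c(0.14, 0.14, 0.16, 0.16, 0.17, 0.18, 0.18, 0.18, 0.18),
    fz2_mean = c(1.50, 1.48, 1.39, 1.29, 1.20, 1.14, 1.12, 1.12, 1.11),
    fz2_sd   = c(0.39, 0.38, 0.36, 0.33, 0.30, 0.29, 0.29, 0.29, 0.29),
    fz3_mean = c(0.70, 0.74, 0.77, 0.83, 0.88, 0.88, 0.86, 0.84, 0.81),
    fz3_sd   = c(0.20, 0.19, 0.18, 0.19, 0.22, 0.21, 0.21, 0.22, 0.19),
    fz4_mean = c(0.88, 0.96, 1.02, 1.11, 1.16, 1.22, 1.25, 1.26, 1.29),
    fz4_sd   = c(0.24, 0.24, 0.26, 0.28, 0.32, 0.33, 0.33, 0.34, 0.35),
    loading_slope_mean = c(11.00, 10.35, 9.23, 7.79, 7.10, 5.92, 5.63, 5.43, 5.71),
    loading_slope_sd   = c(4.58, 4.01, 3.58, 2.99, 2.91, 2.11, 2.07, 1.85, 2.07),
    unloading_slope_mean = c(-5.30, -5.89, -6.26, -6.91, -7.31, -7.41, -7.65, -7.75, -8.02),
    unloading_slope_sd   = c(1.66, 1.87, 2.10, 2.34, 2.71, 2.64, 2.79, 2.92, 3.02),
    t_fz2 = c(0.250, 0.260, 0.245, 0.250, 0.245, 0.250, 0.260, 0.245, 0.245),
    t_fz3 = 0.54,
    t_fz4 = c(0.790, 0.790, 0.805, 0.825, 0.790, 0.790, 0.815, 0.795, 0.825)
  )
  validate_grade_parameters(out)
  out
}

validate_grade_parameters <- function(tbl) {
  stopifnot(is.data.frame(tbl), "grade" %in% names(tbl))
  if (any(tbl$fz3_mean >= tbl$fz2_mean) || any(tbl$fz3_mean >= tbl$fz4_mean)) {
    stop("grade parameter sets must satisfy the M-shape: fz3 below fz2 and fz4",
         call. = FALSE)
  }
  ts <- tbl[, c("t_fz2", "t_fz3", "t_fz4")]
  if (any(ts <= 0) || any(ts >= 1) ||
      any(tbl$t_fz2 >= tbl$t_fz3) || any(tbl$t_fz3 >= tbl$t_fz4)) {
    stop("extremum time anchors must satisfy 0 < t_fz2 < t_fz3 < t_fz4 < 1",
         call. = FALSE)
  }
  sds <- tbl[, grep("_sd$", names(tbl))]
  if (any(sds < 0)) stop("standard deviations must be non-negative", call. = FALSE)
  invisible(tbl)
}

#' Reference per-grade means in long format
#'
#' The per-grade reference means (and SDs) of [default_grade_parameters()]
#' reshaped to one row per grade and parameter, the shape produced by
#' [summarize_by_grade()]. Feed this to [normalize_to_horizontal()] and
#' [regress_normalized()] to recompute the slope-trend regressions directly
#' from the reference table.
#'
#' @return A tibble with columns `grade`, `parameter`, `mean`, `sd`.
#' @export
#' @examples
#' grade_reference_summary() |> normalize_to_horizontal() |> head()
grade_reference_summary <- function() {
  wide <- default_grade_parameters()
  means <- wide |>
    dplyr::select("grade", dplyr::ends_with("_mean")) |>
    tidyr::pivot_longer(-"grade", names_to = "parameter", values_to = "mean") |>
    dplyr::mutate(parameter = sub("_mean$", "", .data$parameter))
  sds <- wide |>
    dplyr::select("grade", dplyr::ends_with("_sd")) |>
    tidyr::pivot_longer(-"grade", names_to = "parameter", values_to = "sd") |>
    dplyr::mutate(parameter = sub("_sd$", "", .data$parameter))
  out <- dplyr::inner_join(means, sds, by = c("grade", "parameter"))
  out$parameter <- factor(out$parameter, levels = PARAMETER_LEVELS)
  dplyr::arrange(out, .data$parameter, .data$grade) |>
    dplyr::mutate(parameter = as.character(.data$parameter))
}
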