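# Per-grade aggregation, normalization to percent of horizontal walking,
# and linear-regression trend statistics.

#' Summarize stance parameters by grade
#'
#' Pools both feet and aggregates every parameter per grade. Two pooling
#' modes are exposed because summary tables in this field are sometimes
#' participant-level and sometimes step-level: `"participant"` (default)
#' first averages each participant's steps, then takes mean and SD across
#' participants; `"step"` pools all steps directly.
#'
#' @param params Parameter table from [compute_stance_parameters()].
#' @param pooling `"participant"` or `"step"`.
#' @return Tibble with columns `grade`, `parameter`, `mean`, `sd`,
#'   `n_steps`, `n_participants`. Grades without any accepted step are
#'   omitted with a warning.
#' @export
summarize_by_grade <- function(params, pooling = c("participant", "step")) {
  pooling <- match.arg(pooling)
  if (nrow(params) == 0) stop("no parameter records to summarize", call. = FALSE)
  long <- params |>
    tidyr::pivot_longer(dplyr::all_of(PARAMETER_LEVELS),
                        names_to = "parameter", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  if (pooling == "participant") {
    out <- long |>
      dplyr::group_by(.data$grade, .data$parameter, .data$participant_id) |>
      dplyr::summarise(p_mean = mean(.data$value), n = dplyr::n(),
                       .groups = "drop") |>
      dplyr::group_by(.data$grade, .data$parameter) |>
      dplyr::summarise(mean = mean(.data$p_mean), sd = sd(.data$p_mean),
                       n_steps = sum(.data$n),
                       n_participants = dplyr::n(), .groups = "drop")
  } else {
    out <- long |>
      dplyr::group_by(.data$grade, .data$parameter) |>
      dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                       n_steps = dplyr::n(),
                       n_participants = dplyr::n_distinct(.data$participant_id),
                       .groups = "drop")
    }
  all_grades <- unique(params$grade)
  dropped <- setdiff(all_grades, unique(out$grade))
  if (length(dropped)) {
    warning("grades without accepted steps omitted: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  out$parameter <- as.character(factor(out$parameter, levels = PARAMETER_LEVELS))
  dplyr::arrange(out, factor(out$parameter, levels = PARAMETER_LEVELS),
                 .data$grade)
}

#' Express per-grade means as percent of horizontal walking
#'
#' Divides each parameter's per-grade mean by its 0%-grade mean and scales
#' by 100, so horizontal walking maps to 100% for every parameter.
#' Negative-valued parameters (the unloading slope) are divided as-is: a
#' more negative value maps above 100%.
#'
#' @param summaries Tibble with `grade`, `parameter`, `mean` (from
#'   [summarize_by_grade()] or [grade_reference_summary()]).
#' @return The input with an added `pct_of_horizontal` column.
#' @export
#' @examples
#' grade_reference_summary() |> normalize_to_horizontal() |>
#'   dplyr::filter(parameter == "fz2")
normalize_to_horizontal <- function(summaries) {
  stopifnot(all(c("grade", "parameter", "mean") %in% names(summaries)))
  ref <- summaries[summaries$grade == 0, c("parameter", "mean")]
  if (nrow(ref) == 0) stop("the 0% grade is required as reference", call. = FALSE)
  if (any(ref$mean == 0)) stop("zero horizontal mean; cannot normalize", call. = FALSE)
  names(ref)[2] <- "mean_horizontal"
  missing <- setdiff(unique(summaries$parameter), ref$parameter)
  if (length(missing)) {
    stop("no 0% reference for parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::left_join(summaries, ref, by = "parameter")
  out$pct_of_horizontal <- 100 * out$mean / out$mean_horizontal
  out$mean_horizontal <- NULL
  out
}

#' Regress percent-of-horizontal series on grade
#'
#' Ordinary least squares of each parameter's percent-of-horizontal series
#' on treadmill grade (percent), one fit per parameter, with slope,
#' coefficient of determination and the regression-ANOVA F test.
#'
#' @param normalized Result of [normalize_to_horizontal()] (needs at least
#'   3 distinct grades).
#' @return An object of class `grade_trend`; use [generics::tidy()] for the
#'   per-parameter table and [ggplot2::autoplot()] to visualise the fits.
#' @export
#' @examples
#' fit <- grade_reference_summary() |> normalize_to_horizontal() |>
#'   regress_normalized()
#' generics::tidy(fit)
regress_normalized <- function(normalized) {
  stopifnot("pct_of_horizontal" %in% names(normalized))
  fit_trend(normalized, response = "pct_of_horizontal", min_grades = 3)
}

#' Per-step regression analysis of variance
#'
#' For each parameter, fits ordinary least squares of the raw per-step
#' parameter value on treadmill grade and reports the regression-ANOVA F
#' test, mirroring a per-parameter linear-regression ANOVA with grade as the
#' independent variable. The conventional significance threshold is 0.05;
#' no multiple-testing correction is applied.
#'
#' @param params Per-step parameter table from
#'   [compute_stance_parameters()]; must span at least two grades.
#' @return A `grade_trend` object; see [regress_normalized()].
#' @export
anova_per_parameter <- function(params) {
  long <- params |>
    tidyr::pivot_longer(dplyr::all_of(PARAMETER_LEVELS),
                        names_to = "parameter", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  fit_trend(long, response = "value", min_grades = 2)
}

fit_trend <- function(data, response, min_grades) {
  if (length(unique(data$grade)) < min_grades) {
    stop("at least ", min_grades, " distinct grades are required", call. = FALSE)
  }
  params <- intersect(PARAMETER_LEVELS, unique(data$parameter))
  fits <- lapply(setNames(params, params), function(p) {
    d <- data[data$parameter == p, ]
    if (length(unique(d$grade)) < 2) {
      stop("parameter ", p, " does not span at least 2 grades", call. = FALSE)
    }
    d$.response <- d[[response]]
    lm(.response ~ grade, data = d)
  })
  structure(list(fits = fits, data = data, response = response),
            class = "grade_trend")
}

#' @export
print.grade_trend <- function(x, ...) {
  cat("<grade_trend> OLS of", x$response, "on grade for",
      length(x$fits), "parameters\n")
  print(generics::tidy(x), ...)
  invisible(x)
}

#' Tidy a grade-trend fit
#'
#' @param x A `grade_trend` object.
#' @param ... Unused.
#' @return One row per parameter: `parameter`, `slope`, `intercept`,
#'   `r_squared` (defined as 0 when the response has zero variance),
#'   `f_statistic`, `p_value`, `n`.
#' @method tidy grade_trend
#' @export
tidy.grade_trend <- function(x, ...) {
  rows <- lapply(names(x$fits), function(p) {
    fit <- x$fits[[p]]
    resp <- fit$model$.response
    degenerate <- stats::sd(resp) < 1e-10 * (1 + abs(mean(resp)))
    sm <- summary(fit)
    r2 <- sm$r.squared
    if (degenerate || !is.finite(r2)) r2 <- 0
    fstat <- sm$fstatistic
    if (degenerate || is.null(fstat) || !is.finite(fstat[1])) {
      f <- NA_real_; pv <- NA_real_
    } else {
      f <- unname(fstat[1])
      pv <- unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
    }
    tibble::tibble(parameter = p, slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   r_squared = r2, f_statistic = f, p_value = pv,
                   n = length(fit$residuals))
  })
  dplyr::bind_rows(rows)
}

#' Glance at a grade-trend fit
#'
#' @param x A `grade_trend` object.
#' @param ... Unused.
#' @return One-row tibble with the number of parameters, grades, points and
#'   the response name.
#' @method glance grade_trend
#' @export
glance.grade_trend <- function(x, ...) {
  tibble::tibble(
    n_parameters = length(x$fits),
    n_grades = length(unique(x$data$grade)),
    n_points = nrow(x$data),
    response = x$response
  )
}

#' @method autoplot grade_trend
#' @export
#' @rdname autoplot.grade_trend
autoplot.grade_trend <- function(object, ...) {
  d <- object$data
  d$parameter <- factor(d$parameter, levels = PARAMETER_LEVELS)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$grade,
                                  y = .data[[object$response]])) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "treadmill grade (%)",
                  y = if (object$response == "pct_of_horizontal")
                    "% of horizontal walking" else "parameter value") +
    ggplot2::theme_minimal()
}

#' Plot a grade-trend fit
#'
#' Scatter of the underlying points with the fitted line, faceted by
#' parameter.
#'
#' @param object A `grade_trend` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot.grade_trend
NULL
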