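# Plotting helpers for normalized stance curves.

#' Plot mean normalized stance curves by grade
#'
#' Averages the 100-sample normalized curves per grade and draws one mean
#' M-curve per grade over percent of stance duration.
#'
#' @param curves Result of [normalize_stances()] (or of [locate_extrema()]).
#' @param max_curves Optional cap on the number of stances averaged per
#'   grade (for speed on large sessions).
#' @return A ggplot object.
#' @export
plot_mean_curves <- function(curves, max_curves = Inf) {
  d <- curves |>
    dplyr::group_by(.data$grade) |>
    dplyr::slice_head(n = if (is.finite(max_curves)) max_curves else dplyr::n()) |>
    dplyr::summarise(
      mean_curve = list(Reduce(`+`, .data$curve) / length(.data$curve)),
      .groups = "drop") |>
    tidyr::unnest_longer("mean_curve", values_to = "force_bw") |>
    dplyr::group_by(.data$grade) |>
    dplyr::mutate(pct_stance = dplyr::row_number() - 1) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pct_stance, y = .data$force_bw,
                                  colour = factor(.data$grade),
                                  group = .data$grade)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "stance duration (%)", y = "force (fraction of body weight)",
                  colour = "grade (%)") +
    ggplot2::theme_minimal()
}

#' @method autoplot stance_curves
#' @export
autoplot.stance_curves <- function(object, ...) plot_mean_curves(object, ...)
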