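#' Run the full extraction pipeline on a session
#'
#' Convenience wrapper chaining [detect_stances()], [normalize_stances()],
#' [locate_extrema()] and [compute_stance_parameters()]. Nothing is dropped
#' silently: every excluded candidate, spline rejection, extremum rejection
#' and flagged slope is collected in the `"log"` attribute, retrievable via
#' [pipeline_log()].
#'
#' @param session An `insole_session`, or a samples tibble (then
#'   `participants` is required).
#' @param participants Participant metadata when `session` is a bare tibble.
#' @param constants Named list overriding entries of [stance_defaults()].
#' @param require_ordering See [finalize_extrema()].
#' @return The per-step parameter tibble.
#' @export
#' @examples
#' s <- generate_session(session_spec(n_participants = 2, steps_per_grade = 4,
#'                                    feet = "left", seed = 3),
#'                       grades = c(-20, 0, 20))
#' p <- extract_parameters(s)
#' pipeline_log(p)$n_accepted
extract_parameters <- function(session, participants = NULL,
                               constants = list(),
                               require_ordering = TRUE) {
  k <- utils::modifyList(stance_defaults(), constants)
  if (inherits(session, "insole_session")) {
    samples <- session$samples
    participants <- session$participants
  } else {
    samples <- session
    if (is.null(participants)) {
      stop("participants metadata is required with a bare samples table",
           call. = FALSE)
    }
  }
  events <- detect_stances(samples,
                           threshold_n = k$threshold_n,
                           gap_tolerance = k$gap_tolerance,
                           min_duration_ms = k$min_duration_ms,
                           max_duration_ms = k$max_duration_ms)
  curves <- normalize_stances(events, participants,
                              filter_sigma = k$filter_sigma,
                              filter_size = k$filter_size)
  extrema <- locate_extrema(curves,
                            edge_margin = k$edge_margin,
                            pool_gap = k$pool_gap,
                            monotony_span = k$monotony_span,
                            require_ordering = require_ordering)
  params <- compute_stance_parameters(extrema,
                                      crossing_fraction = k$crossing_fraction)
  rej <- extrema[extrema$status == "rejected",
                 c("participant_id", "foot", "grade", "step_id",
                   "reject_reason")]
  log <- list(
    n_detected = nrow(events),
    exclusions = stance_exclusions(events),
    spline_rejections = attr(curves, "rejections"),
    extrema_rejections = rej,
    slope_flags = attr(params, "flags"),
    n_accepted = nrow(params),
    constants = k
  )
  attr(params, "log") <- log
  params
}

#' Retrieve the processing log of a pipeline result
#'
#' @param x Result of [extract_parameters()].
#' @return List with counts and the exclusion/rejection/flag tables.
#' @export
pipeline_log <- function(x) attr(x, "log")

#' Orchestrate simulate, extract and analyze with files and a manifest
#'
#' Runs the three stages end to end: simulate a synthetic session (or read
#' one from `input_dir`), extract per-step parameters, and analyze them
#' into grade summaries, percent-of-horizontal series and regression
#' tables. All outputs are delimited text under `output_dir`, plus a JSON
#' manifest with the seed, stage counts (detected, excluded and rejected by
#' reason, accepted) and any deviation of a processing constant from
#' [stance_defaults()]. On error a `FAILED` marker file with the message is
#' left in `output_dir` and the error is rethrown.
#'
#' @param config Named list (or path to a YAML file with the same fields):
#'   `output_dir` (required); optional `input_dir` (read an existing session
#'   instead of simulating), `seed`, `grades`, `session` (list of
#'   [session_spec()] overrides), `constants` (list of [stance_defaults()]
#'   overrides), `pooling`, `require_ordering`.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$output_dir))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tryCatch(
    run_pipeline_stages(config, out_dir),
    error = function(e) {
      writeLines(paste("pipeline failed:", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop(e)
    })
}

run_pipeline_stages <- function(config, out_dir) {
  pooling <- config$pooling %||% "participant"
  require_ordering <- config$require_ordering %||% TRUE
  constants <- config$constants %||% list()
  grades <- config$grades %||% seq(-20, 20, by = 5)

  if (!is.null(config$input_dir)) {
    session <- read_session(config$input_dir)
  } else {
    spec_args <- config$session %||% list()
    if (!is.null(config$seed)) spec_args$seed <- config$seed
    spec <- do.call(session_spec, spec_args)
    session <- generate_session(spec, grades = grades)
    write_session(session, file.path(out_dir, "session"))
  }

  params <- extract_parameters(session, constants = constants,
                               require_ordering = require_ordering)
  log <- pipeline_log(params)
  write_parameters_table(params, file.path(out_dir, "parameters.csv"))
  readr::write_csv(log$exclusions, file.path(out_dir, "exclusions.csv"))
  readr::write_csv(log$extrema_rejections,
                   file.path(out_dir, "extrema_rejections.csv"))

  summaries <- summarize_by_grade(params, pooling = pooling)
  normalized <- normalize_to_horizontal(summaries)
  trend <- regress_normalized(normalized)
  anova <- anova_per_parameter(params)
  readr::write_csv(summaries, file.path(out_dir, "grade_summary.csv"))
  readr::write_csv(normalized, file.path(out_dir, "normalized_series.csv"))
  readr::write_csv(generics::tidy(trend), file.path(out_dir, "regression.csv"))
  readr::write_csv(generics::tidy(anova), file.path(out_dir, "anova.csv"))

  defaults <- stance_defaults()
  k <- log$constants
  deviations <- names(defaults)[vapply(names(defaults), function(nm) {
    !identical(defaults[[nm]], k[[nm]])
  }, logical(1))]
  manifest <- list(
    seed = if (!is.null(session$spec)) session$spec$seed else config$seed,
    grades = grades,
    files = c("parameters.csv", "exclusions.csv", "extrema_rejections.csv",
              "grade_summary.csv", "normalized_series.csv",
              "regression.csv", "anova.csv"),
    counts = list(
      stances_detected = log$n_detected,
      excluded_too_short = sum(log$exclusions$reason == "too_short"),
      excluded_too_long = sum(log$exclusions$reason == "too_long"),
      rejected_too_few_samples = nrow(log$spline_rejections),
      rejected_candidate_count =
        sum(log$extrema_rejections$reject_reason == "candidate_count"),
      rejected_ordering = sum(log$extrema_rejections$reject_reason == "ordering"),
      slope_flags = nrow(log$slope_flags),
      accepted = log$n_accepted,
      grade_summaries = length(unique(summaries$grade))
    ),
    constant_deviations = if (length(deviations)) {
      setNames(lapply(deviations, function(nm) k[[nm]]), deviations)
    } else NULL
  )
  # accounting invariant: nothing is dropped silently
  cnt <- manifest$counts
  stopifnot(cnt$stances_detected ==
              cnt$rejected_too_few_samples + cnt$rejected_candidate_count +
              cnt$rejected_ordering + cnt$accepted)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
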