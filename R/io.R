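# Reading and writing raw force sessions and tabular outputs.
#
# The raw-session dialect is deliberately minimal open delimited text:
#   samples.csv       participant_id, foot, grade, timestamp_ms, force_n
#   participants.csv  participant_id, body_weight_kg [, height_cm, age_yr, sex]
#   ground_truth.csv  optional sidecar written by the synthetic generator
# Timestamps are integer milliseconds; dropped samples are absent rows.
# Forces are Newtons in raw files; body-weight scaling happens only at
# normalization time.

SAMPLE_COLUMNS <- c("participant_id", "foot", "grade", "timestamp_ms", "force_n")

#' Write an insole session to a directory
#'
#' @param session An `insole_session` (see [generate_session()]) or a list
#'   with tibbles `samples`, `participants` and optionally `ground_truth`.
#' @param dir Output directory, created if needed.
#' @return The written file paths, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(samples = file.path(dir, "samples.csv"),
             participants = file.path(dir, "participants.csv"))
  readr::write_csv(session$samples[, SAMPLE_COLUMNS], paths[["samples"]])
  readr::write_csv(session$participants, paths[["participants"]])
  if (!is.null(session$ground_truth)) {
    paths <- c(paths, ground_truth = file.path(dir, "ground_truth.csv"))
    readr::write_csv(session$ground_truth, paths[["ground_truth"]])
  }
  invisible(paths)
}

#' Read an insole session from a directory
#'
#' Validates the raw-session contract: mandatory headers, positive body
#' weights, non-negative forces, and strictly increasing timestamps within
#' each participant/foot/grade series. Unknown columns are ignored with a
#' warning.
#'
#' @param dir Directory containing `samples.csv` and `participants.csv`
#'   (and optionally `ground_truth.csv`).
#' @return An `insole_session`.
#' @export
read_session <- function(dir) {
  sp <- file.path(dir, "samples.csv")
  pp <- file.path(dir, "participants.csv")
  if (!file.exists(sp)) stop("missing samples file: ", sp, call. = FALSE)
  if (!file.exists(pp)) stop("missing participants file: ", pp, call. = FALSE)
  samples <- readr::read_csv(sp, show_col_types = FALSE, progress = FALSE)
  participants <- readr::read_csv(pp, show_col_types = FALSE, progress = FALSE)

  miss <- setdiff(SAMPLE_COLUMNS, names(samples))
  if (length(miss)) {
    stop("samples.csv lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(samples), SAMPLE_COLUMNS)
  if (length(extra)) {
    warning("ignoring unknown sample column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
    samples <- samples[, SAMPLE_COLUMNS]
  }
  if (!all(c("participant_id", "body_weight_kg") %in% names(participants))) {
    stop("participants.csv needs participant_id and body_weight_kg",
         call. = FALSE)
  }
  if (any(is.na(participants$body_weight_kg)) ||
      any(participants$body_weight_kg <= 0)) {
    stop("missing or non-positive body weight in participants.csv",
         call. = FALSE)
  }
  neg <- which(samples$force_n < 0)
  if (length(neg)) {
    stop("negative force reading in samples.csv at data row ", neg[1],
         call. = FALSE)
  }
  bad <- samples |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$participant_id, .data$foot, .data$grade) |>
    dplyr::filter(c(FALSE, diff(.data$timestamp_ms) <= 0)) |>
    dplyr::ungroup()
  if (nrow(bad)) {
    stop("non-monotone timestamps in samples.csv at data row ", bad$.row[1],
         call. = FALSE)
  }
  samples$timestamp_ms <- as.integer(samples$timestamp_ms)

  gt_path <- file.path(dir, "ground_truth.csv")
  ground_truth <- if (file.exists(gt_path)) {
    readr::read_csv(gt_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  structure(list(samples = samples, participants = participants,
                 ground_truth = ground_truth, spec = NULL,
                 grades = sort(unique(samples$grade))),
            class = "insole_session")
}

#' Write / read a per-step parameter table
#'
#' One row per stance event with identifiers and the nine parameters, as
#' delimited text at full float precision, so write-then-read round-trips
#' exactly. An empty record set produces a header-only file. Records from
#' both feet are written with their foot labels; feet are pooled only at
#' analysis time.
#'
#' @param params Parameter tibble from [compute_stance_parameters()].
#' @param path Output file.
#' @return `path`, invisibly (`write_parameters_table`); the parameter
#'   tibble (`read_parameters_table`).
#' @export
write_parameters_table <- function(params, path) {
  cols <- c("participant_id", "foot", "grade", "step_id", "duration_ms",
            PARAMETER_LEVELS)
  keep <- intersect(cols, names(params))
  readr::write_csv(params[, keep], path)
  invisible(path)
}

#' @rdname write_parameters_table
#' @export
read_parameters_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
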