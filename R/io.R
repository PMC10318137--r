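#' Write cohort tables to CSV
#'
#' Writes `participants.csv`, `songs.csv`, `traces.csv` (long format with
#' 0-based `t_sec`) and `surveys.csv` as RFC-4180 CSV with header rows.
#'
#' @param cohort a [simulate_cohort()] result or list with the same
#'   elements.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_cohort_tables <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("participants", "songs", "traces", "surveys")) {
    data.table::fwrite(as.data.table(cohort[[nm]]),
                       file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

required_cols <- list(
  participants = c("participant_id", "age", "gender"),
  songs = c("song_id", "label", "streams"),
  traces = c("participant_id", "song_id", "t_sec", "immersion"),
  surveys = c("participant_id", "song_id", "liking", "replay", "recommend",
              "familiar", "offensive", "lyric_memory"))

#' Read and validate cohort tables
#'
#' Loads the four cohort CSVs, checks the schema (an error names any
#' missing column), normalizes labels to `hit`/`flop`, and verifies that
#' every trace's second index runs contiguously from 0 — a gap is an
#' error, never silently reindexed, because the feature statistics
#' integrate over the full duration.
#'
#' @param dir directory holding `participants.csv`, `songs.csv`,
#'   `traces.csv`, `surveys.csv`; alternatively pass explicit paths.
#' @param participants,songs,traces,surveys optional explicit file paths
#'   overriding `dir`. When no `dir` is given, the participants table may
#'   be omitted (featurization does not need it).
#' @return named list of validated `data.table`s.
#' @export
read_cohort_tables <- function(dir = NULL, participants = NULL, songs = NULL,
                               traces = NULL, surveys = NULL) {
  paths <- list(
    participants = participants %||%
      (if (!is.null(dir)) file.path(dir, "participants.csv")),
    songs = songs %||% file.path(dir, "songs.csv"),
    traces = traces %||% file.path(dir, "traces.csv"),
    surveys = surveys %||% file.path(dir, "surveys.csv"))
  paths <- paths[!vapply(paths, is.null, logical(1))]
  for (nm in c("songs", "traces", "surveys")) {
    if (is.null(paths[[nm]])) stop("no path for ", nm, " table", call. = FALSE)
  }
  out <- list()
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) {
      stop("missing file: ", paths[[nm]], call. = FALSE)
    }
    tab <- data.table::fread(paths[[nm]])
    missing_cols <- setdiff(required_cols[[nm]], names(tab))
    if (length(missing_cols)) {
      stop(sprintf("%s is missing column(s): %s", basename(paths[[nm]]),
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    out[[nm]] <- tab
  }
  out$songs$label <- normalize_label(out$songs$label)
  check_contiguous_seconds(out$traces)
  out
}

check_contiguous_seconds <- function(traces) {
  bad <- as.data.table(traces)[order(t_sec),
    .(ok = identical(as.integer(t_sec), 0:(.N - 1L)),
      gap_at = {
        expected <- 0:(.N - 1L)
        w <- which(as.integer(sort(t_sec)) != expected)
        if (length(w)) expected[w[1]] else NA_integer_
      }),
    by = .(participant_id, song_id)][ok == FALSE]
  if (nrow(bad)) {
    stop(sprintf(
      "non-contiguous seconds in trace (participant %s, song %s): expected t=%d",
      bad$participant_id[1], bad$song_id[1], bad$gap_at[1]), call. = FALSE)
  }
  invisible(traces)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: top-level `seed` plus optional
#' `cohort`, `synthesis`, `ensemble` and `evaluation` blocks whose keys
#' are the corresponding constructor arguments.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}
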