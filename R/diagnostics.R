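# Run provenance and per-stage diagnostics: a file-backed, append-only
# ledger of sequence counts per stage (the basis of the matrix-
# construction funnel chart) and structured records of commands,
# parameters, input digests and external-tool invocations.

#' Open (or create) a run store
#'
#' A run store is a directory holding one JSON file per run. Everything
#' recorded against a run (parameters, stage counts, external calls) is
#' flushed to disk immediately, so records survive process restarts.
#'
#' @param dir directory path; created if absent.
#' @return A handle of class \code{run_store}.
#' @export
run_store <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  structure(list(dir = dir), class = "run_store")
}

run_path <- function(store, run_id) file.path(store$dir, paste0(run_id, ".json"))

load_run <- function(store, run_id) {
  p <- run_path(store, run_id)
  if (!file.exists(p)) stop("unknown run_id '", run_id, "'")
  jsonlite::read_json(p, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

save_run <- function(store, rec) {
  jsonlite::write_json(rec, run_path(store, rec$run_id),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(rec$run_id)
}

#' Start a new run record
#'
#' Records the command, its parameters (serialized losslessly to JSON),
#' the start time, and content digests of any input files.
#'
#' @param store a [run_store].
#' @param command the command or pipeline name.
#' @param parameters named list of parameters.
#' @param inputs character vector of input file paths to digest (md5).
#' @param run_id optional explicit id; default is derived from the
#'   number of existing runs.
#' @return The \code{run_id}.
#' @export
new_run <- function(store, command, parameters = list(),
                    inputs = character(), run_id = NULL) {
  if (is.null(run_id)) {
    existing <- list.files(store$dir, pattern = "\\.json$")
    run_id <- sprintf("run-%04d", length(existing) + 1L)
  }
  if (file.exists(run_path(store, run_id)))
    stop("run_id '", run_id, "' already exists")
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else setNames(list(), character())
  rec <- list(run_id = run_id, command = command,
              parameters = parameters,
              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              finished = NULL,
              input_digests = digests,
              external_calls = list(),
              stages = list())
  save_run(store, rec)
  run_id
}

#' Mark a run finished
#'
#' @param store a [run_store].
#' @param run_id the run.
#' @return Invisibly, the run_id.
#' @export
finish_run <- function(store, run_id) {
  rec <- load_run(store, run_id)
  rec$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  invisible(save_run(store, rec))
}

#' Record the sequence count at a pipeline stage
#'
#' Appends to the run's ordered stage ledger. Re-recording a stage name
#' within one run versions it: all entries are kept, the latest is
#' reported.
#'
#' @param store a [run_store].
#' @param run_id the run.
#' @param stage_name stage label (e.g. \code{"homologize"}).
#' @param n_sequences sequence count at that stage (>= 0).
#' @param reason optional short note on what changed at this stage.
#' @return Invisibly, the run_id.
#' @export
record_stage <- function(store, run_id, stage_name, n_sequences,
                         reason = NA_character_) {
  if (n_sequences < 0) stop("n_sequences must be >= 0")
  rec <- load_run(store, run_id)
  rec$stages[[length(rec$stages) + 1L]] <-
    list(stage_name = stage_name, n_sequences = as.integer(n_sequences),
         reason = reason)
  invisible(save_run(store, rec))
}

#' Log a call to an external program
#'
#' Every external invocation is recorded with its argv, reported
#' version, and a content hash of the executable, so differences in
#' builds or settings are detectable later.
#'
#' @param store a [run_store].
#' @param run_id the run.
#' @param argv character vector: program and arguments.
#' @param version version string as reported by the tool.
#' @return Invisibly, the run_id.
#' @export
log_external_call <- function(store, run_id, argv, version = NA_character_) {
  rec <- load_run(store, run_id)
  exe <- Sys.which(argv[1L])
  digest <- if (nzchar(exe)) unname(tools::md5sum(exe)) else NA_character_
  rec$external_calls[[length(rec$external_calls) + 1L]] <-
    list(argv = as.list(argv), version = version, binary_md5 = digest)
  invisible(save_run(store, rec))
}

#' Retrieve a run record
#'
#' @param store a [run_store].
#' @param run_id the run.
#' @return The stored record (named list).
#' @export
get_run <- function(store, run_id) load_run(store, run_id)

#' Per-stage sequence-count report
#'
#' Deduplicates versioned stages (latest wins, original position kept),
#' then computes the count change between consecutive stages. The
#' resulting funnel — counts falling across homology evaluation,
#' alignment refinement and ortholog decomposition — is the standard
#' matrix-construction diagnostic.
#'
#' @param store a [run_store].
#' @param run_id the run.
#' @param csv_path optional path to also write the table as CSV.
#' @return Data frame with \code{stage_name}, \code{n_sequences},
#'   \code{delta} (NA for the first stage) and \code{delta_reason}.
#' @export
stage_report <- function(store, run_id, csv_path = NULL) {
  rec <- load_run(store, run_id)
  if (length(rec$stages) == 0L) stop("no stages recorded for ", run_id)
  df <- data.frame(
    stage_name = vapply(rec$stages, `[[`, "", "stage_name"),
    n_sequences = vapply(rec$stages, function(s)
      as.integer(s$n_sequences), integer(1)),
    delta_reason = vapply(rec$stages, function(s)
      as.character(s$reason %||% NA_character_), character(1)),
    row.names = NULL)
  df <- df[!duplicated(df$stage_name, fromLast = TRUE), , drop = FALSE]
  rownames(df) <- NULL
  df$delta <- c(NA_integer_, diff(df$n_sequences))
  df <- df[, c("stage_name", "n_sequences", "delta", "delta_reason")]
  if (!is.null(csv_path))
    write.table(df, csv_path, sep = ",", quote = FALSE, row.names = FALSE)
  df
}

#' Plot the stage-count funnel
#'
#' @param store a [run_store].
#' @param run_id the run.
#' @param ... passed to \code{barplot}.
#' @return Invisibly, the report data frame.
#' @export
plot_stage_report <- function(store, run_id, ...) {
  df <- stage_report(store, run_id)
  graphics::barplot(df$n_sequences, names.arg = df$stage_name,
                    las = 2, ylab = "sequences under consideration", ...)
  invisible(df)
}
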