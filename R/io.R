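#' Read and write pipeline tables
#'
#' All pipeline tables (participants, intake records, activity events, visit
#' logs, engagement records, posttest responses, task plans) are plain CSV
#' with a header row; empty cells are unstated values (`NA`). Writers and
#' readers round-trip losslessly.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `read_table_csv()` returns a data frame; `write_table_csv()`
#'   returns `path` invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}

#' Write a synthetic cohort to a directory
#'
#' Writes every table of a cohort as CSV plus a JSON manifest recording the
#' generator configuration, seed and output files, so the run can be
#' reproduced exactly.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("participants", "intake", "engagement", "visits", "events",
              "posttest")
  files <- character(0)
  for (t in tables) {
    if (is.null(cohort[[t]])) next
    f <- file.path(dir, paste0(t, ".csv"))
    write_table_csv(cohort[[t]], f)
    files[t] <- basename(f)
  }
  write_manifest(
    file.path(dir, "manifest.json"),
    config = cohort$config, seed = cohort$config$seed,
    files = as.list(files), stage = "simulate"
  )
}

#' Read a cohort back from a directory written by [write_cohort()]
#'
#' @param dir Directory holding the cohort tables and manifest.
#' @return A `synthetic_cohort`-shaped list (the `config` entry holds the
#'   manifest's config snapshot as a plain list).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  out <- list()
  for (t in names(manifest$files)) {
    out[[t]] <- read_table_csv(file.path(dir, manifest$files[[t]]))
  }
  out$config <- manifest$config
  structure(out, class = "synthetic_cohort")
}

#' Write a stage manifest
#'
#' Records the configuration snapshot, seed, produced files and stage name of
#' a pipeline stage as JSON; re-running the stage with the recorded config
#' and seed reproduces identical outputs.
#'
#' @param path Manifest file path.
#' @param config Configuration list (functions and environments are dropped).
#' @param seed Integer seed used.
#' @param files Named list of produced files.
#' @param stage Stage name.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, files, stage) {
  cfg <- config_to_plain(config)
  jsonlite::write_json(
    list(stage = stage, seed = seed, files = files, config = cfg),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null",
    dataframe = "rows"
  )
  invisible(path)
}

config_to_plain <- function(x) {
  x <- unclass(x)
  if (is.list(x)) return(lapply(x, config_to_plain))
  x
}

#' Export per-wave ledgers and leaderboards as JSON
#'
#' @param ledger A `score_ledger` from [score_events()].
#' @param participants Participant table.
#' @param waves Waves to export.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_leaderboards <- function(ledger, participants, waves, path) {
  out <- lapply(waves, function(w) {
    lb <- leaderboards(ledger, w, participants)
    list(wave = w, individual = lb$individual, department = lb$department)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
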