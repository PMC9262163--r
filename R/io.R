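# CSV round-trip for a study bundle. Column names are fixed:
#   individuals.csv     id, sex, birth_date
#   membership.csv      id, group, entry, exit
#   follows.csv         follow_id, focal, group, time, duration_min
#   grooming.csv        follow_id, groomer, groomee, time
#   aggression.csv      time, group, aggressor, target
#   scans.csv           scan_id, time, group, subject, activity
#   scan_neighbors.csv  scan_id, neighbor, distance_bl
#   covariates.csv      id, year, group, rank, group_size   (optional)
#   demography.csv      id, death_date, last_observed       (optional)

study_tables <- c("individuals", "membership", "follows", "grooming",
                  "aggression", "scans", "scan_neighbors", "covariates",
                  "demography")

#' Read a study bundle from a directory of CSV files
#'
#' @param dir Directory containing the study CSVs (see the package README
#'   for the fixed column layout). `covariates.csv` and `demography.csv`
#'   are optional.
#' @return A named list of tibbles (a "study bundle").
#' @export
read_study <- function(dir) {
  need <- setdiff(study_tables, c("covariates", "demography"))
  out <- list()
  for (tb in study_tables) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(path)) {
      if (tb %in% need) {
        abort(sprintf("missing required input file: %s", path),
              class = "capsoc_error_missing_file")
      }
      next
    }
    out[[tb]] <- readr::read_csv(path, show_col_types = FALSE)
  }
  for (tb in c("follows", "grooming", "aggression", "scans")) {
    if (!is.null(out[[tb]]) && !inherits(out[[tb]]$time, "POSIXct")) {
      out[[tb]]$time <- as.POSIXct(out[[tb]]$time, tz = "UTC")
    }
  }
  date_cols <- list(individuals = "birth_date",
                    membership = c("entry", "exit"),
                    demography = c("death_date", "last_observed"))
  for (tb in names(date_cols)) {
    for (cl in intersect(date_cols[[tb]], names(out[[tb]]))) {
      out[[tb]][[cl]] <- as.Date(out[[tb]][[cl]])
    }
  }
  out
}

#' Write a study bundle to a directory of CSV files
#'
#' @param study Named list of tables as produced by [simulate_study()] or
#'   [read_study()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (tb in intersect(study_tables, names(study))) {
    path <- file.path(dir, paste0(tb, ".csv"))
    readr::write_csv(study[[tb]], path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
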