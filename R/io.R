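#' Read and write life-table CSV files
#'
#' The life-table CSV schema has columns `growth_form`, `source_label`,
#' `stage`, `sigma`, `duration`, one row per stage per sample. Reading
#' validates all life-table invariants and reports offending rows;
#' numeric fields round-trip at full precision. Stage-5 durations are
#' stored as `Inf`.
#'
#' @param tbl A life-table tibble.
#' @param path File path.
#' @return `read_life_tables()` returns the validated tibble;
#'   `write_life_tables()` returns `path` invisibly.
#' @export
write_life_tables <- function(tbl, path) {
  validate_life_tables(tbl)
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_life_tables
#' @export
read_life_tables <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           growth_form = readr::col_character(),
                           source_label = readr::col_character(),
                           stage = readr::col_integer(),
                           sigma = readr::col_double(),
                           duration = readr::col_double()))
  validate_life_tables(tbl)
  tbl
}

#' Read and write transition matrices as JSON
#'
#' Serialises a `transition_matrix` (row-major 5x5 array, fertility
#' entries, asymptotic growth rate, generating survivals and durations,
#' optional provenance such as seed and number of Monte-Carlo trials) at
#' full precision, and reads it back to an identical object.
#'
#' @param tm A `transition_matrix`.
#' @param path File path.
#' @param provenance Optional named list stored verbatim (e.g. `seed`,
#'   `n_trials`).
#' @return `read_matrix_json()` returns the `transition_matrix` (with a
#'   `provenance` attribute if stored); `write_matrix_json()` returns
#'   `path` invisibly.
#' @export
write_matrix_json <- function(tm, path, provenance = NULL) {
  if (!inherits(tm, "transition_matrix")) abort("`tm` must be a transition_matrix.")
  payload <- list(
    A = tm$A, fertility = as.list(tm$fertility), lambda = tm$lambda,
    sigma = tm$sigma, duration = tm$duration, gamma = tm$gamma,
    growth_form = tm$growth_form, shrinkage = tm$shrinkage,
    provenance = provenance)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}

#' @rdname write_matrix_json
#' @export
read_matrix_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  # write/read are symmetric in row-major orientation, so the matrix comes
  # back in R orientation already
  A <- as_projection_matrix(payload$A)
  dur <- as.numeric(payload$duration)
  tm <- new_transition_matrix(
    A, as.numeric(payload$sigma), dur, as.numeric(payload$gamma),
    fertility = c(fertility_4 = as.numeric(payload$fertility$fertility_4),
                  fertility_5 = as.numeric(payload$fertility$fertility_5)),
    growth_form = payload$growth_form,
    shrinkage = if (is.null(payload$shrinkage)) NULL else
      as.numeric(payload$shrinkage))
  attr(tm, "provenance") <- payload$provenance
  tm
}

#' Read and write size-distribution CSV files
#'
#' Schema: `habitat`, `depth_zone`, `year`, `class_1` .. `class_5`.
#' Validation rejects negative or missing counts, naming the offending
#' row and column.
#'
#' @param df A size-distribution tibble (one row per sample).
#' @param path File path.
#' @return `read_size_distributions()` returns the validated tibble;
#'   `write_size_distributions()` returns `path` invisibly.
#' @export
write_size_distributions <- function(df, path) {
  validate_size_distributions(df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_size_distributions
#' @export
read_size_distributions <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_size_distributions(df)
  df
}

validate_size_distributions <- function(df) {
  required <- c("habitat", "depth_zone", "year", CLASS_COLS)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("size-distribution table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(df$habitat %in% c("lagoon", "ocean_facing"))) {
    abort("`habitat` must be 'lagoon' or 'ocean_facing'.")
  }
  for (cl in CLASS_COLS) {
    bad <- which(is.na(df[[cl]]) | df[[cl]] < 0)
    if (length(bad) > 0) {
      abort(sprintf("negative or missing count at row %d, column `%s`.",
                    bad[1], cl))
    }
  }
  invisible(df)
}

#' Write a projected trajectory to CSV
#'
#' @param traj A `coral_trajectory` tibble from [project_series()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(traj, path)
  invisible(path)
}

#' Read and write impact scenarios as YAML
#'
#' The YAML schema mirrors [impact_scenario()]:
#' `recruitment_loss_rate`, `episodic_mortality`, `event_interval`,
#' `affected_classes`, `horizon`. Reading validates bounds before any
#' computation (e.g. a mortality of 1.2 is rejected).
#'
#' @param scenario An `impact_scenario`.
#' @param path File path.
#' @return `read_scenario_yaml()` returns an `impact_scenario`;
#'   `write_scenario_yaml()` returns `path` invisibly.
#' @export
write_scenario_yaml <- function(scenario, path) {
  if (!inherits(scenario, "impact_scenario")) {
    abort("`scenario` must be an impact_scenario().")
  }
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("recruitment_loss_rate", "episodic_mortality",
               "event_interval", "affected_classes", "horizon")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown scenario fields: ", paste(unknown, collapse = ", ")))
  }
  do.call(impact_scenario, raw)
}
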