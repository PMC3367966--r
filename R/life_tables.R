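#' Growth forms recognised by the package
#'
#' Coral taxa are lumped into three functional types by growth form:
#' fast-growing open arborescent corals, branching and encrusting forms,
#' and slow-growing massive corals.
#'
#' @export
GROWTH_FORMS <- c("arborescent", "branching_encrusting", "massive")

#' Construct a single life-table sample
#'
#' A life table holds, for each of the five coral size stages, the annual
#' within-stage survival probability `sigma` and the fixed stage duration
#' `duration` (years an individual spends in the stage before advancing,
#' given survival). The last stage is open-ended: its duration is `Inf` and
#' it has no onward transition.
#'
#' @param sigma Numeric vector of 5 per-stage annual survival probabilities,
#'   each in `[0, 1]`.
#' @param duration Numeric vector of 5 stage durations in years; stages 1-4
#'   must be positive integers, stage 5 may be `Inf` (the default when a
#'   4-vector is supplied).
#' @param growth_form One of `"arborescent"`, `"branching_encrusting"`,
#'   `"massive"`.
#' @param source_label Label identifying the (literature) source of the
#'   sample.
#'
#' @return A tibble with columns `growth_form`, `source_label`, `stage`,
#'   `sigma`, `duration` (one row per stage).
#' @examples
#' life_table(c(0.02, 0.35, 0.65, 0.84, 0.92), c(1, 2, 3, 5),
#'            growth_form = "branching_encrusting")
#' @export
life_table <- function(sigma, duration, growth_form = "branching_encrusting",
                       source_label = "sample_1") {
  growth_form <- match.arg(growth_form, GROWTH_FORMS)
  if (length(duration) == N_STAGES - 1L) duration <- c(duration, Inf)
  tbl <- tibble::tibble(
    growth_form = growth_form,
    source_label = source_label,
    stage = seq_len(N_STAGES),
    sigma = as.numeric(sigma),
    duration = as.numeric(duration)
  )
  validate_life_tables(tbl)
  tbl
}

#' Validate a life-table tibble
#'
#' Checks the invariants of life-table data: five stages per sample, all
#' survival probabilities in `[0, 1]`, integer durations of at least one
#' year for stages 1-4 (stage 5 is open-ended and may be `Inf`).
#'
#' @param tbl A tibble with columns `growth_form`, `source_label`, `stage`,
#'   `sigma`, `duration`.
#' @return `tbl`, invisibly, if valid; otherwise an error naming the
#'   offending rows.
#' @export
validate_life_tables <- function(tbl) {
  required <- c("growth_form", "source_label", "stage", "sigma", "duration")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("life table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(tbl$growth_form %in% GROWTH_FORMS)) {
    bad <- unique(setdiff(tbl$growth_form, GROWTH_FORMS))
    abort(paste0("unknown growth_form: ", paste(bad, collapse = ", ")))
  }
  if (length(s <- which(is.na(tbl$sigma) | tbl$sigma < 0 | tbl$sigma > 1)) > 0) {
    abort(sprintf("column `sigma` must lie in [0, 1]; bad rows: %s",
                  paste(head(s, 5), collapse = ", ")))
  }
  open_ended <- tbl$stage == N_STAGES
  dur_ok <- ifelse(open_ended,
                   is.infinite(tbl$duration) | tbl$duration >= 1,
                   is.finite(tbl$duration) & tbl$duration >= 1 &
                     tbl$duration == round(tbl$duration))
  if (length(s <- which(is.na(dur_ok) | !dur_ok)) > 0) {
    abort(sprintf(
      "column `duration` must be a positive integer (stage 5 may be Inf); bad rows: %s",
      paste(head(s, 5), collapse = ", ")))
  }
  counts <- dplyr::count(tbl, .data$growth_form, .data$source_label)
  if (any(counts$n != N_STAGES)) {
    abort("each (growth_form, source_label) sample must have exactly 5 stages.")
  }
  by_sample <- dplyr::group_by(tbl, .data$growth_form, .data$source_label)
  stages_ok <- dplyr::summarise(by_sample,
                                ok = all(sort(.data$stage) == seq_len(N_STAGES)),
                                .groups = "drop")
  if (!all(stages_ok$ok)) {
    abort("each sample must contain stages 1..5 exactly once.")
  }
  invisible(tbl)
}

#' Probability of advancing a stage under fixed stage durations
#'
#' For a stage with annual survival `sigma` and fixed duration `duration`
#' years, returns the probability `gamma` that a surviving individual
#' advances to the next stage in a given year, assuming the within-stage
#' age structure is stationary:
#' \deqn{\gamma = \frac{\sigma^{T} - \sigma^{T-1}}{\sigma^{T} - 1}.}
#' At `sigma = 1` the limiting value `1/duration` is returned; a one-year
#' stage always gives `gamma = 1` (survivors must exit).
#'
#' @param sigma Annual survival probability in `[0, 1]` (vectorised).
#' @param duration Stage duration, a positive integer in years (vectorised).
#' @return `gamma` in `[0, 1]`.
#' @examples
#' gamma_from_survival(0.9, 1)   # 1: a one-year stage is exited after one step
#' gamma_from_survival(1, 4)     # 0.25: limit 1/T as sigma -> 1
#' gamma_from_survival(0.8, 3)
#' @export
gamma_from_survival <- function(sigma, duration) {
  if (!is.numeric(sigma) || anyNA(sigma) || any(sigma < 0) || any(sigma > 1)) {
    abort("`sigma` must be in [0, 1].")
  }
  if (!is.numeric(duration) || anyNA(duration) || any(duration < 1) ||
      any(duration != round(duration))) {
    abort("`duration` must be a positive integer number of years.")
  }
  both <- vctrs_recycle(sigma, duration)
  sigma <- both[[1]]; duration <- both[[2]]
  out <- numeric(length(sigma))
  # sigma -> 1 is a 0/0 limit; switch to 1/T near 1 to avoid cancellation
  near_one <- sigma > 1 - 1e-9
  out[near_one] <- 1 / duration[near_one]
  i <- !near_one
  s <- sigma[i]; tt <- duration[i]
  out[i] <- (s^tt - s^(tt - 1)) / (s^tt - 1)
  out[duration == 1] <- 1
  out
}

# minimal common-length recycling without importing vctrs
vctrs_recycle <- function(x, y) {
  n <- max(length(x), length(y))
  list(rep_len(x, n), rep_len(y, n))
}
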