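# broom-style tidiers for the package's result objects

#' Tidy a transition matrix into one row per entry
#'
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @return A tibble with `from`, `to` (stage indices), `entry`, and `role`
#'   (`loop`, `growth`, `fertility`, `shrinkage`, `zero`).
#' @export
tidy.transition_matrix <- function(x, ...) {
  A <- x$A
  out <- tidyr::expand_grid(to = 1:5, from = 1:5)
  out$entry <- purrr::map2_dbl(out$to, out$from, function(i, j) A[i, j])
  out$role <- dplyr::case_when(
    out$to == 1 & out$from >= 4 & out$entry > 0 &
      (out$from - out$to) > 1 ~ "fertility",
    out$to == out$from & out$entry > 0 ~ "loop",
    out$to == out$from + 1 & out$entry > 0 ~ "growth",
    out$to == out$from - 1 & out$entry > 0 ~ "shrinkage",
    TRUE ~ "zero")
  dplyr::select(out, "from", "to", "entry", "role")
}

#' @export
glance.transition_matrix <- function(x, ...) {
  tibble::tibble(lambda = x$lambda,
                 fertility_4 = x$fertility[["fertility_4"]],
                 fertility_5 = x$fertility[["fertility_5"]],
                 growth_form = x$growth_form %||% NA_character_)
}

#' Tidy Monte-Carlo matrix results into per-trial eigenvalues
#'
#' @param x An `mc_matrices` object.
#' @param ... Unused.
#' @return The tibble of per-trial asymptotic growth rates.
#' @export
tidy.mc_matrices <- function(x, ...) x$lambda_samples

#' @export
glance.mc_matrices <- function(x, ...) {
  tibble::tibble(growth_form = x$growth_form,
                 n_trials = x$n_trials,
                 lambda_mean_matrix = x$mean_matrix$lambda,
                 lambda_min = min(x$lambda_samples$lambda),
                 lambda_max = max(x$lambda_samples$lambda),
                 lambda_sd = sd(x$lambda_samples$lambda))
}

#' Tidy an elasticity-over-fertility-grid result
#'
#' @param x An `elasticity_result`.
#' @param ... Unused.
#' @return A tibble with `from`, `to`, `mean_elasticity`, `sd_elasticity`.
#' @export
tidy.elasticity_result <- function(x, ...) {
  out <- tidyr::expand_grid(to = 1:5, from = 1:5)
  out$mean_elasticity <- purrr::map2_dbl(out$to, out$from,
                                         function(i, j) x$mean[i, j])
  out$sd_elasticity <- purrr::map2_dbl(out$to, out$from,
                                       function(i, j) x$sd[i, j])
  out
}

#' @export
glance.elasticity_result <- function(x, ...) {
  tibble::tibble(n_combinations = x$n_combinations,
                 grid_min = min(x$grid), grid_max = max(x$grid),
                 total_mean_elasticity = sum(x$mean))
}

#' @export
glance.scenario_result <- function(x, ...) {
  tibble::tibble(
    horizon = max(x$year),
    n_events = attr(x, "n_events"),
    relative_final_cover = attr(x, "relative_final_cover"),
    retention = attr(x, "retention"),
    final_cover_disturbed = tail(x$cover_disturbed, 1),
    final_cover_reference = tail(x$cover_reference, 1))
}

#' @export
tidy.scenario_result <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"year",
                      names_to = "run", names_prefix = "cover_",
                      values_to = "cover_cm2")
}

#' @export
glance.hindcast_fits <- function(x, ...) {
  tibble::tibble(n_combinations = nrow(x),
                 n_accepted = sum(x$accepted),
                 min_max_deviation = min(x$max_deviation),
                 subsampled = isTRUE(attr(x, "subsampled")))
}
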