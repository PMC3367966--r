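#' Define an impact scenario
#'
#' Combines the two mechanisms through which near-field (habitation) and
#' far-field (climate and environmental change) pressures enter the model:
#' a cumulative annual reduction of external recruitment, and episodic mass
#' mortality removing a fixed fraction of the non-recruit size classes at
#' regular intervals. The recruitment reduction is additive-cumulative: at
#' 1% per year, half the recruitment is lost by year 50.
#'
#' @param recruitment_loss_rate Percent of base recruitment lost per year,
#'   accumulating linearly (capped at 100%); e.g. 1 gives 50% loss at year
#'   50, 1.5 gives 75%.
#' @param episodic_mortality Fraction `m` in `[0, 1]` of the affected
#'   classes killed at each event (e.g. 0, 0.25, 0.5, 0.75).
#' @param event_interval Years between events (default 8); events fire
#'   after the year's projection step, first at `t = event_interval`.
#' @param affected_classes Classes hit by events; default `2:5`
#'   (non-recruit classes).
#' @param horizon Forecast length in years (default 50).
#' @return A list of class `impact_scenario`.
#' @export
impact_scenario <- function(recruitment_loss_rate = 0, episodic_mortality = 0,
                            event_interval = 8, affected_classes = 2:5,
                            horizon = 50) {
  check_scalar_number(recruitment_loss_rate, "recruitment_loss_rate", lower = 0)
  check_scalar_number(episodic_mortality, "episodic_mortality", 0, 1)
  check_scalar_number(event_interval, "event_interval", lower = 1)
  check_scalar_number(horizon, "horizon", lower = 1)
  affected_classes <- sort(unique(as.integer(affected_classes)))
  if (!all(affected_classes %in% 1:5)) abort("`affected_classes` must be within 1:5.")
  structure(
    list(recruitment_loss_rate = recruitment_loss_rate,
         episodic_mortality = episodic_mortality,
         event_interval = as.integer(event_interval),
         affected_classes = affected_classes,
         horizon = as.integer(horizon)),
    class = "impact_scenario"
  )
}

#' Recruitment schedule under cumulative annual reduction
#'
#' Year `t`'s import is `base_nu[t] * max(0, 1 - loss_rate * t / 100)`:
#' the loss accumulates additively so that a 1%/yr rate removes exactly
#' 50% of recruitment in year 50 and a 1.5%/yr rate removes 75%.
#'
#' @param base_nu Baseline yearly import, scalar or length-`horizon`
#'   vector.
#' @param loss_rate Percent lost per year, nonnegative.
#' @param horizon Number of years.
#' @return Length-`horizon` vector of reduced yearly imports.
#' @examples
#' recruitment_schedule(1000, 1, 50)[50]   # 500: half lost at year 50
#' recruitment_schedule(1000, 1.5, 50)[50] # 250: 75% lost
#' @export
recruitment_schedule <- function(base_nu, loss_rate, horizon) {
  check_scalar_number(loss_rate, "loss_rate", lower = 0)
  check_scalar_number(horizon, "horizon", lower = 1)
  horizon <- as.integer(horizon)
  base <- if (length(base_nu) == 1L) rep(base_nu, horizon) else as.numeric(base_nu)
  if (length(base) != horizon) {
    abort("`base_nu` must be a scalar or a vector of length `horizon`.")
  }
  if (any(base < 0)) abort("`base_nu` must be nonnegative.")
  base * pmax(0, 1 - loss_rate * seq_len(horizon) / 100)
}

#' Apply one episodic mortality event
#'
#' Multiplies the counts of the affected classes by `1 - mortality`,
#' leaving the other classes untouched.
#'
#' @param n 5-vector of class counts (or one-row tibble).
#' @param mortality Fraction killed, in `[0, 1]`.
#' @param affected_classes Classes hit (default non-recruit classes 2-5).
#' @return The post-event 5-vector.
#' @export
apply_episodic_mortality <- function(n, mortality, affected_classes = 2:5) {
  n <- check_count_vector(n, "n")
  check_scalar_number(mortality, "mortality", 0, 1)
  affected_classes <- as.integer(affected_classes)
  if (!all(affected_classes %in% 1:5)) abort("`affected_classes` must be within 1:5.")
  n[affected_classes] <- n[affected_classes] * (1 - mortality)
  n
}

#' Run a 50-year impact scenario against its undisturbed reference
#'
#' Simulates the disturbed trajectory (yearly projection with the reduced
#' recruitment schedule; after the projection step of every
#' `event_interval`-th year, the episodic mortality is applied) alongside
#' the paired undisturbed run (full recruitment, no events) from the same
#' initial population. A null scenario reproduces the reference exactly.
#'
#' @param tm A `transition_matrix` (zero fertility for the open-population
#'   forecasts).
#' @param n0 Initial 5-vector of class counts (or one-row tibble),
#'   typically an observed or hindcast size distribution.
#' @param base_recruitment Baseline yearly spat import (scalar or
#'   length-`horizon` vector), typically the modal hindcast recruitment.
#' @param scenario An [impact_scenario()].
#' @param config A [cover_config()] for the cover proxy.
#' @return A tibble of class `scenario_result` with columns `year`,
#'   `cover_disturbed`, `cover_reference` and attributes
#'   `relative_final_cover` (final disturbed / final undisturbed, %),
#'   `retention` (final disturbed / initial, %), `n_events`, `scenario`,
#'   and the two full class-count trajectories. Use [glance()] for the
#'   scalar summaries.
#' @export
run_scenario <- function(tm, n0, base_recruitment, scenario = impact_scenario(),
                         config = cover_config()) {
  if (!inherits(scenario, "impact_scenario")) {
    abort("`scenario` must be an impact_scenario().")
  }
  A <- as_projection_matrix(tm)
  n0 <- check_count_vector(n0, "n0")
  h <- scenario$horizon
  nus_ref <- recruitment_schedule(base_recruitment, 0, h)
  nus_dist <- recruitment_schedule(base_recruitment,
                                   scenario$recruitment_loss_rate, h)

  step <- function(n, nu) {
    out <- as.numeric(A %*% n)
    out[1] <- out[1] + nu
    out
  }
  traj_d <- matrix(0, h + 1L, N_STAGES); traj_d[1, ] <- n0
  traj_r <- matrix(0, h + 1L, N_STAGES); traj_r[1, ] <- n0
  nd <- n0; nr <- n0
  n_events <- 0L
  for (t in seq_len(h)) {
    nd <- step(nd, nus_dist[t])
    nr <- step(nr, nus_ref[t])
    if (scenario$episodic_mortality > 0 && t %% scenario$event_interval == 0) {
      nd <- apply_episodic_mortality(nd, scenario$episodic_mortality,
                                     scenario$affected_classes)
      n_events <- n_events + 1L
    }
    traj_d[t + 1L, ] <- nd
    traj_r[t + 1L, ] <- nr
  }
  cover_d <- as.numeric(traj_d %*% cover_weights(config))
  cover_r <- as.numeric(traj_r %*% cover_weights(config))
  out <- tibble::tibble(year = 0:h, cover_disturbed = cover_d,
                        cover_reference = cover_r)
  class(out) <- c("scenario_result", class(out))
  attr(out, "relative_final_cover") <- 100 * cover_d[h + 1] / cover_r[h + 1]
  attr(out, "retention") <- 100 * cover_d[h + 1] / cover_d[1]
  attr(out, "n_events") <- n_events
  attr(out, "scenario") <- scenario
  attr(out, "trajectory_disturbed") <- traj_d
  attr(out, "trajectory_reference") <- traj_r
  out
}

cover_weights <- function(config) {
  w <- rep(0, N_STAGES)
  w[config$classes] <- pi * config$radii[config$classes]^2
  w
}

#' Synergy grid of recruitment reduction and episodic mortality
#'
#' Evaluates [run_scenario()] over the factorial of annual recruitment-loss
#' rates and per-event mortality fractions and reports, for each cell, the
#' final cover relative to the completely undisturbed run (in percent).
#' In this linear model the surface is non-increasing along both axes, and
#' the (0, 0) cell is exactly 100%.
#'
#' @inheritParams run_scenario
#' @param loss_rates Vector of annual loss rates in percent per year.
#' @param mortalities Vector of per-event mortality fractions.
#' @param event_interval,affected_classes,horizon Passed to
#'   [impact_scenario()].
#' @return A tibble of class `synergy_grid`: `loss_rate`, `mortality`,
#'   `relative_final_cover`, `retention`.
#' @export
synergy_grid <- function(tm, n0, base_recruitment,
                         loss_rates = c(0, 0.5, 1, 1.5),
                         mortalities = c(0, 0.25, 0.5, 0.75),
                         event_interval = 8, affected_classes = 2:5,
                         horizon = 50, config = cover_config()) {
  if (length(loss_rates) == 0 || length(mortalities) == 0) {
    abort("`loss_rates` and `mortalities` must be nonempty.")
  }
  cells <- tidyr::expand_grid(loss_rate = sort(as.numeric(loss_rates)),
                              mortality = sort(as.numeric(mortalities)))
  res <- purrr::pmap_dfr(cells, function(loss_rate, mortality) {
    sc <- impact_scenario(recruitment_loss_rate = loss_rate,
                          episodic_mortality = mortality,
                          event_interval = event_interval,
                          affected_classes = affected_classes,
                          horizon = horizon)
    run <- run_scenario(tm, n0, base_recruitment, sc, config)
    tibble::tibble(loss_rate = loss_rate, mortality = mortality,
                   relative_final_cover = attr(run, "relative_final_cover"),
                   retention = attr(run, "retention"))
  })
  class(res) <- c("synergy_grid", class(res))
  res
}

#' Between-habitat homogenisation contrast
#'
#' Quantifies how different the final cover is across habitats under a
#' scenario: the range of final disturbed covers divided by their mean
#' (for two habitats, `|lagoon - ocean| / mean`). Recurrent heavy
#' mortality drives this contrast down — lagoonal cover becomes as low as
#' on ocean-facing reefs — when the habitats differ mainly in recruitment
#' level.
#'
#' @param results Named list (one entry per habitat, at least two) of
#'   `scenario_result` objects from [run_scenario()].
#' @return A one-row tibble: `n_habitats`, `contrast_disturbed`,
#'   `contrast_reference`.
#' @export
homogenization_contrast <- function(results) {
  if (!is.list(results) || length(results) < 2) {
    abort("`results` must be a list of scenario results for at least 2 habitats.")
  }
  finals_d <- purrr::map_dbl(results, function(r) {
    if (!inherits(r, "scenario_result")) abort("all entries must be scenario_result objects.")
    tail(r$cover_disturbed, 1)
  })
  finals_r <- purrr::map_dbl(results, function(r) tail(r$cover_reference, 1))
  contrast <- function(x) {
    m <- mean(x)
    if (m == 0) return(0)
    (max(x) - min(x)) / m
  }
  tibble::tibble(n_habitats = length(results),
                 contrast_disturbed = contrast(finals_d),
                 contrast_reference = contrast(finals_r))
}
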