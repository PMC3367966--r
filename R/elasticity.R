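#' Eigenvalue elasticity matrix
#'
#' Proportional sensitivity of the asymptotic growth rate \eqn{\lambda} to
#' proportional perturbations of each matrix entry:
#' \deqn{e_{ij} = \frac{a_{ij}}{\lambda}\,
#'       \frac{v_i w_j}{\langle v, w\rangle},}
#' with \eqn{w} and \eqn{v} the right (stable stage, scaled to sum 1) and
#' left (reproductive value, scaled so \eqn{\langle v,w\rangle = 1})
#' dominant eigenvectors. Elasticities are nonnegative for a nonnegative
#' matrix, vanish wherever \eqn{a_{ij} = 0}, and sum to one.
#'
#' @param A A `transition_matrix` or nonnegative square matrix with
#'   \eqn{\lambda > 0}.
#' @return A matrix of elasticities summing to 1.
#' @export
elasticity_matrix <- function(A) {
  A <- as_projection_matrix(A)
  ev <- dominant_eigenvectors(A)
  if (ev$lambda <= 0) abort("elasticity undefined for lambda = 0.")
  E <- (A / ev$lambda) * outer(ev$v, ev$w)
  dimnames(E) <- dimnames(A)
  E
}

#' Elasticities averaged over a fertility grid
#'
#' Substitutes every combination of the candidate fertility values into
#' positions `A[1,4]` and `A[1,5]` (all \eqn{|grid|^2} pairs, with no
#' ordering constraint) and reports the entrywise mean and standard
#' deviation of the resulting elasticity matrices. Each individual
#' elasticity matrix sums to one, so the mean does too.
#'
#' @param tm A `transition_matrix` (its current fertilities are replaced).
#' @param grid Positive candidate fertility values; default
#'   `c(1, 10, 100, 1000, 10000)` giving 25 combinations.
#' @return An object of class `elasticity_result`: list with `mean`, `sd`
#'   (5x5 matrices), `grid`, `n_combinations`, and `combinations` (tibble
#'   `fertility_4`, `fertility_5`, `lambda`).
#' @export
elasticity_over_fertility_grid <- function(tm, grid = c(1, 10, 100, 1000, 10000)) {
  if (!inherits(tm, "transition_matrix")) abort("`tm` must be a transition_matrix.")
  grid <- as.numeric(grid)
  if (length(grid) == 0 || anyNA(grid) || any(grid <= 0)) {
    abort("`grid` must be nonempty positive fertility values.")
  }
  combos <- tidyr::expand_grid(fertility_4 = grid, fertility_5 = grid)
  mats <- purrr::pmap(combos, function(fertility_4, fertility_5) {
    elasticity_matrix(set_fertility(tm, fertility_4, fertility_5))
  })
  lambdas <- purrr::map2_dbl(combos$fertility_4, combos$fertility_5,
                             function(f4, f5) set_fertility(tm, f4, f5)$lambda)
  arr <- array(unlist(mats), dim = c(N_STAGES, N_STAGES, length(mats)))
  sd_mat <- if (length(mats) == 1L) matrix(0, N_STAGES, N_STAGES) else
    apply(arr, 1:2, sd)
  structure(
    list(
      mean = apply(arr, 1:2, mean),
      sd = sd_mat,
      grid = grid,
      n_combinations = nrow(combos),
      combinations = dplyr::mutate(combos, lambda = lambdas)
    ),
    class = "elasticity_result"
  )
}

#' Global sensitivity of the projection model to its assumption factors
#'
#' Ranks three assumption factors by how much perturbing each one moves the
#' model outcome away from a control run: (A) fertility values in the
#' matrix, (B) the level of external recruitment (connectivity), and
#' (C) the timing of a fixed total of larval import across the run years.
#' For each factor, the projection is re-run over its variants with the
#' other factors held at control values; the factor's score is the total
#' proportional deviation \eqn{\sum_{variants}\sum_i |n_i - n^{ctrl}_i| /
#' \sum_i n^{ctrl}_i} of the final size-distribution vector (an L1 norm,
#' matching "total" deviation). Variants identical to the control
#' contribute zero.
#'
#' @param tm A `transition_matrix` giving the control matrix (its
#'   fertilities are the control fertilities).
#' @param n0 Initial 5-vector of class counts.
#' @param recruitment Control per-year import series (scalar or
#'   length-`years` vector).
#' @param years Projection length in years.
#' @param fertility_variants List of `c(fertility_4, fertility_5)` pairs.
#' @param recruitment_variants List of per-year series (scalars recycled).
#' @param timing_variants List of per-year series, typically permutations
#'   of the control series holding the total import fixed.
#' @return A `sensitivity_report` tibble: `factor`, `n_variants`,
#'   `total_deviation`, `rank` (1 = most influential).
#' @export
global_sensitivity <- function(tm, n0, recruitment, years,
                               fertility_variants,
                               recruitment_variants,
                               timing_variants) {
  if (!inherits(tm, "transition_matrix")) abort("`tm` must be a transition_matrix.")
  if (length(fertility_variants) == 0 || length(recruitment_variants) == 0 ||
      length(timing_variants) == 0) {
    abort("variant sets must be nonempty.")
  }
  n0 <- check_count_vector(n0, "n0")
  final_of <- function(A, rec) {
    traj <- project_series(A, n0, rec, years, mode = "mixed")
    counts_from_df(traj[nrow(traj), CLASS_COLS])
  }
  control <- final_of(tm, recruitment)
  dev <- function(x) sum(abs(x - control)) / sum(control)

  dev_fert <- sum(purrr::map_dbl(fertility_variants, function(f) {
    dev(final_of(set_fertility(tm, f[1], f[2]), recruitment))
  }))
  dev_rec <- sum(purrr::map_dbl(recruitment_variants, function(r) {
    dev(final_of(tm, r))
  }))
  dev_tim <- sum(purrr::map_dbl(timing_variants, function(r) {
    dev(final_of(tm, r))
  }))

  out <- tibble::tibble(
    factor = c("fertility", "recruitment_level", "recruitment_timing"),
    n_variants = c(length(fertility_variants), length(recruitment_variants),
                   length(timing_variants)),
    total_deviation = c(dev_fert, dev_rec, dev_tim)
  )
  out$rank <- rank(-out$total_deviation, ties.method = "min")
  class(out) <- c("sensitivity_report", class(out))
  out
}
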