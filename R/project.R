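#' Construct a size-distribution record
#'
#' A size distribution is a row of counts in the five radius-defined size
#' classes (spat <1 cm, recruits <5 cm, juveniles <10 cm, medium 10-20 cm,
#' large >20 cm radius), tagged with habitat, depth zone and year.
#'
#' @param counts Numeric vector of 5 nonnegative colony counts.
#' @param habitat `"lagoon"` or `"ocean_facing"`.
#' @param depth_zone Free-form depth label (e.g. `"10m"`).
#' @param year Integer survey year.
#' @return A one-row tibble with columns `habitat`, `depth_zone`, `year`,
#'   `class_1` .. `class_5`.
#' @export
size_distribution <- function(counts, habitat = c("lagoon", "ocean_facing"),
                              depth_zone = "10m", year = 2006L) {
  habitat <- match.arg(habitat)
  counts <- check_count_vector(counts, "counts")
  out <- tibble::tibble(habitat = habitat, depth_zone = depth_zone,
                        year = as.integer(year))
  out[CLASS_COLS] <- as.list(counts)
  out
}

#' Coral-cover proxy configuration
#'
#' Cover is approximated by giving every colony in a class the circular
#' area of a colony at the class's representative radius and summing.
#' Spat (class 1) are excluded by default: they are invisible in
#' phototransects and contribute negligible area.
#'
#' @param radii Representative radii in cm for the included classes, by
#'   default 1, 3, 5, 10 cm for classes 2-5.
#' @param classes Integer subset of `1:5` contributing to cover.
#' @return A list of class `cover_config`.
#' @export
cover_config <- function(radii = c(NA, 1, 3, 5, 10), classes = 2:5) {
  if (length(radii) == 4L) radii <- c(NA, radii)
  radii <- as.numeric(radii)
  if (length(radii) != N_STAGES) abort("`radii` must have 5 entries (class 1 may be NA).")
  classes <- sort(unique(as.integer(classes)))
  if (!all(classes %in% 1:5)) abort("`classes` must be a subset of 1:5.")
  if (anyNA(radii[classes]) || any(radii[classes] <= 0)) {
    abort("`radii` must be positive for every included class.")
  }
  structure(list(radii = radii, classes = classes), class = "cover_config")
}

#' Coral cover proxy of a size distribution
#'
#' Sums, over the included classes, count times the circular area
#' \eqn{\pi r^2} at the class's representative radius. Linear
#' (degree-one homogeneous) in the counts.
#'
#' @param n A 5-vector of class counts, a single-row size-distribution
#'   tibble, or a multi-row tibble with `class_1`..`class_5` columns
#'   (one cover value per row).
#' @param config A [cover_config()].
#' @return Cover in cm^2 (vectorised over rows for tibble input).
#' @examples
#' cover_from_distribution(c(0, 1, 0, 0, 0)) # pi, one 1-cm circle
#' @export
cover_from_distribution <- function(n, config = cover_config()) {
  if (!inherits(config, "cover_config")) abort("`config` must be a cover_config().")
  weights <- rep(0, N_STAGES)
  weights[config$classes] <- pi * config$radii[config$classes]^2
  if (is.data.frame(n) && nrow(n) > 1) {
    m <- as.matrix(n[, CLASS_COLS])
    return(as.numeric(m %*% weights))
  }
  n <- check_count_vector(n, "n")
  sum(n * weights)
}

#' One step of the affine projection with immigration
#'
#' Advances a size distribution one year:
#' \deqn{n(t+1) = A\,n(t) + \nu,}
#' where the immigration vector \eqn{\nu} is zero except for `nu` externally
#' supplied spat entering the smallest class.
#'
#' @param A A `transition_matrix` or 5x5 nonnegative matrix.
#' @param n Current 5-vector of class counts (or one-row tibble).
#' @param nu Nonnegative number of imported spat this year.
#' @return The next 5-vector of (real-valued) class counts.
#' @export
project_one_step <- function(A, n, nu = 0) {
  A <- as_projection_matrix(A)
  n <- check_count_vector(n, "n")
  check_scalar_number(nu, "nu", lower = 0)
  out <- as.numeric(A %*% n)
  out[1] <- out[1] + nu
  out
}

#' Project a population trajectory
#'
#' Iterates the affine projection over `years` annual steps. Counts are
#' kept real-valued throughout: the matrix model is an expectation model
#' and rounding would destroy its fixed-point structure.
#'
#' Recruitment modes:
#' * `"mixed"`: fertilities in `A` and the external supply `recruitment`
#'   both act.
#' * `"closed"`: no external supply; any nonzero `recruitment` is ignored
#'   with a warning and only the fertilities in `A` recruit.
#' * `"imported_only"`: `A` must carry zero fertility (error otherwise) and
#'   recruitment is exclusively external.
#'
#' @param A A `transition_matrix` or 5x5 nonnegative matrix.
#' @param n0 Initial 5-vector of class counts (or one-row tibble).
#' @param recruitment Scalar (constant) or length-`years` vector of yearly
#'   imported spat.
#' @param years Number of annual steps, at least 0.
#' @param mode Recruitment mode, see Details.
#' @param config [cover_config()] used for the `cover_cm2` column.
#' @return A tibble of class `coral_trajectory` with `years + 1` rows:
#'   `year` (0..years), `class_1`..`class_5`, `cover_cm2`.
#' @examples
#' lt <- life_table(c(0.02, 0.35, 0.65, 0.84, 0.92), c(1, 2, 3, 5))
#' tm <- build_transition_matrix(lt)
#' project_series(tm, rep(0, 5), recruitment = 1000, years = 8,
#'                mode = "imported_only")
#' @export
project_series <- function(A, n0, recruitment = 0, years,
                           mode = c("mixed", "closed", "imported_only"),
                           config = cover_config()) {
  mode <- match.arg(mode)
  tm_fert <- if (inherits(A, "transition_matrix")) A$fertility else
    c(fertility_4 = as_projection_matrix(A)[1, 4],
      fertility_5 = as_projection_matrix(A)[1, 5])
  A <- as_projection_matrix(A)
  n0 <- check_count_vector(n0, "n0")
  check_scalar_number(years, "years", lower = 0)
  years <- as.integer(years)
  nus <- if (length(recruitment) == 1L) rep(recruitment, max(years, 1L)) else
    as.numeric(recruitment)
  if (years > 0 && length(nus) != years) {
    abort("`recruitment` must be a scalar or a vector of length `years`.")
  }
  if (any(nus < 0)) abort("`recruitment` must be nonnegative.")
  if (mode == "closed" && any(nus > 0)) {
    warn("closed mode forces external recruitment to zero; ignoring `recruitment`.")
    nus[] <- 0
  }
  if (mode == "imported_only" && any(tm_fert > 0)) {
    abort("imported_only mode requires zero fertility in `A`.")
  }

  traj <- matrix(0, years + 1L, N_STAGES)
  traj[1, ] <- n0
  n <- n0
  if (years > 0) {
    for (t in seq_len(years)) {
      n <- as.numeric(A %*% n)
      n[1] <- n[1] + nus[t]
      traj[t + 1L, ] <- n
    }
  }
  out <- tibble::tibble(year = 0:years)
  out[CLASS_COLS] <- as.data.frame(traj)
  out$cover_cm2 <- cover_from_distribution(out, config)
  class(out) <- c("coral_trajectory", class(out))
  attr(out, "mode") <- mode
  out
}

#' Affine fixed point of projection with constant immigration
#'
#' When the asymptotic growth rate is below one, repeated projection with a
#' constant supply `nu` converges to \eqn{n^* = (I - A)^{-1} \nu e_1};
#' this solves for it directly.
#'
#' @param A A `transition_matrix` or 5x5 nonnegative matrix with spectral
#'   radius below 1.
#' @param nu Constant yearly spat import.
#' @return The equilibrium 5-vector.
#' @export
affine_fixed_point <- function(A, nu) {
  A <- as_projection_matrix(A)
  check_scalar_number(nu, "nu", lower = 0)
  if (dominant_eigenvalue(A) >= 1) {
    abort("fixed point requires spectral radius < 1.")
  }
  as.numeric(solve(diag(N_STAGES) - A, c(nu, rep(0, N_STAGES - 1))))
}
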