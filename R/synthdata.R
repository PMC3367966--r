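# Literature-style survivorship ranges and stage durations per growth form.
# Survival increases with stage (small corals die more); durations are
# short for fast-growing arborescent forms and long for massives. These
# are the package's documented defaults, not measured values; see the
# methods vignette for the calibration rationale.
life_table_priors <- function(growth_form) {
  switch(
    growth_form,
    arborescent = list(
      sigma_lo = c(0.010, 0.24, 0.53, 0.74, 0.83),
      sigma_hi = c(0.026, 0.36, 0.67, 0.84, 0.91),
      duration = c(1, 1, 2, 3, Inf)),
    branching_encrusting = list(
      sigma_lo = c(0.015, 0.28, 0.58, 0.80, 0.89),
      sigma_hi = c(0.035, 0.42, 0.72, 0.88, 0.95),
      duration = c(1, 2, 3, 5, Inf)),
    massive = list(
      sigma_lo = c(0.020, 0.33, 0.63, 0.86, 0.950),
      sigma_hi = c(0.040, 0.47, 0.77, 0.94, 0.985),
      duration = c(1, 4, 6, 10, Inf)),
    abort(sprintf("unknown growth form '%s'", growth_form))
  )
}

#' Generate a literature-style life-table pool
#'
#' Draws `n_samples` synthetic life-table samples for one growth form.
#' Per-stage survivorships are drawn uniformly within bounded, stage-wise
#' increasing ranges (small corals die more; the open-ended large class
#' survives best but always below 1), and stage durations are the
#' growth-form defaults (short for arborescent, long for massive corals).
#'
#' @param growth_form One of [GROWTH_FORMS].
#' @param n_samples Number of samples in the pool (default 10).
#' @param seed Optional integer seed.
#' @return A life-table tibble (5 rows per sample) suitable for
#'   [monte_carlo_mean_matrix()].
#' @export
generate_life_table_pool <- function(growth_form = "branching_encrusting",
                                     n_samples = 10, seed = NULL) {
  growth_form <- match.arg(growth_form, GROWTH_FORMS)
  check_scalar_number(n_samples, "n_samples", lower = 1)
  pri <- life_table_priors(growth_form)
  run_seeded(seed, {
    purrr::map_dfr(seq_len(n_samples), function(s) {
      sigma <- runif(N_STAGES, pri$sigma_lo, pri$sigma_hi)
      life_table(sigma, pri$duration, growth_form = growth_form,
                 source_label = sprintf("synthetic_%02d", s))
    })
  })
}

# radius -> size class, half-open [lower, upper) boundaries at 1,5,10,20 cm
class_from_radius <- function(r) {
  findInterval(r, c(0, 1, 5, 10, 20), left.open = FALSE)
}

# Area of a circle clipped to the rectangle [0,W] x [0,L], by integrating
# the clipped vertical chord over x. The substitution x = cx + r sin(theta)
# removes the square-root singularity at the circle's tangent points.
clipped_circle_area <- function(cx, cy, r, W, L) {
  if (cx - r >= 0 && cx + r <= W && cy - r >= 0 && cy + r <= L) {
    return(pi * r^2)
  }
  f <- function(theta) {
    h <- r * cos(theta)
    chord <- pmax(pmin(cy + h, L) - pmax(cy - h, 0), 0)
    chord * h
  }
  lo <- asin(min(max((max(cx - r, 0) - cx) / r, -1), 1))
  hi <- asin(min(max((min(cx + r, W) - cx) / r, -1), 1))
  if (hi <= lo) return(0)
  stats::integrate(f, lo, hi, rel.tol = 1e-8, subdivisions = 500L)$value
}

#' Simulate a phototransect of circular coral colonies
#'
#' Places colonies uniformly in a 0.5 x 20 m photo corridor (counts are
#' Poisson with mean `density * 10` per class), draws radii within each
#' class's radius band, and applies the edge-truncation bookkeeping used
#' when digitising photo corridors: colonies whose circle crosses the
#' corridor edge are flagged truncated; a truncated colony is included as a
#' large (class 5) colony if its true radius exceeds 20 cm or its visible
#' clipped area is at least that of a 20 cm-radius circle; a small
#' truncated colony is included only if its visible area still falls in
#' its true size class (unequivocal sizing), and excluded as ambiguous
#' otherwise. Spat (class 1) cannot be detected in photographs, so the
#' binned counts always report zero in class 1.
#'
#' @param density_per_m2 Numeric vector of 5 true colony densities per
#'   square metre, by size class.
#' @param seed Optional integer seed.
#' @param habitat,depth_zone,year Tags for the binned size distribution.
#' @param corridor `c(width_cm, length_cm)`, default `c(50, 2000)`.
#' @param radius_bands 2x5 matrix (rows: lower, upper radius in cm) from
#'   which radii are drawn uniformly per class.
#' @return A list with `colonies` (tibble: `x`, `y`, `radius`,
#'   `class_true`, `truncated`, `included`, `class_assigned`,
#'   `visible_area`) and `counts` (a one-row [size_distribution()] of the
#'   included colonies with class 1 forced to zero).
#' @export
simulate_phototransect <- function(density_per_m2, seed = NULL,
                                   habitat = "lagoon", depth_zone = "10m",
                                   year = 2006L,
                                   corridor = c(50, 2000),
                                   radius_bands = default_radius_bands()) {
  density_per_m2 <- check_count_vector(density_per_m2, "density_per_m2")
  W <- corridor[1]; L <- corridor[2]
  area_m2 <- W * L / 1e4
  run_seeded(seed, {
    cols <- purrr::map_dfr(seq_len(N_STAGES), function(k) {
      nk <- rpois(1, density_per_m2[k] * area_m2)
      if (nk == 0) {
        return(tibble::tibble(x = numeric(), y = numeric(), radius = numeric(),
                              class_true = integer()))
      }
      tibble::tibble(
        x = runif(nk, 0, W), y = runif(nk, 0, L),
        radius = runif(nk, radius_bands[1, k], radius_bands[2, k]),
        class_true = k)
    })
    if (nrow(cols) == 0) {
      counts <- size_distribution(rep(0, N_STAGES), habitat, depth_zone, year)
      return(list(colonies = cols, counts = counts))
    }
    cols$truncated <- cols$x - cols$radius < 0 | cols$x + cols$radius > W |
      cols$y - cols$radius < 0 | cols$y + cols$radius > L
    cols$visible_area <- pi * cols$radius^2
    trunc_idx <- which(cols$truncated)
    for (i in trunc_idx) {
      cols$visible_area[i] <- clipped_circle_area(cols$x[i], cols$y[i],
                                                  cols$radius[i], W, L)
    }
    big_area <- pi * 20^2
    assign_one <- function(radius, truncated, visible_area, class_true) {
      if (!truncated) return(class_true)
      if (radius > 20 || visible_area >= big_area) return(5L)
      visible_class <- class_from_radius(sqrt(visible_area / pi))
      if (visible_class == class_true) class_true else NA_integer_
    }
    cols$class_assigned <- purrr::pmap_int(
      cols[c("radius", "truncated", "visible_area", "class_true")], assign_one)
    cols$included <- !is.na(cols$class_assigned)
    binned <- tabulate(cols$class_assigned[cols$included], nbins = N_STAGES)
    binned[1] <- 0 # spat undetectable in phototransects
    list(colonies = cols,
         counts = size_distribution(binned, habitat, depth_zone, year))
  })
}

default_radius_bands <- function() {
  matrix(c(0.2, 1,  5, 10, 20,
           1.0, 5, 10, 20, 32), nrow = 2, byrow = TRUE)
}

#' Spat settlement required to produce a juvenile count
#'
#' Inverts a spat-survivorship assumption: `juveniles / survivorship`
#' settlers are needed to yield the observed juveniles (e.g. 220 juveniles
#' per transect at 1% survivorship require 22000 spat).
#'
#' @param juveniles Nonnegative juvenile count.
#' @param spat_survivorship Survivorship fraction in `(0, 1]`.
#' @return Required number of spat.
#' @examples
#' required_spat(220, 0.01) # 22000
#' @export
required_spat <- function(juveniles, spat_survivorship) {
  check_scalar_number(juveniles, "juveniles", lower = 0)
  check_scalar_number(spat_survivorship, "spat_survivorship")
  if (spat_survivorship <= 0 || spat_survivorship > 1) {
    abort("`spat_survivorship` must be in (0, 1].")
  }
  juveniles / spat_survivorship
}

#' The shipped chagos-like synthetic world
#'
#' Builds the package's default synthetic study system: Monte-Carlo mean
#' transition matrices for the three growth forms from generated life-table
#' pools, and two habitats that differ in larval supply — the lagoon
#' receives 1000 spat per year and the ocean-facing reef 100 (weak lagoonal
#' currents retain larvae) — each with a pre-disturbance population at the
#' open-population equilibrium and a mass-mortality start vector: the
#' lagoon retains a surviving fraction of 0.25 per class (the lagoonal
#' refuge with patchy survival) and the ocean-facing reef 0.01 (near-total
#' mortality). All generating parameters sit on the default hindcast grids
#' so closed-loop parameter recovery is exact.
#'
#' @param seed Integer seed controlling the pools and trials.
#' @param n_trials Monte-Carlo trials per growth form (default 10000).
#' @param growth_form Default growth form used for habitat populations.
#' @param n_samples Life-table samples per pool.
#' @return An object of class `synthetic_world`: list with `pools`,
#'   `matrices` (named lists by growth form), `growth_form`, `habitats`
#'   (tibble: `habitat`, `nu`, `start_fraction`, and list-columns
#'   `pre_disturbance`, `start_vector`), `seed`, `n_trials`.
#' @export
chagos_like_world <- function(seed = 20120605, n_trials = 10000,
                              growth_form = "branching_encrusting",
                              n_samples = 10) {
  growth_form <- match.arg(growth_form, GROWTH_FORMS)
  pools <- purrr::map(setNames(GROWTH_FORMS, GROWTH_FORMS), function(gf) {
    generate_life_table_pool(gf, n_samples = n_samples,
                             seed = seed + match(gf, GROWTH_FORMS))
  })
  matrices <- purrr::imap(pools, function(pool, gf) {
    monte_carlo_mean_matrix(pool, n_trials = n_trials,
                            seed = seed + 10L + match(gf, GROWTH_FORMS))
  })
  tm <- matrices[[growth_form]]$mean_matrix
  habitats <- tibble::tibble(
    habitat = c("lagoon", "ocean_facing"),
    nu = c(1000, 100),
    start_fraction = c(0.25, 0.01)
  )
  habitats$pre_disturbance <- purrr::map(habitats$nu,
                                         function(nu) affine_fixed_point(tm, nu))
  habitats$start_vector <- purrr::map2(habitats$pre_disturbance,
                                       habitats$start_fraction,
                                       function(pre, f) f * pre)
  structure(
    list(pools = pools, matrices = matrices, growth_form = growth_form,
         habitats = habitats, seed = seed, n_trials = as.integer(n_trials)),
    class = "synthetic_world"
  )
}

#' Generate a post-disturbance recovery fixture from a synthetic world
#'
#' Runs the world's true model forward from the true mass-mortality start
#' vectors with the true yearly imports, for each habitat, and returns the
#' resulting "observed" size distributions together with the generating
#' ground truth — the closed loop used for parameter-recovery testing.
#' Optional multiplicative lognormal observation noise can be added to the
#' class counts (default off: recovery tests need a clean baseline).
#'
#' @param world A [chagos_like_world()] (or compatible `synthetic_world`).
#' @param years Recovery length in years (default 8, i.e. 1998 to 2006).
#' @param noise_sd Standard deviation of the lognormal noise on the log
#'   scale; 0 disables noise.
#' @param seed Seed for the noise draws.
#' @return A list of class `recovery_fixture`: `observed` (size-distribution
#'   tibble, one row per habitat), `truth` (list: `nu`, `start_fraction`,
#'   `fertility`, `start_vectors`, `years`), and `world`.
#' @export
generate_recovery_fixture <- function(world, years = 8, noise_sd = 0,
                                      seed = NULL) {
  if (!inherits(world, "synthetic_world")) {
    abort("`world` must come from chagos_like_world().")
  }
  check_scalar_number(years, "years", lower = 0)
  tm <- world$matrices[[world$growth_form]]$mean_matrix
  obs <- purrr::pmap_dfr(world$habitats, function(habitat, nu, start_fraction,
                                                  pre_disturbance, start_vector) {
    traj <- project_series(tm, start_vector, nu, years, mode = "imported_only")
    n_final <- counts_from_df(traj[nrow(traj), CLASS_COLS])
    size_distribution(n_final, habitat = habitat, depth_zone = "10m",
                      year = 1998L + as.integer(years))
  })
  if (noise_sd > 0) {
    obs <- run_seeded(seed, {
      noisy <- as.matrix(obs[, CLASS_COLS])
      eps <- matrix(rnorm(length(noisy), mean = -noise_sd^2 / 2, sd = noise_sd),
                    nrow(noisy))
      obs[CLASS_COLS] <- as.data.frame(noisy * exp(eps))
      obs
    })
  }
  structure(
    list(observed = obs,
         truth = list(nu = setNames(world$habitats$nu, world$habitats$habitat),
                      start_fraction = setNames(world$habitats$start_fraction,
                                                world$habitats$habitat),
                      fertility = c(fertility_4 = 0, fertility_5 = 0),
                      start_vectors = setNames(world$habitats$start_vector,
                                               world$habitats$habitat),
                      years = as.integer(years)),
         world = world),
    class = "recovery_fixture"
  )
}
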