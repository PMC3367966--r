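#' Configuration for the hindcast grid search
#'
#' Defines the assumption grids enumerated when fitting the model to an
#' observed size distribution by forward projection from a post-disturbance
#' start: fertility pairs, candidate yearly spat imports, and "levels of
#' survival" fractions applied to a pre-disturbance distribution to form
#' candidate start vectors (an optional separate grid for class 5 allows
#' surviving large massives).
#'
#' @param pre_disturbance 5-vector: the population just before the mass
#'   mortality that anchors the hindcast. No default is claimed for real
#'   reefs; synthetic worlds supply their own (see [chagos_like_world()]).
#' @param fertility_grid Candidate fertilities substituted (factorially) at
#'   `A[1,4]` and `A[1,5]`; default `c(0, 10, 100, 1000, 10000)`.
#' @param nu_grid Candidate yearly spat numbers; default
#'   `c(0, 10, 100, 1000, 10000, 20000)` (the plausible set extended to
#'   the stated 0-20000 import range).
#' @param nu_mode `"constant"` (one grid value held for all years, default)
#'   or `"per_year"` (independent value each year; the factorial explodes
#'   and is subsampled above `max_combinations`).
#' @param start_fractions Scalar surviving fractions applied to all classes
#'   of `pre_disturbance`; default `c(0, 0.01, 0.05, 0.25)`, spanning
#'   near-total mortality to patchy survival.
#' @param class5_fractions Optional separate surviving-fraction grid for
#'   class 5 (crossed with `start_fractions`); `NULL` uses the scalar
#'   fraction for class 5 too.
#' @param years Projection length (default 8: 1998 to 2006).
#' @param exclude_largest If `TRUE`, class 5 is ignored when scoring fits.
#' @param deviation_threshold Acceptance threshold on per-class relative
#'   deviation (strict `<`; default 0.10).
#' @param max_combinations Cap on enumerated combinations (default 1e6).
#' @param subsample If `TRUE` (default), draw a seeded uniform subsample of
#'   size `max_combinations` when the factorial exceeds the cap; if
#'   `FALSE`, exceeding the cap is an error.
#' @param seed Seed for the subsample draw.
#' @return A list of class `hindcast_config`.
#' @export
hindcast_config <- function(pre_disturbance,
                            fertility_grid = c(0, 10, 100, 1000, 10000),
                            nu_grid = c(0, 10, 100, 1000, 10000, 20000),
                            nu_mode = c("constant", "per_year"),
                            start_fractions = c(0, 0.01, 0.05, 0.25),
                            class5_fractions = NULL,
                            years = 8,
                            exclude_largest = FALSE,
                            deviation_threshold = 0.10,
                            max_combinations = 1e6,
                            subsample = TRUE,
                            seed = 1L) {
  nu_mode <- match.arg(nu_mode)
  pre_disturbance <- check_count_vector(pre_disturbance, "pre_disturbance")
  if (length(fertility_grid) == 0 || any(fertility_grid < 0)) {
    abort("`fertility_grid` must be nonempty and nonnegative.")
  }
  if (length(nu_grid) == 0 || any(nu_grid < 0)) {
    abort("`nu_grid` must be nonempty and nonnegative.")
  }
  if (length(start_fractions) == 0 || any(start_fractions < 0 | start_fractions > 1)) {
    abort("`start_fractions` must be fractions in [0, 1].")
  }
  check_scalar_number(years, "years", lower = 1)
  structure(
    list(pre_disturbance = pre_disturbance,
         fertility_grid = sort(unique(as.numeric(fertility_grid))),
         nu_grid = sort(unique(as.numeric(nu_grid))),
         nu_mode = nu_mode,
         start_fractions = sort(unique(as.numeric(start_fractions))),
         class5_fractions = if (is.null(class5_fractions)) NULL else
           sort(unique(as.numeric(class5_fractions))),
         years = as.integer(years),
         exclude_largest = isTRUE(exclude_largest),
         deviation_threshold = deviation_threshold,
         max_combinations = max_combinations,
         subsample = isTRUE(subsample),
         seed = seed),
    class = "hindcast_config"
  )
}

# classes actually scored: drop class 5 if excluded, drop zero-observed
# classes (relative deviation undefined) with a warning
evaluated_classes <- function(observed, exclude_largest, warn_zero = TRUE) {
  classes <- seq_len(N_STAGES)
  if (exclude_largest) classes <- classes[-N_STAGES]
  zero <- classes[observed[classes] == 0]
  if (length(zero) > 0) {
    if (warn_zero) {
      warn(sprintf(
        "observed count is zero in class(es) %s; dropped from fit evaluation.",
        paste(zero, collapse = ", ")))
    }
    classes <- setdiff(classes, zero)
  }
  if (length(classes) == 0) abort("no classes left to evaluate.")
  classes
}

# Pearson chi-square with modeled counts as expected; adjacent cells with
# expected < 5 pooled left-to-right; df = cells - 1
pearson_chi_square <- function(modeled, observed) {
  stopifnot(length(modeled) == length(observed))
  exp_pool <- c(); obs_pool <- c()
  acc_e <- 0; acc_o <- 0
  for (i in seq_along(modeled)) {
    acc_e <- acc_e + modeled[i]; acc_o <- acc_o + observed[i]
    if (acc_e >= 5 || i == length(modeled)) {
      exp_pool <- c(exp_pool, acc_e); obs_pool <- c(obs_pool, acc_o)
      acc_e <- 0; acc_o <- 0
    }
  }
  # a trailing underfilled cell is merged backwards
  k <- length(exp_pool)
  if (k > 1 && exp_pool[k] < 5) {
    exp_pool[k - 1] <- exp_pool[k - 1] + exp_pool[k]
    obs_pool[k - 1] <- obs_pool[k - 1] + obs_pool[k]
    exp_pool <- exp_pool[-k]; obs_pool <- obs_pool[-k]
    k <- k - 1
  }
  if (any(exp_pool == 0)) {
    return(list(statistic = Inf, df = k - 1L, p_value = 0))
  }
  stat <- sum((obs_pool - exp_pool)^2 / exp_pool)
  df <- k - 1L
  p <- if (df >= 1) pchisq(stat, df, lower.tail = FALSE) else NA_real_
  list(statistic = stat, df = df, p_value = p)
}

#' Score a modeled size distribution against an observed one
#'
#' Computes the per-class relative deviation `|modeled - observed| /
#' observed` and accepts the fit iff every evaluated class deviates by
#' strictly less than the threshold (default 10%). Classes with an observed
#' count of zero are dropped with a warning (the relative deviation is
#' undefined there), and class 5 can be excluded altogether, as needed for
#' shallow-lagoon populations where asexual recruitment produces large
#' colonies faster than the model. A Pearson chi-square statistic over the
#' evaluated classes (modeled counts as expected, adjacent pooling of cells
#' with expected below 5) is attached.
#'
#' @param modeled,observed 5-vectors of class counts (or one-row tibbles).
#' @param exclude_largest If `TRUE`, ignore class 5.
#' @param threshold Acceptance threshold (strict `<`), default 0.10.
#' @return A list of class `fit_result`: `accepted`, `deviations` (length 5,
#'   `NA` where not evaluated), `max_deviation`, `evaluated_classes`,
#'   `chi_square`, `df`, `p_value`, `threshold`.
#' @export
evaluate_fit <- function(modeled, observed, exclude_largest = FALSE,
                         threshold = 0.10) {
  modeled <- check_count_vector(modeled, "modeled")
  observed <- check_count_vector(observed, "observed")
  classes <- evaluated_classes(observed, exclude_largest)
  deviations <- rep(NA_real_, N_STAGES)
  deviations[classes] <- abs(modeled[classes] - observed[classes]) / observed[classes]
  chi <- pearson_chi_square(modeled[classes], observed[classes])
  structure(
    list(accepted = all(deviations[classes] < threshold),
         deviations = setNames(deviations, CLASS_COLS),
         max_deviation = max(deviations[classes]),
         evaluated_classes = classes,
         chi_square = chi$statistic, df = chi$df, p_value = chi$p_value,
         threshold = threshold),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s (max deviation %.4g, threshold %g)\n",
              if (x$accepted) "ACCEPTED" else "rejected",
              x$max_deviation, x$threshold))
  cat("  classes evaluated:", paste(x$evaluated_classes, collapse = ", "), "\n")
  cat(sprintf("  chi-square %.4g on %d df (p = %.3g)\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

# Candidate start vectors from survival fractions
start_candidates <- function(config) {
  base <- config$pre_disturbance
  if (is.null(config$class5_fractions)) {
    tibble::tibble(start_fraction = config$start_fractions,
                   class5_fraction = config$start_fractions)
  } else {
    tidyr::expand_grid(start_fraction = config$start_fractions,
                       class5_fraction = config$class5_fractions)
  }
}

# Candidate per-year import series as a matrix (years x n_candidates)
nu_candidates <- function(config) {
  years <- config$years
  if (config$nu_mode == "constant") {
    matrix(rep(config$nu_grid, each = years), nrow = years)
  } else {
    n_all <- length(config$nu_grid)^years
    grids <- rep(list(config$nu_grid), years)
    names(grids) <- paste0("y", seq_len(years))
    full <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
    t(full)
  }
}

#' Enumerate assumption combinations and score hindcast fits
#'
#' Projects the population forward from every candidate (fertility pair,
#' start vector, yearly import series) combination in the configuration and
#' scores each final modeled size distribution against the observed one
#' with [evaluate_fit()]'s criterion. The affine projection is linear in
#' the start vector and the import series
#' (\eqn{n(T) = A^T n_0 + \sum_t A^{T-t} e_1 \nu_t}), which lets whole
#' grids be evaluated with a handful of matrix products; tests assert
#' equality with step-by-step projection. The chi-square statistic is
#' computed for accepted solutions only.
#'
#' If the factorial exceeds `max_combinations` and subsampling is enabled,
#' a seeded uniform subsample of combinations is scored instead (the
#' per-year import mode needs this: 6 grid values over 8 years alone give
#' about 1.7 million series).
#'
#' @param tm Mean `transition_matrix` for the growth form (fertility
#'   entries are overwritten by the grid).
#' @param observed Observed 5-vector (or one-row size-distribution tibble)
#'   at the end of the hindcast window.
#' @param config A [hindcast_config()].
#' @return A tibble of class `hindcast_fits`, one row per combination:
#'   `fertility_4`, `fertility_5`, `start_fraction`, `class5_fraction`,
#'   `nu_1..nu_years`, `modeled_1..5`, `dev_1..5`, `max_deviation`,
#'   `accepted`, `chi_square`, `df`, `p_value`. Attributes: `config`,
#'   `observed`, `evaluated_classes`, `subsampled`.
#' @export
enumerate_and_fit <- function(tm, observed, config) {
  if (!inherits(tm, "transition_matrix")) abort("`tm` must be a transition_matrix.")
  if (!inherits(config, "hindcast_config")) abort("`config` must be a hindcast_config().")
  observed <- check_count_vector(observed, "observed")
  classes <- evaluated_classes(observed, config$exclude_largest)

  starts <- start_candidates(config)
  nus <- nu_candidates(config) # years x V
  ferts <- tidyr::expand_grid(fertility_4 = config$fertility_grid,
                              fertility_5 = config$fertility_grid)
  years <- config$years

  n_total <- nrow(ferts) * nrow(starts) * ncol(nus)
  subsampled <- FALSE
  if (n_total > config$max_combinations) {
    if (!config$subsample) {
      abort(sprintf(
        "%.3g combinations exceed max_combinations = %.3g and subsampling is disabled.",
        n_total, config$max_combinations))
    }
    subsampled <- TRUE
    idx <- run_seeded(config$seed, {
      tibble::tibble(
        fert = sample.int(nrow(ferts), config$max_combinations, replace = TRUE),
        start = sample.int(nrow(starts), config$max_combinations, replace = TRUE),
        nu = sample.int(ncol(nus), config$max_combinations, replace = TRUE))
    })
  } else {
    idx <- tidyr::expand_grid(fert = seq_len(nrow(ferts)),
                              start = seq_len(nrow(starts)),
                              nu = seq_len(ncol(nus)))
  }

  # start vectors as a 5 x S matrix
  n0s <- vapply(seq_len(nrow(starts)), function(s) {
    n0 <- starts$start_fraction[s] * config$pre_disturbance
    n0[N_STAGES] <- starts$class5_fraction[s] * config$pre_disturbance[N_STAGES]
    n0
  }, numeric(N_STAGES))
  n0s <- matrix(n0s, nrow = N_STAGES)

  pieces <- vector("list", nrow(ferts))
  for (f in seq_len(nrow(ferts))) {
    rows_f <- idx[idx$fert == f, , drop = FALSE]
    if (nrow(rows_f) == 0) next
    A <- set_fertility(tm, ferts$fertility_4[f], ferts$fertility_5[f])$A
    # A^years and the import response columns A^(years-t) e1
    pows <- vector("list", years + 1L)
    pows[[1]] <- diag(N_STAGES)
    for (k in seq_len(years)) pows[[k + 1]] <- A %*% pows[[k]]
    C <- vapply(seq_len(years), function(t) pows[[years - t + 1]][, 1],
                numeric(N_STAGES)) # 5 x years
    C <- matrix(C, nrow = N_STAGES)
    start_part <- pows[[years + 1]] %*% n0s # 5 x S
    nu_part <- C %*% nus                    # 5 x V
    finals <- start_part[, rows_f$start, drop = FALSE] +
      nu_part[, rows_f$nu, drop = FALSE]   # 5 x n_f

    devs <- abs(finals[classes, , drop = FALSE] - observed[classes]) /
      observed[classes]
    max_dev <- apply(devs, 2, max)
    accepted <- max_dev < config$deviation_threshold

    piece <- tibble::tibble(
      fertility_4 = ferts$fertility_4[f],
      fertility_5 = ferts$fertility_5[f],
      start_fraction = starts$start_fraction[rows_f$start],
      class5_fraction = starts$class5_fraction[rows_f$start])
    nu_mat <- t(nus[, rows_f$nu, drop = FALSE])
    colnames(nu_mat) <- paste0("nu_", seq_len(years))
    piece <- dplyr::bind_cols(piece, tibble::as_tibble(nu_mat))
    mod_mat <- t(finals)
    colnames(mod_mat) <- paste0("modeled_", seq_len(N_STAGES))
    piece <- dplyr::bind_cols(piece, tibble::as_tibble(mod_mat))
    dev_full <- matrix(NA_real_, nrow(piece), N_STAGES)
    dev_full[, classes] <- t(devs)
    colnames(dev_full) <- paste0("dev_", seq_len(N_STAGES))
    piece <- dplyr::bind_cols(piece, tibble::as_tibble(dev_full))
    piece$max_deviation <- max_dev
    piece$accepted <- accepted
    pieces[[f]] <- piece
  }
  out <- dplyr::bind_rows(pieces)

  chi_cols <- tibble::tibble(chi_square = rep(NA_real_, nrow(out)),
                             df = NA_integer_, p_value = NA_real_)
  acc_idx <- which(out$accepted)
  for (i in acc_idx) {
    modeled <- as.numeric(out[i, paste0("modeled_", classes)])
    chi <- pearson_chi_square(modeled, observed[classes])
    chi_cols$chi_square[i] <- chi$statistic
    chi_cols$df[i] <- chi$df
    chi_cols$p_value[i] <- chi$p_value
  }
  out <- dplyr::bind_cols(out, chi_cols)
  class(out) <- c("hindcast_fits", class(out))
  attr(out, "config") <- config
  attr(out, "observed") <- observed
  attr(out, "evaluated_classes") <- classes
  attr(out, "subsampled") <- subsampled
  out
}

#' Summarise accepted hindcast solutions as per-year recruitment bounds
#'
#' Over the accepted solutions, reports for every model year the minimum,
#' maximum and modal number of imported spat. The mode is taken over the
#' exact grid values, with ties broken toward the smaller value, and is the
#' recruitment series used for forecast runs. An empty accepted set yields
#' a zero-row summary (attribute `n_accepted = 0`), not an error.
#'
#' @param fits A `hindcast_fits` tibble from [enumerate_and_fit()].
#' @return A tibble of class `recruitment_summary`: `year`, `nu_min`,
#'   `nu_mode`, `nu_max`; attribute `n_accepted`.
#' @export
summarize_recruitment <- function(fits) {
  if (!inherits(fits, "hindcast_fits")) abort("`fits` must come from enumerate_and_fit().")
  acc <- dplyr::filter(fits, .data$accepted)
  nu_cols <- grep("^nu_", names(fits), value = TRUE)
  if (nrow(acc) == 0) {
    out <- tibble::tibble(year = integer(), nu_min = numeric(),
                          nu_mode = numeric(), nu_max = numeric())
  } else {
    out <- purrr::map_dfr(seq_along(nu_cols), function(j) {
      x <- acc[[nu_cols[j]]]
      tibble::tibble(year = j, nu_min = min(x), nu_mode = modal_value(x),
                     nu_max = max(x))
    })
  }
  class(out) <- c("recruitment_summary", class(out))
  attr(out, "n_accepted") <- nrow(acc)
  out
}

#' @export
print.recruitment_summary <- function(x, ...) {
  n <- attr(x, "n_accepted")
  if (n == 0) {
    cat("<recruitment_summary> no accepted solutions\n")
    return(invisible(x))
  }
  cat(sprintf("<recruitment_summary> over %d accepted solutions\n", n))
  NextMethod()
  invisible(x)
}
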