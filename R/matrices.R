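new_transition_matrix <- function(A, sigma, duration, gamma, fertility,
                                  growth_form = NULL, shrinkage = NULL) {
  dimnames(A) <- list(STAGE_LABELS, STAGE_LABELS)
  structure(
    list(
      A = A,
      P = unname(diag(A)),
      G = unname(A[cbind(2:N_STAGES, 1:(N_STAGES - 1))]),
      fertility = fertility,
      lambda = dominant_eigenvalue(A),
      sigma = sigma,
      duration = duration,
      gamma = gamma,
      growth_form = growth_form,
      shrinkage = shrinkage
    ),
    class = "transition_matrix"
  )
}

#' Build a five-stage coral transition matrix from a life table
#'
#' Assembles the Lefkovitch projection matrix `A` for one growth form.
#' For stages 1-4 the growth rate \eqn{G_i = \sigma_i \gamma_i} is placed on
#' the subdiagonal and the loop \eqn{P_i = \sigma_i (1 - \gamma_i)} on the
#' diagonal, so that \eqn{G_i + P_i = \sigma_i}. The open-ended fifth stage
#' is absorbing: \eqn{P_5 = \sigma_5} and there is no onward growth term.
#' Fertility (local recruitment, including asexual propagation into stage 1)
#' may enter only at positions `A[1,4]` and `A[1,5]`: only the two largest,
#' sexually mature classes reproduce, and fertility is taken to increase
#' steeply from class 4 to class 5 (default `fertility_5 = 10 * fertility_4`,
#' and `fertility_5 >= fertility_4` is enforced; use [set_fertility()] for
#' unconstrained grid substitution).
#'
#' Tissue loss without colony death ("shrinkage" by predation, breakage or
#' partial mortality) is by default absorbed into the diagonal loops. The
#' optional `shrinkage` argument instead makes it explicit: a fraction
#' `shrinkage[i]` of the surviving non-growing individuals of stage i drops
#' one class (a superdiagonal entry), for use in degradation scenarios.
#' Column sums (less fertility) still equal the stage survivals.
#'
#' @param life_table A single life-table sample as returned by
#'   [life_table()] (or one sample's rows of a pool).
#' @param fertility_4,fertility_5 Nonnegative per-capita recruitment of
#'   stages 4 and 5 into stage 1. Default 0 (fully open population).
#' @param gamma_method `"fixed_duration"` (default) uses
#'   [gamma_from_survival()]; `"lambda_iterative"` replaces \eqn{\sigma}
#'   by \eqn{\sigma/\lambda} in the stage-advance formula and solves for
#'   \eqn{\lambda} by fixed-point iteration.
#' @param shrinkage Optional numeric vector of 5 per-stage retrogression
#'   fractions in `[0, 1]` (entry 1 is ignored: stage 1 cannot shrink).
#' @return A `transition_matrix` object: list with the 5x5 matrix `A`,
#'   loops `P`, growth rates `G`, `fertility`, dominant eigenvalue
#'   `lambda`, and the generating `sigma`, `duration`, `gamma`.
#' @examples
#' lt <- life_table(c(0.02, 0.35, 0.65, 0.84, 0.92), c(1, 2, 3, 5))
#' tm <- build_transition_matrix(lt)
#' tm$lambda # < 1 without fertility
#' @export
build_transition_matrix <- function(life_table, fertility_4 = 0,
                                    fertility_5 = NULL,
                                    gamma_method = c("fixed_duration",
                                                     "lambda_iterative"),
                                    shrinkage = NULL) {
  gamma_method <- match.arg(gamma_method)
  if (is.data.frame(life_table)) {
    validate_life_tables(life_table)
    if (dplyr::n_distinct(life_table$source_label) != 1L ||
        dplyr::n_distinct(life_table$growth_form) != 1L) {
      abort("`life_table` must be a single sample; use monte_carlo_mean_matrix() for pools.")
    }
    life_table <- life_table[order(life_table$stage), ]
    sigma <- life_table$sigma
    duration <- life_table$duration
    growth_form <- life_table$growth_form[1]
  } else {
    abort("`life_table` must be a life-table tibble; see life_table().")
  }
  check_scalar_number(fertility_4, "fertility_4", lower = 0)
  if (is.null(fertility_5)) fertility_5 <- 10 * fertility_4
  check_scalar_number(fertility_5, "fertility_5", lower = 0)
  if (fertility_4 > 0 && fertility_5 < fertility_4) {
    abort("`fertility_5` must be >= `fertility_4` (fertility increases with size).")
  }
  if (!is.null(shrinkage)) {
    shrinkage <- as.numeric(shrinkage)
    if (length(shrinkage) != N_STAGES || anyNA(shrinkage) ||
        any(shrinkage < 0) || any(shrinkage > 1)) {
      abort("`shrinkage` must be 5 fractions in [0, 1].")
    }
  }

  if (gamma_method == "fixed_duration") {
    gamma <- c(gamma_from_survival(pmax(sigma[1:4], 0), duration[1:4]), 0)
    A <- assemble_matrix(sigma, gamma, fertility_4, fertility_5, shrinkage)
  } else {
    # replace sigma by sigma/lambda in the stage-advance formula and iterate
    lambda <- 1
    for (iter in 1:200) {
      ratio <- pmin(sigma[1:4] / lambda, 1)
      gamma <- c(gamma_from_survival(ratio, duration[1:4]), 0)
      A <- assemble_matrix(sigma, gamma, fertility_4, fertility_5, shrinkage)
      lambda_new <- dominant_eigenvalue(A)
      if (lambda_new <= 0) break
      if (abs(lambda_new - lambda) < 1e-12) break
      lambda <- lambda_new
    }
  }
  new_transition_matrix(A, sigma, duration, gamma,
                        fertility = c(fertility_4 = fertility_4,
                                      fertility_5 = fertility_5),
                        growth_form = growth_form, shrinkage = shrinkage)
}

assemble_matrix <- function(sigma, gamma, fertility_4, fertility_5,
                            shrinkage = NULL) {
  A <- matrix(0, N_STAGES, N_STAGES)
  stay <- sigma * (1 - gamma) # survivors that do not advance
  for (i in 1:(N_STAGES - 1)) {
    A[i, i] <- stay[i]
    A[i + 1, i] <- sigma[i] * gamma[i]
  }
  A[N_STAGES, N_STAGES] <- stay[N_STAGES]
  if (!is.null(shrinkage)) {
    for (i in 2:N_STAGES) {
      drop_i <- A[i, i] * shrinkage[i]
      A[i - 1, i] <- A[i - 1, i] + drop_i
      A[i, i] <- A[i, i] - drop_i
    }
  }
  A[1, 4] <- A[1, 4] + fertility_4
  A[1, 5] <- A[1, 5] + fertility_5
  A
}

#' Replace the fertility entries of a transition matrix
#'
#' Substitutes new values at positions `A[1,4]` and `A[1,5]` and recomputes
#' the dominant eigenvalue. Unlike [build_transition_matrix()] no ordering
#' between the two fertilities is enforced, so that factorial grids (all
#' combinations of candidate fertilities) can be scanned.
#'
#' @param tm A `transition_matrix`.
#' @param fertility_4,fertility_5 Nonnegative replacement values.
#' @return A new `transition_matrix`.
#' @export
set_fertility <- function(tm, fertility_4, fertility_5) {
  if (!inherits(tm, "transition_matrix")) {
    abort("`tm` must be a transition_matrix.")
  }
  check_scalar_number(fertility_4, "fertility_4", lower = 0)
  check_scalar_number(fertility_5, "fertility_5", lower = 0)
  A <- tm$A
  base <- A
  base[1, 4] <- base[1, 4] - tm$fertility[["fertility_4"]]
  base[1, 5] <- base[1, 5] - tm$fertility[["fertility_5"]]
  base[1, 4] <- base[1, 4] + fertility_4
  base[1, 5] <- base[1, 5] + fertility_5
  new_transition_matrix(base, tm$sigma, tm$duration, tm$gamma,
                        fertility = c(fertility_4 = fertility_4,
                                      fertility_5 = fertility_5),
                        growth_form = tm$growth_form, shrinkage = tm$shrinkage)
}

#' Dominant eigenvalue (asymptotic growth rate) of a projection matrix
#'
#' Returns the spectral radius of a nonnegative matrix, the long-run annual
#' multiplication factor of the corresponding closed population. Without
#' fertility the coral matrix is lower triangular and the spectral radius
#' is read off the diagonal exactly; otherwise a dense eigendecomposition
#' is used (for a nonnegative matrix the Perron root is real and equals
#' the largest eigenvalue modulus).
#'
#' @param A A `transition_matrix` or a nonnegative square numeric matrix.
#' @return The spectral radius, a nonnegative number.
#' @examples
#' dominant_eigenvalue(diag(5) * 0.5) # 0.5
#' @export
dominant_eigenvalue <- function(A) {
  A <- as_projection_matrix(A)
  if (all(A[upper.tri(A)] == 0)) {
    return(max(diag(A)))
  }
  max(Mod(eigen(A, only.values = TRUE)$values))
}

# Right (stable stage, sum 1) and left (reproductive value, <v,w> = 1)
# dominant eigenvectors of a nonnegative matrix.
dominant_eigenvectors <- function(A) {
  er <- eigen(A)
  k <- which.max(Mod(er$values))
  w <- Re(er$vectors[, k])
  if (sum(w) < 0) w <- -w
  w <- w / sum(w)
  el <- eigen(t(A))
  kl <- which.max(Mod(el$values))
  v <- Re(el$vectors[, kl])
  if (sum(v) < 0) v <- -v
  v <- v / sum(v * w)
  list(lambda = Mod(er$values[k]), w = w, v = v)
}

#' Monte-Carlo mean transition matrix from a life-table pool
#'
#' Emulates life-table uncertainty analysis: in each trial, every stage's
#' (survival, duration) pair is drawn independently and uniformly from the
#' pool entries available for that stage, a transition matrix is built, and
#' its asymptotic growth rate recorded. The arithmetic mean matrix over all
#' trials (samples are unrelated repeat estimates) is returned together
#' with the per-trial eigenvalues, whose spread measures parameter
#' uncertainty. Without fertility every trial matrix is substochastic, so
#' all eigenvalues are below one.
#'
#' @param pool Life-table tibble holding one or more samples of a single
#'   growth form (rows as in [life_table()]).
#' @param n_trials Number of Monte-Carlo trials (default 10000).
#' @param seed Optional integer seed; the result is reproducible given the
#'   seed.
#' @param fertility_4,fertility_5 Fertilities applied to every trial matrix
#'   (default 0).
#' @return An object of class `mc_matrices`: list with `mean_matrix`
#'   (a `transition_matrix`), `lambda_samples` (tibble `trial`, `lambda`),
#'   `n_trials`, `seed`, `growth_form`.
#' @examples
#' pool <- generate_life_table_pool("massive", n_samples = 4, seed = 1)
#' mc <- monte_carlo_mean_matrix(pool, n_trials = 200, seed = 2)
#' mc$mean_matrix$lambda
#' @export
monte_carlo_mean_matrix <- function(pool, n_trials = 10000, seed = NULL,
                                    fertility_4 = 0, fertility_5 = 0) {
  validate_life_tables(pool)
  if (nrow(pool) == 0) abort("`pool` is empty.")
  if (dplyr::n_distinct(pool$growth_form) != 1L) {
    abort("`pool` must contain a single growth form; split and call per form.")
  }
  check_scalar_number(n_trials, "n_trials", lower = 1)
  growth_form <- pool$growth_form[1]

  by_stage <- lapply(seq_len(N_STAGES), function(i) {
    rows <- pool[pool$stage == i, c("sigma", "duration")]
    as.matrix(rows)
  })

  draws <- run_seeded(seed, {
    vapply(by_stage, function(m) sample.int(nrow(m), n_trials, replace = TRUE),
           integer(n_trials))
  })
  draws <- matrix(draws, nrow = n_trials) # n_trials x 5 indices

  sigma_draws <- matrix(vapply(seq_len(N_STAGES),
                               function(i) by_stage[[i]][draws[, i], "sigma"],
                               numeric(n_trials)), nrow = n_trials)
  dur_draws <- matrix(vapply(seq_len(N_STAGES),
                             function(i) by_stage[[i]][draws[, i], "duration"],
                             numeric(n_trials)), nrow = n_trials)

  # per-trial entries, vectorised over trials
  gamma_draws <- matrix(0, n_trials, N_STAGES)
  for (i in 1:(N_STAGES - 1)) {
    gamma_draws[, i] <- gamma_from_survival(sigma_draws[, i], dur_draws[, i])
  }
  P_draws <- sigma_draws * (1 - gamma_draws)
  G_draws <- sigma_draws[, 1:4] * gamma_draws[, 1:4]

  trial_lambda <- if (fertility_4 == 0 && fertility_5 == 0) {
    # zero fertility: lower-triangular matrices, lambda = max loop
    apply(P_draws, 1, max)
  } else {
    vapply(seq_len(n_trials), function(t) {
      A <- assemble_matrix(sigma_draws[t, ], c(gamma_draws[t, 1:4], 0),
                           fertility_4, fertility_5)
      dominant_eigenvalue(A)
    }, numeric(1))
  }

  sigma_mean <- colMeans(sigma_draws)
  gamma_mean <- colMeans(gamma_draws)
  A_mean <- matrix(0, N_STAGES, N_STAGES)
  diag(A_mean) <- colMeans(P_draws)
  A_mean[cbind(2:5, 1:4)] <- colMeans(G_draws)
  A_mean[1, 4] <- A_mean[1, 4] + fertility_4
  A_mean[1, 5] <- A_mean[1, 5] + fertility_5

  mean_matrix <- new_transition_matrix(
    A_mean, sigma_mean, colMeans(dur_draws), gamma_mean,
    fertility = c(fertility_4 = fertility_4, fertility_5 = fertility_5),
    growth_form = growth_form)

  structure(
    list(
      mean_matrix = mean_matrix,
      lambda_samples = tibble::tibble(trial = seq_len(n_trials),
                                      lambda = trial_lambda),
      n_trials = as.integer(n_trials),
      seed = seed,
      growth_form = growth_form
    ),
    class = "mc_matrices"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix%s>  lambda = %.4f\n",
              if (!is.null(x$growth_form)) paste0(": ", x$growth_form) else "",
              x$lambda))
  print(round(x$A, 4))
  invisible(x)
}

#' @export
print.mc_matrices <- function(x, ...) {
  rng <- range(x$lambda_samples$lambda)
  cat(sprintf(
    "<mc_matrices: %s>  %d trials, mean-matrix lambda = %.4f, trial lambda in [%.4f, %.4f]\n",
    x$growth_form, x$n_trials, x$mean_matrix$lambda, rng[1], rng[2]))
  print(round(x$mean_matrix$A, 4))
  invisible(x)
}
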