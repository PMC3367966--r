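test_that("stage-advance probability follows the fixed-duration form", {
  # one-year stages are always exited by survivors; sigma -> 1 gives 1/T
  expect_equal(gamma_from_survival(0.9, 1), 1)
  expect_equal(gamma_from_survival(1, 4), 0.25)
  expect_equal(gamma_from_survival(0, 3), 0)
  # closed form for a generic stage
  s <- 0.8; tt <- 3
  expect_equal(gamma_from_survival(s, tt), (s^tt - s^(tt - 1)) / (s^tt - 1))
  # continuity near sigma = 1
  expect_equal(gamma_from_survival(1 - 1e-10, 5), 0.2, tolerance = 1e-6)
  expect_error(gamma_from_survival(1.2, 2), "sigma")
  expect_error(gamma_from_survival(0.5, 0), "duration")
  expect_error(gamma_from_survival(0.5, 2.5), "duration")
})

test_that("stage-advance probability matches a cohort microsimulation", {
  # independent oracle: stochastic cohort with per-step binomial survival
  # and forced exit after T survived steps; stationary advance fraction
  withr::with_seed(42, {
    for (case in list(c(0.8, 3), c(0.5, 2), c(0.95, 5))) {
      sim <- microsim_gamma(case[1], case[2])
      expect_equal(sim, gamma_from_survival(case[1], case[2]), tolerance = 0.01)
    }
  })
})

test_that("matrix entries satisfy G_i + P_i = sigma_i with an absorbing last stage", {
  tm <- unit_tm()
  expect_equal(tm$G + tm$P[1:4], tm$sigma[1:4])
  expect_equal(tm$P[5], tm$sigma[5])
  expect_equal(tm$A[5, 4], tm$sigma[4] * tm$gamma[4])
  # no onward transition and no entries outside the structural positions
  expect_true(all(tm$A[upper.tri(tm$A)] == 0))
  # direct product example: sigma 0.8, gamma 0.3
  expect_equal(0.8 * 0.3, 0.24)
  expect_equal(0.8 * (1 - 0.3), 0.56)
  # conservation over randomized life tables
  withr::with_seed(7, {
    for (i in 1:20) {
      tmi <- build_transition_matrix(random_life_table())
      expect_equal(tmi$G + tmi$P[1:4], tmi$sigma[1:4], tolerance = 1e-12)
    }
  })
})

test_that("fertility is restricted to A[1,4] and A[1,5] and ordered", {
  tm <- build_transition_matrix(unit_life_table(), fertility_4 = 10)
  expect_equal(tm$A[1, 4], 10)
  expect_equal(tm$A[1, 5], 100) # default 10x scaling from class 4 to 5
  expect_error(build_transition_matrix(unit_life_table(), fertility_4 = 10,
                                       fertility_5 = 5), "fertility_5")
  expect_error(build_transition_matrix(unit_life_table(), fertility_4 = -1))
  # unconstrained substitution for grid scans
  tm2 <- set_fertility(tm, 100, 1)
  expect_equal(tm2$A[1, 4], 100)
  expect_equal(tm2$A[1, 5], 1)
})

test_that("degenerate life tables give degenerate matrices", {
  lt0 <- life_table(rep(0, 5), c(1, 2, 3, 5))
  tm0 <- build_transition_matrix(lt0)
  expect_equal(tm0$A, matrix(0, 5, 5), ignore_attr = TRUE)
  expect_equal(tm0$lambda, 0)
})

test_that("zero-fertility matrices are subcritical", {
  withr::with_seed(11, {
    for (i in 1:25) {
      tmi <- build_transition_matrix(random_life_table())
      expect_lt(tmi$lambda, 1)
    }
  })
})

test_that("explicit shrinkage moves survivors down a class and conserves survival", {
  shr <- c(0, 0.2, 0.2, 0.1, 0.1)
  tm <- build_transition_matrix(unit_life_table(), shrinkage = shr)
  expect_gt(tm$A[1, 2], 0) # retrogression entries on the superdiagonal
  # column sums still equal stage survivals
  expect_equal(unname(colSums(tm$A)), tm$sigma)
})

test_that("dominant eigenvalue equals the spectral radius and power-iteration limit", {
  expect_equal(dominant_eigenvalue(diag(5) * 0.5), 0.5)
  withr::with_seed(3, {
    for (i in 1:10) {
      A <- matrix(runif(25, 0, 0.4), 5, 5) # dense: exercises the eigen path
      lam <- dominant_eigenvalue(A)
      x <- rep(1, 5)
      for (k in 1:300) {
        x_new <- A %*% x
        ratio <- sum(x_new) / sum(x)
        x <- x_new / sum(x_new)
      }
      expect_equal(lam, ratio, tolerance = 1e-8)
    }
  })
  # the triangular shortcut agrees with dense eigen
  tm <- unit_tm()
  expect_equal(dominant_eigenvalue(tm),
               max(Mod(eigen(tm$A)$values)), tolerance = 1e-12)
})

test_that("lambda-iterative stage durations converge to a self-consistent lambda", {
  tm <- build_transition_matrix(unit_life_table(),
                                gamma_method = "lambda_iterative")
  # gamma built from sigma/lambda must reproduce lambda
  ratio <- pmin(tm$sigma[1:4] / tm$lambda, 1)
  gam <- gamma_from_survival(ratio, c(1, 2, 3, 5)[1:4])
  expect_equal(gam, tm$gamma[1:4], tolerance = 1e-8)
})

test_that("a singleton pool collapses the Monte-Carlo spread to zero", {
  pool <- unit_life_table()
  mc <- monte_carlo_mean_matrix(pool, n_trials = 50, seed = 1)
  expect_equal(mc$mean_matrix$A, unit_tm()$A)
  expect_equal(sd(mc$lambda_samples$lambda), 0)
})

test_that("Monte-Carlo mean converges to the exhaustive-enumeration expectation", {
  lt1 <- life_table(c(0.02, 0.30, 0.60, 0.80, 0.90), c(1, 2, 3, 5),
                    source_label = "a")
  lt2 <- life_table(c(0.04, 0.40, 0.70, 0.88, 0.94), c(1, 2, 3, 5),
                    source_label = "b")
  pool <- dplyr::bind_rows(lt1, lt2)
  # oracle: exact expectation by enumerating all 2^5 stage combinations
  combos <- expand.grid(rep(list(1:2), 5))
  mats <- apply(combos, 1, function(idx) {
    sig <- ifelse(idx == 1, lt1$sigma, lt2$sigma)
    lt <- life_table(sig, c(1, 2, 3, 5), source_label = "c")
    build_transition_matrix(lt)$A
  })
  exact_mean <- matrix(rowMeans(mats), 5, 5)

  n_trials <- 10000
  mc <- monte_carlo_mean_matrix(pool, n_trials = n_trials, seed = 99)
  # Monte-Carlo error scales as 1/sqrt(n): entry half-ranges are < 0.1
  expect_equal(mc$mean_matrix$A, exact_mean, ignore_attr = TRUE,
               tolerance = 5 * 0.1 / sqrt(n_trials) / max(exact_mean))
  expect_true(all(mc$lambda_samples$lambda < 1))
})

test_that("Monte-Carlo results are bit-identical given the seed", {
  pool <- generate_life_table_pool("arborescent", 6, seed = 5)
  mc1 <- monte_carlo_mean_matrix(pool, 300, seed = 42)
  mc2 <- monte_carlo_mean_matrix(pool, 300, seed = 42)
  expect_identical(mc1$mean_matrix$A, mc2$mean_matrix$A)
  expect_identical(mc1$lambda_samples, mc2$lambda_samples)
  mc3 <- monte_carlo_mean_matrix(pool, 300, seed = 43)
  expect_false(identical(mc1$lambda_samples, mc3$lambda_samples))
})

test_that("empty or multi-form pools are rejected", {
  pool <- generate_life_table_pool("massive", 2, seed = 1)
  expect_error(monte_carlo_mean_matrix(pool[0, ], 10), "empty|5 stages")
  mixed <- dplyr::bind_rows(pool, generate_life_table_pool("arborescent", 1, seed = 2))
  expect_error(monte_carlo_mean_matrix(mixed, 10), "single growth form")
  expect_error(monte_carlo_mean_matrix(pool, 0), "n_trials")
})
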