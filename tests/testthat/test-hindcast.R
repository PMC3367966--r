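test_that("fit evaluation applies the strict 10% rule per class", {
  obs <- c(100, 50, 20, 10, 5)
  perfect <- evaluate_fit(obs, obs)
  expect_true(perfect$accepted)
  expect_equal(unname(perfect$deviations), rep(0, 5))
  expect_equal(perfect$chi_square, 0)
  # a class at exactly 10% deviation is rejected (strict <)
  at_ten <- obs; at_ten[2] <- 55
  expect_false(evaluate_fit(at_ten, obs)$accepted)
  just_under <- obs; just_under[2] <- 54.9
  expect_true(evaluate_fit(just_under, obs)$accepted)
})

test_that("class 5 can be excluded and zero-observed classes are dropped", {
  obs <- c(100, 50, 20, 10, 5)
  bad5 <- obs; bad5[5] <- 50
  expect_false(evaluate_fit(bad5, obs)$accepted)
  fit <- evaluate_fit(bad5, obs, exclude_largest = TRUE)
  expect_true(fit$accepted)
  expect_equal(fit$evaluated_classes, 1:4)
  # zero observed count: relative deviation undefined, class dropped
  obs0 <- c(100, 0, 20, 10, 5)
  expect_warning(fit0 <- evaluate_fit(obs0 + 1, obs0), "zero")
  expect_false(2 %in% fit0$evaluated_classes)
})

test_that("the chi-square pools small expected cells and penalises misfit", {
  obs <- c(100, 50, 20, 10, 5)
  off <- c(80, 60, 25, 12, 3)
  fit <- evaluate_fit(off, obs)
  manual <- sum((c(100, 50, 20, 15) - c(80, 60, 25, 15))^2 / c(80, 60, 25, 15))
  expect_equal(fit$chi_square, manual)
  expect_equal(fit$df, 3L)
  expect_gt(fit$chi_square, 0)
  expect_lt(fit$p_value, 1)
})

test_that("enumeration by matrix algebra equals step-by-step projection", {
  tm <- test_mean_matrix()
  w <- test_world()
  pre <- w$habitats$pre_disturbance[[1]]
  cfg <- hindcast_config(pre, fertility_grid = c(0, 100), nu_grid = c(0, 1000),
                         start_fractions = c(0.05), years = 8)
  obs <- c(900, 30, 6, 2, 0.5)
  fits <- enumerate_and_fit(tm, obs, cfg)
  for (r in seq_len(nrow(fits))) {
    A <- set_fertility(tm, fits$fertility_4[r], fits$fertility_5[r])
    n0 <- fits$start_fraction[r] * pre
    nus <- as.numeric(unlist(fits[r, paste0("nu_", 1:8)]))
    traj <- project_series(A, n0, nus, 8, mode = "mixed")
    expect_equal(as.numeric(unlist(fits[r, paste0("modeled_", 1:5)])),
                 final_counts(traj), tolerance = 1e-10)
  }
})

test_that("a grid-interior generating parameterization is recovered exactly", {
  w <- test_world()
  fx <- test_fixture()
  tm <- test_mean_matrix()
  for (h in seq_len(nrow(w$habitats))) {
    habitat <- w$habitats$habitat[h]
    cfg <- hindcast_config(w$habitats$pre_disturbance[[h]])
    obs <- fx$observed[fx$observed$habitat == habitat, ]
    fits <- enumerate_and_fit(tm, obs, cfg)
    truth_rows <- dplyr::filter(
      fits, .data$fertility_4 == 0, .data$fertility_5 == 0,
      .data$start_fraction == w$habitats$start_fraction[h],
      .data$nu_1 == w$habitats$nu[h])
    expect_equal(nrow(truth_rows), 1L)
    expect_true(truth_rows$accepted)
    expect_lt(truth_rows$max_deviation, 1e-6)
    # the modal recruitment over accepted solutions is the generating one
    summ <- summarize_recruitment(fits)
    expect_equal(summ$nu_mode, rep(w$habitats$nu[h], 8))
    expect_true(all(summ$nu_min <= summ$nu_mode & summ$nu_mode <= summ$nu_max))
  }
})

test_that("per-year import series are also recovered on a reduced grid", {
  w <- test_world()
  fx <- test_fixture()
  tm <- test_mean_matrix()
  h <- which(w$habitats$habitat == "lagoon")
  cfg <- hindcast_config(w$habitats$pre_disturbance[[h]],
                         fertility_grid = 0,
                         nu_grid = c(0, 1000, 10000),
                         nu_mode = "per_year",
                         start_fractions = c(0, 0.25))
  obs <- fx$observed[fx$observed$habitat == "lagoon", ]
  fits <- enumerate_and_fit(tm, obs, cfg)
  summ <- summarize_recruitment(fits)
  # modal per-year import equals the generating series in >= 6 of 8 years
  expect_gte(sum(summ$nu_mode == w$habitats$nu[h]), 6)
})

test_that("a decaying model cannot match a nonzero observation", {
  tm <- test_mean_matrix()
  cfg <- hindcast_config(pre_disturbance = rep(0, 5), fertility_grid = 0,
                         nu_grid = 0, start_fractions = c(0, 0.05))
  fits <- enumerate_and_fit(tm, c(900, 30, 6, 2, 0.5), cfg)
  expect_equal(sum(fits$accepted), 0L)
  summ <- summarize_recruitment(fits)
  expect_equal(nrow(summ), 0L)
  expect_equal(attr(summ, "n_accepted"), 0L)
})

test_that("imported-only solutions outfit closed-recruitment solutions on the fixture", {
  w <- test_world()
  fx <- test_fixture()
  tm <- test_mean_matrix()
  h <- which(w$habitats$habitat == "lagoon")
  obs <- fx$observed[fx$observed$habitat == "lagoon", ]
  pre <- w$habitats$pre_disturbance[[h]]
  closed <- enumerate_and_fit(tm, obs, hindcast_config(
    pre, fertility_grid = c(10, 100, 1000, 10000), nu_grid = 0))
  imported <- enumerate_and_fit(tm, obs, hindcast_config(
    pre, fertility_grid = 0, nu_grid = c(0, 10, 100, 1000, 10000, 20000)))
  expect_lt(min(imported$max_deviation), min(closed$max_deviation))
})

test_that("shrinking the acceptance threshold never grows the accepted set", {
  w <- test_world()
  fx <- test_fixture()
  tm <- test_mean_matrix()
  pre <- w$habitats$pre_disturbance[[1]]
  obs <- fx$observed[fx$observed$habitat == "lagoon", ]
  thresholds <- c(0.30, 0.10, 0.05, 0.01)
  ns <- sapply(thresholds, function(th) {
    cfg <- hindcast_config(pre, deviation_threshold = th)
    sum(enumerate_and_fit(tm, obs, cfg)$accepted)
  })
  expect_true(all(diff(ns) <= 0))
})

test_that("subsampling beyond the cap is seeded and deterministic", {
  w <- test_world()
  tm <- test_mean_matrix()
  pre <- w$habitats$pre_disturbance[[1]]
  cfg <- hindcast_config(pre, nu_mode = "per_year",
                         fertility_grid = 0, start_fractions = 0.05,
                         nu_grid = c(0, 10, 100, 1000),
                         max_combinations = 500, seed = 7)
  obs <- c(900, 30, 6, 2, 0.5)
  f1 <- enumerate_and_fit(tm, obs, cfg)
  f2 <- enumerate_and_fit(tm, obs, cfg)
  expect_true(attr(f1, "subsampled"))
  expect_equal(nrow(f1), 500L)
  expect_identical(f1$max_deviation, f2$max_deviation)
  cfg_no <- hindcast_config(pre, nu_mode = "per_year", fertility_grid = 0,
                            start_fractions = 0.05,
                            nu_grid = c(0, 10, 100, 1000),
                            max_combinations = 500, subsample = FALSE)
  expect_error(enumerate_and_fit(tm, obs, cfg_no), "exceed")
})

test_that("recruitment modes break ties toward the smaller grid value", {
  # two accepted series voting 100/100 and 100/1000 give mode 100 in year 1
  expect_equal(coraldemog:::modal_value(c(100, 100)), 100)
  expect_equal(coraldemog:::modal_value(c(100, 1000)), 100)
  expect_equal(coraldemog:::modal_value(c(1000, 100, 1000)), 1000)
})
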