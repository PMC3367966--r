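test_that("cumulative recruitment reduction is additive in time", {
  sched <- recruitment_schedule(1000, 1, 50)
  expect_equal(sched[50], 500)            # 1%/yr: half lost at year 50
  expect_equal(recruitment_schedule(1000, 1.5, 50)[50], 250) # 75% lost
  expect_equal(recruitment_schedule(1000, 0, 50), rep(1000, 50))
  # the loss saturates at 100%
  expect_equal(recruitment_schedule(1000, 4, 50)[30:50], rep(0, 21))
  expect_error(recruitment_schedule(1000, -1, 50), "loss_rate")
})

test_that("episodic mortality hits only the affected classes", {
  n <- c(10, 8, 6, 4, 2)
  expect_equal(apply_episodic_mortality(n, 0), n)
  hit <- apply_episodic_mortality(n, 0.75)
  expect_equal(hit, c(10, 2, 1.5, 1, 0.5)) # classes 2-5 quartered, spat spared
  expect_error(apply_episodic_mortality(n, 1.2), "mortality")
  # cover decomposes linearly across affected and spared classes
  cfg <- cover_config(radii = c(0.5, 1, 3, 5, 10), classes = 1:5)
  m <- 0.4
  expect_equal(cover_from_distribution(apply_episodic_mortality(n, m), cfg),
               cover_from_distribution(c(n[1], rep(0, 4)), cfg) +
                 (1 - m) * cover_from_distribution(c(0, n[2:5]), cfg))
})

test_that("a null scenario reproduces the undisturbed reference bit for bit", {
  tm <- unit_tm()
  n0 <- affine_fixed_point(tm, 1000)
  run <- run_scenario(tm, n0, 1000, impact_scenario())
  expect_identical(run$cover_disturbed, run$cover_reference)
  expect_equal(attr(run, "relative_final_cover"), 100)
  expect_equal(glance(run)$retention, 100, tolerance = 1e-12)
})

test_that("events fire every interval after the projection step", {
  tm <- unit_tm()
  n0 <- affine_fixed_point(tm, 1000)
  sc <- impact_scenario(episodic_mortality = 0.5, event_interval = 8,
                        horizon = 50)
  run <- run_scenario(tm, n0, 1000, sc)
  expect_equal(attr(run, "n_events"), 6L) # years 8, 16, 24, 32, 40, 48
  # the year-8 state is one projected step then a 50% kill of classes 2-5
  traj <- attr(run, "trajectory_disturbed")
  ref <- attr(run, "trajectory_reference")
  expect_equal(traj[8, ], ref[8, ]) # identical before the first event year
  stepped <- project_one_step(tm, traj[8, ], 1000)
  expect_equal(traj[9, ], apply_episodic_mortality(stepped, 0.5))
})

test_that("the synergy surface is monotone with an exact undisturbed corner", {
  tm <- unit_tm()
  n0 <- affine_fixed_point(tm, 1000) * 0.4
  grid <- synergy_grid(tm, n0, 1000, loss_rates = c(0, 1, 1.5),
                       mortalities = c(0, 0.25, 0.5), horizon = 50)
  corner <- grid$relative_final_cover[grid$loss_rate == 0 & grid$mortality == 0]
  expect_equal(corner, 100)
  wide <- tidyr::pivot_wider(grid[c("loss_rate", "mortality", "relative_final_cover")],
                             names_from = "mortality",
                             values_from = "relative_final_cover")
  m <- as.matrix(wide[-1])
  expect_true(all(apply(m, 1, diff) <= 1e-9)) # non-increasing in mortality
  expect_true(all(apply(m, 2, diff) <= 1e-9)) # non-increasing in loss rate
  # the mortality-free column reproduces run_scenario's better-case endpoint
  sc <- impact_scenario(recruitment_loss_rate = 1, horizon = 50)
  solo <- run_scenario(tm, n0, 1000, sc)
  expect_equal(grid$relative_final_cover[grid$loss_rate == 1 & grid$mortality == 0],
               attr(solo, "relative_final_cover"))
})

test_that("habitat contrast arithmetic and homogenisation under heavy mortality", {
  tm <- test_mean_matrix()
  w <- test_world()
  fx <- test_fixture()
  # the lagoon holds both a richer standing stock (the 1998 refuge) and a
  # larger larval supply; recurrent heavy mortality erodes the
  # standing-stock advantage and recruitment loss the supply advantage
  make_run <- function(habitat, scenario) {
    obs <- fx$observed[fx$observed$habitat == habitat, ]
    nu <- w$habitats$nu[w$habitats$habitat == habitat]
    run_scenario(tm, obs, nu, scenario)
  }
  undisturbed <- impact_scenario()
  heavy <- impact_scenario(recruitment_loss_rate = 1.5,
                           episodic_mortality = 0.75)
  runs_u <- list(lagoon = make_run("lagoon", undisturbed),
                 ocean_facing = make_run("ocean_facing", undisturbed))
  runs_h <- list(lagoon = make_run("lagoon", heavy),
                 ocean_facing = make_run("ocean_facing", heavy))
  # identical results give zero contrast; 2x cover gives 2/3
  expect_equal(homogenization_contrast(
    list(a = runs_u$lagoon, b = runs_u$lagoon))$contrast_disturbed, 0)
  fake <- runs_u$lagoon
  fake$cover_disturbed <- 2 * runs_u$ocean_facing$cover_disturbed
  expect_equal(homogenization_contrast(
    list(a = fake, b = runs_u$ocean_facing))$contrast_disturbed, 2 / 3,
    tolerance = 1e-12)
  expect_error(homogenization_contrast(list(a = runs_u$lagoon)), "2 habitats")
  # heavy recurrent mortality with recruitment loss erodes the
  # recruitment-driven lagoon advantage: the habitats homogenise
  cu <- homogenization_contrast(runs_u)$contrast_disturbed
  ch <- homogenization_contrast(runs_h)$contrast_disturbed
  expect_lt(ch, cu)
})

test_that("scenario bounds are validated before computation", {
  expect_error(impact_scenario(episodic_mortality = 1.2), "episodic_mortality")
  expect_error(impact_scenario(recruitment_loss_rate = -5), "recruitment_loss_rate")
  expect_error(impact_scenario(horizon = 0), "horizon")
  expect_error(impact_scenario(event_interval = 0), "event_interval")
})
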