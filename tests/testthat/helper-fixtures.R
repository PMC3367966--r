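# Shared fixtures, built once per test run.

.test_cache <- new.env(parent = emptyenv())

# The shipped synthetic study system at its default size.
test_world <- function() {
  if (is.null(.test_cache$world)) {
    .test_cache$world <- chagos_like_world()
  }
  .test_cache$world
}

test_fixture <- function() {
  if (is.null(.test_cache$fixture)) {
    .test_cache$fixture <- generate_recovery_fixture(test_world(), years = 8)
  }
  .test_cache$fixture
}

test_mean_matrix <- function() {
  w <- test_world()
  w$matrices[[w$growth_form]]$mean_matrix
}

# A small deterministic branching/encrusting matrix for unit tests.
unit_life_table <- function() {
  life_table(c(0.02, 0.35, 0.65, 0.84, 0.92), c(1, 2, 3, 5),
             growth_form = "branching_encrusting")
}

unit_tm <- function() build_transition_matrix(unit_life_table())

# Random valid life table under a local seed.
random_life_table <- function(label = "r1") {
  sigma <- sort(runif(5, 0.01, 0.99))
  duration <- c(1, sample(1:4, 1), sample(2:6, 1), sample(3:10, 1))
  life_table(sigma, duration, growth_form = "massive", source_label = label)
}

# Independent cohort microsimulation of one stage with fixed duration:
# constant inflow of settlers, binomial survival each step, forced exit
# after `duration` survived steps. Returns the stationary per-step fraction
# of within-stage survivors that advance.
microsim_gamma <- function(sigma, duration, inflow = 2e5, steps = 60,
                           burnin = 20) {
  ages <- rep(0, duration) # counts by completed years in stage
  fracs <- numeric(0)
  for (s in seq_len(steps)) {
    survivors <- rbinom(duration, ages, sigma)
    advanced <- survivors[duration]
    stay <- c(0, survivors[-duration])
    ages <- stay
    ages[1] <- ages[1] + inflow
    if (s > burnin) fracs <- c(fracs, advanced / sum(survivors))
  }
  mean(fracs)
}

final_counts <- function(traj) {
  as.numeric(unlist(traj[nrow(traj), paste0("class_", 1:5)]))
}
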