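# In-code fixtures shared across test files.

# Minimal hand-built roster (one year).
tiny_roster <- function(year = 2019) {
  data.frame(
    enrollee_id = c("a", "b", "c"),
    year = as.integer(year),
    sex = c("F", "M", "F"),
    age = c(30L, 5L, 72L),
    contracted = c(TRUE, FALSE, TRUE),
    community_id = "c1",
    stringsAsFactors = FALSE
  )
}

# One latent state pinning every attender at `multiplier` times
# `base_cost` of expected annual cost: everyone attends exactly once
# (general outpatient) and per-visit costs are lognormal with the mean
# solved for the target. multiplier = 0 switches attendance off.
planted_state <- function(multiplier, base_cost = 2000, sdlog = 0.5) {
  data.frame(
    state = "planted",
    p_zero = if (multiplier == 0) 1 else 0,
    visit_mu = 0, visit_size = 1,
    mix_gop = 1, mix_cop = 0, mix_sop = 0, mix_hosp = 0,
    cost_meanlog = if (multiplier == 0) 0
                   else log(multiplier * base_cost) - sdlog^2 / 2,
    stringsAsFactors = FALSE
  )
}

# Simulate a single-state cohort for planted-class recovery checks.
planted_cohort <- function(multiplier, n = 5000, base_cost = 2000,
                           seed = 1, sdlog = 0.5) {
  simulate_population(sim_config(
    n_enrollees = n, years = 2019L, seed = seed,
    latent_states = planted_state(multiplier, base_cost, sdlog),
    initial_state_probs = 1,
    transition_matrix = matrix(1, 1, 1),
    cost_sdlog = sdlog
  ))
}

# Classes of all occupied groups of a simulated one-year population,
# with weights normalised by an explicit reference mean.
occupied_classes <- function(sim, reference_mean) {
  people <- aggregate_claims(sim$roster, sim$claims, sim$config$years[1])
  groups <- build_group_table(people, default_taxonomy())
  w <- compute_weights(groups, reference_mean = reference_mean)
  ct <- build_class_table(groups, w)
  occ <- groups$n > 0
  ct$group_class$class[match(groups$group_id[occ], ct$group_class$group_id)]
}
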