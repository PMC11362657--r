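#' Default latent morbidity states
#'
#' Five ordered morbidity states drive the generator, from `healthy` to
#' `very_severe`. Per state: `p_zero`, the probability of no visit at
#' all in a year (zero inflation — the source of non-attenders);
#' `visit_mu` and `visit_size`, mean and dispersion of the
#' negative-binomial count of visits beyond the first for attenders;
#' `mix_*`, the consultation-category probabilities per visit (general
#' outpatient, chronic outpatient, special-disease outpatient,
#' hospitalization); `cost_meanlog`, the log-scale location of the
#' per-visit lognormal cost. Severity raises visit rates, shifts the
#' category mix toward chronic/special/hospital care and raises costs.
#'
#' The per-visit cost locations are derived from per-state annual cost
#' targets: state s aims at `cost_multiplier[s]` times the population's
#' per-capita mean annual cost (default 2000 currency units), with
#' multipliers 0.1, 0.5, 2, 6 and 12 — the interiors of utilization
#' classes 1–5 — so that groups dominated by one state carry a cost
#' weight well inside one class band.
#'
#' @param per_capita_cost target per-capita mean annual cost over all
#'   enrollees (at the default state prevalences).
#' @param cost_sdlog,hosp_cost_mult must match the values passed to
#'   [sim_config()] for the annual-cost targets to hold.
#' @return data frame, one row per state.
#' @export
default_latent_states <- function(per_capita_cost = 2000, cost_sdlog = 0.8,
                                  hosp_cost_mult = 8) {
  st <- data.frame(
    state = c("healthy", "mild", "moderate", "severe", "very_severe"),
    p_zero = c(0.60, 0.25, 0.10, 0.03, 0.01),
    visit_mu = c(0.8, 2, 4, 7, 10),
    visit_size = c(1, 1.2, 1.5, 2, 2),
    mix_gop = c(0.92, 0.75, 0.55, 0.35, 0.25),
    mix_cop = c(0.05, 0.15, 0.25, 0.30, 0.25),
    mix_sop = c(0.02, 0.05, 0.10, 0.15, 0.20),
    mix_hosp = c(0.01, 0.05, 0.10, 0.20, 0.30),
    cost_multiplier = c(0.1, 0.5, 2, 6, 12),
    stringsAsFactors = FALSE
  )
  # annual target = P(attend) * E[visits] * E[cost per visit]; solve for
  # the lognormal location given the category mix and hospital factor
  per_visit_mean <- st$cost_multiplier * per_capita_cost /
    ((1 - st$p_zero) * (1 + st$visit_mu) *
       (1 + (hosp_cost_mult - 1) * st$mix_hosp))
  st$cost_meanlog <- log(per_visit_mean) - cost_sdlog^2 / 2
  st
}

#' Default year-to-year morbidity transition matrix
#'
#' Row-stochastic transitions between the latent states from one
#' calendar year to the next. States move at most one severity step per
#' year (a birth-death chain) and severe states are sticky. The
#' deterioration rates are derived from the recovery rates by detailed
#' balance with `stationary`, so that distribution is exactly invariant:
#' under the `"stable"` scenario the state mix holds still and scenario
#' tilts act against a flat baseline.
#'
#' @param stationary target stationary state distribution (defaults to
#'   the default initial distribution of [sim_config()]).
#' @param recovery per-state probability of moving one state healthier,
#'   for states 2..k.
#' @return row-stochastic matrix with `stationary` as its stationary
#'   distribution.
#' @export
default_transition_matrix <- function(stationary = c(0.50, 0.30, 0.13,
                                                     0.05, 0.02),
                                      recovery = c(0.25, 0.20, 0.15, 0.12)) {
  k <- length(stationary)
  stopifnot(length(recovery) == k - 1, all(stationary > 0),
            abs(sum(stationary) - 1) < 1e-8)
  worsen <- stationary[-1L] * recovery / stationary[-k]   # detailed balance
  m <- diag(1 - c(worsen, 0) - c(0, recovery))
  m[cbind(seq_len(k - 1L), seq_len(k - 1L) + 1L)] <- worsen
  m[cbind(seq_len(k - 1L) + 1L, seq_len(k - 1L))] <- recovery
  if (any(m < 0)) stop("recovery rates too large: negative staying probability")
  s <- default_latent_states()$state[seq_len(k)]
  dimnames(m) <- list(from = s, to = s)
  m
}

#' Configure the synthetic claims generator
#'
#' Builds and validates the configuration for
#' [simulate_population()]. Defaults emulate a county-scale enrolled
#' population: a demography skewed toward working ages with a sizeable
#' elderly share, family-doctor contracting that rises with age,
#' zero-inflated negative-binomial visit counts producing a 25–40%
#' non-attender fraction, right-skewed (lognormal) per-visit costs with
#' an 8x hospitalization factor, and sticky year-to-year morbidity
#' transitions.
#'
#' @param n_enrollees number of enrollees (fixed across years; ages
#'   increment, no churn).
#' @param years calendar years to simulate (consecutive).
#' @param seed integer seed fixing the output exactly.
#' @param age_probs probabilities over the six default age bands.
#' @param p_female probability of sex `F`.
#' @param contract_prob per-age-band probability of a family-doctor
#'   contract.
#' @param n_communities number of medical communities (membership
#'   uniform, fixed over years).
#' @param latent_states per-state parameter table, see
#'   [default_latent_states()].
#' @param initial_state_probs state distribution in the first year.
#' @param transition_matrix see [default_transition_matrix()].
#' @param scenario `"stable"`, `"improving"` or `"deteriorating"`:
#'   tilts the transition matrix via [scenario_shift()].
#' @param shift_strength fraction of transition mass moved one state
#'   toward the scenario's direction.
#' @param cost_sdlog shared lognormal log-scale sd of per-visit costs.
#' @param hosp_cost_mult multiplicative cost factor for hospitalization
#'   visits.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n_enrollees = 10000,
                       years = 2019:2021,
                       seed = 1L,
                       age_probs = c(0.07, 0.12, 0.36, 0.20, 0.20, 0.05),
                       p_female = 0.5,
                       contract_prob = c(0.30, 0.30, 0.35, 0.50, 0.70, 0.75),
                       n_communities = 1L,
                       latent_states = default_latent_states(),
                       initial_state_probs = c(0.50, 0.30, 0.13, 0.05, 0.02),
                       transition_matrix = default_transition_matrix(),
                       scenario = c("stable", "improving", "deteriorating"),
                       shift_strength = 0.2,
                       cost_sdlog = 0.8,
                       hosp_cost_mult = 8) {
  scenario <- match.arg(scenario)
  k <- nrow(latent_states)
  stopifnot(
    n_enrollees >= 1, length(years) >= 1, !is.unsorted(years),
    length(age_probs) == 6, length(contract_prob) == 6,
    p_female >= 0, p_female <= 1,
    length(initial_state_probs) == k,
    nrow(transition_matrix) == k, ncol(transition_matrix) == k,
    shift_strength >= 0, shift_strength <= 1,
    cost_sdlog >= 0, hosp_cost_mult > 0
  )
  check_prob <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(what, " must be a probability vector summing to 1")
  }
  check_prob(age_probs, "age_probs")
  check_prob(initial_state_probs, "initial_state_probs")
  for (i in seq_len(k)) {
    check_prob(transition_matrix[i, ], paste0("transition_matrix row ", i))
    check_prob(unlist(latent_states[i, c("mix_gop", "mix_cop", "mix_sop",
                                         "mix_hosp")]),
               paste0("category mix of state ", latent_states$state[i]))
  }
  if (any(latent_states$p_zero < 0 | latent_states$p_zero > 1))
    stop("p_zero must lie in [0, 1]")
  structure(list(
    n_enrollees = as.integer(n_enrollees), years = as.integer(years),
    seed = as.integer(seed), age_probs = age_probs, p_female = p_female,
    contract_prob = contract_prob, n_communities = as.integer(n_communities),
    latent_states = latent_states,
    initial_state_probs = initial_state_probs,
    transition_matrix = transition_matrix, scenario = scenario,
    shift_strength = shift_strength, cost_sdlog = cost_sdlog,
    hosp_cost_mult = hosp_cost_mult
  ), class = "sim_config")
}

#' Tilt a transition matrix toward a scenario
#'
#' For `"improving"`, a fraction `strength` of every destination
#' probability is moved one state toward the healthiest state;
#' `"deteriorating"` mirrors this toward the sickest state; `"stable"`
#' returns the matrix unchanged. The result is always row-stochastic.
#'
#' @param m row-stochastic transition matrix (states ordered healthiest
#'   first).
#' @param scenario `"stable"`, `"improving"` or `"deteriorating"`.
#' @param strength fraction of mass shifted, in `[0, 1]`.
#' @return transition matrix of the same shape.
#' @export
scenario_shift <- function(m, scenario = c("stable", "improving",
                                           "deteriorating"),
                           strength = 0.2) {
  scenario <- match.arg(scenario)
  stopifnot(is.matrix(m), nrow(m) == ncol(m), all(m >= 0),
            all(abs(rowSums(m) - 1) < 1e-8), strength >= 0, strength <= 1)
  if (scenario == "stable" || strength == 0) return(m)
  k <- ncol(m)
  out <- m * (1 - strength)
  if (scenario == "improving") {
    out[, 1L] <- out[, 1L] + strength * m[, 1L]           # nothing left of 1
    out[, seq_len(k - 1L)] <- out[, seq_len(k - 1L)] +
      strength * m[, seq_len(k - 1L) + 1L]
  } else {
    out[, k] <- out[, k] + strength * m[, k]              # nothing right of k
    out[, seq_len(k - 1L) + 1L] <- out[, seq_len(k - 1L) + 1L] +
      strength * m[, seq_len(k - 1L)]
  }
  out
}

#' Simulate a multi-year enrolled population with claims
#'
#' Draws a fixed cohort of enrollees, evolves a latent morbidity state
#' per enrollee across years by the (scenario-tilted) transition
#' matrix, and emits for every year a roster and claim lines in the
#' package's standard schema, plus a ledger of the true latent states
#' for recovery tests. Claim lines are aggregated per enrollee-year and
#' consultation category (`n_visits` carries the visit count). Output
#' is a deterministic function of the configuration, including its
#' seed.
#'
#' @param config a [sim_config()].
#' @return list of class `"sim_data"` with data frames `roster`
#'   (all years stacked, [read_roster()] schema plus resolved `age`),
#'   `claims` ([read_claims()] schema) and `states` (`enrollee_id`,
#'   `year`, `state`), plus the `config`.
#' @examples
#' sim <- simulate_population(sim_config(n_enrollees = 500, seed = 7))
#' head(sim$claims)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n <- config$n_enrollees
  years <- config$years
  st <- config$latent_states
  k <- nrow(st)
  bands <- default_age_bands()

  id <- sprintf("e%07d", seq_len(n))
  band <- sample.int(6L, n, replace = TRUE, prob = config$age_probs)
  lo <- bands$lower[band]
  hi <- ifelse(is.finite(bands$upper[band]), bands$upper[band], 95)
  age0 <- as.integer(lo + floor(stats::runif(n) * (hi - lo + 1)))
  sex <- ifelse(stats::runif(n) < config$p_female, "F", "M")
  contracted <- stats::runif(n) < config$contract_prob[band]
  community <- paste0("c", 1L + (seq_len(n) - 1L) %% config$n_communities)

  trans <- scenario_shift(config$transition_matrix, config$scenario,
                          config$shift_strength)
  mix <- as.matrix(st[c("mix_gop", "mix_cop", "mix_sop", "mix_hosp")])

  state <- integer(n)
  roster_l <- claims_l <- states_l <- vector("list", length(years))
  for (yi in seq_along(years)) {
    yr <- years[yi]
    if (yi == 1L) {
      state <- sample.int(k, n, replace = TRUE,
                          prob = config$initial_state_probs)
    } else {
      nxt <- integer(n)
      for (s in seq_len(k)) {
        i <- which(state == s)
        if (length(i))
          nxt[i] <- sample.int(k, length(i), replace = TRUE, prob = trans[s, ])
      }
      state <- nxt
    }
    age <- age0 + (yi - 1L)

    attends <- stats::runif(n) >= st$p_zero[state]
    visits <- integer(n)
    ia <- which(attends)
    visits[ia] <- 1L + stats::rnbinom(length(ia), size = st$visit_size[state[ia]],
                                      mu = st$visit_mu[state[ia]])
    # one row per visit, then collapse to (enrollee, category) claim lines
    vidx <- rep.int(ia, visits[ia])
    if (length(vidx)) {
      vstate <- state[vidx]
      u <- stats::runif(length(vidx))
      cum <- t(apply(mix, 1L, cumsum))
      vcat <- 1L + (u > cum[vstate, 1L]) + (u > cum[vstate, 2L]) +
        (u > cum[vstate, 3L])
      vcost <- stats::rlnorm(length(vidx), st$cost_meanlog[vstate],
                             config$cost_sdlog)
      vcost <- round_money(vcost * ifelse(vcat == 4L, config$hosp_cost_mult, 1))
      key <- (vidx - 1L) * 4L + vcat
      cost_s <- rowsum_money(vcost, key)
      nv_s <- rowsum(rep.int(1L, length(vidx)), key)
      ukey <- as.integer(rownames(cost_s))
      claims_l[[yi]] <- data.frame(
        enrollee_id = id[(ukey - 1L) %/% 4L + 1L],
        year = yr,
        category = CATEGORIES[(ukey - 1L) %% 4L + 1L],
        cost = cost_s[, 1L],
        n_visits = as.integer(nv_s[, 1L]),
        stringsAsFactors = FALSE
      )
    } else {
      claims_l[[yi]] <- data.frame(
        enrollee_id = character(), year = integer(), category = character(),
        cost = numeric(), n_visits = integer(), stringsAsFactors = FALSE
      )
    }
    roster_l[[yi]] <- data.frame(
      enrollee_id = id, year = yr, sex = sex, age = age,
      contracted = contracted, community_id = community,
      stringsAsFactors = FALSE
    )
    states_l[[yi]] <- data.frame(
      enrollee_id = id, year = yr, state = st$state[state],
      stringsAsFactors = FALSE
    )
  }
  unrowname <- function(d) { rownames(d) <- NULL; d }
  structure(list(
    roster = unrowname(do.call(rbind, roster_l)),
    claims = unrowname(do.call(rbind, claims_l)),
    states = unrowname(do.call(rbind, states_l)),
    config = config
  ), class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat("Synthetic enrolled population:", x$config$n_enrollees, "enrollees,",
      "years", paste(range(x$config$years), collapse = "-"),
      sprintf("(scenario: %s)\n", x$config$scenario))
  cat(" ", nrow(x$claims), "claim lines,",
      sum(x$claims$n_visits), "visits, total cost",
      format(sum_money(x$claims$cost), big.mark = ","), "\n")
  invisible(x)
}
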