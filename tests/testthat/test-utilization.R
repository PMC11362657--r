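test_that("weights are mean cost over reference mean; non-attenders weigh 0", {
  sim <- simulate_population(sim_config(n_enrollees = 4000, years = 2019L,
                                        seed = 21))
  people <- aggregate_claims(sim$roster, sim$claims, 2019)
  groups <- build_group_table(people, default_taxonomy())
  w <- compute_weights(groups)
  ref <- attr(w, "reference_mean")
  expect_equal(ref, sum(people$total_cost) / nrow(people), tolerance = 1e-9)
  expect_equal(w$weight[groups$pattern == "nonatt"], 0)
  # conservation identity: sum over groups of weight * n * ref = total cost
  occ <- groups$n > 0
  expect_equal(sum(w$weight[occ] * groups$n[occ] * ref),
               sum(people$total_cost), tolerance = 1e-8)
})

test_that("a uniform-cost attending population has all weights equal to 1", {
  n <- 60
  people <- data.frame(
    enrollee_id = sprintf("e%03d", 1:n), year = 2019L,
    sex = rep(c("M", "F"), n / 2), age = rep(c(10, 30, 70), n / 3),
    contracted = TRUE, community_id = "c1",
    visits_gop = 1L, visits_cop = 0L, visits_sop = 0L, visits_hosp = 0L,
    cost_gop = 500, cost_cop = 0, cost_sop = 0, cost_hosp = 0,
    total_visits = 1L, total_cost = 500, stringsAsFactors = FALSE
  )
  groups <- build_group_table(people, default_taxonomy())
  w <- compute_weights(groups)
  expect_true(all(abs(w$weight[groups$n > 0] - 1) < 1e-12))
})

test_that("attendees-only reference excludes the non-attender group", {
  g <- data.frame(
    group_id = c("nonatt|*|*|*|*", "gop|c1|18-45|F|v1"),
    pattern = c("nonatt", "gop"), year = 2019L,
    n = c(50L, 50L), aggregate_cost = c(0, 10000),
    mean_cost = c(0, 200), stringsAsFactors = FALSE
  )
  class(g) <- c("hrg_table", "data.frame")
  w_all <- compute_weights(g)
  w_att <- compute_weights(g, reference = "attendees_only")
  expect_equal(attr(w_all, "reference_mean"), 100)
  expect_equal(attr(w_att, "reference_mean"), 200)
  expect_equal(w_all$weight[2], 2)
  expect_equal(w_att$weight[2], 1)
})

test_that("classify_weight follows the documented band boundaries", {
  expect_identical(
    classify_weight(c(0, 0.1, 0.2, 0.21, 1.0, 1.01, 4.0, 4.5, 8.0, 8.01)),
    c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L))
  expect_error(classify_weight(-0.1), ">= 0")
  # non-decreasing over random weights
  set.seed(404)
  w <- sort(c(0, rexp(10000, 1 / 3)))
  expect_true(all(diff(classify_weight(w)) >= 0L))
})

test_that("the class table partitions headcount and expense exactly", {
  sim <- simulate_population(sim_config(n_enrollees = 8000, years = 2019L,
                                        seed = 31))
  people <- aggregate_claims(sim$roster, sim$claims, 2019)
  groups <- build_group_table(people, default_taxonomy())
  ct <- build_class_table(groups, compute_weights(groups))
  expect_identical(sum(ct$classes$n), nrow(people))
  expect_identical(sum(round(ct$classes$expense * 100)),
                   sum(round(people$total_cost * 100)))
  # class 0 holds exactly the non-attenders and no money
  expect_identical(ct$classes$n[1], sum(people$total_visits == 0L))
  expect_identical(ct$classes$expense[1], 0)
  # shares sum to 100 up to reporting rounding
  expect_lt(abs(sum(ct$classes$pct_n) - 100), 0.03)
  expect_lt(abs(sum(ct$classes$pct_expense) - 100), 0.03)
})

test_that("reported shares agree with independent long division", {
  set.seed(77)
  n <- rmultinom(1, 250000, prob = c(0.3, 0.35, 0.2, 0.07, 0.05, 0.03))[, 1]
  ct <- class_table_from_counts(2019, n)
  manual <- floor(100 * n / sum(n) * 100 + 0.5) / 100
  expect_equal(ct$classes$pct_n, manual)
  # single non-empty class holds a 100.00% share
  one <- class_table_from_counts(2020, c(0, 500))
  expect_equal(one$classes$pct_n, c(0, 100))
})

test_that("planted cost multipliers are recovered as the planted classes", {
  base <- 2000
  for (k in 0:5) {
    m <- c(0, 0.1, 0.5, 2, 6, 12)[k + 1]
    sim <- planted_cohort(m, n = 5000, base_cost = base, seed = 100 + k)
    cls <- occupied_classes(sim, reference_mean = base)
    expect_true(all(cls == k),
                info = sprintf("multiplier %g should map to class %d", m, k))
  }
})

test_that("a fixed class map re-tallies a year under base-year classes", {
  sim <- simulate_population(sim_config(n_enrollees = 4000,
                                        years = 2019:2020, seed = 41))
  a <- year_class_table(sim$roster, sim$claims, 2019)
  b <- year_class_table(sim$roster, sim$claims, 2020,
                        class_map = a$group_class)
  # same groups keep their base-year class wherever occupied both years
  joined <- merge(a$group_class, b$group_class, by = "group_id")
  occ_a <- attr(a, "groups")$n > 0
  both <- joined$group_id %in% attr(a, "groups")$group_id[occ_a]
  expect_true(all(joined$class.x[both] == joined$class.y[both]))
  expect_identical(sum(b$classes$n), 4000L)
})
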