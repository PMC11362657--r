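make_alloc <- function(n_communities = 3, seed = 51) {
  sim <- simulate_population(sim_config(n_enrollees = 2000, years = 2019L,
                                        seed = seed,
                                        n_communities = n_communities))
  people <- aggregate_claims(sim$roster, sim$claims, 2019)
  groups <- build_group_table(people, default_taxonomy())
  w <- compute_weights(groups)
  list(people = people, weights = w,
       alloc = allocate_budget(people, default_taxonomy(), w))
}

test_that("per-enrollee budgets are base rate times group weight", {
  x <- make_alloc()
  alloc <- x$alloc
  expect_equal(alloc$base_rate, attr(x$weights, "reference_mean"))
  expect_equal(alloc$enrollee$budget,
               alloc$base_rate * alloc$enrollee$weight)
  # community budgets sum the members, and sum to the total
  s <- rowsum(alloc$enrollee$budget, alloc$enrollee$community_id)
  expect_equal(alloc$community$budget,
               unname(s[match(alloc$community$community_id, rownames(s)), 1]))
  expect_equal(sum(alloc$community$budget), sum(alloc$enrollee$budget))
})

test_that("with base rate = reference mean the budget reproduces total cost", {
  x <- make_alloc()
  expect_equal(sum(x$alloc$enrollee$budget), sum(x$people$total_cost),
               tolerance = 1e-9)
})

test_that("uniform weights reduce to pure capitation", {
  x <- make_alloc()
  w1 <- x$weights
  w1$weight[!is.na(w1$weight)] <- 1
  alloc <- allocate_budget(x$people, default_taxonomy(), w1, base_rate = 350)
  expect_equal(sum(alloc$enrollee$budget), 350 * nrow(x$people))
})

test_that("a single community receives the whole budget", {
  x <- make_alloc(n_communities = 1)
  expect_equal(nrow(x$alloc$community), 1L)
  expect_equal(x$alloc$community$budget, sum(x$alloc$enrollee$budget))
})

test_that("the weight floor lifts only zero-weight enrollees", {
  x <- make_alloc()
  floored <- allocate_budget(x$people, default_taxonomy(), x$weights,
                             floor_weight = 0.1)
  w0 <- x$alloc$enrollee$weight
  expect_true(all(floored$enrollee$weight >= 0.1))
  expect_true(all(floored$enrollee$weight[w0 == 0] == 0.1))
  above <- w0 >= 0.1
  expect_equal(floored$enrollee$weight[above], w0[above])
})

test_that("settlement applies the min/max rule with balance retention", {
  alloc <- structure(list(
    year = 2019L, base_rate = 1,
    enrollee = data.frame(),
    community = data.frame(community_id = c("c1", "c2", "c3"),
                           n = c(1L, 1L, 1L), budget = c(100, 100, 100),
                           stringsAsFactors = FALSE)
  ), class = "budget_allocation")
  s <- settle_budget(alloc, data.frame(community_id = c("c1", "c2", "c3"),
                                       actual = c(120, 80, 100)))
  expect_equal(s$payment, c(100, 80, 100))
  expect_equal(s$retained_balance, c(0, 20, 0))
  expect_equal(s$overrun, c(20, 0, 0))
  expect_equal(s$payment + s$retained_balance, s$budget)
})

test_that("fund conservation holds exactly on simulated settlements", {
  x <- make_alloc(n_communities = 5)
  actual <- rowsum(x$people$total_cost, x$people$community_id)
  s <- settle_budget(x$alloc,
                     data.frame(community_id = rownames(actual),
                                actual = actual[, 1]))
  expect_identical(sum(round(s$payment * 100)) +
                     sum(round(s$retained_balance * 100)),
                   sum(round(s$budget * 100)))
  expect_true(all(s$retained_balance >= 0 & s$payment >= 0))
})

test_that("budget and settlement inputs are validated", {
  x <- make_alloc()
  bad_people <- x$people
  bad_people$community_id[1] <- ""
  expect_error(allocate_budget(bad_people, default_taxonomy(), x$weights),
               "community")
  # a group with missing weight is an error
  w <- x$weights[x$weights$group_id != x$alloc$enrollee$group_id[1], ]
  expect_error(allocate_budget(x$people, default_taxonomy(), w), "weight")
  expect_error(settle_budget(x$alloc,
                             data.frame(community_id = "c1", actual = 10)),
               "community")
  expect_error(settle_budget(x$alloc,
                             data.frame(community_id = c("c1", "c2", "c3"),
                                        actual = c(-5, 10, 10))),
               ">= 0")
})
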