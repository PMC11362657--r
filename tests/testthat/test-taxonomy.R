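# Independent probe population: every consultation-pattern combination
# crossed with contract, sex, representative ages and visit totals.
# Built here from first principles so it does not share code with the
# package's own coverage checker.
probe_people <- function() {
  g <- expand.grid(
    gop = 0:1, cop = 0:1, sop = 0:1, hosp = 0:1,
    age = c(3, 10, 30, 50, 70, 85),
    sex = c("M", "F"), contracted = c(TRUE, FALSE),
    total = c(0, 1, 2, 3, 4, 5, 6, 9),
    stringsAsFactors = FALSE
  )
  npos <- g$gop + g$cop + g$sop + g$hosp
  g <- g[(npos == 0 & g$total == 0) | (npos > 0 & g$total >= npos), ]
  # put the surplus visits on the first claimed category
  vm <- as.matrix(g[c("gop", "cop", "sop", "hosp")])
  first <- apply(vm, 1, function(r) which(r > 0)[1])
  extra <- g$total - rowSums(vm)
  for (i in seq_len(nrow(vm))) {
    if (!is.na(first[i])) vm[i, first[i]] <- vm[i, first[i]] + extra[i]
  }
  data.frame(
    enrollee_id = sprintf("p%05d", seq_len(nrow(g))),
    year = 2019L, sex = g$sex, age = g$age, contracted = g$contracted,
    community_id = "c1",
    visits_gop = vm[, 1], visits_cop = vm[, 2], visits_sop = vm[, 3],
    visits_hosp = vm[, 4],
    cost_gop = 0, cost_cop = 0, cost_sop = 0, cost_hosp = 0,
    total_visits = rowSums(vm), total_cost = 0,
    stringsAsFactors = FALSE
  )
}

test_that("the default taxonomy enumerates 214 groups, 213 attending", {
  ids <- enumerate_groups(default_taxonomy())
  expect_length(ids, 214L)
  expect_false(anyDuplicated(ids) > 0)
  expect_equal(sum(!startsWith(ids, "nonatt")), 213L)
  expect_equal(sum(startsWith(ids, "nonatt")), 1L)
})

test_that("enumeration matches a brute-force count of satisfiable cells", {
  tax <- default_taxonomy()
  ids <- enumerate_groups(tax)
  hit <- unique(assign_group(probe_people(), tax))
  expect_setequal(hit, ids)
  # arithmetic re-count from the documented structure
  expect_equal(length(ids), 1 + 2 * 6 * 2 * 4 + 2 * 6 * 2 * 4 + 2 * 3 * 3 + 3)
})

test_that("a single-axis taxonomy yields its forced group count", {
  tax <- taxonomy(list(
    taxonomy_rule("att", when = list(attender = TRUE), axes = "sex"),
    taxonomy_rule("nonatt", when = list(attender = FALSE))
  ))
  expect_length(enumerate_groups(tax), 3L)  # male, female, non-attender
})

test_that("assignment honours the documented precedence and carve-outs", {
  tax <- default_taxonomy()
  person <- function(age, sex = "F", contracted = TRUE,
                     gop = 0, cop = 0, sop = 0, hosp = 0) {
    data.frame(enrollee_id = "x", year = 2019L, sex = sex, age = age,
               contracted = contracted, community_id = "c1",
               visits_gop = gop, visits_cop = cop, visits_sop = sop,
               visits_hosp = hosp, cost_gop = 0, cost_cop = 0, cost_sop = 0,
               cost_hosp = 0, total_visits = gop + cop + sop + hosp,
               total_cost = 0, stringsAsFactors = FALSE)
  }
  # no visits at age 5: the non-attender group
  expect_match(assign_group(person(5), tax), "^nonatt")
  # early-childhood chronic, regardless of sex or contract
  expect_equal(assign_group(person(5, "F", TRUE, cop = 2), tax),
               assign_group(person(5, "M", FALSE, cop = 2), tax))
  expect_match(assign_group(person(5, cop = 2), tax), "^childchron")
  # special without chronic, no hospitalization
  expect_match(assign_group(person(40, sop = 3), tax), "^special")
  expect_match(assign_group(person(40, sop = 3, cop = 1), tax), "^spchron")
  # hospitalization outranks every outpatient pattern
  expect_match(assign_group(person(40, gop = 2, cop = 1, sop = 1, hosp = 1),
                            tax), "^hosp")
  # chronic-only adults use coarse bands without a sex split
  expect_equal(assign_group(person(50, "F", TRUE, cop = 5), tax),
               "chronic|c1|46-59|*|v4+")
  # general-outpatient-only keeps the full cross
  expect_equal(assign_group(person(30, "M", FALSE, gop = 2), tax),
               "gop|c0|18-45|M|v2-3")
})

test_that("assignment is total, closed and deterministic on simulated data", {
  sim <- simulate_population(sim_config(n_enrollees = 10000, years = 2019L,
                                        seed = 3))
  people <- aggregate_claims(sim$roster, sim$claims, 2019)
  tax <- default_taxonomy()
  g1 <- assign_group(people, tax)
  expect_false(anyNA(g1))
  expect_true(all(g1 %in% enumerate_groups(tax)))
  expect_identical(g1, assign_group(people, tax))
  # everyone with no visits is a non-attender and vice versa
  expect_identical(startsWith(g1, "nonatt"), people$total_visits == 0L)
})

test_that("the group table partitions the population and conserves cost", {
  sim <- simulate_population(sim_config(n_enrollees = 5000, years = 2019L,
                                        seed = 9))
  people <- aggregate_claims(sim$roster, sim$claims, 2019)
  tab <- build_group_table(people, default_taxonomy())
  expect_equal(nrow(tab), 214L)
  expect_identical(sum(tab$n), nrow(people))
  expect_identical(sum(round(tab$aggregate_cost * 100)),
                   sum(round(people$total_cost * 100)))
  # empty groups retained with undefined mean cost
  expect_true(any(tab$n == 0L))
  expect_true(all(is.na(tab$mean_cost[tab$n == 0L])))
  expect_true(all(!is.na(tab$mean_cost[tab$n > 0L])))
  # the non-attender group exists and costs nothing
  na_row <- tab[tab$pattern == "nonatt", ]
  expect_gt(na_row$n, 0L)
  expect_equal(na_row$mean_cost, 0)
})

test_that("mixed-year input and invalid configurations are rejected", {
  sim <- simulate_population(sim_config(n_enrollees = 200, years = 2019:2020,
                                        seed = 2))
  people <- do.call(rbind, lapply(2019:2020, function(y)
    aggregate_claims(sim$roster, sim$claims, y)))
  expect_error(build_group_table(people, default_taxonomy()), "years")
  # overlapping bands are a validation error
  expect_error(band_table(c("a", "b"), c(0, 5), c(6, 10)), "gaps or overlaps")
  # a taxonomy with a coverage hole errors at validation time
  expect_error(taxonomy(list(
    taxonomy_rule("gop_only", when = list(gop = "pos"),
                  axes = c("age", "sex")),
    taxonomy_rule("nonatt", when = list(attender = FALSE))
  )), "cover")
})

test_that("the shipped YAML taxonomy equals the built-in default", {
  path <- system.file("extdata", "taxonomy_default.yaml",
                      package = "healthperf")
  expect_true(nzchar(path))
  tax <- read_taxonomy(path)
  expect_identical(enumerate_groups(tax),
                   enumerate_groups(default_taxonomy()))
  # and survives a write/read round-trip
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_taxonomy(tax, tmp)
  expect_identical(enumerate_groups(read_taxonomy(tmp)),
                   enumerate_groups(tax))
})
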