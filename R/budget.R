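#' Allocate risk-adjusted capitation budgets
#'
#' Each enrollee's budget is `base_rate` times the cost weight of their
#' health-risk group; community budgets are the sums over their members.
#' With `base_rate` equal to the reference population's per-capita mean
#' cost and weights computed over all enrollees, the total budget equals
#' that reference population's total cost — pure capitation scaled by
#' relative risk. Weights typically come from a stated reference year
#' (e.g. the year before the budget year); which year is a deliberate,
#' explicit modelling input.
#'
#' Non-attender groups have weight 0 and hence zero budget by default;
#' `floor_weight` imposes a minimum weight (e.g. 0.1) if a zero budget
#' for never-attenders is undesirable.
#'
#' @param people per-enrollee profiles (one year) from
#'   [aggregate_claims()], with `community_id` set.
#' @param tax taxonomy used to assign each enrollee's group.
#' @param weights cost weights from [compute_weights()] (any year's).
#' @param base_rate money per enrollee: the per-capita budget for an
#'   average-risk (weight 1) person. Defaults to the `reference_mean`
#'   attribute carried by `weights`.
#' @param floor_weight minimum weight applied to every enrollee
#'   (default 0, i.e. off).
#' @return an object of class `"budget_allocation"`: list with `year`,
#'   `base_rate`, `enrollee` (data frame `enrollee_id`, `community_id`,
#'   `group_id`, `weight`, `budget`) and `community` (data frame
#'   `community_id`, `n`, `budget`).
#' @export
allocate_budget <- function(people, tax, weights, base_rate = NULL,
                            floor_weight = 0) {
  if (is.null(base_rate)) base_rate <- attr(weights, "reference_mean")
  stopifnot(is.numeric(base_rate), length(base_rate) == 1L, base_rate >= 0,
            floor_weight >= 0)
  if (any(is.na(people$community_id) | people$community_id == ""))
    stop("every enrollee must belong to a community")
  gid <- assign_group(people, tax)
  w <- weights$weight[match(gid, weights$group_id)]
  if (anyNA(w))
    stop("no cost weight for group(s): ",
         paste(utils::head(unique(gid[is.na(w)]), 3), collapse = ", "))
  w <- pmax(w, floor_weight)
  budget <- base_rate * w
  enrollee <- data.frame(
    enrollee_id = people$enrollee_id,
    community_id = people$community_id,
    group_id = gid, weight = w, budget = budget,
    stringsAsFactors = FALSE
  )
  s <- rowsum(budget, people$community_id)
  community <- data.frame(
    community_id = rownames(s),
    n = as.integer(table(people$community_id)[rownames(s)]),
    budget = s[, 1L],
    stringsAsFactors = FALSE
  )
  structure(list(year = unique(people$year), base_rate = base_rate,
                 enrollee = enrollee, community = community),
            class = "budget_allocation")
}

#' Settle community budgets against actual expenses
#'
#' Budgets are compared with actual expenses per community under
#' balance retention: the payment is capped at the budget (the excess is
#' not compensated) and any surplus is retained by the community. So
#' `payment = min(actual, budget)`, `retained_balance =
#' max(budget - actual, 0)`, and per community `payment +
#' retained_balance = budget` — the fund never pays out more than the
#' allocated total. Settlement is computed on amounts rounded to the
#' cent, so these identities are exact.
#'
#' @param allocation a `"budget_allocation"` from [allocate_budget()].
#' @param actuals data frame with columns `community_id` and `actual`
#'   (non-negative money): realized expenses per community.
#' @return data frame of class `"settlement"` with one row per
#'   community: `community_id`, `budget`, `actual`, `payment`,
#'   `retained_balance`, `overrun` (informational excess of actual over
#'   budget).
#' @examples
#' \dontrun{
#' settle_budget(alloc, data.frame(community_id = "c1", actual = 120))
#' }
#' @export
settle_budget <- function(allocation, actuals) {
  stopifnot(inherits(allocation, "budget_allocation"),
            all(c("community_id", "actual") %in% names(actuals)))
  if (any(actuals$actual < 0)) stop("actual expenses must be >= 0")
  com <- allocation$community
  i <- match(com$community_id, actuals$community_id)
  if (anyNA(i))
    stop("no actual expenses reported for community(ies): ",
         paste(utils::head(com$community_id[is.na(i)], 3), collapse = ", "))
  # settle in integer cents: payment + retained_balance = budget exactly
  bc <- cents(round_money(com$budget))
  ac <- cents(round_money(actuals$actual[i]))
  out <- data.frame(
    community_id = com$community_id,
    budget = bc / 100,
    actual = ac / 100,
    payment = pmin(ac, bc) / 100,
    retained_balance = pmax(bc - ac, 0) / 100,
    overrun = pmax(ac - bc, 0) / 100,
    stringsAsFactors = FALSE
  )
  class(out) <- c("settlement", "data.frame")
  out
}
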