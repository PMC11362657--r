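#' Compute cost weights for health-risk groups
#'
#' A group's cost weight is its mean annual cost divided by the
#' per-capita reference mean cost of the same year, so weight 1 marks
#' average resource consumption. The reference population defaults to
#' all enrollees (non-attenders included), which is the per-enrollee
#' basis capitation budgets are priced on; `"attendees_only"` restricts
#' it to enrollees with at least one visit. An explicit numeric
#' `reference_mean` overrides both — used, e.g., to put several years on
#' a common reference-year scale.
#'
#' Empty groups get weight `NA`; the non-attender group (mean cost 0)
#' gets weight 0.
#'
#' @param groups an `"hrg_table"` from [build_group_table()].
#' @param reference `"all_enrollees"` (default) or `"attendees_only"`.
#' @param reference_mean optional positive number: the per-capita mean
#'   cost to normalise by, replacing the in-sample reference.
#' @return data frame with columns `group_id`, `year`, `weight`, plus
#'   attribute `reference_mean`.
#' @export
compute_weights <- function(groups,
                            reference = c("all_enrollees", "attendees_only"),
                            reference_mean = NULL) {
  reference <- match.arg(reference)
  if (is.null(reference_mean)) {
    keep <- if (reference == "all_enrollees") rep(TRUE, nrow(groups))
            else groups$pattern != "nonatt"
    n_ref <- sum(groups$n[keep])
    if (n_ref == 0) stop("reference population is empty")
    reference_mean <- sum_money(groups$aggregate_cost[keep]) / n_ref
  }
  if (!is.finite(reference_mean) || reference_mean <= 0)
    stop("degenerate population: reference mean cost must be positive")
  out <- data.frame(
    group_id = groups$group_id,
    year = groups$year,
    weight = ifelse(groups$n > 0, groups$mean_cost / reference_mean, NA_real_),
    stringsAsFactors = FALSE
  )
  attr(out, "reference_mean") <- reference_mean
  out
}

#' Classify cost weights into the six resource-utilization classes
#'
#' Bands are lower-exclusive / upper-inclusive: class 0 holds weight 0
#' exactly (non-attenders); class 1 is (0, 0.2]; class 2 (0.2, 1];
#' class 3 (1, 4] — strictly above-average consumption; class 4 (4, 8];
#' class 5 above 8. The function is non-decreasing in the weight.
#'
#' @param weight numeric vector of non-negative cost weights (`NA`
#'   passes through).
#' @param cuts increasing positive cut points separating classes 1..5
#'   (default `c(0.2, 1, 4, 8)`).
#' @return integer vector of classes in `0:5` (generally
#'   `0:length(cuts)+1`).
#' @examples
#' classify_weight(c(0, 0.15, 1, 1.01, 9.7))  # 0 1 2 3 5
#' @export
classify_weight <- function(weight, cuts = c(0.2, 1, 4, 8)) {
  stopifnot(is.numeric(cuts), length(cuts) >= 1, all(diff(cuts) > 0),
            all(cuts > 0))
  if (any(weight < 0, na.rm = TRUE)) stop("cost weights must be >= 0")
  cls <- 1L + findInterval(weight, cuts, left.open = TRUE)
  cls[!is.na(weight) & weight == 0] <- 0L
  cls
}

#' Build the utilization-class table for one year
#'
#' Every enrollee inherits the class of their health-risk group; the
#' table tallies headcount and expense per class and their percentage
#' shares. Internal totals are exact; shares are reported rounded half
#' away from zero to 2 decimal places, as in published tables.
#'
#' For year-over-year comparisons ([assess_trend()]) the group-to-class
#' map of a base year can be imposed on a later year via `class_map`:
#' people and expenses are then re-tallied under the base year's class
#' definitions, so share movements reflect enrollees actually moving
#' between groups rather than groups drifting across weight cut points
#' as the reference mean shifts (a constant case-mix basis).
#'
#' @param groups an `"hrg_table"` from [build_group_table()].
#' @param weights matching output of [compute_weights()]; may be `NULL`
#'   when `class_map` is given.
#' @param cuts class cut points, see [classify_weight()].
#' @param class_map optional `group_class` data frame from a previously
#'   built `"utilization_classes"` (columns `group_id`, `class`): fixes
#'   each group's class instead of classifying this year's weights.
#' @return an object of class `"utilization_classes"`: a list with
#'   `year`, `cuts`, `group_class` (data frame `group_id`, `weight`,
#'   `class`), and `classes` (data frame `class`, `n`, `pct_n`,
#'   `expense`, `pct_expense`).
#' @export
build_class_table <- function(groups, weights = NULL, cuts = c(0.2, 1, 4, 8),
                              class_map = NULL) {
  occupied <- groups$n > 0
  if (is.null(class_map)) {
    if (is.null(weights)) stop("either `weights` or `class_map` is required")
    if (!all(groups$group_id %in% weights$group_id))
      stop("weights do not cover every group of the year")
    w <- weights$weight[match(groups$group_id, weights$group_id)]
    if (anyNA(w[occupied])) stop("non-empty group with missing weight")
    cls <- classify_weight(w, cuts)
  } else {
    cls <- class_map$class[match(groups$group_id, class_map$group_id)]
    w <- if (is.null(weights)) rep(NA_real_, nrow(groups))
         else weights$weight[match(groups$group_id, weights$group_id)]
    # groups the base year never occupied: fall back to this year's weight
    fill <- occupied & is.na(cls)
    if (any(fill)) {
      if (anyNA(w[fill]))
        stop("class_map does not cover every non-empty group and no ",
             "weights were given to classify the remainder")
      cls[fill] <- classify_weight(w[fill], cuts)
    }
  }
  levels <- 0:(length(cuts) + 1L)
  f <- factor(cls[occupied], levels = levels)
  n_by <- integer(length(levels))
  exp_by <- numeric(length(levels))
  sn <- rowsum(groups$n[occupied], f)
  se <- rowsum_money(groups$aggregate_cost[occupied], f)
  at <- match(rownames(sn), as.character(levels))
  n_by[at] <- as.integer(sn[, 1L])
  exp_by[at] <- se[, 1L]
  n_tot <- sum(n_by)
  exp_tot <- sum_money(exp_by)
  if (n_tot == 0) stop("empty population")
  tbl <- data.frame(
    class = levels,
    n = n_by,
    pct_n = round_half_up(100 * n_by / n_tot, 2),
    expense = exp_by,
    pct_expense = if (exp_tot > 0) round_half_up(100 * exp_by / exp_tot, 2)
                  else NA_real_,
    row.names = NULL
  )
  structure(list(
    year = unique(groups$year),
    cuts = cuts,
    group_class = data.frame(group_id = groups$group_id, weight = w,
                             class = cls, stringsAsFactors = FALSE),
    classes = tbl
  ), class = "utilization_classes")
}

#' Build a class table from published per-class counts
#'
#' Constructs a `"utilization_classes"` object directly from per-class
#' headcounts (and optionally expenses), e.g. to re-derive percentage
#' shares from a printed distribution table or to compare against one.
#'
#' @param year calendar year label.
#' @param n integer headcounts for classes `0..length(n)-1`.
#' @param expense optional per-class expenses (same length).
#' @param cuts class cut points (metadata only here).
#' @return an object of class `"utilization_classes"` (without a
#'   `group_class` map).
#' @examples
#' ct <- class_table_from_counts(2019,
#'   c(194742, 257985, 116307, 38822, 36279, 17230))
#' ct$classes$pct_n
#' @export
class_table_from_counts <- function(year, n, expense = NULL,
                                    cuts = c(0.2, 1, 4, 8)) {
  stopifnot(length(n) >= 2, all(n >= 0))
  n_tot <- sum(n)
  tbl <- data.frame(
    class = seq_along(n) - 1L,
    n = as.integer(n),
    pct_n = round_half_up(100 * n / n_tot, 2),
    expense = if (is.null(expense)) NA_real_ else expense,
    pct_expense = if (is.null(expense)) NA_real_
                  else round_half_up(100 * expense / sum_money(expense), 2),
    row.names = NULL
  )
  structure(list(year = year, cuts = cuts, group_class = NULL, classes = tbl),
            class = "utilization_classes")
}

#' @export
print.utilization_classes <- function(x, ...) {
  cat("Resource-utilization classes, year", x$year, "\n")
  print(x$classes, row.names = FALSE)
  invisible(x)
}
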