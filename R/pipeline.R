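#' One-year pipeline: claims to utilization-class table
#'
#' Convenience wrapper chaining [aggregate_claims()],
#' [build_group_table()], [compute_weights()] and
#' [build_class_table()] for a single calendar year.
#'
#' @param roster,claims data frames in the package schemas.
#' @param year calendar year.
#' @param tax taxonomy (default [default_taxonomy()]).
#' @param reference,reference_mean passed to [compute_weights()].
#' @param cuts class cut points, see [classify_weight()].
#' @return a `"utilization_classes"` object; the intermediate group
#'   table and weights are attached as attributes `groups` and
#'   `weights`.
#' @export
year_class_table <- function(roster, claims, year, tax = default_taxonomy(),
                             reference = "all_enrollees",
                             reference_mean = NULL,
                             cuts = c(0.2, 1, 4, 8),
                             class_map = NULL) {
  people <- aggregate_claims(roster, claims, year)
  groups <- build_group_table(people, tax)
  weights <- compute_weights(groups, reference = reference,
                             reference_mean = reference_mean)
  ct <- build_class_table(groups, weights, cuts = cuts,
                          class_map = class_map)
  attr(ct, "groups") <- groups
  attr(ct, "weights") <- weights
  ct
}

#' Two-year pipeline: claims to health-performance verdict
#'
#' Runs the full assessment between a base year and a comparison year.
#' With `basis = "fixed"` (default) the base year's group-to-class map
#' and per-capita reference mean are held fixed when tallying the
#' comparison year, so the verdict reflects enrollees moving between
#' health-risk groups on a constant case-mix basis. With
#' `basis = "per_year"` each year is classified against its own
#' reference mean, reproducing the published-table style of per-year
#' distributions (noisier across years, since re-centring the average
#' lets whole groups drift across weight cut points).
#'
#' @param roster,claims data frames in the package schemas.
#' @param year_from,year_to base and comparison calendar years.
#' @param tax taxonomy (default [default_taxonomy()]).
#' @param epsilon tolerance in percentage points, see [assess_trend()].
#' @param basis `"fixed"` or `"per_year"`, see above.
#' @param cuts class cut points, see [classify_weight()].
#' @return a `"trend_verdict"`; the two class tables are attached as
#'   attributes `table_from` and `table_to`.
#' @export
assess_years <- function(roster, claims, year_from, year_to,
                         tax = default_taxonomy(), epsilon = 0,
                         basis = c("fixed", "per_year"),
                         cuts = c(0.2, 1, 4, 8)) {
  basis <- match.arg(basis)
  a <- year_class_table(roster, claims, year_from, tax, cuts = cuts)
  b <- if (basis == "fixed")
    year_class_table(roster, claims, year_to, tax, cuts = cuts,
                     reference_mean = attr(attr(a, "weights"),
                                           "reference_mean"),
                     class_map = a$group_class)
  else
    year_class_table(roster, claims, year_to, tax, cuts = cuts)
  v <- assess_trend(a, b, epsilon = epsilon)
  attr(v, "table_from") <- a
  attr(v, "table_to") <- b
  v
}
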