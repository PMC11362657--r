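#' Assess health performance between two years
#'
#' Compares utilization-class share distributions of two years. The
#' low-utilization block is classes 0 and 1 (non-attenders plus healthy
#' attenders); the high-utilization block is classes 4 and 5 (the more
#' seriously and severely ill). Population health is judged improving
#' when the low block's share rises while the high block's share falls,
#' worsening in the mirrored case, unchanged when both movements are
#' within the tolerance, and mixed otherwise. Headcount shares and
#' expense shares are judged independently; the overall verdict is their
#' common value when they agree and `"mixed"` when they disagree. When
#' either table lacks expense data the expense verdict is `NA` and the
#' overall verdict follows headcount alone.
#'
#' @param from,to `"utilization_classes"` objects ([build_class_table()]
#'   or [class_table_from_counts()]) for the base and comparison year.
#' @param epsilon tolerance in percentage points; movements of at most
#'   `epsilon` in absolute value count as no change. Default 0 (strict
#'   sign comparison); raise it for small, noisy populations.
#' @return an object of class `"trend_verdict"`: list with `year_from`,
#'   `year_to`, the four share deltas (percentage points, `to - from`),
#'   `headcount_verdict`, `expense_verdict` and `overall_verdict`.
#' @examples
#' a <- class_table_from_counts(2019, c(300, 400, 200, 50, 30, 20))
#' b <- class_table_from_counts(2020, c(350, 420, 150, 40, 25, 15))
#' assess_trend(a, b)
#' @export
assess_trend <- function(from, to, epsilon = 0) {
  stopifnot(inherits(from, "utilization_classes"),
            inherits(to, "utilization_classes"), epsilon >= 0)
  if (!identical(from$classes$class, to$classes$class))
    stop("class tables are not comparable: different class sets")
  if (!identical(from$cuts, to$cuts))
    stop("class tables are not comparable: different weight cut points")
  k <- length(from$classes$class)
  low <- from$classes$class %in% c(0L, 1L)
  high <- from$classes$class %in% c(k - 2L, k - 1L)

  d_low_n <- sum(to$classes$pct_n[low]) - sum(from$classes$pct_n[low])
  d_high_n <- sum(to$classes$pct_n[high]) - sum(from$classes$pct_n[high])

  have_exp <- !anyNA(from$classes$pct_expense) && !anyNA(to$classes$pct_expense)
  d_low_e <- if (have_exp)
    sum(to$classes$pct_expense[low]) - sum(from$classes$pct_expense[low])
    else NA_real_
  d_high_e <- if (have_exp)
    sum(to$classes$pct_expense[high]) - sum(from$classes$pct_expense[high])
    else NA_real_

  hv <- share_verdict(d_low_n, d_high_n, epsilon)
  ev <- if (have_exp) share_verdict(d_low_e, d_high_e, epsilon)
        else NA_character_
  overall <- if (is.na(ev)) hv else if (hv == ev) hv else "mixed"

  structure(list(
    year_from = from$year, year_to = to$year, epsilon = epsilon,
    delta_low_headcount = d_low_n, delta_high_headcount = d_high_n,
    delta_low_expense = d_low_e, delta_high_expense = d_high_e,
    headcount_verdict = hv, expense_verdict = ev, overall_verdict = overall
  ), class = "trend_verdict")
}

#' Verdict from low/high share movements
#'
#' The elementary sign rule behind [assess_trend()]: `"improving"` when
#' the low-class share rises by more than `epsilon` and the high-class
#' share falls by more than `epsilon`; `"worsening"` in the mirrored
#' case; `"unchanged"` when both movements are within `epsilon`;
#' `"mixed"` otherwise.
#'
#' @param delta_low,delta_high share changes in percentage points.
#' @param epsilon non-negative tolerance in percentage points.
#' @return one of `"improving"`, `"worsening"`, `"unchanged"`, `"mixed"`.
#' @export
share_verdict <- function(delta_low, delta_high, epsilon = 0) {
  stopifnot(epsilon >= 0)
  if (delta_low > epsilon && delta_high < -epsilon) "improving"
  else if (delta_low < -epsilon && delta_high > epsilon) "worsening"
  else if (abs(delta_low) <= epsilon && abs(delta_high) <= epsilon) "unchanged"
  else "mixed"
}

#' @export
print.trend_verdict <- function(x, ...) {
  cat(sprintf("Health performance %s -> %s (epsilon = %g pp)\n",
              x$year_from, x$year_to, x$epsilon))
  cat(sprintf("  headcount: low classes %+.2f pp, high classes %+.2f pp -> %s\n",
              x$delta_low_headcount, x$delta_high_headcount,
              x$headcount_verdict))
  if (!is.na(x$expense_verdict))
    cat(sprintf("  expense:   low classes %+.2f pp, high classes %+.2f pp -> %s\n",
                x$delta_low_expense, x$delta_high_expense, x$expense_verdict))
  cat("  overall:", x$overall_verdict, "\n")
  invisible(x)
}
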