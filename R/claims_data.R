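#' Read an enrollee roster from CSV
#'
#' The roster lists every insured person for one or more calendar years.
#' Expected columns: `enrollee_id`, `year`, `sex` (`M`/`F`), `birth_year`
#' or `age` (at least one), `contracted` (`0`/`1`, family-doctor contract),
#' `community_id`. Files are UTF-8, comma-delimited, with a header row.
#'
#' Age is resolved as `year - birth_year` when only `birth_year` is given;
#' an explicit `age` column takes precedence.
#'
#' @param path path to the roster CSV.
#' @param year optional integer; if given, only rows for that calendar
#'   year are returned (an error is raised if none match).
#' @return a data frame with columns `enrollee_id` (character), `year`
#'   (integer), `sex` (`"M"`/`"F"`), `age` (integer), `contracted`
#'   (logical), `community_id` (character).
#' @seealso [write_roster()], [aggregate_claims()]
#' @export
read_roster <- function(path, year = NULL) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  required <- c("enrollee_id", "year", "sex", "contracted", "community_id")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("roster is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!("birth_year" %in% names(raw)) && !("age" %in% names(raw)))
    stop("roster must contain a 'birth_year' or an 'age' column")

  yr <- suppressWarnings(as.integer(raw$year))
  bad <- which(is.na(yr))
  if (length(bad))
    stop("unparseable year at data row(s): ", paste(utils::head(bad, 5), collapse = ", "))

  if ("age" %in% names(raw)) {
    age <- suppressWarnings(as.integer(raw$age))
  } else {
    by <- suppressWarnings(as.integer(raw$birth_year))
    age <- yr - by
  }
  bad <- which(is.na(age) | age < 0)
  if (length(bad))
    stop("unparseable or negative age at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))

  sex <- toupper(trimws(raw$sex))
  bad <- which(!sex %in% c("M", "F"))
  if (length(bad))
    stop("unparseable sex (expected M or F) at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))

  contracted <- trimws(raw$contracted)
  bad <- which(!contracted %in% c("0", "1"))
  if (length(bad))
    stop("unparseable contracted flag (expected 0 or 1) at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))

  roster <- data.frame(
    enrollee_id  = trimws(raw$enrollee_id),
    year         = yr,
    sex          = sex,
    age          = age,
    contracted   = contracted == "1",
    community_id = trimws(raw$community_id),
    stringsAsFactors = FALSE
  )
  if (any(roster$enrollee_id == ""))
    stop("empty enrollee_id in roster")
  if (!is.null(year)) {
    roster <- roster[roster$year == as.integer(year), , drop = FALSE]
    if (!nrow(roster)) stop("no roster rows for year ", year)
    rownames(roster) <- NULL
  }
  dup <- duplicated(roster[c("enrollee_id", "year")])
  if (any(dup)) {
    ids <- unique(roster$enrollee_id[dup])
    stop("duplicate (enrollee_id, year) roster rows for: ",
         paste(utils::head(ids, 5), collapse = ", "))
  }
  roster
}

#' Write an enrollee roster to CSV
#'
#' Emits the dialect [read_roster()] accepts, so write -> read round-trips
#' exactly.
#'
#' @param roster data frame as returned by [read_roster()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  out <- data.frame(
    enrollee_id  = roster$enrollee_id,
    year         = roster$year,
    sex          = roster$sex,
    age          = roster$age,
    contracted   = as.integer(roster$contracted),
    community_id = roster$community_id
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read claim lines from CSV
#'
#' One row per claim line. Expected columns: `enrollee_id`, `year`,
#' `category` (`GOP` general outpatient, `COP` chronic-disease outpatient,
#' `SOP` special-disease outpatient, `HOSP` hospitalization), `cost`
#' (non-negative, local currency), and optional `n_visits` (positive
#' integer, default 1 — one claim line counts as one visit unless stated).
#'
#' @param path path to the claims CSV.
#' @param year optional integer filter on calendar year.
#' @return data frame with columns `enrollee_id`, `year`, `category`
#'   (one of `"gop"`, `"cop"`, `"sop"`, `"hosp"`), `cost` (2-dp numeric),
#'   `n_visits` (integer).
#' @seealso [write_claims()], [aggregate_claims()]
#' @export
read_claims <- function(path, year = NULL) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  required <- c("enrollee_id", "year", "category", "cost")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("claims file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  yr <- suppressWarnings(as.integer(raw$year))
  if (anyNA(yr))
    stop("unparseable year at data row(s): ",
         paste(utils::head(which(is.na(yr)), 5), collapse = ", "))

  code <- toupper(trimws(raw$category))
  cat_map <- stats::setNames(names(CATEGORY_FILE_CODES), CATEGORY_FILE_CODES)
  bad <- which(!code %in% names(cat_map))
  if (length(bad))
    stop("unknown consultation category at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (expected GOP, COP, SOP or HOSP)")

  cost <- suppressWarnings(as.numeric(raw$cost))
  bad <- which(is.na(cost) | cost < 0)
  if (length(bad))
    stop("unparseable or negative cost at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))

  if ("n_visits" %in% names(raw)) {
    nv <- suppressWarnings(as.integer(raw$n_visits))
    bad <- which(is.na(nv) | nv < 1)
    if (length(bad))
      stop("n_visits must be a positive integer; bad data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  } else {
    nv <- rep.int(1L, nrow(raw))
  }

  claims <- data.frame(
    enrollee_id = trimws(raw$enrollee_id),
    year        = yr,
    category    = unname(cat_map[code]),
    cost        = round_money(cost),
    n_visits    = nv,
    stringsAsFactors = FALSE
  )
  if (!is.null(year)) {
    claims <- claims[claims$year == as.integer(year), , drop = FALSE]
    rownames(claims) <- NULL
  }
  claims
}

#' Write claim lines to CSV
#'
#' @param claims data frame as returned by [read_claims()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_claims <- function(claims, path) {
  out <- data.frame(
    enrollee_id = claims$enrollee_id,
    year        = claims$year,
    category    = unname(CATEGORY_FILE_CODES[claims$category]),
    cost        = sprintf("%.2f", claims$cost),
    n_visits    = claims$n_visits
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Aggregate claim lines into per-enrollee-year profiles
#'
#' Collapses raw claim lines onto the roster, producing exactly one row
#' per enrolled person for the chosen year. Enrollees without any claim
#' appear with zero visits and zero cost — these are the non-attenders,
#' which downstream grouping places in their own group (utilization
#' class 0).
#'
#' @param roster roster data frame ([read_roster()]).
#' @param claims claims data frame ([read_claims()]).
#' @param year calendar year to aggregate (required if the roster spans
#'   several years).
#' @param orphans what to do with claims whose `enrollee_id` is not on
#'   the roster for that year: `"error"` (default) stops; `"drop"`
#'   removes them with a warning. Silent loss would corrupt shares, so
#'   there is no silent mode.
#' @return a data frame (one row per enrollee) with `enrollee_id`,
#'   `year`, `sex`, `age`, `contracted`, `community_id`, per-category
#'   visit counts `visits_gop` .. `visits_hosp`, per-category costs
#'   `cost_gop` .. `cost_hosp`, and totals `total_visits`, `total_cost`.
#' @examples
#' roster <- data.frame(enrollee_id = c("a", "b"), year = 2019,
#'                      sex = c("F", "M"), age = c(30, 70),
#'                      contracted = c(TRUE, FALSE),
#'                      community_id = "c1")
#' claims <- data.frame(enrollee_id = "a", year = 2019, category = "gop",
#'                      cost = 120, n_visits = 2L)
#' aggregate_claims(roster, claims, year = 2019)
#' @export
aggregate_claims <- function(roster, claims, year = NULL,
                             orphans = c("error", "drop")) {
  orphans <- match.arg(orphans)
  if (is.null(year)) {
    yrs <- unique(roster$year)
    if (length(yrs) != 1L)
      stop("roster spans several years; pass `year` explicitly")
    year <- yrs
  }
  year <- as.integer(year)
  roster <- roster[roster$year == year, , drop = FALSE]
  if (!nrow(roster)) stop("no roster rows for year ", year)
  if (anyDuplicated(roster$enrollee_id))
    stop("duplicate enrollee_id in roster for year ", year)
  claims <- claims[claims$year == year, , drop = FALSE]

  orphan <- !(claims$enrollee_id %in% roster$enrollee_id)
  if (any(orphan)) {
    ids <- unique(claims$enrollee_id[orphan])
    msg <- paste0(sum(orphan), " claim line(s) reference enrollees absent ",
                  "from the ", year, " roster (e.g. ",
                  paste(utils::head(ids, 3), collapse = ", "), ")")
    if (orphans == "error") stop(msg, "; use orphans = \"drop\" to discard")
    warning(msg, "; dropped")
    claims <- claims[!orphan, , drop = FALSE]
  }

  out <- roster[c("enrollee_id", "year", "sex", "age", "contracted",
                  "community_id")]
  n <- nrow(out)
  idx <- match(claims$enrollee_id, out$enrollee_id)
  for (cat in CATEGORIES) {
    vis <- numeric(n); cst <- numeric(n)
    sel <- claims$category == cat
    if (any(sel)) {
      v <- rowsum(claims$n_visits[sel], idx[sel])
      c2 <- rowsum_money(claims$cost[sel], idx[sel])
      at <- as.integer(rownames(v))
      vis[at] <- v[, 1L]
      cst[at] <- c2[, 1L]
    }
    out[[paste0("visits_", cat)]] <- as.integer(vis)
    out[[paste0("cost_", cat)]] <- cst
  }
  out$total_visits <- out$visits_gop + out$visits_cop + out$visits_sop +
    out$visits_hosp
  out$total_cost <- (cents(out$cost_gop) + cents(out$cost_cop) +
                     cents(out$cost_sop) + cents(out$cost_hosp)) / 100
  rownames(out) <- NULL
  out
}
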