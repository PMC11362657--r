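#' Age bands and visit levels
#'
#' Helpers building the band tables used by [taxonomy()]. Bands are
#' closed integer ranges evaluated on age (in whole years) at the claim
#' year; visit levels are closed integer ranges on the annual visit
#' count. The defaults partition ages 0–6, 7–17, 18–45, 46–59, 60–79 and
#' 80+, and visit counts 1, 2–3, 4–5 and 6+ (the 0-visit level is the
#' non-attender group, handled by its own rule).
#'
#' @param label band labels.
#' @param lower,upper inclusive integer bounds (`Inf` for unbounded).
#' @return a data frame with columns `label`, `lower`, `upper`.
#' @export
band_table <- function(label, lower, upper) {
  stopifnot(length(label) == length(lower), length(lower) == length(upper))
  if (any(lower > upper)) stop("band lower bound exceeds upper bound")
  o <- order(lower)
  b <- data.frame(label = as.character(label)[o], lower = lower[o],
                  upper = upper[o], stringsAsFactors = FALSE)
  gaps <- b$lower[-1L] != b$upper[-nrow(b)] + 1L
  if (nrow(b) > 1L && any(gaps))
    stop("bands must partition their range with no gaps or overlaps")
  b
}

#' @rdname band_table
#' @export
default_age_bands <- function() {
  band_table(c("0-6", "7-17", "18-45", "46-59", "60-79", "80+"),
             c(0, 7, 18, 46, 60, 80), c(6, 17, 45, 59, 79, Inf))
}

#' @rdname band_table
#' @export
default_visit_levels <- function() {
  band_table(c("v1", "v2-3", "v4-5", "v6+"), c(1, 2, 4, 6), c(1, 3, 5, Inf))
}

band_of <- function(x, bands) {
  i <- findInterval(x, bands$lower)
  i[x > bands$upper[pmax(i, 1L)]] <- 0L  # falls in a gap (validated away)
  out <- rep(NA_character_, length(x))
  ok <- i >= 1L
  out[ok] <- bands$label[i[ok]]
  out
}

#' Build a taxonomy rule
#'
#' A rule is one row of the precedence-ordered rule list of a
#' [taxonomy()]. The first rule whose `when` conditions all hold claims
#' the enrollee-year; the rule's `axes` then determine which cell
#' (group) within the rule the person occupies.
#'
#' @param pattern short stable label for the rule (first field of every
#'   `group_id` it emits).
#' @param when named list of matching conditions. Recognised names:
#'   `gop`, `cop`, `sop`, `hosp` — each `"pos"` (visits > 0) or `"zero"`;
#'   `attender` — `TRUE`/`FALSE` (any visit at all);
#'   `age_min`, `age_max` — inclusive bounds in whole years.
#' @param axes character subset of `c("contract", "age", "sex",
#'   "visits")`: the axes crossed within the rule. Axes not listed are
#'   collapsed (shown as `*` in the group id).
#' @param age_bands,visit_levels optional [band_table()] overrides used
#'   only inside this rule (coarsenings).
#' @return an object of class `"hrg_rule"`.
#' @export
taxonomy_rule <- function(pattern, when = list(), axes = character(),
                          age_bands = NULL, visit_levels = NULL) {
  known <- c("gop", "cop", "sop", "hosp", "attender", "age_min", "age_max")
  if (length(when) && (is.null(names(when)) || !all(names(when) %in% known)))
    stop("unknown `when` condition; allowed: ", paste(known, collapse = ", "))
  bad <- setdiff(axes, c("contract", "age", "sex", "visits"))
  if (length(bad)) stop("unknown axis: ", paste(bad, collapse = ", "))
  structure(list(pattern = pattern, when = when, axes = axes,
                 age_bands = age_bands, visit_levels = visit_levels),
            class = "hrg_rule")
}

#' Health-risk taxonomy
#'
#' A taxonomy is an ordered list of rules (first match wins) plus the
#' default age bands and visit levels shared by rules that do not
#' override them. [default_taxonomy()] ships the package's standard
#' 214-group configuration; [taxonomy()] builds custom ones.
#'
#' @param rules list of [taxonomy_rule()] objects, in precedence order.
#' @param age_bands,visit_levels default [band_table()]s.
#' @return an object of class `"hrg_taxonomy"`.
#' @seealso [enumerate_groups()], [assign_group()], [read_taxonomy()]
#' @export
taxonomy <- function(rules, age_bands = default_age_bands(),
                     visit_levels = default_visit_levels()) {
  stopifnot(length(rules) > 0, all(vapply(rules, inherits, TRUE, "hrg_rule")))
  tax <- structure(list(rules = rules, age_bands = age_bands,
                        visit_levels = visit_levels),
                   class = "hrg_taxonomy")
  validate_taxonomy(tax)
  tax
}

#' Default 214-group taxonomy
#'
#' The standard configuration: one non-attender group; hospitalized
#' enrollees (any other category pattern) crossed by contract, six age
#' bands, sex and four visit levels (96 groups); the same cross for
#' general-outpatient-only attenders (96 groups); chronic-disease
#' outpatients aged 7+ without special-disease or hospitalization claims,
#' crossed by contract, three coarse age bands (7–45, 46–59, 60+) and
#' three coarse visit levels (1, 2–3, 4+; 18 groups); and three
#' carve-outs of one group each — special-disease outpatients with
#' chronic-disease claims, special-disease outpatients without them, and
#' early-childhood (0–6) chronic-disease patients. Total:
#' 1 + 96 + 96 + 18 + 3 = 214 groups, of which 213 are attending.
#'
#' Precedence: hospitalization, then special-with-chronic, special-only,
#' early-childhood chronic, chronic-only, general-outpatient-only, and
#' finally the non-attender rule for enrollees with no visits at all.
#' The visit level of a multi-category attender uses total visits across
#' all categories.
#'
#' @return an `"hrg_taxonomy"` object.
#' @export
default_taxonomy <- function() {
  full_axes <- c("contract", "age", "sex", "visits")
  chronic_age <- band_table(c("7-45", "46-59", "60+"),
                            c(7, 46, 60), c(45, 59, Inf))
  chronic_visits <- band_table(c("v1", "v2-3", "v4+"),
                               c(1, 2, 4), c(1, 3, Inf))
  taxonomy(list(
    taxonomy_rule("hosp",       when = list(hosp = "pos"), axes = full_axes),
    taxonomy_rule("spchron",    when = list(sop = "pos", cop = "pos")),
    taxonomy_rule("special",    when = list(sop = "pos", cop = "zero")),
    taxonomy_rule("childchron", when = list(cop = "pos", age_max = 6)),
    taxonomy_rule("chronic",    when = list(cop = "pos", age_min = 7),
                  axes = c("contract", "age", "visits"),
                  age_bands = chronic_age, visit_levels = chronic_visits),
    taxonomy_rule("gop",        when = list(gop = "pos"), axes = full_axes),
    taxonomy_rule("nonatt",     when = list(attender = FALSE))
  ))
}

#' Validate a taxonomy
#'
#' Checks that age bands and visit levels are gap- and overlap-free,
#' that rule patterns are unique, and that the rule list is total: a
#' probe population covering every consultation-category pattern, age
#' band, sex, contract status and visit level must all be matched by
#' some rule.
#'
#' @param tax an `"hrg_taxonomy"`.
#' @return `tax`, invisibly; errors describe the violation.
#' @export
validate_taxonomy <- function(tax) {
  stopifnot(inherits(tax, "hrg_taxonomy"))
  pats <- vapply(tax$rules, `[[`, "", "pattern")
  if (anyDuplicated(pats))
    stop("duplicate rule pattern label: ", pats[duplicated(pats)][1L])
  if (tax$age_bands$lower[1L] != 0)
    stop("default age bands must start at 0")
  probe <- probe_population(tax)
  g <- assign_group(probe, tax, .validate = FALSE)
  if (anyNA(g)) {
    miss <- probe[is.na(g), , drop = FALSE][1L, ]
    stop("taxonomy does not cover, e.g., age ", miss$age, ", sex ", miss$sex,
         ", visits (gop,cop,sop,hosp) = (", miss$visits_gop, ",",
         miss$visits_cop, ",", miss$visits_sop, ",", miss$visits_hosp, ")")
  }
  invisible(tax)
}

# Exhaustive probe persons: every category presence pattern x contract x
# sex x representative age per band x representative total-visit count per
# level (subject to pattern feasibility).
probe_population <- function(tax) {
  ages <- pmin(tax$age_bands$lower, 120)
  for (r in tax$rules)
    if (!is.null(r$age_bands)) ages <- c(ages, pmin(r$age_bands$lower, 120))
  ages <- unique(ages)
  counts <- unique(c(0, tax$visit_levels$lower,
                     unlist(lapply(tax$rules, function(r)
                       if (is.null(r$visit_levels)) NULL else r$visit_levels$lower))))
  pat <- expand.grid(gop = 0:1, cop = 0:1, sop = 0:1, hosp = 0:1)
  grid <- merge(merge(pat, data.frame(age = ages)),
                expand.grid(sex = c("M", "F"), contracted = c(TRUE, FALSE),
                            total = counts, stringsAsFactors = FALSE))
  npos <- grid$gop + grid$cop + grid$sop + grid$hosp
  grid <- grid[(npos == 0 & grid$total == 0) | (npos > 0 & grid$total >= npos), ]
  # spread total visits: one per present category, remainder on the first
  vm <- as.matrix(grid[c("gop", "cop", "sop", "hosp")])
  first <- max.col(vm, ties.method = "first")
  extra <- pmax(grid$total - rowSums(vm), 0)
  at <- cbind(seq_len(nrow(vm)), first)
  vm[at] <- vm[at] + ifelse(grid$total > 0, extra, 0)
  out <- data.frame(
    enrollee_id = sprintf("p%06d", seq_len(nrow(grid))),
    year = 2000L, sex = grid$sex, age = grid$age,
    contracted = grid$contracted, community_id = "probe",
    visits_gop = vm[, 1L], visits_cop = vm[, 2L], visits_sop = vm[, 3L],
    visits_hosp = vm[, 4L], stringsAsFactors = FALSE
  )
  out$total_visits <- rowSums(vm)
  for (cat in CATEGORIES) out[[paste0("cost_", cat)]] <- 0
  out$total_cost <- 0
  out
}

rule_bands <- function(rule, tax) {
  list(age = if (is.null(rule$age_bands)) tax$age_bands else rule$age_bands,
       visits = if (is.null(rule$visit_levels)) tax$visit_levels
                else rule$visit_levels)
}

#' Enumerate every group a taxonomy can emit
#'
#' Expands each rule over its crossed axes, in rule order, producing the
#' full deterministic list of group identifiers. The shipped
#' [default_taxonomy()] yields exactly 214 groups (213 attending plus
#' the non-attender group).
#'
#' Group ids are pipe-delimited cell descriptors,
#' `pattern|contract|ageband|sex|visitlevel`, with `*` for collapsed
#' axes — stable keys for joining group tables across years.
#'
#' @param tax an `"hrg_taxonomy"`.
#' @return character vector of group ids.
#' @examples
#' length(enumerate_groups(default_taxonomy()))  # 214
#' @export
enumerate_groups <- function(tax) {
  stopifnot(inherits(tax, "hrg_taxonomy"))
  unlist(lapply(tax$rules, function(r) {
    b <- rule_bands(r, tax)
    parts <- list(
      contract = if ("contract" %in% r$axes) c("c1", "c0") else "*",
      age      = if ("age" %in% r$axes) b$age$label else "*",
      sex      = if ("sex" %in% r$axes) c("M", "F") else "*",
      visits   = if ("visits" %in% r$axes) b$visits$label else "*"
    )
    g <- expand.grid(visits = parts$visits, sex = parts$sex, age = parts$age,
                     contract = parts$contract, stringsAsFactors = FALSE)
    paste(r$pattern, g$contract, g$age, g$sex, g$visits, sep = "|")
  }), use.names = FALSE)
}

#' Assign enrollee-years to health-risk groups
#'
#' Pure, vectorized assignment: rules are tried in precedence order and
#' the first match claims the row; the group id is then built from the
#' rule's crossed axes. Enrollees with no visits always land in the
#' non-attender rule of the default taxonomy.
#'
#' @param people per-enrollee-year profiles from [aggregate_claims()].
#' @param tax an `"hrg_taxonomy"`.
#' @param .validate internal; skip the coverage error for probe runs.
#' @return character vector of group ids, one per row of `people`.
#' @export
assign_group <- function(people, tax, .validate = TRUE) {
  stopifnot(inherits(tax, "hrg_taxonomy"))
  n <- nrow(people)
  out <- rep(NA_character_, n)
  pending <- rep(TRUE, n)
  for (r in tax$rules) {
    if (!any(pending)) break
    m <- pending
    for (nm in names(r$when)) {
      v <- r$when[[nm]]
      m <- m & switch(nm,
        gop  = if (v == "pos") people$visits_gop > 0 else people$visits_gop == 0,
        cop  = if (v == "pos") people$visits_cop > 0 else people$visits_cop == 0,
        sop  = if (v == "pos") people$visits_sop > 0 else people$visits_sop == 0,
        hosp = if (v == "pos") people$visits_hosp > 0 else people$visits_hosp == 0,
        attender = if (isTRUE(v)) people$total_visits > 0
                   else people$total_visits == 0,
        age_min = people$age >= v,
        age_max = people$age <= v)
    }
    if (!any(m)) next
    b <- rule_bands(r, tax)
    contract <- if ("contract" %in% r$axes)
      ifelse(people$contracted[m], "c1", "c0") else "*"
    ageb <- if ("age" %in% r$axes) band_of(people$age[m], b$age) else "*"
    sex <- if ("sex" %in% r$axes) people$sex[m] else "*"
    visl <- if ("visits" %in% r$axes)
      band_of(people$total_visits[m], b$visits) else "*"
    out[m] <- paste(r$pattern, contract, ageb, sex, visl, sep = "|")
    pending[m] <- FALSE
  }
  if (.validate && anyNA(out))
    stop(sum(is.na(out)), " enrollee-year(s) matched no taxonomy rule")
  out
}

#' Build the health-risk group table for one year
#'
#' Assigns every enrollee-year to a group and tallies headcount,
#' aggregate cost and mean cost per group. Groups the taxonomy can emit
#' but that are empty in this population are retained with `n = 0` and
#' `mean_cost = NA`. Group member sets partition the population, and
#' aggregate costs conserve total cost exactly.
#'
#' @param people per-enrollee-year profiles from [aggregate_claims()],
#'   all from one calendar year.
#' @param tax an `"hrg_taxonomy"`.
#' @return a data frame of class `"hrg_table"` with columns `group_id`,
#'   `pattern`, `year`, `n`, `aggregate_cost`, `mean_cost` and attribute
#'   `assignment` (the per-row group ids, in input order).
#' @export
build_group_table <- function(people, tax) {
  yrs <- unique(people$year)
  if (length(yrs) != 1L)
    stop("`people` mixes years (", paste(yrs, collapse = ", "),
         "); build one table per year")
  gid <- assign_group(people, tax)
  all_groups <- enumerate_groups(tax)
  f <- factor(gid, levels = all_groups)
  if (anyNA(f)) stop("assignment produced a group id outside the taxonomy")
  n <- as.integer(table(f))
  agg <- rep(0, length(all_groups))
  s <- rowsum_money(people$total_cost, f)  # zero-count levels dropped
  agg[match(rownames(s), all_groups)] <- s[, 1L]
  out <- data.frame(
    group_id = all_groups,
    pattern = sub("\\|.*$", "", all_groups),
    year = yrs,
    n = n,
    aggregate_cost = agg,
    mean_cost = ifelse(n > 0, agg / n, NA_real_),
    stringsAsFactors = FALSE
  )
  class(out) <- c("hrg_table", "data.frame")
  attr(out, "assignment") <- gid
  out
}

#' @export
print.hrg_taxonomy <- function(x, ...) {
  cat("Health-risk taxonomy:", length(x$rules), "rules,",
      length(enumerate_groups(x)), "groups\n")
  for (r in x$rules) {
    b <- rule_bands(r, x)
    k <- prod(c(if ("contract" %in% r$axes) 2L,
                if ("age" %in% r$axes) nrow(b$age),
                if ("sex" %in% r$axes) 2L,
                if ("visits" %in% r$axes) nrow(b$visits), 1L))
    cat(sprintf("  %-10s %3d group(s)  axes: %s\n", r$pattern, k,
                if (length(r$axes)) paste(r$axes, collapse = ", ") else "-"))
  }
  invisible(x)
}

#' Read / write a taxonomy as YAML
#'
#' Serializes the rule list and band tables so a taxonomy can be shipped
#' or edited as a plain-text configuration file. The default
#' configuration is installed at
#' `system.file("extdata", "taxonomy_default.yaml", package = "healthperf")`.
#'
#' @param path YAML file path.
#' @return `read_taxonomy()` returns an `"hrg_taxonomy"`;
#'   `write_taxonomy()` returns `path` invisibly.
#' @export
read_taxonomy <- function(path) {
  y <- yaml::read_yaml(path)
  parse_bands <- function(b) {
    band_table(vapply(b, `[[`, "", "label"),
               vapply(b, function(x) as.numeric(x$lower), 0),
               vapply(b, function(x) {
                 u <- x$upper
                 if (is.character(u) && u == "inf") Inf else as.numeric(u)
               }, 0))
  }
  rules <- lapply(y$rules, function(r) {
    taxonomy_rule(r$pattern,
                  when = if (is.null(r$when)) list() else r$when,
                  axes = if (is.null(r$axes)) character() else unlist(r$axes),
                  age_bands = if (is.null(r$age_bands)) NULL
                              else parse_bands(r$age_bands),
                  visit_levels = if (is.null(r$visit_levels)) NULL
                                 else parse_bands(r$visit_levels))
  })
  taxonomy(rules, age_bands = parse_bands(y$age_bands),
           visit_levels = parse_bands(y$visit_levels))
}

#' @rdname read_taxonomy
#' @param tax an `"hrg_taxonomy"`.
#' @export
write_taxonomy <- function(tax, path) {
  dump_bands <- function(b) {
    lapply(seq_len(nrow(b)), function(i) {
      list(label = b$label[i], lower = b$lower[i],
           upper = if (is.infinite(b$upper[i])) "inf" else b$upper[i])
    })
  }
  y <- list(
    age_bands = dump_bands(tax$age_bands),
    visit_levels = dump_bands(tax$visit_levels),
    rules = lapply(tax$rules, function(r) {
      out <- list(pattern = r$pattern)
      if (length(r$when)) out$when <- r$when
      if (length(r$axes)) out$axes <- as.list(r$axes)
      if (!is.null(r$age_bands)) out$age_bands <- dump_bands(r$age_bands)
      if (!is.null(r$visit_levels))
        out$visit_levels <- dump_bands(r$visit_levels)
      out
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
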