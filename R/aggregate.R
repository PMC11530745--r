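# Year x stratum x category count tables with explicit denominator handling.
#
# Denominator rules: records with unknown gestation are counted in `total`
# but excluded from category counts and from the `known_gestation`
# denominator; for age- or deprivation-stratified tables the percentage
# denominator additionally requires a known stratum; onset tables count
# unknown-onset preterm births in the preterm totals but in neither onset
# column, and their percentage denominator is births with known onset.

STRATIFIERS <- c("none", "maternal_age_band", "simd_quintile", "gestation_week", "onset")

DEFAULT_AGE_BREAKS <- c(20, 25, 30, 35, 40)

age_band_of <- function(age, breaks = DEFAULT_AGE_BREAKS) {
  labels <- c(paste0("<", breaks[1]),
              paste(utils::head(breaks, -1), utils::tail(breaks, -1) - 1, sep = "-"),
              paste0(">=", breaks[length(breaks)]))
  idx <- findInterval(age, breaks) + 1L
  factor(labels[idx], levels = labels)
}

#' Construct a count table from pre-aggregated counts
#'
#' Builds a `count_table` from already-aggregated data (for instance the
#' published yearly tables of a registry report) rather than from records.
#' Invariants are checked: non-negative integer counts, per-year category
#' counts summing to the known-gestation denominator for unstratified
#' tables, and `known_gestation <= total`.
#'
#' @param cells data.frame with columns `year`, `stratum`, `category`,
#'   `count`.
#' @param denominators data.frame with columns `year`, `stratum`, `total`,
#'   `known_gestation`, `known_gestation_and_stratum`, `known_onset`.
#' @param plurality "singleton" or "multiple".
#' @param stratifier one of `r paste0('"', STRATIFIERS, '"', collapse = ", ")`.
#' @return a `count_table` object.
#' @export
count_table <- function(cells, denominators, plurality, stratifier = "none") {
  stratifier <- match.arg(stratifier, STRATIFIERS)
  plurality <- match.arg(plurality, PLURALITY_LEVELS)
  need <- c("year", "stratum", "category", "count")
  if (!all(need %in% names(cells)))
    gestage_error("cells needs columns year, stratum, category, count", "gestage_config_error")
  dneed <- c("year", "stratum", "total", "known_gestation",
             "known_gestation_and_stratum", "known_onset")
  if (!all(dneed %in% names(denominators)))
    gestage_error("denominators missing required columns", "gestage_config_error")
  if (any(cells$count < 0) || any(cells$count != round(cells$count)))
    gestage_error("counts must be non-negative integers", "gestage_domain_error")
  x <- structure(list(cells = cells[need], denominators = denominators[dneed],
                      plurality = plurality, stratifier = stratifier),
                 class = "count_table")
  check_conservation(x)
  x
}

# conservation invariants, asserted on every table build
check_conservation <- function(x) {
  if (nrow(x$cells) == 0) return(invisible(x))
  d <- x$denominators
  if (any(d$known_gestation > d$total))
    gestage_error("known_gestation exceeds total", "gestage_domain_error")
  if (x$stratifier %in% c("none", "gestation_week")) {
    s <- stats::aggregate(count ~ year, data = x$cells, sum)
    m <- merge(s, d[c("year", "known_gestation")], by = "year")
    if (any(m$count != m$known_gestation))
      gestage_error("category counts do not sum to known-gestation denominator",
                    "gestage_domain_error")
  }
  if (x$stratifier == "onset") {
    known <- x$cells[x$cells$category != "unknown_onset", ]
    s <- stats::aggregate(count ~ year + stratum, data = known, sum)
    m <- merge(s, d, by = c("year", "stratum"))
    if (any(m$count != m$known_onset))
      gestage_error("onset counts do not sum to known-onset denominator",
                    "gestage_domain_error")
    if (any(m$known_onset > m$known_gestation_and_stratum))
      gestage_error("known_onset exceeds preterm count", "gestage_domain_error")
  }
  invisible(x)
}

#' Aggregate birth records into a year x stratum x category count table
#'
#' Counts records by calendar year, stratum and gestational category under
#' the registry denominator rules (see the package vignette): unknown
#' gestation is excluded from category counts but kept in the `total`
#' denominator; unknown stratum (age/deprivation) is reported as its own
#' stratum and excluded from stratified percentage denominators; for the
#' onset stratifier, preterm births with unassignable onset are kept in the
#' preterm totals but in neither onset column.
#'
#' @param records a `birth_records` data frame.
#' @param plurality which records to tabulate ("singleton" or "multiple").
#' @param stratifier one of "none" (categories preterm/term/post_term),
#'   "maternal_age_band", "simd_quintile", "gestation_week" (counts per
#'   completed week 22-44) or "onset" (spontaneous/provider-initiated counts
#'   within each preterm sub-category).
#' @param age_breaks lower bounds of the interior maternal age bands
#'   (default 20, 25, 30, 35, 40, giving <20 ... >=40).
#' @return a `count_table`.
#' @examples
#' rec <- generate_records(synthetic_config(years = 2019, births_per_year = 300))
#' count_births(rec, "singleton")
#' @export
count_births <- function(records, plurality = "singleton", stratifier = "none",
                         age_breaks = DEFAULT_AGE_BREAKS) {
  stopifnot(inherits(records, "birth_records"))
  stratifier <- match.arg(stratifier, STRATIFIERS)
  plurality <- match.arg(plurality, PLURALITY_LEVELS)
  r <- records[records$plurality == plurality & records$live_birth, , drop = FALSE]
  if (nrow(r) == 0) {
    empty_cells <- data.frame(year = integer(0), stratum = character(0),
                              category = character(0), count = integer(0))
    empty_den <- data.frame(year = integer(0), stratum = character(0),
                            total = integer(0), known_gestation = integer(0),
                            known_gestation_and_stratum = integer(0),
                            known_onset = integer(0))
    return(count_table(empty_cells, empty_den, plurality, stratifier))
  }
  years <- sort(unique(as.integer(r$year)))
  gc <- categorize_gestation(r$gestation_weeks)
  known <- gc$category != "unknown"

  stratum_of <- switch(stratifier,
    none = , gestation_week = , onset = factor(rep("all", nrow(r))),
    maternal_age_band = {
      b <- age_band_of(r$maternal_age_years, age_breaks)
      factor(ifelse(is.na(b), "unknown", as.character(b)),
             levels = c(levels(b), "unknown"))
    },
    simd_quintile = factor(ifelse(is.na(r$simd_quintile), "unknown",
                                  as.character(r$simd_quintile)),
                           levels = c(as.character(1:5), "unknown")))

  if (stratifier == "onset") return(onset_table(r, gc, years, plurality))

  category <- switch(stratifier,
    gestation_week = factor(ifelse(known, as.character(r$gestation_weeks), NA),
                            levels = as.character(22:44)),
    factor(ifelse(known, as.character(gc$category), NA), levels = GEST_CATEGORIES))

  grid <- expand.grid(year = years, stratum = levels(stratum_of),
                      category = levels(category), stringsAsFactors = FALSE)
  tab <- as.data.frame(table(year = r$year[known], stratum = stratum_of[known],
                             category = category[known]), stringsAsFactors = FALSE)
  tab$year <- as.integer(tab$year)
  cells <- merge(grid, tab, by = c("year", "stratum", "category"), all.x = TRUE)
  cells$count <- ifelse(is.na(cells$Freq), 0L, as.integer(cells$Freq))
  cells$Freq <- NULL
  cells <- cells[order(cells$year, cells$stratum, cells$category), ]

  dgrid <- expand.grid(year = years, stratum = levels(stratum_of),
                       stringsAsFactors = FALSE)
  cnt <- function(keep) {
    t <- as.data.frame(table(year = r$year[keep], stratum = stratum_of[keep]),
                       stringsAsFactors = FALSE)
    t$year <- as.integer(t$year)
    m <- merge(dgrid, t, by = c("year", "stratum"), all.x = TRUE)
    ifelse(is.na(m$Freq[order(m$year, m$stratum)]), 0L,
           as.integer(m$Freq[order(m$year, m$stratum)]))
  }
  dgrid <- dgrid[order(dgrid$year, dgrid$stratum), ]
  denominators <- data.frame(
    dgrid,
    total = cnt(rep(TRUE, nrow(r))),
    known_gestation = cnt(known))
  denominators$known_gestation_and_stratum <-
    ifelse(denominators$stratum == "unknown", 0L, denominators$known_gestation)
  denominators$known_onset <- NA_integer_
  rownames(cells) <- rownames(denominators) <- NULL
  count_table(cells, denominators, plurality, stratifier)
}

# Table of spontaneous / provider-initiated counts within preterm
# sub-categories (strata: all, moderate_late, very, extremely).
onset_table <- function(r, gc, years, plurality) {
  pre <- gc$category == "preterm"
  rp <- r[pre, , drop = FALSE]
  sub <- as.character(gc$preterm_subcategory[pre])
  ons <- if (nrow(rp)) as.character(assign_onset(rp)$onset) else character(0)
  ons[ons == "unknown"] <- "unknown_onset"
  strata <- c("all", PRETERM_SUBCATEGORIES)
  cats <- c("spontaneous", "provider_initiated", "unknown_onset")
  rows <- list()
  dens <- list()
  for (st in strata) {
    keep <- if (st == "all") rep(TRUE, nrow(rp)) else sub == st
    for (y in years) {
      k <- keep & rp$year == y
      counts <- vapply(cats, function(ca) sum(ons[k] == ca), integer(1))
      rows[[length(rows) + 1]] <- data.frame(year = y, stratum = st,
                                             category = cats, count = counts)
      dens[[length(dens) + 1]] <- data.frame(
        year = y, stratum = st,
        total = sum(r$year == y),
        known_gestation = sum(r$year == y & gc$category != "unknown"),
        known_gestation_and_stratum = sum(k),
        known_onset = sum(counts[1:2]))
    }
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  count_table(cells, do.call(rbind, dens), plurality, "onset")
}

#' Count table from a pre-aggregated yearly category table
#'
#' Registry trend reports publish yearly counts in a wide layout: total
#' births, births with unknown gestation, and counts per gestational
#' category. This converts that layout (one row per year, columns `year`,
#' `total`, `unknown_gestation`, `preterm`, `term`, `post_term`) to a
#' `count_table`, deriving the known-gestation denominator as
#' total - unknown_gestation.
#'
#' @param df wide yearly data.frame as above.
#' @param plurality "singleton" or "multiple".
#' @return a `count_table` with stratifier "none".
#' @export
yearly_count_table <- function(df, plurality = "singleton") {
  need <- c("year", "total", "unknown_gestation", GEST_CATEGORIES)
  if (!all(need %in% names(df)))
    gestage_error(paste("need columns:", paste(need, collapse = ", ")),
                  "gestage_config_error")
  cells <- data.frame(
    year = rep(df$year, times = 3),
    stratum = "all",
    category = rep(GEST_CATEGORIES, each = nrow(df)),
    count = c(df$preterm, df$term, df$post_term))
  known <- df$total - df$unknown_gestation
  denominators <- data.frame(year = df$year, stratum = "all", total = df$total,
                             known_gestation = known,
                             known_gestation_and_stratum = known,
                             known_onset = NA_integer_)
  count_table(cells, denominators, plurality, "none")
}

#' Count table from a pre-aggregated onset-of-labour table
#'
#' Converts the published preterm onset layout (one row per year and preterm
#' sub-category, columns `year`, `subcategory` ("all", "moderate_late",
#' "very", "extremely"), `spontaneous`, `provider_initiated`, `total`) to an
#' onset-stratified `count_table`. Preterm births whose onset could not be
#' assigned are `total - spontaneous - provider_initiated`; they stay in the
#' sub-category totals but in neither onset column. Whole-population
#' denominators are taken from the matching yearly table.
#'
#' @param onset_df onset layout data.frame as above.
#' @param yearly_df wide yearly table as in [yearly_count_table()].
#' @param plurality "singleton" or "multiple".
#' @return a `count_table` with stratifier "onset".
#' @export
onset_count_table <- function(onset_df, yearly_df, plurality = "singleton") {
  need <- c("year", "subcategory", "spontaneous", "provider_initiated", "total")
  if (!all(need %in% names(onset_df)))
    gestage_error(paste("need columns:", paste(need, collapse = ", ")),
                  "gestage_config_error")
  o <- onset_df
  o$stratum <- ifelse(o$subcategory == "all", "all", o$subcategory)
  unknown <- o$total - o$spontaneous - o$provider_initiated
  if (any(unknown < 0))
    gestage_error("onset counts exceed sub-category totals", "gestage_domain_error")
  cells <- rbind(
    data.frame(year = o$year, stratum = o$stratum, category = "spontaneous",
               count = o$spontaneous),
    data.frame(year = o$year, stratum = o$stratum, category = "provider_initiated",
               count = o$provider_initiated),
    data.frame(year = o$year, stratum = o$stratum, category = "unknown_onset",
               count = unknown))
  y <- yearly_df[match(o$year, yearly_df$year), ]
  denominators <- data.frame(
    year = o$year, stratum = o$stratum, total = y$total,
    known_gestation = y$total - y$unknown_gestation,
    known_gestation_and_stratum = o$total,
    known_onset = o$spontaneous + o$provider_initiated)
  count_table(cells, denominators, plurality, "onset")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %s births, stratifier = %s: %d cells, years %d-%d\n",
              x$plurality, x$stratifier, nrow(x$cells),
              min(x$cells$year), max(x$cells$year)))
  invisible(x)
}

#' Percentages from a count table
#'
#' Computes the percentage for every cell using the denominator the
#' stratifier calls for: births with known gestation (unstratified and
#' week tables), known gestation and known stratum (age/deprivation tables),
#' or known onset of labour (onset tables). Unrounded percentages are
#' returned in `pct`; `pct_display` is rounded half away from zero to
#' `digits` decimal places for presentation. Cells with a zero denominator
#' are undefined (`NA`), never 0.
#'
#' @param table a `count_table`.
#' @param digits decimal places for `pct_display` (default 1).
#' @return data.frame: `year`, `stratum`, `category`, `count`,
#'   `denominator_kind`, `denominator`, `pct`, `pct_display`.
#' @export
percentages <- function(table, digits = 1) {
  stopifnot(inherits(table, "count_table"))
  kind <- switch(table$stratifier,
                 none = "known_gestation",
                 gestation_week = "known_gestation",
                 maternal_age_band = "known_gestation_and_stratum",
                 simd_quintile = "known_gestation_and_stratum",
                 onset = "known_onset")
  m <- merge(table$cells, table$denominators[c("year", "stratum", kind)],
             by = c("year", "stratum"))
  names(m)[names(m) == kind] <- "denominator"
  m$denominator_kind <- kind
  m$pct <- ifelse(m$denominator > 0, 100 * m$count / m$denominator, NA_real_)
  m$pct_display <- round_half_up(m$pct, digits)
  m[order(m$year, m$stratum, m$category),
    c("year", "stratum", "category", "count", "denominator_kind",
      "denominator", "pct", "pct_display")]
}

#' Serialise a count table to tidy CSV
#'
#' One row per cell with its percentage denominator, in the layout
#' `plurality, stratifier, year, stratum, category, count,
#' denominator_kind, denominator`.
#'
#' @param table a `count_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  p <- percentages(table)
  out <- data.frame(plurality = table$plurality, stratifier = table$stratifier,
                    p[c("year", "stratum", "category", "count",
                        "denominator_kind", "denominator")])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
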