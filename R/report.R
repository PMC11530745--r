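# End-to-end pipeline: records -> classification -> count tables -> trend
# summaries, written as tidy CSVs with a machine-readable run manifest.

#' Pipeline run configuration
#'
#' @param input path to a record-level CSV (read with [read_records()]), or
#'   `NULL` to generate a synthetic cohort.
#' @param synthetic a [synthetic_config()] used when `input` is `NULL`.
#' @param dialect [record_dialect()] for reading `input`.
#' @param pluralities which pluralities to analyse.
#' @param stratifiers stratified tables to produce in addition to the
#'   unstratified, week-of-gestation and onset tables.
#' @param week_years years for the week-by-week distribution table (default:
#'   four evenly spaced years of the observed range).
#' @param start_year,end_year endpoint years for the differences (defaults:
#'   observed range).
#' @param output_dir directory for the output CSVs and manifest.
#' @param alpha two-sided level for intervals.
#' @param digits decimal places for displayed percentages.
#' @param seed seed recorded in the manifest and used for any synthetic
#'   generation (overrides `synthetic$seed` when given).
#' @param verbose log stage-tagged progress lines to standard error.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, synthetic = synthetic_config(),
                       dialect = record_dialect(),
                       pluralities = c("singleton", "multiple"),
                       stratifiers = c("maternal_age_band", "simd_quintile"),
                       week_years = NULL, start_year = NULL, end_year = NULL,
                       output_dir = tempfile("gestage_run_"),
                       alpha = 0.05, digits = 1, seed = NULL, verbose = TRUE) {
  if (alpha <= 0 || alpha >= 1)
    gestage_error("alpha must be in (0, 1)", "gestage_config_error")
  if (!is.null(start_year) && !is.null(end_year) && start_year >= end_year)
    gestage_error("start_year must precede end_year", "gestage_config_error")
  structure(list(input = input, synthetic = synthetic, dialect = dialect,
                 pluralities = match.arg(pluralities, PLURALITY_LEVELS, several.ok = TRUE),
                 stratifiers = stratifiers, week_years = week_years,
                 start_year = start_year, end_year = end_year,
                 output_dir = output_dir, alpha = alpha, digits = digits,
                 seed = seed, verbose = verbose),
            class = "run_config")
}

log_stage <- function(cfg, stage, ...) {
  if (isTRUE(cfg$verbose))
    message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full trend pipeline
#'
#' Reads (or synthesises) pregnancy-level records, classifies them,
#' aggregates them under the registry denominator rules, estimates the
#' trend statistics and writes, per plurality: the yearly category
#' counts/percentages table, a week-by-week distribution table for selected
#' years, a trend-summary table (endpoint percentages, absolute and
#' relative differences with CIs, per-year odds ratios) covering the main
#' categories and the preterm sub-category-by-onset combinations, the
#' onset-by-sub-category table, any requested age/deprivation stratified
#' tables, and the between-extreme-strata gap tables. A JSON manifest
#' records the configuration, seed, package and R versions, and a
#' denominator conservation audit.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the output directory, the written file
#'   paths, the count tables and the trend summaries.
#' @export
run_pipeline <- function(config = run_config()) {
  cfg <- config
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cfg$input)) {
    if (!is.null(cfg$seed)) cfg$synthetic$seed <- as.integer(cfg$seed)
    log_stage(cfg, "records", "generating synthetic cohort (seed %d)", cfg$synthetic$seed)
    records <- generate_records(cfg$synthetic)
  } else {
    log_stage(cfg, "records", "reading %s", cfg$input)
    records <- read_records(cfg$input, cfg$dialect)
    if (nrow(attr(records, "row_errors")))
      log_stage(cfg, "records", "%d rows rejected", nrow(attr(records, "row_errors")))
  }

  files <- character(0)
  tables <- list()
  trends <- list()
  audit <- list()
  for (pl in cfg$pluralities) {
    if (!any(records$plurality == pl)) next
    log_stage(cfg, "aggregate", "%s births", pl)
    tab <- count_births(records, pl)
    onset <- count_births(records, pl, "onset")
    years <- sort(unique(tab$cells$year))
    y0 <- cfg$start_year %||% min(years)
    y1 <- cfg$end_year %||% max(years)
    wk_years <- cfg$week_years %||%
      unique(round(seq(min(years), max(years), length.out = min(4, length(years)))))
    weeks <- count_births(records, pl, "gestation_week")
    wk_cells <- weeks$cells[weeks$cells$year %in% wk_years, ]
    tables[[pl]] <- list(category = tab, onset = onset, weeks = weeks)

    out <- function(d, name) {
      f <- file.path(cfg$output_dir, paste0(name, "_", pl, ".csv"))
      utils::write.csv(d, f, row.names = FALSE, quote = FALSE)
      files <<- c(files, f)
      f
    }
    out(percentages(tab, cfg$digits), "category_counts")
    out(cbind(week = wk_cells$category,
              wk_cells[c("year", "stratum", "count")]), "week_distribution")
    out(percentages(onset, cfg$digits), "onset_counts")

    log_stage(cfg, "trends", "%s births, %d vs %d", pl, y1, y0)
    tl <- list()
    for (cat in GEST_CATEGORIES)
      tl[[cat]] <- try_trend(tab, cat, "all", y0, y1, cfg$alpha)
    # published convention: onset-split percentages are of all births with
    # known gestation and (for preterm) known onset of labour
    for (st in c("all", PRETERM_SUBCATEGORIES))
      for (on in c("spontaneous", "provider_initiated"))
        tl[[paste(st, on, sep = ".")]] <-
          onset_trend(onset, st, on, y0, y1, cfg$alpha)
    tl <- tl[!vapply(tl, is.null, logical(1))]
    trends[[pl]] <- tl
    out(do.call(rbind, lapply(tl, summary)), "trend_summary")

    for (strat in cfg$stratifiers) {
      stab <- count_births(records, pl, strat)
      tables[[pl]][[strat]] <- stab
      out(percentages(stab, cfg$digits), paste0("by_", strat))
      lv <- setdiff(unique(stab$denominators$stratum), "unknown")
      gp <- gap_table(stab, "preterm", c(lv[1], lv[length(lv)]))
      out(gp, paste0("gap_", strat))
    }

    audit[[pl]] <- denominator_audit(tab)
  }

  manifest <- list(
    package = "gestage",
    package_version = as.character(utils::packageVersion("gestage")),
    r_version = R.version.string,
    seed = cfg$seed %||% (if (is.null(cfg$input)) cfg$synthetic$seed else NA),
    input = cfg$input %||% "synthetic",
    pluralities = cfg$pluralities, stratifiers = cfg$stratifiers,
    alpha = cfg$alpha, digits = cfg$digits,
    endpoint_years = c(cfg$start_year %||% NA, cfg$end_year %||% NA),
    or_adjustment = "none (unadjusted per-category odds ratios)",
    denominator_audit = audit)
  mf <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, mf)
  log_stage(cfg, "done", "%d files in %s", length(files), cfg$output_dir)
  invisible(list(output_dir = cfg$output_dir, files = files,
                 tables = tables, trends = trends, manifest = manifest))
}

# a trend fit that may legitimately fail on sparse categories (e.g.
# post-term multiples): returns NULL instead of propagating fit errors
try_trend <- function(tab, category, stratum, y0, y1, alpha) {
  tryCatch(gestage_trend(tab, category, stratum, start_year = y0, end_year = y1,
                         alpha = alpha),
           gestage_fit_error = function(e) NULL,
           gestage_domain_error = function(e) NULL)
}

# trend for an onset split as a share of all births with known gestation
# and known onset of labour (the published trend-table convention)
onset_trend <- function(onset_tab, stratum, onset_cat, y0, y1, alpha) {
  cells <- onset_tab$cells
  ev <- cells[cells$stratum == stratum & cells$category == onset_cat, ]
  unk <- cells[cells$stratum == stratum & cells$category == "unknown_onset", ]
  d <- onset_tab$denominators[onset_tab$denominators$stratum == stratum, ]
  m <- merge(merge(ev[c("year", "count")], unk[c("year", "count")], by = "year",
                   suffixes = c("", "_unknown")),
             d[c("year", "known_gestation")], by = "year")
  m <- m[order(m$year), ]
  trials <- m$known_gestation - m$count_unknown
  keep <- trials > 0
  tryCatch(
    gestage_trend.default(m$count[keep], trials[keep], m$year[keep],
                          start_year = y0, end_year = y1, alpha = alpha,
                          category_key = paste(stratum, onset_cat, sep = ".")),
    gestage_fit_error = function(e) NULL,
    gestage_domain_error = function(e) NULL,
    gestage_config_error = function(e) NULL)
}

denominator_audit <- function(tab) {
  p <- percentages(tab)
  s <- stats::aggregate(count ~ year, data = tab$cells, sum)
  d <- tab$denominators
  list(years = range(d$year),
       total_births = sum(d$total),
       known_gestation = sum(d$known_gestation),
       conservation_ok = all(merge(s, d, by = "year")$count ==
                               merge(s, d, by = "year")$known_gestation))
}

#' Between-strata gap table
#'
#' Per-year percentage of births in a category for two strata (typically
#' the extreme deprivation quintiles or age bands), with the absolute
#' difference in percentage points and the ratio between them — the
#' standard inequality-gap presentation. Percentages, differences and
#' ratios are computed on unrounded proportions and displayed rounded half
#' away from zero to 1 dp.
#'
#' @param table a stratified `count_table`.
#' @param category outcome category (default "preterm").
#' @param strata length-2 character vector: the stratum of interest and the
#'   reference stratum (difference and ratio are first vs second).
#' @return data.frame: `year`, `pct_a`, `pct_b`, `abs_diff`, `ratio`
#'   (display-rounded), plus unrounded `pct_a_raw`, `pct_b_raw`.
#' @export
gap_table <- function(table, category = "preterm", strata) {
  stopifnot(inherits(table, "count_table"), length(strata) == 2)
  p <- percentages(table)
  p <- p[p$category == category & p$stratum %in% strata, ]
  a <- p[p$stratum == strata[1], ]; b <- p[p$stratum == strata[2], ]
  m <- merge(a[c("year", "pct")], b[c("year", "pct")], by = "year",
             suffixes = c("_a", "_b"))
  data.frame(year = m$year,
             pct_a = round_half_up(m$pct_a, 1), pct_b = round_half_up(m$pct_b, 1),
             abs_diff = round_half_up(m$pct_a - m$pct_b, 1),
             ratio = round_half_up(m$pct_a / m$pct_b, 1),
             pct_a_raw = m$pct_a, pct_b_raw = m$pct_b)
}
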