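# Pregnancy-level birth records: validation and CSV input/output.
#
# A record is one pregnancy outcome: a multiple pregnancy (twins or more,
# at least one baby live born) is counted as ONE record, never expanded to
# per-baby rows. Unknown values are held as NA internally and as empty cells
# in CSV; they are a distinct state, never a numeric sentinel.

RECORD_FIELDS <- c("year", "gestation_weeks", "plurality", "maternal_age_years",
                   "simd_quintile", "diagnosis_codes", "induction_flag",
                   "mode_of_delivery", "labour_duration_hours", "live_birth")

PLURALITY_LEVELS <- c("singleton", "multiple")
INDUCTION_LEVELS <- c("yes", "no")
MODE_LEVELS <- c("vaginal", "cs_elective", "cs_emergency", "cs_unspecified")

#' Construct and validate pregnancy-level birth records
#'
#' Validates a data frame of pregnancy-level birth outcomes and returns it
#' classed as `birth_records`. One row is one pregnancy: a multiple pregnancy
#' with at least one live-born baby is a single record. Unknown values are
#' `NA` (empty cells on CSV). Validated invariants: known gestation lies in
#' the 22-44 completed-weeks inclusion window; known SIMD quintile is 1-5
#' (1 = most deprived); known labour duration is non-negative.
#'
#' @param df data frame with columns `year` (integer), `gestation_weeks`
#'   (integer or NA), `plurality` ("singleton"/"multiple"),
#'   `maternal_age_years` (integer or NA), `simd_quintile` (1-5 or NA),
#'   `diagnosis_codes` (ICD-10 codes, `;`-separated string, may be empty),
#'   `induction_flag` ("yes"/"no"/NA), `mode_of_delivery` ("vaginal",
#'   "cs_elective", "cs_emergency", "cs_unspecified" or NA),
#'   `labour_duration_hours` (non-negative or NA), `live_birth` (logical).
#' @return the validated data frame with class `birth_records`.
#' @seealso [read_records()], [generate_records()]
#' @export
birth_records <- function(df) {
  missing_cols <- setdiff(RECORD_FIELDS, names(df))
  if (length(missing_cols))
    gestage_error(paste("missing record columns:", paste(missing_cols, collapse = ", ")),
                  "gestage_config_error")
  df <- df[RECORD_FIELDS]
  df$year <- as.integer(df$year)
  df$gestation_weeks <- as.integer(df$gestation_weeks)
  df$maternal_age_years <- as.integer(df$maternal_age_years)
  df$simd_quintile <- as.integer(df$simd_quintile)
  df$plurality <- as.character(df$plurality)
  df$induction_flag <- as.character(df$induction_flag)
  df$mode_of_delivery <- as.character(df$mode_of_delivery)
  df$diagnosis_codes <- as.character(df$diagnosis_codes)
  df$diagnosis_codes[is.na(df$diagnosis_codes)] <- ""
  df$labour_duration_hours <- as.numeric(df$labour_duration_hours)
  df$live_birth <- as.logical(df$live_birth)
  bad <- record_violations(df)
  if (any(bad != ""))
    gestage_error(paste0("invalid birth records at rows ",
                         paste(utils::head(which(bad != ""), 5), collapse = ", "),
                         ": ", bad[bad != ""][1]),
                  "gestage_row_error")
  class(df) <- c("birth_records", "data.frame")
  df
}

# per-row invariant check; returns "" for valid rows, else a message
record_violations <- function(df) {
  msg <- character(nrow(df))
  flag <- function(cond, text) {
    cond[is.na(cond)] <- FALSE
    msg[cond & msg == ""] <<- text
  }
  flag(is.na(df$year), "missing year")
  flag(!is.na(df$gestation_weeks) &
         (df$gestation_weeks < GESTATION_WINDOW[1] | df$gestation_weeks > GESTATION_WINDOW[2]),
       sprintf("gestation_weeks outside %d-%d", GESTATION_WINDOW[1], GESTATION_WINDOW[2]))
  flag(is.na(df$plurality) | !df$plurality %in% PLURALITY_LEVELS,
       "plurality must be singleton or multiple")
  flag(!is.na(df$simd_quintile) & !df$simd_quintile %in% 1:5, "simd_quintile must be 1-5")
  flag(!is.na(df$induction_flag) & !df$induction_flag %in% INDUCTION_LEVELS,
       "induction_flag must be yes/no or unknown")
  flag(!is.na(df$mode_of_delivery) & !df$mode_of_delivery %in% MODE_LEVELS,
       "unrecognised mode_of_delivery")
  flag(!is.na(df$labour_duration_hours) & df$labour_duration_hours < 0,
       "labour_duration_hours must be non-negative")
  flag(is.na(df$live_birth), "missing live_birth")
  msg
}

#' Column-mapping dialect for record CSV files
#'
#' Registry extracts name and code their columns differently; a dialect maps
#' file columns and coded values onto the canonical record fields used by
#' this package. A dialect can be built in code or loaded from a YAML file
#' with the same two top-level keys.
#'
#' @param columns named character vector or list mapping canonical field
#'   names (see [birth_records()]) to the column names used in the file.
#'   Fields not mentioned keep their canonical name.
#' @param values named list of named character vectors, one per coded field
#'   (`plurality`, `induction_flag`, `mode_of_delivery`), each mapping file
#'   codes to canonical levels, e.g.
#'   `list(mode_of_delivery = c("1" = "vaginal", "2" = "cs_elective"))`.
#' @param na_strings character vector of cell values treated as unknown
#'   (default: the empty cell).
#' @param file path to a YAML dialect file; when given, other arguments are
#'   ignored.
#' @return a `record_dialect` list.
#' @export
record_dialect <- function(columns = NULL, values = NULL, na_strings = "", file = NULL) {
  if (!is.null(file)) {
    cfg <- yaml::read_yaml(file)
    return(record_dialect(columns = cfg$columns, values = lapply(cfg$values, unlist),
                          na_strings = cfg$na_strings %||% ""))
  }
  columns <- as.list(columns %||% list())
  unknown <- setdiff(names(columns), RECORD_FIELDS)
  if (length(unknown))
    gestage_error(paste("dialect maps unknown fields:", paste(unknown, collapse = ", ")),
                  "gestage_config_error")
  structure(list(columns = columns, values = values %||% list(),
                 na_strings = na_strings),
            class = "record_dialect")
}

#' Read pregnancy-level birth records from CSV
#'
#' Reads a one-header-row CSV of pregnancy outcomes, applies the column and
#' value mappings of `dialect`, and validates every row. Rows violating the
#' record invariants (e.g. gestation outside 22-44 weeks, unparseable year)
#' are dropped and reported as row-indexed diagnostics in the
#' `row_errors` attribute; the read fails only when the fraction of bad rows
#' exceeds `max_error_fraction`. Cells matching the dialect's `na_strings`
#' (by default the empty cell) become unknown (`NA`).
#'
#' @param path CSV file path.
#' @param dialect a [record_dialect()]; default assumes canonical column
#'   names and values.
#' @param max_error_fraction abort when more than this fraction of data rows
#'   is invalid (default 0.5).
#' @return a `birth_records` data frame; attribute `row_errors` is a
#'   data.frame (`row`, `message`) describing any rejected rows.
#' @export
read_records <- function(path, dialect = record_dialect(), max_error_fraction = 0.5) {
  if (!file.exists(path))
    gestage_error(paste("no such file:", path), "gestage_config_error")
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = dialect$na_strings)
  for (field in names(dialect$columns)) {
    src <- dialect$columns[[field]]
    if (!src %in% names(raw))
      gestage_error(paste0("dialect maps '", field, "' to missing column '", src, "'"),
                    "gestage_config_error")
    names(raw)[names(raw) == src] <- field
  }
  missing_cols <- setdiff(RECORD_FIELDS, names(raw))
  if (length(missing_cols))
    gestage_error(paste("missing mandatory columns:", paste(missing_cols, collapse = ", ")),
                  "gestage_config_error")
  raw <- raw[RECORD_FIELDS]
  for (field in names(dialect$values)) {
    map <- dialect$values[[field]]
    coded <- !is.na(raw[[field]]) & raw[[field]] %in% names(map)
    raw[[field]][coded] <- map[raw[[field]][coded]]
  }

  # parse numerics leniently: unparseable cells become errors, not NA-unknowns
  numeric_fields <- c("year", "gestation_weeks", "maternal_age_years",
                      "simd_quintile", "labour_duration_hours")
  parse_bad <- character(nrow(raw))
  for (field in numeric_fields) {
    v <- suppressWarnings(as.numeric(raw[[field]]))
    bad <- !is.na(raw[[field]]) & is.na(v)
    parse_bad[bad & parse_bad == ""] <- paste("unparseable", field)
    raw[[field]] <- v
  }
  raw$diagnosis_codes[is.na(raw$diagnosis_codes)] <- ""
  raw$live_birth <- toupper(raw$live_birth) %in% c("TRUE", "T", "1", "YES")

  msg <- record_violations(raw)
  msg[parse_bad != ""] <- parse_bad[parse_bad != ""]
  bad_rows <- which(msg != "")
  if (nrow(raw) > 0 && length(bad_rows) / nrow(raw) > max_error_fraction)
    gestage_error(sprintf("%d of %d rows invalid (max_error_fraction = %g); first: row %d, %s",
                          length(bad_rows), nrow(raw), max_error_fraction,
                          bad_rows[1], msg[bad_rows[1]]),
                  "gestage_row_error")
  out <- birth_records(raw[msg == "", , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "row_errors") <- data.frame(row = bad_rows,
                                        message = msg[bad_rows])
  out
}

#' Write birth records to CSV
#'
#' Writes records in the canonical column layout with unknowns as empty
#' cells, so that `read_records(write_records(x))` round-trips exactly.
#'
#' @param records a `birth_records` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(inherits(records, "birth_records"))
  df <- as.data.frame(records)
  df$plurality <- as.character(df$plurality)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
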