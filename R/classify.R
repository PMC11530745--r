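# Gestational-age categorisation and the hierarchical onset-of-labour rules.

#' Gestational age category levels
#'
#' Category levels used throughout the package. Completed weeks of gestation
#' are categorised by the established international definitions: preterm
#' (<37 weeks), term (37-41 weeks), post-term (>=42 weeks); preterm births are
#' sub-categorised as moderate to late (32-36 weeks), very (28-31 weeks) and
#' extremely (<28 weeks) preterm.
#'
#' @name gest_categories
#' @keywords internal
NULL

GEST_CATEGORIES <- c("preterm", "term", "post_term")
PRETERM_SUBCATEGORIES <- c("extremely", "very", "moderate_late")
GESTATION_WINDOW <- c(22L, 44L)

#' Categorise completed weeks of gestation
#'
#' Partitions completed weeks of gestation at birth into preterm (<37 weeks),
#' term (37-41 weeks) and post-term (>=42 weeks), with preterm births
#' sub-categorised as extremely (<28), very (28-31) or moderate to late
#' (32-36) preterm. Unknown gestation (`NA`) maps to an unknown category.
#'
#' @param weeks integer vector of completed weeks at birth; `NA` for unknown.
#'   Known values must lie in the live-birth inclusion window 22 to 44 weeks.
#' @return a data.frame with one row per input: `category` (factor with
#'   levels preterm/term/post_term/unknown) and `preterm_subcategory` (factor
#'   with levels extremely/very/moderate_late/not_applicable).
#' @examples
#' categorize_gestation(c(22, 27, 28, 31, 32, 36, 37, 41, 42, 44, NA))
#' @export
categorize_gestation <- function(weeks) {
  weeks <- as.integer(weeks)
  known <- !is.na(weeks)
  if (any(known & (weeks < GESTATION_WINDOW[1] | weeks > GESTATION_WINDOW[2])))
    gestage_error(
      sprintf("gestation weeks outside the %d-%d inclusion window; filter records upstream",
              GESTATION_WINDOW[1], GESTATION_WINDOW[2]),
      "gestage_domain_error")
  category <- rep("unknown", length(weeks))
  category[known & weeks < 37] <- "preterm"
  category[known & weeks >= 37 & weeks <= 41] <- "term"
  category[known & weeks >= 42] <- "post_term"
  sub <- rep("not_applicable", length(weeks))
  sub[known & weeks < 28] <- "extremely"
  sub[known & weeks >= 28 & weeks <= 31] <- "very"
  sub[known & weeks >= 32 & weeks <= 36] <- "moderate_late"
  data.frame(
    category = factor(category, levels = c(GEST_CATEGORIES, "unknown")),
    preterm_subcategory = factor(sub, levels = c(PRETERM_SUBCATEGORIES, "not_applicable")))
}

#' Detect a preterm pre-labour rupture of membranes diagnosis
#'
#' Returns `TRUE` when any recorded ICD-10 code denotes premature rupture of
#' membranes (codes O42.0-O42.9). Matching is prefix-based on the normalised
#' code (upper-cased, dots stripped), so both "O42.1" and "O421" match, in any
#' diagnostic position.
#'
#' @param codes character vector of ICD-10 codes for one record, or a single
#'   string with codes separated by `;` (the CSV encoding used by
#'   [read_records()]). An empty vector/string gives `FALSE`.
#' @return logical scalar.
#' @examples
#' match_pprom(c("Z37.0", "O42.1")) # TRUE
#' match_pprom("O420;Z370")         # TRUE
#' match_pprom("O41.1")             # FALSE
#' @export
match_pprom <- function(codes) {
  if (length(codes) == 0) return(FALSE)
  if (length(codes) == 1 && is.character(codes) && grepl(";", codes, fixed = TRUE))
    codes <- strsplit(codes, ";", fixed = TRUE)[[1]]
  codes <- toupper(gsub(".", "", trimws(codes), fixed = TRUE))
  any(startsWith(codes[!is.na(codes) & nzchar(codes)], "O42"))
}

#' Onset-of-labour rule table
#'
#' The hierarchical rule set used by [assign_onset()], exposed as a data frame
#' for audit. Rules are applied in order; the first matching rule assigns the
#' onset class and mechanism.
#'
#' @return data.frame with columns `rule_group`, `pprom_code`, `induction`,
#'   `mode_of_delivery`, `labour_duration`, `onset`, `mechanism`.
#' @export
onset_rules <- function() {
  data.frame(
    rule_group = 1:7,
    pprom_code = c("yes", rep("no", 6)),
    induction = c("any", "yes", rep("no_or_unknown", 5)),
    mode_of_delivery = c("any", "any", "any_vaginal", "any_cs", "any_cs",
                         "elective_cs", "emergency_cs"),
    labour_duration = c("any", "any", "any", "0", ">0", "unknown", "unknown"),
    onset = c("spontaneous", "provider_initiated", "spontaneous",
              "provider_initiated", "spontaneous", "provider_initiated",
              "spontaneous"),
    mechanism = c("p_prom", "induction_of_labour", "spontaneous_without_p_prom",
                  "prelabour_cs", "spontaneous_without_p_prom",
                  "prelabour_cs", "spontaneous_without_p_prom"))
}

#' Assign onset of labour to preterm birth records
#'
#' Applies the hierarchical onset-of-labour algorithm to preterm birth
#' records. In step 1 all records are checked against rule group 1 (a
#' P-PROM diagnosis, ICD-10 O42.x, in any position: spontaneous onset); the
#' remainder are checked against group 2 (induction of labour recorded:
#' provider-initiated), and so on through group 7. Records matching no rule
#' (e.g. unknown mode of delivery with no induction) receive an unknown
#' onset. Onset of labour is only defined for preterm births; passing any
#' non-preterm record is an error.
#'
#' @param records a `birth_records` data frame (see [birth_records()]), all
#'   rows preterm (known gestation < 37 weeks).
#' @return data.frame with one row per record: `onset` (factor:
#'   spontaneous / provider_initiated / unknown), `mechanism` (factor:
#'   p_prom / spontaneous_without_p_prom / induction_of_labour /
#'   prelabour_cs / none) and `rule_group` (integer 1-7, `NA` when no rule
#'   matched).
#' @examples
#' rec <- birth_records(data.frame(
#'   year = 2019, gestation_weeks = 30, plurality = "singleton",
#'   maternal_age_years = 30, simd_quintile = 3, diagnosis_codes = "O42.0",
#'   induction_flag = "yes", mode_of_delivery = "cs_elective",
#'   labour_duration_hours = 0, live_birth = TRUE))
#' assign_onset(rec)  # rule group 1 wins: spontaneous with P-PROM
#' @export
assign_onset <- function(records) {
  gw <- records$gestation_weeks
  if (any(is.na(gw)) || any(gw >= 37))
    gestage_error("onset of labour is only defined for preterm births (<37 weeks, known gestation)",
                  "gestage_domain_error")
  n <- nrow(records)
  pprom <- vapply(records$diagnosis_codes, match_pprom, logical(1), USE.NAMES = FALSE)
  ind <- as.character(records$induction_flag)
  mode <- as.character(records$mode_of_delivery)
  dur <- records$labour_duration_hours
  is_cs <- mode %in% c("cs_elective", "cs_emergency", "cs_unspecified")

  group <- rep(NA_integer_, n)
  hit <- function(cond) is.na(group) & !is.na(cond) & cond
  group[hit(pprom)] <- 1L
  group[hit(!is.na(ind) & ind == "yes")] <- 2L
  # groups 3-7 require induction "no or unknown"
  no_ind <- is.na(ind) | ind == "no"
  group[hit(no_ind & !is.na(mode) & mode == "vaginal")] <- 3L
  group[hit(no_ind & is_cs & !is.na(dur) & dur == 0)] <- 4L
  group[hit(no_ind & is_cs & !is.na(dur) & dur > 0)] <- 5L
  group[hit(no_ind & !is.na(mode) & mode == "cs_elective" & is.na(dur))] <- 6L
  group[hit(no_ind & !is.na(mode) & mode == "cs_emergency" & is.na(dur))] <- 7L

  rules <- onset_rules()
  onset <- ifelse(is.na(group), "unknown", rules$onset[group])
  mech <- ifelse(is.na(group), "none", rules$mechanism[group])
  data.frame(
    onset = factor(onset, levels = c("spontaneous", "provider_initiated", "unknown")),
    mechanism = factor(mech, levels = c("p_prom", "spontaneous_without_p_prom",
                                        "induction_of_labour", "prelabour_cs", "none")),
    rule_group = group)
}
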