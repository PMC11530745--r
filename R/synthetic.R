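# Synthetic national maternity-registry cohort generator.
#
# Emulates the statistical structure of a national maternity discharge
# registry (one record per pregnancy): yearly birth counts, a logit-linear
# calendar-year trend in preterm risk with maternal-age and deprivation
# offsets, a declining post-term share, an onset-of-labour mixture realised
# through the concrete fields (diagnosis codes, induction flag, mode of
# delivery, labour duration) that the rule-based onset algorithm consumes,
# and small per-field missingness.

AGE_BANDS <- c("<20", "20-24", "25-29", "30-34", "35-39", ">=40")
AGE_BAND_RANGE <- list("<20" = c(16L, 19L), "20-24" = c(20L, 24L),
                       "25-29" = c(25L, 29L), "30-34" = c(30L, 34L),
                       "35-39" = c(35L, 39L), ">=40" = c(40L, 45L))

# Default completed-weeks distribution over 22..44, the empirical shape of a
# recent national singleton year; drawn within each category by
# renormalising the matching slice. Configurable via synthetic_config().
DEFAULT_WEEK_SHAPE <- c(
  6, 14, 17, 28, 46, 55, 64, 69, 83, 109, 152, 225, 394, 697, 1449,  # 22-36
  3826, 7058, 14100, 11215, 7135,                                     # 37-41
  756, 8, 1)                                                          # 42-44
names(DEFAULT_WEEK_SHAPE) <- 22:44

#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the generative model used by [generate_records()].
#' Defaults emulate the scale and structure of recent national data:
#' about 50,000 singleton births a year over 2005-2019, ~1.5% of records
#' multiple pregnancies, an overall preterm level of ~6.4% drifting upward
#' by an odds ratio of 1.01 per year, a post-term share of ~2.6% of
#' non-preterm births falling by 5% per year in odds, a 60/40
#' spontaneous/provider-initiated onset mixture among singleton preterm
#' births, and sub-0.5% missingness in gestation, maternal age and
#' deprivation quintile.
#'
#' @param years inclusive calendar-year range of the cohort.
#' @param births_per_year target number of singleton records per year.
#' @param multiple_fraction proportion of all records that are multiple
#'   pregnancies (a multiple pregnancy is one record).
#' @param preterm_intercept_logodds,preterm_year_slope parameters of
#'   logit P(preterm) = a + b (year - reference year); the reference year is
#'   the midpoint of `years`, so the intercept sets the mid-period level and
#'   exp(b) is the per-year odds ratio.
#' @param subcategory_weights conditional split of preterm births into
#'   moderate_late / very / extremely (must sum to 1).
#' @param postterm_intercept_logodds,postterm_year_slope same logit-linear
#'   model for P(post-term | not preterm) among singletons (post-term
#'   multiple births are vanishingly rare and are not generated).
#' @param age_distribution,simd_distribution categorical weights over the
#'   six maternal age bands and the five deprivation quintiles.
#' @param age_effects,simd_effects additive log-odds offsets on preterm risk
#'   per age band / quintile (defaults reproduce the U-shaped age profile
#'   and the deprivation gradient seen in national data).
#' @param multiple_preterm_offset additive log-odds offset on preterm risk
#'   for multiple pregnancies (default calibrated so ~59% of multiples are
#'   preterm at mid-period).
#' @param onset_mixture list with: `spontaneous`, named P(spontaneous |
#'   preterm, subcategory); `multiple_shift`, additive logit shift of the
#'   spontaneous probability for multiples; `pprom_share`, P-PROM share of
#'   spontaneous onsets; `iol_share`, induction share of provider-initiated
#'   onsets.
#' @param missingness named list of per-field unknown probabilities
#'   (`gestation`, `maternal_age`, `simd`, `induction`, `mode`, `duration`).
#' @param week_distribution positive weights over completed weeks 22-44 used
#'   within categories (names "22".."44").
#' @param seed integer random seed; a fixed seed gives a byte-identical
#'   cohort.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(years = 2005:2019,
                             births_per_year = 50000,
                             multiple_fraction = 0.015,
                             preterm_intercept_logodds = logit(0.064),
                             preterm_year_slope = log(1.01),
                             subcategory_weights = c(moderate_late = 0.8327,
                                                     very = 0.1103,
                                                     extremely = 0.0570),
                             postterm_intercept_logodds = logit(0.0256),
                             postterm_year_slope = log(0.95),
                             age_distribution = c("<20" = 0.056, "20-24" = 0.174,
                                                  "25-29" = 0.272, "30-34" = 0.296,
                                                  "35-39" = 0.167, ">=40" = 0.035),
                             simd_distribution = c(0.256, 0.211, 0.186, 0.182, 0.165),
                             age_effects = logit(c(0.077, 0.066, 0.061,
                                                   0.059, 0.065, 0.079)) - logit(0.064),
                             simd_effects = logit(c(0.077, 0.067, 0.059,
                                                    0.055, 0.051)) - logit(0.064),
                             multiple_preterm_offset = logit(0.587) - logit(0.064),
                             onset_mixture = list(
                               spontaneous = c(moderate_late = 0.601,
                                               very = 0.582,
                                               extremely = 0.657),
                               multiple_shift = logit(0.43) - logit(0.60),
                               pprom_share = 1 / 3,
                               iol_share = 0.45),
                             missingness = list(gestation = 0.002,
                                                maternal_age = 0.00005,
                                                simd = 0.0034,
                                                induction = 0.001,
                                                mode = 0.0005,
                                                duration = 0.01),
                             week_distribution = DEFAULT_WEEK_SHAPE,
                             seed = 1L) {
  cfg <- list(years = as.integer(years), births_per_year = births_per_year,
              multiple_fraction = multiple_fraction,
              preterm_intercept_logodds = preterm_intercept_logodds,
              preterm_year_slope = preterm_year_slope,
              subcategory_weights = subcategory_weights,
              postterm_intercept_logodds = postterm_intercept_logodds,
              postterm_year_slope = postterm_year_slope,
              age_distribution = age_distribution,
              simd_distribution = simd_distribution,
              age_effects = stats::setNames(age_effects, AGE_BANDS),
              simd_effects = simd_effects,
              multiple_preterm_offset = multiple_preterm_offset,
              onset_mixture = onset_mixture,
              missingness = missingness,
              week_distribution = week_distribution,
              reference_year = as.integer(round(mean(range(years)))),
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) gestage_error(msg, "gestage_config_error")
  chk(length(cfg$years) >= 1 && !anyNA(cfg$years), "years must be non-empty integers")
  chk(cfg$births_per_year >= 1, "births_per_year must be positive")
  probs <- c(cfg$multiple_fraction, unlist(cfg$missingness),
             cfg$onset_mixture$spontaneous, cfg$onset_mixture$pprom_share,
             cfg$onset_mixture$iol_share)
  chk(all(probs >= 0 & probs <= 1), "all probabilities must be in [0, 1]")
  sum1 <- function(w) all(w >= 0) && abs(sum(w) - 1) < 1e-9
  chk(sum1(cfg$subcategory_weights), "subcategory_weights must be non-negative and sum to 1")
  chk(sum1(cfg$age_distribution / sum(cfg$age_distribution)) &&
        length(cfg$age_distribution) == 6, "age_distribution needs 6 non-negative weights")
  chk(all(cfg$simd_distribution >= 0) && length(cfg$simd_distribution) == 5,
      "simd_distribution needs 5 non-negative weights")
  chk(all(cfg$week_distribution >= 0) && length(cfg$week_distribution) == 23 &&
        identical(names(cfg$week_distribution), as.character(22:44)),
      "week_distribution must be non-negative with names 22..44")
  chk(setequal(names(cfg$onset_mixture$spontaneous), PRETERM_SUBCATEGORIES),
      "onset_mixture$spontaneous needs one entry per preterm subcategory")
  invisible(cfg)
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

sample_weeks <- function(n, lo, hi, shape) {
  if (n == 0) return(integer(0))
  w <- shape[as.character(lo:hi)]
  if (sum(w) <= 0) w <- rep(1, hi - lo + 1)  # degenerate slice: uniform
  sample(lo:hi, n, replace = TRUE, prob = w)
}

#' Generate a synthetic pregnancy-level cohort
#'
#' Draws one record per pregnancy according to the generative model in a
#' [synthetic_config()]: per-year record counts; gestational category from
#' two logit-linear calendar-year models (preterm, and post-term among
#' non-preterm singletons) with maternal-age, deprivation and plurality
#' offsets; completed weeks within each category from the configured
#' discrete distribution; and, for preterm records, an onset mechanism
#' (P-PROM / spontaneous labour / induction / pre-labour caesarean) that is
#' written into the concrete record fields so that [assign_onset()] recovers
#' the configured onset mixture exactly in expectation. Field-level
#' missingness is applied last. The draw is deterministic for a fixed
#' `config$seed` and leaves the caller's RNG state untouched.
#'
#' @param config a [synthetic_config()].
#' @return a `birth_records` data frame (see [birth_records()]).
#' @examples
#' cfg <- synthetic_config(years = 2018:2019, births_per_year = 500)
#' rec <- generate_records(cfg)
#' table(rec$year, rec$plurality)
#' @export
generate_records <- function(config) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  validate_synthetic_config(config)
  cfg <- config
  n_mult_py <- round(cfg$births_per_year * cfg$multiple_fraction / (1 - cfg$multiple_fraction))
  n_py <- cfg$births_per_year + n_mult_py

  with_seed(cfg$seed, {
    year <- rep(cfg$years, each = n_py)
    n <- length(year)
    is_mult <- rep(rep(c(FALSE, TRUE), c(cfg$births_per_year, n_mult_py)),
                   times = length(cfg$years))

    band <- sample(AGE_BANDS, n, replace = TRUE,
                   prob = cfg$age_distribution / sum(cfg$age_distribution))
    bi <- match(band, AGE_BANDS)
    lo <- vapply(AGE_BAND_RANGE, `[`, integer(1), 1)[bi]
    hi <- vapply(AGE_BAND_RANGE, `[`, integer(1), 2)[bi]
    age <- lo + as.integer(floor(stats::runif(n) * (hi - lo + 1L)))
    simd <- sample(1:5, n, replace = TRUE,
                   prob = cfg$simd_distribution / sum(cfg$simd_distribution))

    dy <- year - cfg$reference_year
    eta <- cfg$preterm_intercept_logodds + cfg$preterm_year_slope * dy +
      cfg$age_effects[band] + cfg$simd_effects[simd] +
      ifelse(is_mult, cfg$multiple_preterm_offset, 0)
    preterm <- stats::runif(n) < inv_logit(eta)

    post <- rep(FALSE, n)
    np <- !preterm & !is_mult
    post[np] <- stats::runif(sum(np)) <
      inv_logit(cfg$postterm_intercept_logodds + cfg$postterm_year_slope * dy[np])

    subcat <- rep(NA_character_, n)
    subcat[preterm] <- sample(names(cfg$subcategory_weights), sum(preterm),
                              replace = TRUE, prob = cfg$subcategory_weights)

    weeks <- integer(n)
    shape <- cfg$week_distribution
    fill <- function(idx, lo, hi) weeks[idx] <<- sample_weeks(length(idx), lo, hi, shape)
    fill(which(subcat == "extremely"), 22L, 27L)
    fill(which(subcat == "very"), 28L, 31L)
    fill(which(subcat == "moderate_late"), 32L, 36L)
    fill(which(!preterm & !post), 37L, 41L)
    fill(which(post), 42L, 44L)

    # onset mechanism for preterm records, realised through record fields
    codes <- character(n)
    induction <- rep("no", n)
    mode <- character(n)
    dur <- rep(NA_real_, n)

    ip <- which(preterm)
    p_sp <- inv_logit(logit(cfg$onset_mixture$spontaneous[subcat[ip]]) +
                        ifelse(is_mult[ip], cfg$onset_mixture$multiple_shift, 0))
    spont <- stats::runif(length(ip)) < p_sp
    u <- stats::runif(length(ip))
    mech <- character(length(ip))
    mech[spont] <- ifelse(u[spont] < cfg$onset_mixture$pprom_share,
                          "p_prom", "spontaneous_without_p_prom")
    mech[!spont] <- ifelse(u[!spont] < cfg$onset_mixture$iol_share,
                           "induction_of_labour", "prelabour_cs")

    v <- stats::runif(length(ip))
    for (m in unique(mech)) {
      j <- which(mech == m); k <- ip[j]
      switch(m,
        p_prom = {
          codes[k] <- "O42.0"
          mode[k] <- ifelse(v[j] < 0.6, "vaginal", "cs_emergency")
          dur[k] <- stats::rgamma(length(k), 2, 0.25)
        },
        induction_of_labour = {
          induction[k] <- "yes"
          mode[k] <- ifelse(v[j] < 0.7, "vaginal", "cs_emergency")
          dur[k] <- stats::rgamma(length(k), 2, 0.2)
        },
        spontaneous_without_p_prom = {
          # routes: vaginal (rule 3), CS in labour (rule 5),
          # emergency CS with unrecorded duration (rule 7)
          mode[k] <- ifelse(v[j] < 0.85, "vaginal",
                            ifelse(v[j] < 0.97, "cs_emergency", "cs_emergency"))
          dur[k] <- stats::rgamma(length(k), 2, 0.25)
          dur[k][v[j] >= 0.97] <- NA  # rule 7: duration unknown
        },
        prelabour_cs = {
          # routes: CS with zero labour (rule 4), elective CS with
          # unrecorded duration (rule 6)
          mode[k] <- ifelse(v[j] < 0.9,
                            ifelse(v[j] < 0.72, "cs_elective", "cs_emergency"),
                            "cs_elective")
          dur[k] <- 0
          dur[k][v[j] >= 0.9] <- NA  # rule 6
        })
    }

    # term / post-term records: plausible delivery fields, no O42 codes
    it <- which(!preterm)
    vt <- stats::runif(length(it))
    induction[it] <- ifelse(vt < 0.3, "yes", "no")
    mode[it] <- ifelse(vt < 0.7, "vaginal",
                       ifelse(vt < 0.82, "cs_elective", "cs_emergency"))
    dur[it] <- stats::rgamma(length(it), 2, 0.25)
    dur[it][mode[it] == "cs_elective"] <- 0

    # field-level missingness
    drop <- function(x, p) { x[stats::runif(length(x)) < p] <- NA; x }
    weeks <- drop(weeks, cfg$missingness$gestation)
    age <- drop(age, cfg$missingness$maternal_age)
    simd <- drop(simd, cfg$missingness$simd)
    induction <- drop(induction, cfg$missingness$induction)
    mode <- drop(mode, cfg$missingness$mode)
    dur <- drop(dur, cfg$missingness$duration)

    birth_records(data.frame(
      year = year,
      gestation_weeks = weeks,
      plurality = ifelse(is_mult, "multiple", "singleton"),
      maternal_age_years = age,
      simd_quintile = simd,
      diagnosis_codes = codes,
      induction_flag = induction,
      mode_of_delivery = mode,
      labour_duration_hours = round(dur, 1),
      live_birth = TRUE))
  })
}
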