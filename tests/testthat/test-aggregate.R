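hand_cohort <- function() {
  # 10 records for 2019: 2 unknown gestation, 1 unknown SIMD, 1 unknown age,
  # 1 multiple pregnancy, 1 unknown-onset preterm
  bind_records(
    make_record(gestation_weeks = 36, simd_quintile = 1, maternal_age_years = 19),
    make_record(gestation_weeks = 30, simd_quintile = 2, maternal_age_years = 24,
                induction_flag = NA, mode_of_delivery = NA,
                labour_duration_hours = NA),            # preterm, unknown onset
    make_record(gestation_weeks = 27, simd_quintile = 3, diagnosis_codes = "O42.0"),
    make_record(gestation_weeks = NA, simd_quintile = 4),
    make_record(gestation_weeks = NA, simd_quintile = 5),
    make_record(gestation_weeks = 40, simd_quintile = NA),
    make_record(gestation_weeks = 40, maternal_age_years = NA),
    make_record(gestation_weeks = 42, simd_quintile = 5, maternal_age_years = 41),
    make_record(gestation_weeks = 39, simd_quintile = 2, maternal_age_years = 35),
    make_record(gestation_weeks = 33, plurality = "multiple", simd_quintile = 1))
}

test_that("denominators follow the known-gestation / known-stratum rules", {
  tab <- count_births(hand_cohort(), "singleton")
  d <- tab$denominators
  expect_equal(d$total, 9)            # multiples excluded
  expect_equal(d$known_gestation, 7)  # two unknown gestations
  cnt <- function(cat) tab$cells$count[tab$cells$category == cat]
  expect_equal(cnt("preterm"), 3)
  expect_equal(cnt("term"), 3)
  expect_equal(cnt("post_term"), 1)

  simd <- count_births(hand_cohort(), "singleton", "simd_quintile")
  ds <- simd$denominators
  expect_equal(sum(ds$known_gestation_and_stratum), 6)  # 7 known gest - 1 unknown SIMD
  expect_equal(ds$known_gestation_and_stratum[ds$stratum == "unknown"], 0)
  expect_equal(sum(ds$total), 9)

  age <- count_births(hand_cohort(), "singleton", "maternal_age_band")
  da <- age$denominators
  expect_equal(sum(da$known_gestation_and_stratum), 6)
  expect_equal(da$known_gestation_and_stratum[da$stratum == "<20"], 1)
  expect_equal(da$known_gestation_and_stratum[da$stratum == ">=40"], 1)
})

test_that("unknown-onset preterm births stay in totals but not in onset columns", {
  ot <- count_births(hand_cohort(), "singleton", "onset")
  all_row <- ot$denominators[ot$denominators$stratum == "all", ]
  expect_equal(all_row$known_gestation_and_stratum, 3)  # preterm count
  expect_equal(all_row$known_onset, 2)                  # one unassignable
  cells <- ot$cells[ot$cells$stratum == "all", ]
  expect_equal(cells$count[cells$category == "unknown_onset"], 1)
  # the only very-preterm record has unknown onset: it stays in the
  # sub-category total but the onset-share denominator is empty
  very <- ot$denominators[ot$denominators$stratum == "very", ]
  expect_equal(very$known_gestation_and_stratum, 1)
  expect_equal(very$known_onset, 0)
  p <- percentages(ot)
  expect_true(is.na(p$pct[p$stratum == "very" & p$category == "spontaneous"]))
})

test_that("counts are conserved when aggregating (and sum across strata)", {
  rec <- generate_records(synthetic_config(years = 2018:2019, births_per_year = 1500,
                                           seed = 21))
  for (pl in c("singleton", "multiple")) {
    tab <- count_births(rec, pl)
    s <- aggregate(count ~ year, data = tab$cells, sum)
    expect_equal(s$count,
                 tab$denominators$known_gestation[order(tab$denominators$year)])
    # week-of-gestation table sums to the same denominator
    wk <- count_births(rec, pl, "gestation_week")
    sw <- aggregate(count ~ year, data = wk$cells, sum)
    expect_equal(sw$count, s$count)
    # stratified counts (including the unknown-stratum residue) reproduce
    # the unstratified table exactly
    for (strat in c("maternal_age_band", "simd_quintile")) {
      st <- count_births(rec, pl, strat)
      ss <- aggregate(count ~ year + category, data = st$cells, sum)
      un <- aggregate(count ~ year + category, data = tab$cells, sum)
      m <- merge(ss, un, by = c("year", "category"))
      expect_equal(m$count.x, m$count.y)
    }
  }
})

test_that("empty input gives an empty table with zero denominators", {
  rec <- hand_cohort()[0, ]
  class(rec) <- c("birth_records", "data.frame")
  tab <- count_births(rec, "singleton")
  expect_equal(nrow(tab$cells), 0)
  expect_equal(sum(tab$denominators$total), 0)
})

test_that("percentages use the published denominator conventions and rounding", {
  y <- read_yearly_fixture("singleton")
  tab <- yearly_count_table(y, "singleton")
  # known gestation = total - unknown
  d <- tab$denominators
  expect_equal(d$known_gestation[d$year == 2019], 47519 - 12)
  p <- percentages(tab)
  expect_equal(p$pct_display[p$year == 2019 & p$category == "preterm"], 7.2)
  expect_equal(p$pct_display[p$year == 2005 & p$category == "preterm"], 6.5)

  ym <- read_yearly_fixture("multiple")
  expect_equal(round_half_up(100 * sum(ym$preterm) /
                               sum(ym$total - ym$unknown_gestation), 1), 58.7)
})

test_that("zero denominators give undefined percentages, and rounding is half-up", {
  cells <- data.frame(year = 2019, stratum = "all",
                      category = c("preterm", "term", "post_term"), count = 0L)
  dens <- data.frame(year = 2019, stratum = "all", total = 0L, known_gestation = 0L,
                     known_gestation_and_stratum = 0L, known_onset = NA)
  tab <- count_table(cells, dens, "singleton", "none")
  expect_true(all(is.na(percentages(tab)$pct)))

  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(0 / 100 * 100, 1), 0)
  expect_equal(round_half_up(1.005, 2), 1.01)
})

test_that("the constructor rejects tables violating conservation", {
  cells <- data.frame(year = 2019, stratum = "all",
                      category = c("preterm", "term", "post_term"),
                      count = c(10L, 80L, 5L))
  dens <- data.frame(year = 2019, stratum = "all", total = 100L,
                     known_gestation = 100L, known_gestation_and_stratum = 100L,
                     known_onset = NA)
  expect_error(count_table(cells, dens, "singleton", "none"),
               class = "gestage_domain_error")
  dens$known_gestation <- 101L
  expect_error(count_table(cells, dens, "singleton", "none"),
               class = "gestage_domain_error")
})
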