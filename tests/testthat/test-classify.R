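test_that("gestational categorisation partitions the 22-44 week window", {
  gc <- categorize_gestation(22:44)
  expect_equal(as.vector(table(gc$category)[c("preterm", "term", "post_term")]),
               c(15, 5, 3))
  expect_false(any(gc$category == "unknown"))
  # each week maps to exactly one category
  expect_equal(sum(table(gc$category)), 23)
})

test_that("category and subcategory boundaries follow the international definitions", {
  gc <- categorize_gestation(c(22, 27, 28, 31, 32, 36, 37, 41, 42, 44))
  expect_equal(as.character(gc$category),
               c(rep("preterm", 6), "term", "term", "post_term", "post_term"))
  expect_equal(as.character(gc$preterm_subcategory),
               c("extremely", "extremely", "very", "very", "moderate_late",
                 "moderate_late", rep("not_applicable", 4)))
  # subcategory is not_applicable exactly when not preterm
  expect_equal(gc$preterm_subcategory == "not_applicable", gc$category != "preterm")
})

test_that("unknown gestation maps to unknown category; window violations error", {
  gc <- categorize_gestation(c(NA, 36))
  expect_equal(as.character(gc$category), c("unknown", "preterm"))
  expect_equal(as.character(gc$preterm_subcategory)[1], "not_applicable")
  expect_error(categorize_gestation(45), class = "gestage_domain_error")
  expect_error(categorize_gestation(21), class = "gestage_domain_error")
})

test_that("P-PROM code matching is prefix-based in any position", {
  expect_true(match_pprom("O42.1"))
  expect_true(match_pprom(c("Z37.0", "O42.9")))
  expect_true(match_pprom("O420;Z370"))
  expect_true(match_pprom("o42"))
  expect_false(match_pprom("O41.1"))
  expect_false(match_pprom(character(0)))
  expect_false(match_pprom(""))
})

test_that("each onset rule group is reached by its canonical record", {
  cases <- list(
    # codes, induction, mode, duration -> group, onset, mechanism
    list("O42.0", "yes", "cs_elective", 0, 1, "spontaneous", "p_prom"),
    list("", "yes", "cs_elective", 0, 2, "provider_initiated", "induction_of_labour"),
    list("", "no", "vaginal", 5, 3, "spontaneous", "spontaneous_without_p_prom"),
    list("", "no", "cs_emergency", 0, 4, "provider_initiated", "prelabour_cs"),
    list("", "no", "cs_unspecified", 3, 5, "spontaneous", "spontaneous_without_p_prom"),
    list("", "no", "cs_elective", NA, 6, "provider_initiated", "prelabour_cs"),
    list("", "no", "cs_emergency", NA, 7, "spontaneous", "spontaneous_without_p_prom"))
  for (cs in cases) {
    rec <- make_record(gestation_weeks = 30, diagnosis_codes = cs[[1]],
                       induction_flag = cs[[2]], mode_of_delivery = cs[[3]],
                       labour_duration_hours = cs[[4]])
    out <- assign_onset(rec)
    expect_equal(out$rule_group, cs[[5]])
    expect_equal(as.character(out$onset), cs[[6]])
    expect_equal(as.character(out$mechanism), cs[[7]])
  }
})

test_that("the hierarchy is order-dependent: a P-PROM code beats induction", {
  rec <- make_record(diagnosis_codes = "O42.0", induction_flag = "yes",
                     mode_of_delivery = "vaginal", labour_duration_hours = 4)
  out <- assign_onset(rec)
  expect_equal(out$rule_group, 1)
  expect_equal(as.character(out$onset), "spontaneous")
})

test_that("vaginal delivery with unknown induction reaches the spontaneous rule", {
  rec <- make_record(induction_flag = NA, mode_of_delivery = "vaginal",
                     labour_duration_hours = 3)
  expect_equal(assign_onset(rec)$rule_group, 3)
})

test_that("records matching no rule get unknown onset with no rule group", {
  residue <- bind_records(
    make_record(induction_flag = NA, mode_of_delivery = NA,
                labour_duration_hours = NA),
    # unspecified CS with unknown duration matches neither rule 6 nor 7
    make_record(induction_flag = "no", mode_of_delivery = "cs_unspecified",
                labour_duration_hours = NA))
  out <- assign_onset(residue)
  expect_equal(as.character(out$onset), c("unknown", "unknown"))
  expect_equal(as.character(out$mechanism), c("none", "none"))
  expect_true(all(is.na(out$rule_group)))
})

test_that("onset assignment rejects non-preterm records", {
  expect_error(assign_onset(make_record(gestation_weeks = 37)),
               class = "gestage_domain_error")
  expect_error(assign_onset(make_record(gestation_weeks = NA)),
               class = "gestage_domain_error")
})

test_that("complete records always receive an onset, and onset matches mechanism", {
  set.seed(7)
  n <- 500
  recs <- birth_records(data.frame(
    year = 2019, gestation_weeks = sample(22:36, n, TRUE), plurality = "singleton",
    maternal_age_years = 30, simd_quintile = 3,
    diagnosis_codes = sample(c("", "O42.0", "Z37.0", "O41.1"), n, TRUE),
    induction_flag = sample(c("yes", "no"), n, TRUE),
    mode_of_delivery = sample(c("vaginal", "cs_elective", "cs_emergency",
                                "cs_unspecified"), n, TRUE),
    labour_duration_hours = sample(c(0, 2, 8), n, TRUE),
    live_birth = TRUE))
  out <- assign_onset(recs)
  # no unknown onsets when induction, mode and duration are all recorded
  expect_false(any(out$onset == "unknown"))
  expect_false(any(is.na(out$rule_group)))
  spont_mech <- c("p_prom", "spontaneous_without_p_prom")
  expect_equal(out$onset == "spontaneous", as.character(out$mechanism) %in% spont_mech)
  prov_mech <- c("induction_of_labour", "prelabour_cs")
  expect_equal(out$onset == "provider_initiated",
               as.character(out$mechanism) %in% prov_mech)
  # rule group is absent exactly when onset is unknown (never, here)
  expect_equal(is.na(out$rule_group), as.character(out$onset) == "unknown")
})

test_that("the rule table mirrors the implemented hierarchy", {
  rules <- onset_rules()
  expect_equal(rules$rule_group, 1:7)
  expect_setequal(unique(rules$onset), c("spontaneous", "provider_initiated"))
})
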