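# builders for single records and small cohorts used across tests

make_record <- function(year = 2019, gestation_weeks = 30, plurality = "singleton",
                        maternal_age_years = 30, simd_quintile = 3,
                        diagnosis_codes = "", induction_flag = "no",
                        mode_of_delivery = "vaginal", labour_duration_hours = 6,
                        live_birth = TRUE) {
  birth_records(data.frame(
    year = year, gestation_weeks = gestation_weeks, plurality = plurality,
    maternal_age_years = maternal_age_years, simd_quintile = simd_quintile,
    diagnosis_codes = diagnosis_codes, induction_flag = induction_flag,
    mode_of_delivery = mode_of_delivery,
    labour_duration_hours = labour_duration_hours, live_birth = live_birth))
}

bind_records <- function(...) {
  birth_records(do.call(rbind, lapply(list(...), as.data.frame)))
}

extdata <- function(name) {
  path <- system.file("extdata", name, package = "gestage")
  if (path == "") path <- file.path("../../inst/extdata", name)
  path
}

read_yearly_fixture <- function(which = c("singleton", "multiple")) {
  which <- match.arg(which)
  utils::read.csv(extdata(sprintf("scotland_%s_yearly.csv", which)))
}
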