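library(data.table)

TGA <- "transient global amnesia"

# minimal valid report row set; override columns as needed
mk_reports <- function(ids, sex = "female", age_band = "45-64",
                       country = "france", reporter = "physician",
                       serious = TRUE, reaction_onset_date = NA,
                       age_years = NA_real_) {
  data.table(report_id = ids, sex = sex, age_band = age_band,
             country = country, reporter = reporter, serious = serious,
             reaction_onset_date = reaction_onset_date, age_years = age_years)
}

# six-report store: R1-R3 expose drug x (R1, R2 cases), R4-R6 unexposed
# (R4 a case); target PT is TGA -> (a,b,c,d) = (2,1,1,2)
toy_store <- function() {
  report_store(
    reports = mk_reports(sprintf("R%d", 1:6),
                         sex = c("female", "female", "male", "female", "male", "unknown"),
                         age_band = c("45-64", "45-64", "65-74", "45-64", "18-44", "unknown"),
                         reporter = c("physician", "consumer", "physician",
                                      "pharmacist", "physician", "unknown")),
    drugs = data.table(
      report_id = c("R1", "R2", "R3", "R4", "R5", "R6"),
      active_ingredient = c("drug x", "drug x", "drug x", "drug y", "drug y", "drug z"),
      role = c("suspect", "interacting", "suspect", "suspect", "concomitant", "suspect")),
    reactions = data.table(
      report_id = c("R1", "R1", "R2", "R3", "R4", "R5", "R6"),
      term = c(TGA, "headache", TGA, "nausea", TGA, "rash", "dizziness")))
}

# store with unicode names, dates, unknown seriousness; exercises round trips
rt_store <- function() {
  report_store(
    reports = mk_reports(sprintf("U%d", 1:5),
                         sex = c("female", "male", "unknown", "female", "male"),
                         serious = c(TRUE, FALSE, NA, TRUE, NA),
                         reaction_onset_date = c("2021-05-10", NA, "2021-06-01", NA, "2021-07-04"),
                         age_years = c(64, NA, 33, 81, NA),
                         age_band = c("45-64", "unknown", "18-44", "75+", "unknown")),
    drugs = data.table(
      report_id = c("U1", "U1", "U2", "U3", "U4", "U5"),
      active_ingredient = c("tozinameran", "caféine", "drug a", "drug b", "drug c", "drug a"),
      role = c("suspect", "concomitant", "suspect", "interacting", "suspect", "suspect"),
      start_date = c("2021-05-01", NA, NA, "2021-05-20", NA, "2021-07-10")),
    reactions = data.table(
      report_id = c("U1", "U2", "U3", "U3", "U4", "U5"),
      term = c(TGA, "headache", TGA, "fatigue", "naïveté reaction", TGA)))
}

expect_store_equal <- function(s1, s2) {
  o1 <- data.table::copy(s1$reports); data.table::setorderv(o1, "report_id")
  o2 <- data.table::copy(s2$reports); data.table::setorderv(o2, "report_id")
  expect_equal(as.data.frame(o1), as.data.frame(o2), ignore_attr = TRUE)
  key_d <- c("report_id", "active_ingredient", "role", "start_date")
  d1 <- data.table::copy(s1$drugs); data.table::setorderv(d1, key_d[1:3])
  d2 <- data.table::copy(s2$drugs); data.table::setorderv(d2, key_d[1:3])
  expect_equal(as.data.frame(d1[, key_d, with = FALSE]),
               as.data.frame(d2[, key_d, with = FALSE]), ignore_attr = TRUE)
  r1 <- data.table::copy(s1$reactions); data.table::setorderv(r1, c("report_id", "term"))
  r2 <- data.table::copy(s2$reactions); data.table::setorderv(r2, c("report_id", "term"))
  expect_equal(as.data.frame(r1), as.data.frame(r2), ignore_attr = TRUE)
}

# random small store generator for property-style tests
random_store <- function(n, n_drugs = 8, n_events = 5, seed = 1) {
  cfg <- sim_config(n, n_drugs = n_drugs, n_events = n_events,
                    mean_drugs = 2, mean_events = 1.5, seed = seed)
  generate_database(cfg)
}
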