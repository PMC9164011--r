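test_that("reading empty and small files counts reports correctly", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), f)
  expect_equal(n_total(read_reports(f)), 0L)

  s <- toy_store()
  expect_equal(n_total(s), 6L)
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_reports(filter_reports(s, sex = "female"), f2)
  expect_equal(n_total(read_reports(f2)), 3L)
})

test_that("duplicate report ids raise an integrity error", {
  expect_error(
    report_store(mk_reports(c("R1", "R1")),
                 data.table(report_id = c("R1", "R1"),
                            active_ingredient = "x", role = "suspect"),
                 data.table(report_id = c("R1", "R1"), term = "tga")),
    "duplicate report_id")
})

test_that("reports without drugs or reactions are rejected", {
  expect_error(
    report_store(mk_reports(c("R1", "R2")),
                 data.table(report_id = "R1", active_ingredient = "x", role = "suspect"),
                 data.table(report_id = c("R1", "R2"), term = "tga")),
    "without any drug")
  expect_error(
    report_store(mk_reports("R1"),
                 data.table(report_id = "R1", active_ingredient = "x", role = "suspect"),
                 data.table(report_id = character(), term = character())),
    "without any reaction")
})

test_that("off-vocabulary demographics map to unknown with a warning; bad roles error", {
  expect_warning(
    s <- report_store(mk_reports("R1", sex = "hermaphrodite"),
                      data.table(report_id = "R1", active_ingredient = "x", role = "suspect"),
                      data.table(report_id = "R1", term = "tga")),
    "sex")
  expect_equal(s$reports$sex, "unknown")
  expect_error(
    report_store(mk_reports("R1"),
                 data.table(report_id = "R1", active_ingredient = "x", role = "prescribed"),
                 data.table(report_id = "R1", term = "tga")),
    "invalid drug role")
})

test_that("exact ages are binned onto the closed band list (lower bound inclusive)", {
  s <- report_store(
    mk_reports(sprintf("A%d", 1:6), age_band = "unknown",
               age_years = c(1, 2, 44, 45, 75, NA)),
    data.table(report_id = sprintf("A%d", 1:6), active_ingredient = "x", role = "suspect"),
    data.table(report_id = sprintf("A%d", 1:6), term = "tga"))
  expect_equal(s$reports$age_band,
               c("unknown", "2-11", "18-44", "45-64", "75+", "unknown"))
})

test_that("round trips are field-for-field identities in both formats", {
  for (fmt in c("jsonl", "csv")) {
    for (mk in list(rt_store, toy_store)) {
      s <- mk()
      f <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_reports(s, f, fmt)
      expect_store_equal(read_reports(f, fmt), s)
    }
    # empty store round-trips to empty
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    es <- filter_reports(toy_store(), sex = "female", reporter = "pharmacist",
                         age_band = "75+")
    expect_equal(n_total(es), 0L)
    write_reports(es, f, fmt)
    expect_equal(n_total(read_reports(f, fmt)), 0L)
  }
})

test_that("malformed jsonl lines are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"report_id":"R1","drugs":[{"active_ingredient":"x","role":"suspect"}],"reactions":["tga"],"sex":"female","age_band":"45-64","country":"fr","reporter":"physician","serious":true}',
               '{not json'), f)
  expect_error(read_reports(f), "line 2")
})

test_that("filter_reports selects exactly the matching stratum and composes", {
  s <- toy_store()
  expect_equal(n_total(filter_reports(s, sex = "female")), 3L)
  expect_equal(n_total(filter_reports(s, reporter = "lawyer")), 0L)
  # composition equals conjunction (brute-force oracle over the raw table)
  comp <- filter_reports(filter_reports(s, sex = "female"), age_band = "45-64")
  both <- s$reports$report_id[s$reports$sex == "female" & s$reports$age_band == "45-64"]
  expect_setequal(comp$reports$report_id, both)
  expect_error(filter_reports(s, colour = "blue"), "unknown stratum")
  expect_error(filter_reports(s, sex = "woman"), "not a level")
  # the original store is untouched
  expect_equal(n_total(s), 6L)
})

test_that("a field's levels partition the store (unknown included)", {
  s <- random_store(300, seed = 7)
  for (field in c("sex", "age_band", "reporter")) {
    lv <- unique(s$reports[[field]])
    counts <- vapply(lv, function(v)
      n_total(do.call(filter_reports, setNames(list(s, v), c("", field)))), 0L)
    expect_equal(sum(counts), n_total(s))
    expect_true(all(counts <= n_total(s)))
  }
})

test_that("time to onset is the floored day difference, flagged when negative", {
  s <- report_store(
    mk_reports(c("T1", "T2", "T3"),
               reaction_onset_date = c("2021-05-11", "2021-05-01", NA)),
    data.table(report_id = c("T1", "T1", "T2", "T3"),
               active_ingredient = c("x", "y", "x", "x"),
               role = c("suspect", "concomitant", "suspect", "suspect"),
               start_date = c("2021-05-04", "2021-01-01", "2021-05-10", "2021-05-01")),
    data.table(report_id = c("T1", "T2", "T3"), term = "tga"))
  tto <- time_to_onset(s)
  # concomitant start dates never define exposure onset
  expect_equal(tto[report_id == "T1", days], 7)
  expect_true(tto[report_id == "T2", flagged])
  expect_true(is.na(tto[report_id == "T2", days]))
  expect_true(is.na(tto[report_id == "T3", days]) && !tto[report_id == "T3", flagged])
})
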