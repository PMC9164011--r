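test_that("generation is deterministic given the seed and leaves the RNG alone", {
  cfg <- sim_config(500, seed = 77)
  set.seed(1); before <- runif(1)
  s1 <- generate_database(cfg)
  s2 <- generate_database(cfg)
  expect_store_equal(s1, s2)
  set.seed(1); expect_identical(runif(1), before)
  s3 <- generate_database(sim_config(500, seed = 78))
  expect_false(identical(s1$drugs, s3$drugs))
})

test_that("every generated report has at least one drug and one reaction", {
  cfg <- sim_config(2000, mean_drugs = 1.2, mean_events = 1.1, seed = 3,
                    signals = list(list(drug = "drug_002", event = "event_002",
                                        theta = 8)))
  s <- generate_database(cfg)
  expect_setequal(unique(s$drugs$report_id), s$reports$report_id)
  expect_setequal(unique(s$reactions$report_id), s$reports$report_id)
  # injected drug is always suspect
  expect_true(all(s$drugs[active_ingredient == "drug_002", role] == "suspect"))
})

test_that("empirical marginal presence matches the configured law within 3 SE", {
  n <- 1e5
  cfg <- sim_config(n, n_drugs = 50, n_events = 30, seed = 12)
  s <- generate_database(cfg)
  # analytic presence probability under truncated-Poisson slot sampling:
  # P(drug in report) = 1 - E[(1-f)^K], K ~ Pois(mu) | K >= 1
  p_present <- function(f, mu) {
    1 - (exp(-mu * f) - exp(-mu)) / (1 - exp(-mu))
  }
  pres <- table(unique(s$drugs[, .(report_id, active_ingredient)])$active_ingredient) / n
  for (rank in c(1, 3, 10)) {
    f <- cfg$drug_freqs[rank]
    p <- p_present(f, cfg$mean_drugs)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(pres[[sprintf("drug_%03d", rank)]] - p), 3.5 * se)
  }
})

test_that("theta = 1 behaves as the null and infeasible tilts error", {
  covers <- vapply(1:10, function(sd) {
    s <- generate_database(sim_config(20000,
      signals = list(list(drug = "drug_005", event = "event_005", theta = 1)),
      seed = sd))
    r <- disproportionality(s, "event_005", "drug_005")
    r$ci_low <= 1 && r$ci_high >= 1
  }, NA)
  expect_gte(sum(covers), 9L)
  expect_error(
    generate_database(sim_config(100, n_drugs = 2, n_events = 2,
                                 mean_drugs = 3, mean_events = 3,
                                 signals = list(list(drug = "drug_001",
                                                     event = "event_001",
                                                     theta = 50)),
                                 seed = 1)),
    "infeasible")
})

test_that("the fixture reproduces every pinned marginal count exactly", {
  fx <- build_tga_fixture(n_filler = 500)
  fc <- pvsignal:::tga_fixture_counts()
  cs <- is_case(fx, TGA)
  ex <- is_exposed(fx, covid19_vaccine_group())
  expect_equal(sum(cs), 852L)
  expect_equal(sum(cs & ex), 289L)

  grp <- fx$reports[cs & ex]
  all <- fx$reports[cs]
  cnt <- function(x, lev) as.integer(table(factor(x, levels = lev)))
  for (var in c("sex", "age_band", "country", "reporter")) {
    want_grp <- fc[[var]]$group
    got <- cnt(grp[[var]], names(want_grp))
    expect_equal(got, unname(want_grp), info = var)
  }
  expect_equal(sum(all$serious), 620L)
  expect_equal(sum(grp$serious), 178L)

  # vaccine member split 147/69/60/12/1
  memb <- fx$drugs[report_id %in% grp$report_id &
                     active_ingredient %in% covid19_vaccine_group()$members]
  expect_equal(as.integer(table(factor(memb$active_ingredient,
                                       levels = names(fc$members)))),
               unname(fc$members))

  # co-reported counts 31/27/24
  co <- co_reported_terms(fx, TGA, covid19_vaccine_group())
  expect_equal(co[match(c("headache", "confusional state", "fatigue"), co$term), n],
               c(31L, 27L, 24L))

  # deterministic across calls
  expect_store_equal(fx, build_tga_fixture(n_filler = 500))
})

test_that("fixture all-case margins match the published column (with ledgered unknown adjustments)", {
  fx <- build_tga_fixture(n_filler = 0)
  all <- fx$reports
  expect_equal(as.integer(table(factor(all$sex, levels = c("female", "male", "unknown")))),
               c(495L, 337L, 20L))
  expect_equal(as.integer(table(factor(all$age_band, levels = pvsignal:::pv_age_bands))),
               c(1L, 3L, 34L, 286L, 261L, 104L, 163L))
  expect_equal(sum(all$country == "united states of america"), 404L)
  expect_equal(sum(all$reporter == "physician"), 277L)
  expect_equal(sum(all$reporter == "pharmacist"), 39L)
  expect_equal(sum(all$reporter == "other_health_professional"), 80L)
  expect_equal(sum(all$reporter == "consumer"), 268L)
  expect_equal(sum(all$reporter == "lawyer"), 4L)
})

test_that("recovery experiment summarises bias, coverage and null calibration", {
  cfg <- sim_config(20000, signals = list(list(drug = "drug_010",
                                               event = "event_005", theta = 6)),
                    seed = 55)
  rec <- recovery_experiment(cfg, n_replicates = 3)
  expect_equal(nrow(rec$injected), 3L)
  expect_true(all(c("median_ror", "rel_bias_log_ror", "coverage_theta",
                    "flag_rate") %in% names(rec$summary)))
  expect_true(all(rec$injected$theta == 6))
  expect_true(rec$summary$median_ror > 2)
})
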