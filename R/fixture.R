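# Marginal counts of the reference TGA case series (852 worldwide
# spontaneous reports of transient global amnesia, 289 of them associated
# with a COVID-19 vaccine). Where the published reporter counts do not sum
# to the column total (reports can carry several reporter qualifications),
# the named categories are kept exact and the remainder goes to "unknown";
# the published all-case country column over-counts by one, absorbed into
# "unknown". Joint cells are not pinned by any published table and are
# filled by a fixed deterministic interleaving rule.
tga_fixture_counts <- function() {
  list(
    n_cases = 852L, n_group = 289L,
    members = c(tozinameran = 147L, azd1222 = 69L, elasomeran = 60L,
                "jnj-78436735" = 12L, "covid-19 vaccine unspecified" = 1L),
    sex = list(
      group = c(female = 187L, male = 101L, unknown = 1L),
      other = c(female = 308L, male = 236L, unknown = 19L)),
    age_band = list(
      group = c("2-11" = 0L, "12-17" = 0L, "18-44" = 9L, "45-64" = 101L,
                "65-74" = 96L, "75+" = 36L, unknown = 47L),
      other = c("2-11" = 1L, "12-17" = 3L, "18-44" = 25L, "45-64" = 185L,
                "65-74" = 165L, "75+" = 68L, unknown = 116L)),
    country = list(
      group = c("united states of america" = 136L, germany = 18L,
                "united kingdom" = 34L, netherlands = 27L, spain = 14L,
                france = 12L, australia = 14L, italy = 6L, sweden = 10L,
                switzerland = 4L, austria = 1L, portugal = 2L, czechia = 3L,
                denmark = 1L, norway = 2L, finland = 2L, ireland = 2L,
                latvia = 1L),
      other = c("united states of america" = 268L, germany = 61L,
                "united kingdom" = 31L, netherlands = 17L, spain = 24L,
                france = 24L, australia = 20L, italy = 27L, canada = 26L,
                sweden = 6L, switzerland = 8L, austria = 9L, japan = 10L,
                portugal = 5L, czechia = 2L, denmark = 4L, norway = 3L,
                finland = 2L, brazil = 3L, ireland = 1L, unknown = 12L)),
    reporter = list(
      group = c(physician = 48L, pharmacist = 5L,
                other_health_professional = 5L, consumer = 87L, lawyer = 0L,
                unknown = 144L),
      other = c(physician = 229L, pharmacist = 34L,
                other_health_professional = 75L, consumer = 181L, lawyer = 4L,
                unknown = 40L)),
    serious = list(
      group = c("true" = 178L, "false" = 111L),
      other = c("true" = 442L, "false" = 121L)),
    # co-reported PT counts among the vaccine-associated cases
    co_terms = c(headache = 31L, "confusional state" = 27L, fatigue = 24L),
    # non-vaccine ingredients with at least four cases, by case count
    other_drugs = c(atorvastatin = 41L, "influenza vaccine" = 23L,
                    simvastatin = 18L, tadalafil = 17L, sildenafil = 17L,
                    zolpidem = 15L, rosuvastatin = 15L,
                    "alendronic acid" = 11L, baclofen = 7L, heparin = 7L,
                    enzalutamide = 6L, etoricoxib = 4L, iodixanol = 4L,
                    "ibandronic acid" = 4L))
}

expand_counts <- function(counts) rep(names(counts), counts)

# deterministic interleaving: position i gets element order(((i-1)*p) %% n);
# p coprime with n makes this a permutation, a different p per variable
# decorrelates the block structure of the expanded count vectors
det_perm <- function(n, p) {
  if (n <= 1L) return(seq_len(n))
  order(((seq_len(n) - 1L) * p) %% n)
}

scatter <- function(counts, p) {
  v <- expand_counts(counts)
  v[det_perm(length(v), p)]
}

#' Deterministic TGA reference fixture
#'
#' Builds a fully deterministic [report_store] reproducing, exactly, the
#' published marginal characteristics of the worldwide spontaneous-report
#' series of transient global amnesia (TGA): 852 case reports — 289 of them
#' exposed to a COVID-19 vaccine (member split 147/69/60/12/1), 620 serious,
#' sex/age/country/reporter margins per the published characteristics table,
#' and co-reported headache/confusional state/fatigue counts of 31/27/24
#' among vaccine cases — plus synthetic background filler reports so that
#' non-case cells of contingency tables are populated.
#'
#' Because the source database's full margins (total reports, per-drug
#' report totals) were never published, the filler is synthetic: ROR and IC
#' values computed on this fixture are well-defined but are not expected to
#' match any published disproportionality estimate. Only the descriptive
#' case percentages are reproduced exactly.
#'
#' Joint cells not pinned by the published margins are filled by a fixed
#' interleaving rule; the filler uses an internally fixed seed, so the
#' fixture is bit-identical across calls.
#'
#' @param n_filler number of background (non-case) filler reports; default
#'   20000.
#' @return a validated [report_store] of `852 + n_filler` reports.
#' @export
build_tga_fixture <- function(n_filler = 20000L) {
  fc <- tga_fixture_counts()
  n_grp <- fc$n_group
  n_oth <- fc$n_cases - n_grp

  col <- function(var, p_grp, p_oth)
    c(scatter(fc[[var]]$group, p_grp), scatter(fc[[var]]$other, p_oth))
  sex <- col("sex", 211L, 419L)
  age_band <- col("age_band", 83L, 241L)
  country <- col("country", 127L, 353L)
  reporter <- col("reporter", 179L, 431L)
  ser <- col("serious", 151L, 311L)

  ids <- sprintf("TGA%05d", seq_len(fc$n_cases))
  # exact ages: deterministic grid inside each band; unknown band -> NA
  band_lo <- c("2-11" = 2, "12-17" = 12, "18-44" = 18, "45-64" = 45,
               "65-74" = 65, "75+" = 75)
  band_w <- c("2-11" = 10, "12-17" = 6, "18-44" = 27, "45-64" = 20,
              "65-74" = 10, "75+" = 16)
  age_years <- ifelse(age_band == "unknown", NA_real_,
                      band_lo[age_band] + (seq_len(fc$n_cases) %% band_w[age_band]))

  # time to onset: piecewise-linear quantile profiles (days), approximating
  # the published medians (5 d for vaccine cases, 7 d overall); start dates
  # on a fixed calendar grid
  qgrid <- function(n, anchors) {
    round(stats::approx(x = c(0, 0.25, 0.5, 0.75, 1), y = anchors,
                        xout = (seq_len(n) - 0.5) / n)$y)
  }
  delay <- c(qgrid(n_grp, c(0, 1, 5, 15, 90)), qgrid(n_oth, c(0, 1, 8, 90, 400)))
  start_date <- as.Date("2021-03-01") + (seq_len(fc$n_cases) * 7L) %% 180L
  onset <- start_date + delay

  reports <- data.table(
    report_id = ids, sex = sex, age_band = age_band, country = country,
    reporter = reporter,
    serious = ser == "true",
    reaction_onset_date = onset, age_years = age_years)

  member_vec <- expand_counts(fc$members)
  other_named <- expand_counts(fc$other_drugs)
  filler_drug <- sprintf("other drug %03d", seq_len(n_oth - length(other_named)))
  ingredient <- c(member_vec, other_named, filler_drug)
  drugs <- data.table(report_id = ids, active_ingredient = ingredient,
                      role = "suspect", start_date = start_date)

  reactions <- data.table(report_id = ids, term = "transient global amnesia")
  co <- fc$co_terms
  co_ids <- ids[seq_len(sum(co))]
  reactions <- rbindlist(list(reactions,
                              data.table(report_id = co_ids,
                                         term = rep(names(co), co))))

  cases <- report_store(reports, drugs, reactions)
  if (n_filler == 0L) return(cases)
  filler <- generate_database(tga_filler_config(n_filler))
  report_store(rbindlist(list(cases$reports, filler$reports)),
               rbindlist(list(cases$drugs, filler$drugs)),
               rbindlist(list(cases$reactions, filler$reactions)))
}

# background recipe for the fixture's non-case reports: the analysed
# ingredients get realistic-looking reporting frequencies so every 2x2
# table has a populated b cell; events exclude the target PT so the case
# count stays exactly 852
tga_filler_config <- function(n_filler) {
  drug_freqs <- c(
    tozinameran = 0.060, azd1222 = 0.035, elasomeran = 0.030,
    "jnj-78436735" = 0.010, "covid-19 vaccine unspecified" = 0.001,
    atorvastatin = 0.012, simvastatin = 0.008, rosuvastatin = 0.006,
    tadalafil = 0.003, sildenafil = 0.005, zolpidem = 0.004,
    "alendronic acid" = 0.004, etoricoxib = 0.003, baclofen = 0.003,
    iodixanol = 0.002, "ibandronic acid" = 0.002, heparin = 0.006,
    enzalutamide = 0.002, "influenza vaccine" = 0.008)
  bg <- setNames((seq_len(40L))^-1, sprintf("background drug %02d", seq_len(40L)))
  bg <- bg / sum(bg) * (1 - sum(drug_freqs))
  drug_freqs <- c(drug_freqs, bg)
  event_names <- c(
    "nausea", "headache", "dizziness", "fatigue", "pyrexia", "rash",
    "vomiting", "diarrhoea", "pruritus", "dyspnoea", "myalgia", "arthralgia",
    "chills", "asthenia", "injection site pain", "insomnia", "anxiety",
    "confusional state", "syncope", "tremor", "paraesthesia", "hypertension",
    "chest pain", "cough", "abdominal pain", "pain", "oedema peripheral",
    "palpitations", "tinnitus", "vertigo")
  sim_config(n_reports = n_filler,
             drug_names = names(drug_freqs), drug_freqs = drug_freqs,
             event_names = event_names, event_zipf = 1,
             mean_drugs = 2, mean_events = 1.5,
             id_prefix = "F", seed = 777001L)
}
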