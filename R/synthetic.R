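#' Synthetic spontaneous-reporting database recipe
#'
#' Describes the data-generating process the case/non-case design assumes:
#' many drugs and events with skewed (Zipf-like) background reporting
#' frequencies, multi-drug multi-event reports, demographic and reporter
#' strata, and optional injected drug–event associations with a known
#' reporting-rate multiplier theta. All randomness is behind one seed.
#'
#' Counts of drugs and events per report are truncated-Poisson (minimum 1).
#' For an injected signal, presence of the signal drug and signal event is
#' drawn from the tilted joint distribution obtained by multiplying the
#' independence cell `P(drug & event)` by `theta` and renormalizing, so the
#' presence odds ratio of the pair is exactly `theta`; the two entities are
#' removed from background sampling so the tilt is not diluted.
#'
#' @param n_reports number of reports (>= 1).
#' @param n_drugs,n_events catalogue sizes (ignored when explicit names are
#'   given).
#' @param drug_zipf,event_zipf Zipf exponents for the background frequency
#'   laws (frequency of rank r proportional to `r^-s`).
#' @param drug_names,event_names optional explicit catalogues.
#' @param drug_freqs,event_freqs optional explicit frequency vectors
#'   (normalized internally; recycled against the catalogue).
#' @param mean_drugs,mean_events Poisson means for entries per report
#'   (truncated at 1).
#' @param role_probs probabilities of the three drug roles for background
#'   entries; injected signal drugs are always `suspect`.
#' @param strata_probs named list of probability vectors for `sex`,
#'   `age_band`, `reporter`, `serious` (levels as names; `serious` uses
#'   `"true"`, `"false"`, `"unknown"`), and `country`.
#' @param signals list of `list(drug=, event=, theta=)` entries; drugs and
#'   events must be distinct across signals.
#' @param id_prefix prefix for generated report ids.
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_reports,
                       n_drugs = 200L, n_events = 100L,
                       drug_zipf = 1, event_zipf = 1,
                       drug_names = NULL, event_names = NULL,
                       drug_freqs = NULL, event_freqs = NULL,
                       mean_drugs = 2, mean_events = 1.5,
                       role_probs = c(suspect = 0.7, interacting = 0.05,
                                      concomitant = 0.25),
                       strata_probs = default_strata_probs(),
                       signals = list(), id_prefix = "S",
                       seed = 1L) {
  stopifnot(n_reports >= 1, mean_drugs > 0, mean_events > 0)
  if (is.null(drug_names)) drug_names <- sprintf("drug_%03d", seq_len(n_drugs))
  if (is.null(event_names)) event_names <- sprintf("event_%03d", seq_len(n_events))
  drug_names <- normalize_name(drug_names)
  event_names <- normalize_name(event_names)
  if (is.null(drug_freqs)) drug_freqs <- seq_along(drug_names)^(-drug_zipf)
  if (is.null(event_freqs)) event_freqs <- seq_along(event_names)^(-event_zipf)
  stopifnot(length(drug_freqs) == length(drug_names),
            length(event_freqs) == length(event_names),
            all(drug_freqs > 0), all(event_freqs > 0))
  drug_freqs <- drug_freqs / sum(drug_freqs)
  event_freqs <- event_freqs / sum(event_freqs)
  role_probs <- role_probs / sum(role_probs)
  stopifnot(identical(sort(names(role_probs)), sort(pv_roles)))
  for (s in signals) {
    stopifnot(!is.null(s$drug), !is.null(s$event), !is.null(s$theta), s$theta > 0)
    if (!normalize_name(s$drug) %in% drug_names) stop("signal drug not in catalogue: ", s$drug)
    if (!normalize_name(s$event) %in% event_names) stop("signal event not in catalogue: ", s$event)
  }
  sd <- vapply(signals, function(s) normalize_name(s$drug), "")
  se <- vapply(signals, function(s) normalize_name(s$event), "")
  if (anyDuplicated(sd) || anyDuplicated(se))
    stop("signals must use distinct drugs and distinct events")
  structure(list(n_reports = as.integer(n_reports),
                 drug_names = drug_names, event_names = event_names,
                 drug_freqs = drug_freqs, event_freqs = event_freqs,
                 mean_drugs = mean_drugs, mean_events = mean_events,
                 role_probs = role_probs, strata_probs = strata_probs,
                 signals = signals, id_prefix = id_prefix,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default demographic/reporter strata probabilities
#'
#' Loosely modelled on the marginal composition of a large international
#' safety database: adult-skewed ages, a female majority, a mix of
#' health-professional and consumer reporters, and roughly half of reports
#' serious. These are background defaults for the generator, not estimates
#' of any particular database.
#'
#' @return named list of probability vectors.
#' @export
default_strata_probs <- function() {
  list(
    sex = c(female = 0.55, male = 0.40, unknown = 0.05),
    age_band = c("2-11" = 0.02, "12-17" = 0.03, "18-44" = 0.25, "45-64" = 0.30,
                 "65-74" = 0.18, "75+" = 0.10, unknown = 0.12),
    reporter = c(physician = 0.30, pharmacist = 0.05,
                 other_health_professional = 0.10, consumer = 0.30,
                 lawyer = 0.005, unknown = 0.245),
    serious = c("true" = 0.45, "false" = 0.40, unknown = 0.15),
    country = c("united states of america" = 0.45, germany = 0.09,
                "united kingdom" = 0.08, france = 0.06, netherlands = 0.05,
                japan = 0.05, australia = 0.04, other = 0.18))
}

# truncated Poisson, minimum 1, by inverse-cdf conditioning
rtpois <- function(n, lambda) {
  p0 <- stats::ppois(0, lambda)
  qpois(p0 + runif(n) * (1 - p0), lambda)
}

#' Generate a synthetic report database
#'
#' Draws `n_reports` independent reports under the recipe in a
#' [sim_config]: background drug/event sets from the configured frequency
#' laws, demographics from the strata probabilities, and for every
#' configured signal a joint-probability tilt that makes the presence odds
#' ratio of the (drug, event) pair exactly `theta`. Deterministic given the
#' config seed; the caller's RNG state is untouched.
#'
#' Marginal presence of a signal entity keeps its background level: the
#' per-report presence probability used in the tilt is
#' `1 - (1 - f)^mu`, the probability a catalogue item of frequency `f`
#' appears at least once among a truncated-Poisson(mu) number of draws.
#' A configured tilt with `theta * p_drug * p_event > 1` is infeasible and
#' raises a config error.
#'
#' @param config a [sim_config].
#' @return a [report_store].
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_database_impl(config))
}

generate_database_impl <- function(config) {
  n <- config$n_reports
  sp <- config$strata_probs
  draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  ser <- draw(sp$serious)
  reports <- data.table(
    report_id = sprintf("%s%07d", config$id_prefix, seq_len(n)),
    sex = draw(sp$sex), age_band = draw(sp$age_band),
    country = draw(sp$country), reporter = draw(sp$reporter),
    serious = ifelse(ser == "true", TRUE, ifelse(ser == "false", FALSE, NA)),
    reaction_onset_date = as.Date(NA), age_years = NA_real_)

  sig_drugs <- vapply(config$signals, function(s) normalize_name(s$drug), "")
  sig_events <- vapply(config$signals, function(s) normalize_name(s$event), "")
  p_present <- function(f, mu) 1 - (1 - f)^mu
  drug_present <- matrix(FALSE, n, length(config$signals))
  event_present <- matrix(FALSE, n, length(config$signals))
  for (i in seq_along(config$signals)) {
    s <- config$signals[[i]]
    pD <- p_present(config$drug_freqs[match(sig_drugs[i], config$drug_names)],
                    config$mean_drugs)
    pE <- p_present(config$event_freqs[match(sig_events[i], config$event_names)],
                    config$mean_events)
    if (s$theta * pD * pE > 1)
      stop(sprintf("infeasible signal tilt: theta * p_drug * p_event = %.3f > 1",
                   s$theta * pD * pE))
    q <- c(s$theta * pD * pE, pD * (1 - pE), (1 - pD) * pE, (1 - pD) * (1 - pE))
    cell <- sample.int(4L, n, replace = TRUE, prob = q / sum(q))
    drug_present[, i] <- cell <= 2L
    event_present[, i] <- cell == 1L | cell == 3L
  }

  bg <- function(names, freqs, exclude) {
    keep <- !(names %in% exclude)
    list(names = names[keep], freqs = freqs[keep] / sum(freqs[keep]))
  }
  dbg <- bg(config$drug_names, config$drug_freqs, sig_drugs)
  ebg <- bg(config$event_names, config$event_freqs, sig_events)

  n_sig_d <- if (length(config$signals)) rowSums(drug_present) else rep(0L, n)
  n_sig_e <- if (length(config$signals)) rowSums(event_present) else rep(0L, n)
  kd <- pmax(rtpois(n, config$mean_drugs) - n_sig_d, 0L)
  kd[kd + n_sig_d == 0L] <- 1L
  ke <- pmax(rtpois(n, config$mean_events) - n_sig_e, 0L)
  ke[ke + n_sig_e == 0L] <- 1L

  drugs <- unique(data.table(
    row = rep(seq_len(n), kd),
    active_ingredient = sample(dbg$names, sum(kd), replace = TRUE, prob = dbg$freqs)))
  drugs[, role := sample(names(config$role_probs), .N, replace = TRUE,
                         prob = config$role_probs)]
  if (length(config$signals)) {
    sig_rows <- rbindlist(lapply(seq_along(config$signals), function(i) {
      w <- which(drug_present[, i])
      if (!length(w)) return(NULL)
      data.table(row = w, active_ingredient = sig_drugs[i], role = "suspect")
    }))
    drugs <- rbindlist(list(drugs, sig_rows))
  }
  drugs[, `:=`(report_id = reports$report_id[row], row = NULL)]
  drugs[, start_date := as.Date(NA)]

  reactions <- unique(data.table(
    row = rep(seq_len(n), ke),
    term = sample(ebg$names, sum(ke), replace = TRUE, prob = ebg$freqs)))
  if (length(config$signals)) {
    sig_rx <- rbindlist(lapply(seq_along(config$signals), function(i) {
      w <- which(event_present[, i])
      if (!length(w)) return(NULL)
      data.table(row = w, term = sig_events[i])
    }))
    reactions <- rbindlist(list(reactions, sig_rx))
  }
  reactions[, `:=`(report_id = reports$report_id[row], row = NULL)]
  data.table::setcolorder(drugs, c("report_id", "active_ingredient", "role", "start_date"))
  data.table::setcolorder(reactions, c("report_id", "term"))
  new_report_store(reports, drugs, reactions)
}

#' Parameter-recovery and null-calibration experiment
#'
#' Repeatedly generates databases under a [sim_config] (replicate `r` uses
#' `seed + r`), estimates the disproportionality of every injected pair and
#' of the eligible null pairs sharing the signal events, and summarises
#' estimator quality: relative bias of the log reporting odds ratio,
#' empirical CI coverage of the true `theta`, the fraction of replicates in
#' which the injected pair is flagged (IC025 > 0), and the fraction of null
#' pairs flagged.
#'
#' With no configured signals the experiment is a pure null calibration:
#' supply `null_events` to choose which event margins are screened.
#'
#' @param config a [sim_config].
#' @param n_replicates number of replicates (>= 2).
#' @param min_cases eligibility threshold for null-pair screening.
#' @param null_events events to screen for null pairs; defaults to the
#'   signal events (or the 20 most frequent events when no signals).
#' @return an object of class `recovery_summary`: list with `injected`
#'   (per replicate x signal data.table), `null_pairs` (pooled eligible
#'   null-pair rows), and `summary` (list of scalars).
#' @export
recovery_experiment <- function(config, n_replicates, min_cases = 4L,
                                null_events = NULL) {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 2)
  sig_drugs <- vapply(config$signals, function(s) normalize_name(s$drug), "")
  sig_events <- vapply(config$signals, function(s) normalize_name(s$event), "")
  if (is.null(null_events)) {
    null_events <- if (length(sig_events)) sig_events
    else head(config$event_names[order(-config$event_freqs)], 20L)
  }
  inj <- vector("list", n_replicates)
  nul <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    store <- generate_database(cfg)
    if (length(config$signals)) {
      rows <- rbindlist(lapply(seq_along(config$signals), function(i) {
        res <- disproportionality(store, sig_events[i], sig_drugs[i])
        res[, `:=`(event = sig_events[i], theta = config$signals[[i]]$theta,
                   replicate = r)]
        res
      }))
      inj[[r]] <- rows
    }
    sc <- scan_pairs(store, null_events, min_cases = min_cases)
    if (nrow(sc)) {
      sc <- sc[!(ingredient %in% sig_drugs)]
      sc[, replicate := r]
      nul[[r]] <- sc
    }
  }
  injected <- rbindlist(inj)
  null_pairs <- rbindlist(nul)
  summary <- list(n_replicates = n_replicates)
  if (nrow(injected)) {
    summary$median_ror <- stats::median(injected$ror)
    summary$rel_bias_log_ror <-
      (mean(log(injected$ror)) - mean(log(injected$theta))) / mean(log(injected$theta))
    summary$coverage_theta <-
      mean(injected$ci_low <= injected$theta & injected$theta <= injected$ci_high)
    summary$flag_rate <- mean(injected$signal)
  }
  if (nrow(null_pairs)) {
    summary$null_flag_rate <- mean(null_pairs$signal)
    summary$null_ci_covers_1 <- mean(null_pairs$covers_1)
    summary$n_null_pairs <- nrow(null_pairs)
  }
  structure(list(injected = injected, null_pairs = null_pairs, summary = summary),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat("<recovery_summary>\n")
  for (k in names(x$summary))
    cat(sprintf("  %-20s %s\n", k, format(x$summary[[k]], digits = 4)))
  invisible(x)
}
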