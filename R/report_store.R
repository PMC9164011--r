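#' Build a report store from its component tables
#'
#' A `report_store` is the in-memory model of a spontaneous-reporting
#' database: one row per individual case safety report plus two long-format
#' tables holding the report's drugs (with their reporter-assigned role) and
#' its reaction preferred terms (PTs). It is the unit every analysis in this
#' package operates on; `n_total(store)` is the N of every 2x2 table.
#'
#' @param reports data.frame with columns `report_id`, `sex`, `age_band`,
#'   `country`, `reporter`, `serious` (logical, `NA` = unknown). Optional:
#'   `reaction_onset_date` (Date or "YYYY-MM-DD"), `age_years` (numeric exact
#'   age, used only by descriptive summaries).
#' @param drugs data.frame with columns `report_id`, `active_ingredient`,
#'   `role` (one of `r paste(pv_roles, collapse = ", ")`); optional
#'   `start_date`.
#' @param reactions data.frame with columns `report_id`, `term`.
#' @param validate run full integrity checks (default `TRUE`).
#' @return an object of class `report_store`.
#' @details Invariants enforced: report ids unique; every report has at
#'   least one drug and one reaction (a case/non-case design is undefined
#'   otherwise); demographic fields drawn from the closed vocabularies, with
#'   off-vocabulary values mapped to `"unknown"` under a warning; drug roles
#'   are strict. Ingredient and term strings are normalized (trim,
#'   lowercase, collapse whitespace).
#' @export
report_store <- function(reports, drugs, reactions, validate = TRUE) {
  reports <- as.data.table(reports)
  drugs <- as.data.table(drugs)
  reactions <- as.data.table(reactions)

  need <- c("report_id", "sex", "age_band", "country", "reporter", "serious")
  miss <- setdiff(need, names(reports))
  if (length(miss)) stop("reports is missing column(s): ", paste(miss, collapse = ", "))
  if (!"reaction_onset_date" %in% names(reports))
    reports[, reaction_onset_date := as.Date(NA)]
  if (!"age_years" %in% names(reports)) reports[, age_years := NA_real_]

  reports[, report_id := as.character(report_id)]
  dup <- unique(reports$report_id[duplicated(reports$report_id)])
  if (length(dup))
    stop("duplicate report_id(s): ", paste(head(dup, 5), collapse = ", "))

  reports[, sex := coerce_level(sex, pv_sex_levels, "sex")]
  reports[, age_band := coerce_level(normalize_age_band(age_band), pv_age_bands, "age_band")]
  reports[, reporter := coerce_level(reporter, pv_reporter_levels, "reporter")]
  cn <- normalize_name(reports$country)
  cn[is.na(cn) | cn == ""] <- "unknown"
  reports[, country := cn]
  reports[, serious := as.logical(serious)]
  reports[, reaction_onset_date := as_iso_date(reaction_onset_date)]
  reports[, age_years := as.numeric(age_years)]
  # age is stored banded; an exact age fills in a missing band (band edges
  # inclusive of their lower bound)
  fixable <- reports$age_band == "unknown" & !is.na(reports$age_years)
  if (any(fixable)) reports[fixable, age_band := age_to_band(age_years)]

  drugs[, report_id := as.character(report_id)]
  drugs[, active_ingredient := normalize_name(active_ingredient)]
  drugs[, role := normalize_name(role)]
  if (!"start_date" %in% names(drugs)) drugs[, start_date := as.Date(NA)]
  drugs[, start_date := as_iso_date(start_date)]
  reactions[, report_id := as.character(report_id)]
  reactions[, term := normalize_name(term)]

  if (validate) {
    if (any(is.na(drugs$active_ingredient) | drugs$active_ingredient == ""))
      stop("empty active_ingredient")
    badrole <- setdiff(unique(drugs$role), pv_roles)
    if (length(badrole))
      stop("invalid drug role(s): ", paste(badrole, collapse = ", "),
           " (must be one of ", paste(pv_roles, collapse = ", "), ")")
    orphan <- setdiff(c(drugs$report_id, reactions$report_id), reports$report_id)
    if (length(orphan))
      stop("drug/reaction rows reference unknown report_id(s): ",
           paste(head(orphan, 5), collapse = ", "))
    nodrug <- setdiff(reports$report_id, drugs$report_id)
    if (length(nodrug))
      stop(length(nodrug), " report(s) without any drug entry (rejected; e.g. ",
           paste(head(nodrug, 3), collapse = ", "), ")")
    norx <- setdiff(reports$report_id, reactions$report_id)
    if (length(norx))
      stop(length(norx), " report(s) without any reaction term (e.g. ",
           paste(head(norx, 3), collapse = ", "), ")")
  }

  structure(list(reports = reports, drugs = drugs, reactions = reactions),
            class = "report_store")
}

# fast internal constructor: inputs already canonical data.tables
new_report_store <- function(reports, drugs, reactions) {
  structure(list(reports = reports, drugs = drugs, reactions = reactions),
            class = "report_store")
}

#' Number of reports in a store
#'
#' @param store a `report_store`.
#' @return integer count; the N (denominator) of every contingency table
#'   built from this store.
#' @export
n_total <- function(store) {
  stopifnot(inherits(store, "report_store"))
  nrow(store$reports)
}

#' @export
print.report_store <- function(x, ...) {
  cat(sprintf("<report_store> %d reports, %d drug entries (%d ingredients), %d reaction entries (%d PTs)\n",
              nrow(x$reports), nrow(x$drugs), data.table::uniqueN(x$drugs$active_ingredient),
              nrow(x$reactions), data.table::uniqueN(x$reactions$term)))
  invisible(x)
}

empty_store <- function() {
  new_report_store(
    reports = data.table(report_id = character(), sex = character(),
                         age_band = character(), country = character(),
                         reporter = character(), serious = logical(),
                         reaction_onset_date = as.Date(character()),
                         age_years = numeric()),
    drugs = data.table(report_id = character(), active_ingredient = character(),
                       role = character(), start_date = as.Date(character())),
    reactions = data.table(report_id = character(), term = character()))
}

#' Read individual case safety reports
#'
#' Ingest a line-oriented report file into a validated [report_store]. Two
#' plain-text serializations are supported:
#' \describe{
#'   \item{jsonl}{one JSON object per line with keys `report_id`, `drugs`
#'     (array of `{active_ingredient, role, start_date}`), `reactions`
#'     (array of strings), `sex`, `age_band`, `country`, `reporter`,
#'     `serious`, `reaction_onset_date`, optional `age_years`.}
#'   \item{csv}{one row per report; `drugs` is pipe-delimited
#'     `"name:role"` subfields (a third `:YYYY-MM-DD` subfield carries the
#'     start date when present), `reactions` is pipe-delimited terms.}
#' }
#' Off-vocabulary demographic levels are mapped to `"unknown"` with a
#' warning; duplicated `report_id`s and reports with no drugs or no
#' reactions are integrity errors; a malformed line is reported with its
#' line number.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension.
#' @return a [report_store].
#' @seealso [write_reports()] for the inverse; the pair is a field-for-field
#'   round trip.
#' @export
read_reports <- function(path, format = c("jsonl", "csv")) {
  if (missing(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "jsonl") read_reports_jsonl(path) else read_reports_csv(path)
}

read_reports_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_store())
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    recs[[i]] <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) stop(sprintf("parse error at line %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
  }
  pick <- function(r, k, default = NA) if (!is.null(r[[k]])) r[[k]] else default
  reports <- rbindlist(lapply(recs, function(r) data.table(
    report_id = as.character(pick(r, "report_id")),
    sex = as.character(pick(r, "sex", "unknown")),
    age_band = as.character(pick(r, "age_band", "unknown")),
    country = as.character(pick(r, "country", "unknown")),
    reporter = as.character(pick(r, "reporter", "unknown")),
    serious = if (is.null(r$serious) || identical(r$serious, "unknown")) NA else as.logical(r$serious),
    reaction_onset_date = as.character(pick(r, "reaction_onset_date", NA_character_)),
    age_years = as.numeric(pick(r, "age_years", NA_real_)))))
  drugs <- rbindlist(lapply(seq_along(recs), function(i) {
    dl <- recs[[i]]$drugs
    if (is.null(dl) || !length(dl)) return(NULL)
    data.table(
      report_id = as.character(recs[[i]]$report_id),
      active_ingredient = vapply(dl, function(d) as.character(d$active_ingredient %||% ""), ""),
      role = vapply(dl, function(d) as.character(d$role %||% ""), ""),
      start_date = vapply(dl, function(d) as.character(d$start_date %||% NA_character_), ""))
  }))
  reactions <- rbindlist(lapply(seq_along(recs), function(i) {
    rx <- recs[[i]]$reactions
    if (is.null(rx) || !length(rx)) return(NULL)
    data.table(report_id = as.character(recs[[i]]$report_id),
               term = vapply(rx, as.character, ""))
  }))
  report_store(reports, drugs, reactions)
}

read_reports_csv <- function(path) {
  dt <- fread(path, colClasses = "character", na.strings = c("", "NA"))
  if (!nrow(dt)) return(empty_store())
  split_drugs <- function(id, s) {
    if (is.na(s) || s == "") return(NULL)
    parts <- strsplit(strsplit(s, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.table(report_id = id,
               active_ingredient = vapply(parts, `[`, "", 1L),
               role = vapply(parts, function(p) if (length(p) >= 2) p[2] else "", ""),
               start_date = vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_, ""))
  }
  drugs <- rbindlist(Map(split_drugs, dt$report_id, dt$drugs))
  reactions <- rbindlist(Map(function(id, s) {
    if (is.na(s) || s == "") return(NULL)
    data.table(report_id = id, term = strsplit(s, "|", fixed = TRUE)[[1]])
  }, dt$report_id, dt$reactions))
  reports <- dt[, .(report_id, sex, age_band, country, reporter,
                    serious = ifelse(serious %in% c("true", "TRUE", "True"), TRUE,
                                     ifelse(serious %in% c("false", "FALSE", "False"), FALSE, NA)),
                    reaction_onset_date = if ("reaction_onset_date" %in% names(dt)) reaction_onset_date else NA_character_,
                    age_years = if ("age_years" %in% names(dt)) as.numeric(age_years) else NA_real_)]
  report_store(reports, drugs, reactions)
}

#' Write a report store to disk
#'
#' Serializes a store in either of the formats accepted by
#' [read_reports()]; reading the file back reproduces the store
#' field-for-field.
#'
#' @param store a [report_store].
#' @param path output file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_reports <- function(store, path, format = c("jsonl", "csv")) {
  stopifnot(inherits(store, "report_store"))
  if (missing(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  format <- match.arg(format)
  if (format == "jsonl") write_reports_jsonl(store, path) else write_reports_csv(store, path)
  invisible(path)
}

write_reports_jsonl <- function(store, path) {
  rp <- store$reports
  dr <- split(store$drugs, by = "report_id", keep.by = FALSE)
  rx <- split(store$reactions, by = "report_id", keep.by = FALSE)
  lines <- vapply(seq_len(nrow(rp)), function(i) {
    id <- rp$report_id[i]
    di <- dr[[id]]
    obj <- list(
      report_id = id,
      drugs = lapply(seq_len(nrow(di)), function(j) {
        d <- list(active_ingredient = di$active_ingredient[j], role = di$role[j])
        if (!is.na(di$start_date[j])) d$start_date <- format(di$start_date[j])
        d
      }),
      reactions = as.list(rx[[id]]$term),
      sex = rp$sex[i], age_band = rp$age_band[i], country = rp$country[i],
      reporter = rp$reporter[i],
      serious = if (is.na(rp$serious[i])) "unknown" else rp$serious[i])
    if (!is.na(rp$reaction_onset_date[i]))
      obj$reaction_onset_date <- format(rp$reaction_onset_date[i])
    if (!is.na(rp$age_years[i])) obj$age_years <- rp$age_years[i]
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
}

write_reports_csv <- function(store, path) {
  rp <- copy(store$reports)
  enc_drug <- store$drugs[, .(drugs = paste(ifelse(
    is.na(start_date),
    paste(active_ingredient, role, sep = ":"),
    paste(active_ingredient, role, format(start_date), sep = ":")),
    collapse = "|")), by = report_id]
  enc_rx <- store$reactions[, .(reactions = paste(term, collapse = "|")), by = report_id]
  out <- merge(merge(rp, enc_drug, by = "report_id", all.x = TRUE, sort = FALSE),
               enc_rx, by = "report_id", all.x = TRUE, sort = FALSE)
  out[, serious := ifelse(is.na(serious), "unknown", ifelse(serious, "true", "false"))]
  out[, reaction_onset_date := ifelse(is.na(reaction_onset_date), "",
                                      format(reaction_onset_date))]
  setorderv(out, "report_id")
  ord <- c("report_id", "sex", "age_band", "country", "reporter", "serious",
           "reaction_onset_date", "age_years", "drugs", "reactions")
  fwrite(out[, ord, with = FALSE], path)
}

#' Restrict a store to one or more strata
#'
#' Returns a new store containing exactly the reports matching every named
#' level; used for subgroup (age- and sex-specific) and sensitivity
#' (physician-reported-only) analyses, which recompute all margins within
#' the stratum. Filtering on `"unknown"` levels is supported, so the levels
#' of a field partition the store.
#'
#' @param store a [report_store].
#' @param ... named levels, e.g. `sex = "female"`, `age_band = "45-64"`,
#'   `reporter = "physician"`, `country = ...`, `serious = TRUE` (or
#'   `"unknown"`). Multiple names are conjoined.
#' @return a new [report_store]; the input is untouched.
#' @export
filter_reports <- function(store, ...) {
  stopifnot(inherits(store, "report_store"))
  crit <- list(...)
  if (!length(crit)) return(store)
  allowed <- c("sex", "age_band", "country", "reporter", "serious")
  bad <- setdiff(names(crit), allowed)
  if (length(bad) || is.null(names(crit)) || any(names(crit) == ""))
    stop("unknown stratum name(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  keep <- rep(TRUE, nrow(store$reports))
  for (f in names(crit)) {
    v <- crit[[f]]
    col <- store$reports[[f]]
    if (f == "serious") {
      if (identical(v, "unknown")) keep <- keep & is.na(col)
      else keep <- keep & !is.na(col) & col == as.logical(v)
    } else {
      v <- if (f == "age_band") normalize_age_band(v) else normalize_name(v)
      lv <- switch(f, sex = pv_sex_levels, age_band = pv_age_bands,
                   reporter = pv_reporter_levels, NULL)
      if (!is.null(lv) && !v %in% lv)
        stop(sprintf("'%s' is not a level of stratum '%s'", v, f))
      keep <- keep & col == v
    }
  }
  ids <- store$reports$report_id[keep]
  new_report_store(store$reports[keep],
                   store$drugs[report_id %in% ids],
                   store$reactions[report_id %in% ids])
}

#' Time to onset per report
#'
#' Days from the earliest start date of a suspect or interacting drug to the
#' reaction onset date (floor of the calendar-day difference). Absent when
#' either date is missing. Negative differences are data errors: they are
#' flagged (`flagged = TRUE`, `days = NA`) rather than silently dropped.
#'
#' @param store a [report_store].
#' @return data.table with columns `report_id`, `days`, `flagged`.
#' @export
time_to_onset <- function(store) {
  stopifnot(inherits(store, "report_store"))
  st <- store$drugs[role %in% c("suspect", "interacting") & !is.na(start_date),
                    .(start = min(start_date)), by = report_id]
  out <- merge(store$reports[, .(report_id, onset = reaction_onset_date)],
               st, by = "report_id", all.x = TRUE, sort = FALSE)
  out[, days := as.numeric(floor(as.numeric(onset - start)))]
  out[, flagged := !is.na(days) & days < 0]
  out[flagged == TRUE, days := NA_real_]
  out[, .(report_id, days, flagged)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# bin an exact age onto the canonical bands; ages below 2 (or missing) are
# "unknown" since the youngest band starts at 2
age_to_band <- function(age) {
  out <- rep("unknown", length(age))
  lo <- c(2, 12, 18, 45, 65, 75)
  bands <- c("2-11", "12-17", "18-44", "45-64", "65-74", "75+")
  idx <- findInterval(age, lo)
  ok <- !is.na(age) & idx >= 1L
  out[ok] <- bands[idx[ok]]
  out
}
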