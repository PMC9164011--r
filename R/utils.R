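#' @importFrom data.table data.table as.data.table rbindlist setorder setorderv
#'   copy fread fwrite setnames setcolorder setattr uniqueN := .N .SD
#' @importFrom stats quantile rpois qpois runif rgamma qnorm setNames
#' @importFrom utils head
NULL

# data.table NSE variable bindings (R CMD check)
utils::globalVariables(c(
  ".", "report_id", "active_ingredient", "role", "term", "n_cases",
  "ingredient", "a", "b", "d", "ror", "ci_low", "ci_high", "ic", "ic025",
  "signal", "covers_1", "label", "pct_cases", "pct_group", "parent_group",
  "level", "variable", "is_member", "start_date", "days", "flagged", "n",
  "pct", "event", "sex", "age_band", "reporter", "country", "serious",
  "reaction_onset_date", "age_years", "onset", "stratum", "replicate",
  "theta", "n_exposed", "se", "aa", "bb", "cc", "dd", "corrected",
  "estimable", "drugs", "reactions"
))

#' Closed vocabularies for report fields
#'
#' Canonical factor levels used throughout the package: patient sex, age
#' band (the granularity at which age is stored), reporter qualification
#' and drug roles. Values outside these vocabularies are mapped to
#' `"unknown"` on ingestion (with a warning), except drug roles, which are
#' mandatory and strict.
#'
#' @name vocabularies
#' @keywords internal
NULL

pv_sex_levels <- c("female", "male", "unknown")
pv_age_bands <- c("2-11", "12-17", "18-44", "45-64", "65-74", "75+", "unknown")
pv_reporter_levels <- c("physician", "pharmacist", "other_health_professional",
                        "consumer", "lawyer", "unknown")
pv_roles <- c("suspect", "interacting", "concomitant")

#' Normalize a free-text name
#'
#' Trim, lowercase and collapse internal whitespace. No spelling
#' reconciliation is attempted: `"Tozinameran "` and `"tozinameran"` are the
#' same ingredient, `"tozinameranum"` is not.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Map assorted age-band spellings (unicode dashes, ">=75", "≥75 years")
# onto the canonical bands.
normalize_age_band <- function(x) {
  x <- normalize_name(x)
  x <- gsub("–|—|−", "-", x)
  x <- gsub("[[:space:]]*years?$", "", x)
  x <- sub("^(>=|≥)[[:space:]]*75.*$", "75+", x)
  x[x %in% c("75", "75 and over")] <- "75+"
  x
}

# Coerce a character vector onto a closed vocabulary; off-vocabulary or
# missing values become "unknown" with a single consolidated warning.
coerce_level <- function(x, levels, field) {
  x <- normalize_name(x)
  x[is.na(x) | x == ""] <- "unknown"
  bad <- !(x %in% levels)
  if (any(bad)) {
    warning(sprintf("%d value(s) of '%s' outside vocabulary mapped to 'unknown' (e.g. %s)",
                    sum(bad), field, paste(head(unique(x[bad]), 3), collapse = ", ")),
            call. = FALSE)
    x[bad] <- "unknown"
  }
  x
}

# Round half away from zero to one decimal; the fixed rule used for every
# percentage this package prints.
round_half_up1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

pct1 <- function(count, total) {
  if (length(total) == 1L) {
    if (is.na(total) || total <= 0) return(rep(NA_real_, length(count)))
    return(round_half_up1(100 * count / total))
  }
  ifelse(!is.na(total) & total > 0, round_half_up1(100 * count / total), NA_real_)
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

as_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  as.Date(x, format = "%Y-%m-%d")
}
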