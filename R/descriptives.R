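#' Median and interquartile range
#'
#' Quartiles by linear interpolation between order statistics (the
#' convention under which a fractional bound such as 63.75 arises from
#' integer day counts): with sorted values `x[1..n]`, the p-quantile is
#' `x[h] + (h - floor(h)) * (x[h+1] - x[h])` at `h = (n-1)p + 1`. Missing
#' values are excluded and their count reported.
#'
#' @param values numeric vector.
#' @return list with `median`, `q1`, `q3`, `n` (values used), `n_missing`,
#'   `estimable` (`FALSE` when nothing remains after exclusion, in which
#'   case the quantile fields are `NA`).
#' @export
median_iqr <- function(values) {
  n_missing <- sum(is.na(values))
  x <- values[!is.na(values)]
  if (!length(x))
    return(list(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                n = 0L, n_missing = n_missing, estimable = FALSE))
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2], q1 = q[1], q3 = q[3],
       n = length(x), n_missing = n_missing, estimable = TRUE)
}

#' Characteristics table for the cases of a target event
#'
#' Two-column descriptive summary of the case reports (reports listing the
#' target PT): counts and percentages by sex, age band, country, reporter
#' qualification and seriousness, for all cases and for the cases exposed
#' to a chosen drug group. Percentages use the package-wide rounding rule
#' (half away from zero, one decimal) and are computed from the integer
#' counts, so each variable's level counts — unknown levels included — sum
#' exactly to the column total.
#'
#' @param store a [report_store].
#' @param target_pt the case-defining PT.
#' @param group a [drug_group] (or ingredient name) for the second column.
#' @param roles exposure roles for the group column.
#' @return a `characteristics_table`: data.table with columns `variable`,
#'   `level`, `n_cases`, `pct_cases`, `n_group`, `pct_group`; attributes
#'   `total_cases`, `total_group`.
#' @export
characteristics <- function(store, target_pt, group,
                            roles = c("suspect", "interacting")) {
  stopifnot(inherits(store, "report_store"))
  if (n_total(store) == 0L) stop("store is empty")
  group <- as_drug_group(group)
  cs <- is_case(store, target_pt)
  ex <- is_exposed(store, group, roles)
  all_cases <- store$reports[cs]
  grp_cases <- store$reports[cs & ex]
  n_all <- nrow(all_cases); n_grp <- nrow(grp_cases)

  count_var <- function(values, levels) {
    values <- as.character(values)
    tab <- table(factor(values, levels = levels))
    data.table(level = names(tab), n = as.integer(tab))
  }
  ser_level <- function(x) ifelse(is.na(x), "unknown", ifelse(x, "serious", "non-serious"))
  country_levels <- unique(c(
    names(sort(table(all_cases$country), decreasing = TRUE)), "unknown"))
  specs <- list(
    sex = list(all = all_cases$sex, grp = grp_cases$sex, lev = pv_sex_levels),
    age_band = list(all = all_cases$age_band, grp = grp_cases$age_band, lev = pv_age_bands),
    country = list(all = all_cases$country, grp = grp_cases$country, lev = country_levels),
    reporter = list(all = all_cases$reporter, grp = grp_cases$reporter, lev = pv_reporter_levels),
    seriousness = list(all = ser_level(all_cases$serious), grp = ser_level(grp_cases$serious),
                       lev = c("serious", "non-serious", "unknown")))
  out <- rbindlist(lapply(names(specs), function(v) {
    s <- specs[[v]]
    ca <- count_var(s$all, s$lev)
    cg <- count_var(s$grp, s$lev)
    data.table(variable = v, level = ca$level,
               n_cases = ca$n, pct_cases = pct1(ca$n, n_all),
               n_group = cg$n, pct_group = pct1(cg$n, n_grp))
  }))
  setattr(out, "total_cases", n_all)
  setattr(out, "total_group", n_grp)
  setattr(out, "class", c("characteristics_table", class(out)))
  out
}

#' @export
print.characteristics_table <- function(x, ...) {
  cat(sprintf("<characteristics_table> %d cases, %d exposed to group\n",
              attr(x, "total_cases"), attr(x, "total_group")))
  print(as.data.table(x))
  invisible(x)
}

#' Terms co-reported with the target event
#'
#' For the cases exposed to a drug group, the frequency of every other
#' preferred term listed alongside the target PT, as a count and a percent
#' of the group-exposed cases. Sorted by count descending (ties:
#' alphabetical).
#'
#' @inheritParams characteristics
#' @return data.table with columns `term`, `n`, `pct`.
#' @export
co_reported_terms <- function(store, target_pt, group,
                              roles = c("suspect", "interacting")) {
  stopifnot(inherits(store, "report_store"))
  if (n_total(store) == 0L) stop("store is empty")
  group <- as_drug_group(group)
  target_pt <- normalize_name(target_pt)
  cs <- is_case(store, target_pt)
  ex <- is_exposed(store, group, roles)
  ids <- store$reports$report_id[cs & ex]
  denom <- length(ids)
  co <- unique(store$reactions[report_id %in% ids & term != target_pt])
  out <- co[, .(n = .N), by = term]
  if (!nrow(out)) return(data.table(term = character(), n = integer(), pct = numeric()))
  out[, pct := pct1(n, denom)]
  setorderv(out, c("n", "term"), order = c(-1L, 1L))
  out[]
}

#' Descriptive summary of quantitative case variables
#'
#' Median (IQR) of exact age and of time to onset, over all cases and over
#' the group-exposed cases. Exact age is optional in the data model (age is
#' stored banded); when absent the age summary is flagged not estimable.
#'
#' @inheritParams characteristics
#' @return data.table with one row per (variable, column): `variable`,
#'   `column`, `median`, `q1`, `q3`, `n`, `n_missing`.
#' @export
case_quantitative_summary <- function(store, target_pt, group,
                                      roles = c("suspect", "interacting")) {
  group <- as_drug_group(group)
  cs <- is_case(store, target_pt)
  ex <- is_exposed(store, group, roles)
  tto <- time_to_onset(store)
  one <- function(vals, variable, column) {
    m <- median_iqr(vals)
    data.table(variable = variable, column = column, median = m$median,
               q1 = m$q1, q3 = m$q3, n = m$n, n_missing = m$n_missing)
  }
  rbindlist(list(
    one(store$reports$age_years[cs], "age_years", "all_cases"),
    one(store$reports$age_years[cs & ex], "age_years", "group_cases"),
    one(tto$days[cs], "time_to_onset_days", "all_cases"),
    one(tto$days[cs & ex], "time_to_onset_days", "group_cases")))
}
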