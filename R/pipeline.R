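#' Analysis configuration
#'
#' Bundles the parameters of a full disproportionality run: the
#' case-defining preferred term, the eligibility threshold, the exposure
#' roles, drug groups analysed jointly, the subgroup strata and the ranking
#' rule for the output table.
#'
#' @param target_pt the case-defining PT (non-empty).
#' @param min_cases eligibility threshold on the `a` cell (default 4).
#' @param roles exposure roles, default suspect + interacting.
#' @param groups list of [drug_group]s analysed jointly (may be empty). The
#'   first group is the one subgroup/sensitivity analyses report on.
#' @param strata list of named strata for subgroup analysis, e.g.
#'   `list(list(sex = "female"), list(age_band = "45-64"))`.
#' @param ranking `"by_ror"` (default; mirrors the conventional signal
#'   table, ROR descending) or `"by_cases"` (case count descending).
#' @param confidence CI level, default 0.95.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(target_pt, min_cases = 4L,
                            roles = c("suspect", "interacting"),
                            groups = list(), strata = list(),
                            ranking = c("by_ror", "by_cases"),
                            confidence = 0.95) {
  target_pt <- normalize_name(target_pt)
  if (!nzchar(target_pt)) stop("target_pt must be non-empty")
  if (min_cases < 1) stop("min_cases must be >= 1")
  roles <- match.arg(roles, pv_roles, several.ok = TRUE)
  groups <- lapply(groups, as_drug_group)
  structure(list(target_pt = target_pt, min_cases = as.integer(min_cases),
                 roles = roles, groups = groups, strata = strata,
                 ranking = match.arg(ranking), confidence = confidence),
            class = "analysis_config")
}

#' Run the full disproportionality analysis
#'
#' Eligibility filtering, per-ingredient and per-group ROR/IC estimation,
#' and ranking into a signal table. One row per eligible ingredient (case
#' count at or above `min_cases`) and per configured group meeting the same
#' threshold; the signal rows are exactly those with IC025 > 0. Ingredients
#' that are members of a configured group are marked with their parent
#' group and carry their share of the group's cases (`pct_group`), the
#' nesting used when a vaccine brand is read as a fraction of the combined
#' vaccine row; every row carries its share of all cases (`pct_cases`).
#' Percentages are rounded half-away-from-zero to one decimal.
#'
#' Top-level rows (groups and non-member ingredients) are sorted per
#' `config$ranking` (ties: case count desc, then ROR desc, then name);
#' member rows follow their parent group, by case count.
#'
#' @param store a [report_store].
#' @param config an [analysis_config].
#' @return a `signal_table`: data.table with columns `label`,
#'   `parent_group`, `n_cases`, `pct_cases`, `pct_group`, `ror`, `ci_low`,
#'   `ci_high`, `ror_signal`, `ic`, `ic025`, `signal`, `corrected`,
#'   `estimable`, `n`; attributes `target_pt`, `n_total`, `total_cases`,
#'   `min_cases`.
#' @export
run_disproportionality <- function(store, config) {
  stopifnot(inherits(store, "report_store"), inherits(config, "analysis_config"))
  if (n_total(store) == 0L) stop("store is empty")
  total_cases <- sum(is_case(store, config$target_pt))

  elig <- eligible_drugs(store, config$target_pt, config$min_cases, config$roles)
  ing_rows <- if (nrow(elig)) rbindlist(lapply(elig$ingredient, function(ing)
    disproportionality(store, config$target_pt, ing, config$roles, config$confidence)))
  else NULL

  grp_rows <- NULL
  grp_cases <- list()
  if (length(config$groups)) {
    grp_rows <- rbindlist(lapply(config$groups, function(g) {
      r <- disproportionality(store, config$target_pt, g, config$roles, config$confidence)
      grp_cases[[g$name]] <<- r$n_cases
      r
    }))
    grp_rows <- grp_rows[n_cases >= config$min_cases]
  }

  out <- rbindlist(list(grp_rows, ing_rows), use.names = TRUE, fill = TRUE)
  if (!nrow(out)) {
    out <- not_estimable_row(character(0))[0]
    out[, `:=`(parent_group = character(0), pct_cases = numeric(0), pct_group = numeric(0))]
  } else {
    out[, parent_group := NA_character_]
    out[, pct_group := NA_real_]
    for (g in config$groups) {
      memb <- out$label %in% g$members & !(out$label %in% vapply(config$groups, `[[`, "", "name"))
      if (any(memb) && !is.null(grp_cases[[g$name]]) && grp_cases[[g$name]] > 0) {
        out[memb, parent_group := g$name]
        out[memb, pct_group := pct1(n_cases, grp_cases[[g$name]])]
      }
    }
    out[, pct_cases := pct1(n_cases, total_cases)]
    out <- rank_signal_table(out, config$ranking)
  }
  setcolorder(out, c("label", "parent_group", "n_cases", "pct_cases", "pct_group",
                     "ror", "ci_low", "ci_high", "ror_signal", "ic", "ic025",
                     "signal", "corrected", "estimable", "n"))
  setattr(out, "target_pt", config$target_pt)
  setattr(out, "n_total", n_total(store))
  setattr(out, "total_cases", total_cases)
  setattr(out, "min_cases", config$min_cases)
  setattr(out, "class", c("signal_table", class(out)))
  out
}

rank_signal_table <- function(out, ranking) {
  top <- out[is.na(parent_group)]
  if (ranking == "by_ror") {
    setorderv(top, c("ror", "n_cases", "label"), order = c(-1L, -1L, 1L), na.last = TRUE)
  } else {
    setorderv(top, c("n_cases", "ror", "label"), order = c(-1L, -1L, 1L), na.last = TRUE)
  }
  pieces <- lapply(seq_len(nrow(top)), function(i) {
    row <- top[i]
    kids <- out[!is.na(parent_group) & parent_group == row$label]
    if (nrow(kids)) {
      setorderv(kids, c("n_cases", "label"), order = c(-1L, 1L))
      rbindlist(list(row, kids))
    } else row
  })
  rbindlist(pieces)
}

#' @export
print.signal_table <- function(x, ...) {
  cat(sprintf("<signal_table> target PT '%s': %d rows, N = %d, cases = %d (min_cases = %d)\n",
              attr(x, "target_pt"), nrow(x), attr(x, "n_total"),
              attr(x, "total_cases"), attr(x, "min_cases")))
  print(as.data.table(x))
  invisible(x)
}

#' Subgroup disproportionality for the configured group
#'
#' Restricts the store to one stratum, rebuilds the 2x2 table of the first
#' configured group within it (N, margins and the expected count are all
#' recomputed inside the stratum) and returns a one-row result. An empty
#' stratum, or one with an empty exposure margin, yields a structured
#' not-estimable row, because descriptive strata legitimately include
#' unknown levels.
#'
#' @param store a [report_store].
#' @param config an [analysis_config] with at least one group.
#' @param stratum named list, e.g. `list(sex = "female")`.
#' @return one-row data.table as [disproportionality()], plus a `stratum`
#'   label column.
#' @export
run_subgroup <- function(store, config, stratum) {
  stopifnot(inherits(config, "analysis_config"), length(config$groups) >= 1)
  sub <- do.call(filter_reports, c(list(store), stratum))
  g <- config$groups[[1L]]
  res <- if (n_total(sub) == 0L) not_estimable_row(g$name)
  else disproportionality(sub, config$target_pt, g, config$roles, config$confidence)
  res[, stratum := paste(names(stratum), unlist(lapply(stratum, as.character)),
                         sep = "=", collapse = ",")]
  setcolorder(res, "stratum")
  res[]
}

#' All configured subgroup analyses
#'
#' Applies [run_subgroup()] to every stratum in `config$strata` and stacks
#' the one-row results (the subgroup analysis table).
#'
#' @inheritParams run_subgroup
#' @return data.table, one row per stratum.
#' @export
run_all_subgroups <- function(store, config) {
  if (!length(config$strata)) stop("config has no strata")
  rbindlist(lapply(config$strata, function(s) run_subgroup(store, config, s)))
}

#' Physician-reported-only sensitivity analysis
#'
#' The configured group's disproportionality recomputed on the subset of
#' reports filed by physicians — a robustness check on case validity, since
#' physician reports carry the most reliable diagnoses.
#'
#' @inheritParams run_subgroup
#' @return one-row data.table.
#' @export
run_sensitivity_physician <- function(store, config) {
  run_subgroup(store, config, list(reporter = "physician"))
}

#' Screen many drug/event pairs at once
#'
#' Vectorized disproportionality over every eligible (ingredient, event)
#' pair for a set of target events: for each event, ingredients listed with
#' a qualifying role in at least `min_cases` of its cases. Used for
#' database-wide screening and for null-calibration experiments.
#'
#' @param store a [report_store].
#' @param target_pts character vector of event PTs to screen.
#' @param min_cases eligibility threshold (default 4).
#' @param roles exposure roles.
#' @param confidence CI level.
#' @return data.table with one row per eligible pair: `event`, `ingredient`,
#'   `a`, `b`, `c`, `d`, `ror`, `ci_low`, `ci_high`, `ror_signal`, `ic`,
#'   `ic025`, `signal`, `corrected`, `covers_1` (does the ROR CI cover 1).
#' @export
scan_pairs <- function(store, target_pts, min_cases = 4L,
                       roles = c("suspect", "interacting"), confidence = 0.95) {
  stopifnot(inherits(store, "report_store"))
  roles <- match.arg(roles, pv_roles, several.ok = TRUE)
  N <- n_total(store)
  expo <- unique(store$drugs[role %in% roles, .(report_id, active_ingredient)])
  expo_n <- expo[, .(n_exposed = .N), by = .(ingredient = active_ingredient)]
  z <- qnorm(1 - (1 - confidence) / 2)
  res <- lapply(normalize_name(target_pts), function(pt) {
    case_ids <- unique(store$reactions[term == pt, report_id])
    n_case <- length(case_ids)
    if (!n_case) return(NULL)
    acounts <- expo[report_id %in% case_ids, .(a = .N), by = .(ingredient = active_ingredient)]
    acounts <- acounts[a >= min_cases]
    if (!nrow(acounts)) return(NULL)
    tab <- merge(acounts, expo_n, by = "ingredient")
    tab[, `:=`(b = n_exposed - a, c = n_case - a)]
    tab[, d := N - a - b - c]
    tab[, corrected := a == 0 | b == 0 | c == 0 | d == 0]
    tab[, `:=`(aa = a + 0.5 * corrected, bb = b + 0.5 * corrected,
               cc = c + 0.5 * corrected, dd = d + 0.5 * corrected)]
    tab[, ror := aa * dd / (bb * cc)]
    tab[, se := sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)]
    tab[, `:=`(ci_low = exp(log(ror) - z * se), ci_high = exp(log(ror) + z * se))]
    e <- with(tab, (a + b) * (a + c) / N)
    tab[, ic := log2((a + 0.5) / (e + 0.5))]
    tab[, ic025 := ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)]
    tab[, `:=`(ror_signal = ci_low > 1, signal = ic025 > 0,
               covers_1 = ci_low <= 1 & ci_high >= 1, event = pt)]
    tab[, .(event, ingredient, a, b, c, d, ror, ci_low, ci_high, ror_signal,
            ic, ic025, signal, corrected, covers_1)]
  })
  out <- rbindlist(res)
  if (!nrow(out)) return(out)
  setorderv(out, c("event", "a", "ingredient"), order = c(1L, -1L, 1L))
  out[]
}

#' Write a signal table (or any pipeline result) to TSV
#'
#' Stable, documented column order; numbers written in full precision.
#'
#' @param x data.table result from the pipeline.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
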