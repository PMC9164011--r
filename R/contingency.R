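#' Define a drug group
#'
#' A named set of active ingredients analysed jointly. Exposure to the group
#' means exposure to any member; each report still counts once in a 2x2
#' table however many members it lists. A singleton group is equivalent to
#' its lone ingredient.
#'
#' @param name group label.
#' @param members character vector of active-ingredient names (normalized on
#'   construction); must be non-empty.
#' @return an object of class `drug_group`.
#' @export
drug_group <- function(name, members) {
  members <- unique(normalize_name(members))
  if (!length(members) || any(members == ""))
    stop("drug_group members must be a non-empty set of non-empty names")
  structure(list(name = as.character(name), members = members),
            class = "drug_group")
}

#' @export
print.drug_group <- function(x, ...) {
  cat(sprintf("<drug_group> %s: {%s}\n", x$name, paste(x$members, collapse = ", ")))
  invisible(x)
}

# accept a bare ingredient name wherever a group is expected
as_drug_group <- function(x) {
  if (inherits(x, "drug_group")) return(x)
  if (is.character(x) && length(x) == 1L) return(drug_group(x, x))
  stop("expected a drug_group or a single ingredient name")
}

#' Built-in COVID-19 vaccine group
#'
#' The four marketed COVID-19 vaccine active ingredients analysed jointly,
#' plus the "unspecified" label under which one case was coded.
#'
#' @return a [drug_group].
#' @export
covid19_vaccine_group <- function() {
  drug_group("covid-19 vaccine",
             c("tozinameran", "elasomeran", "azd1222", "jnj-78436735",
               "covid-19 vaccine unspecified"))
}

#' Case status of each report
#'
#' A report is a case when the target preferred term (PT) is among its
#' reaction terms — exact match after normalization, never substring
#' matching ("amnesia" does not make a "transient global amnesia" case).
#'
#' @param store a [report_store].
#' @param target_pt the case-defining PT.
#' @return logical vector in store report order.
#' @export
is_case <- function(store, target_pt) {
  stopifnot(inherits(store, "report_store"))
  target_pt <- normalize_name(target_pt)
  if (!nzchar(target_pt)) stop("target_pt must be non-empty")
  ids <- unique(store$reactions[term == target_pt, report_id])
  store$reports$report_id %in% ids
}

#' Exposure status of each report
#'
#' A report is exposed to a drug group when some drug entry names a member
#' of the group with a qualifying role. By default only `suspect` and
#' `interacting` entries confer exposure; purely concomitant listings do
#' not.
#'
#' @param store a [report_store].
#' @param group a [drug_group] or a single ingredient name.
#' @param roles qualifying roles; subset of
#'   `c("suspect", "interacting", "concomitant")`.
#' @return logical vector in store report order.
#' @export
is_exposed <- function(store, group, roles = c("suspect", "interacting")) {
  stopifnot(inherits(store, "report_store"))
  group <- as_drug_group(group)
  roles <- match.arg(roles, pv_roles, several.ok = TRUE)
  ids <- unique(store$drugs[active_ingredient %in% group$members & role %in% roles,
                            report_id])
  store$reports$report_id %in% ids
}

#' Build the 2x2 case/non-case contingency table
#'
#' Report-level counts for one drug(-group)/event pair: `a` exposed cases,
#' `b` exposed non-cases, `c` unexposed cases, `d` unexposed non-cases.
#' Each report contributes to exactly one cell, so `a+b+c+d` always equals
#' the number of reports in the (possibly stratified) store — the comparator
#' is "all other reports in the same store".
#'
#' @inheritParams is_exposed
#' @param target_pt the case-defining preferred term.
#' @return an object of class `contingency_table`: list with `a`, `b`, `c`,
#'   `d`, `n`, `label`, `target_pt`.
#' @export
build_table <- function(store, target_pt, group,
                        roles = c("suspect", "interacting")) {
  if (n_total(store) == 0L) stop("cannot build a contingency table from an empty store")
  group <- as_drug_group(group)
  cs <- is_case(store, target_pt)
  ex <- is_exposed(store, group, roles)
  tab <- contingency_table(a = sum(cs & ex), b = sum(!cs & ex),
                           c = sum(cs & !ex), d = sum(!cs & !ex),
                           label = group$name, target_pt = normalize_name(target_pt))
  stopifnot(tab$n == n_total(store))
  tab
}

#' Construct a contingency table from cell counts
#'
#' @param a,b,c,d non-negative integer cell counts (exposed cases, exposed
#'   non-cases, unexposed cases, unexposed non-cases).
#' @param label,target_pt optional labels carried along for reporting.
#' @return a `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, label = NA_character_,
                              target_pt = NA_character_) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("cells must be non-negative counts")
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), n = as.numeric(a + b + c + d),
                 label = label, target_pt = target_pt),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s x %s\n",
              x$label %||% "?", x$target_pt %||% "?"))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"), c("case", "non-case")))
  print(m)
  cat(sprintf("N = %d\n", as.integer(x$n)))
  invisible(x)
}

#' Ingredients eligible for disproportionality analysis
#'
#' Counts, per active ingredient, the cases in which the ingredient is
#' listed with a qualifying role (each report counted once per ingredient)
#' and keeps those at or above the case-count threshold. The default
#' threshold of 4 reflects the usual screening rule that a pair must occur
#' in at least a handful of cases before a disproportionality estimate is
#' worth ranking.
#'
#' @inheritParams build_table
#' @param min_cases minimum number of cases (`a` cell); inclusive, >= 1.
#' @return data.table with columns `ingredient`, `n_cases`, sorted by case
#'   count descending then ingredient name.
#' @export
eligible_drugs <- function(store, target_pt, min_cases = 4L,
                           roles = c("suspect", "interacting")) {
  stopifnot(inherits(store, "report_store"), min_cases >= 1)
  roles <- match.arg(roles, pv_roles, several.ok = TRUE)
  target_pt <- normalize_name(target_pt)
  case_ids <- unique(store$reactions[term == target_pt, report_id])
  expo <- unique(store$drugs[role %in% roles, .(report_id, active_ingredient)])
  counts <- expo[report_id %in% case_ids, .(n_cases = .N), by = .(ingredient = active_ingredient)]
  counts <- counts[n_cases >= min_cases]
  setorderv(counts, c("n_cases", "ingredient"), order = c(-1L, 1L))
  counts[]
}
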