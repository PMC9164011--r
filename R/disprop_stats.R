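#' Reporting Odds Ratio with Woolf confidence interval
#'
#' The ROR compares the odds of the target reaction being reported with the
#' drug (group) against the odds of it being reported with all other drugs:
#' `ror = (a*d)/(b*c)`. The interval is the log-scale normal (Woolf)
#' interval `exp(log(ror) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When any
#' cell is zero the Haldane–Anscombe correction (+0.5 added to all four
#' cells) is applied to both the point estimate and the interval, and the
#' result is flagged `corrected`.
#'
#' @param table a [contingency_table].
#' @param confidence interval level, default 0.95.
#' @return list with `ror`, `ci_low`, `ci_high`, `corrected`, `confidence`.
#' @export
ror_with_ci <- function(table, confidence = 0.95) {
  stopifnot(inherits(table, "contingency_table"),
            confidence > 0, confidence < 1)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (a + b == 0 || c + d == 0)
    stop("undefined exposure margin: a+b and c+d must both be positive")
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - confidence) / 2)
  list(ror = ror, ci_low = exp(log(ror) - z * se), ci_high = exp(log(ror) + z * se),
       corrected = corrected, confidence = confidence)
}

#' Shrunken Information Component from observed and expected counts
#'
#' `ic = log2((O + 0.5) / (E + 0.5))`, the shrinkage-stabilised base-2 log
#' of the observed co-reporting count over the count expected under
#' independence, and its 2.5th credibility percentile
#' `ic025 = ic - 3.3*(O+0.5)^(-1/2) - 2*(O+0.5)^(-3/2)` (the standard
#' closed-form approximation to the lower end of the 95% credibility
#' interval of the gamma posterior; see [ic025_mc()] for the exact
#' Monte-Carlo counterpart). The +0.5 shrinkage keeps `O = 0` well-defined
#' and damps spurious disproportionality at tiny counts.
#'
#' @param o observed count (the `a` cell); non-negative.
#' @param e expected count under independence, `(a+b)*(a+c)/N`; positive.
#' @return list with `ic`, `ic025`, `o`, `e`.
#' @export
ic_from_counts <- function(o, e) {
  stopifnot(o >= 0, e >= 0)
  ic <- log2((o + 0.5) / (e + 0.5))
  ic025 <- ic - 3.3 * (o + 0.5)^(-0.5) - 2 * (o + 0.5)^(-1.5)
  list(ic = ic, ic025 = ic025, o = o, e = e)
}

#' Information Component of a contingency table
#'
#' Computes O = `a` and E = `(a+b)(a+c)/N` from the 2x2 table and applies
#' [ic_from_counts()]. A positive IC means the pair is reported more often
#' than expected were drug and event independent; the IC025 > 0 rule is the
#' signal criterion.
#'
#' @param table a [contingency_table] with `n > 0`.
#' @return list with `ic`, `ic025`, `o`, `e`.
#' @export
information_component <- function(table) {
  stopifnot(inherits(table, "contingency_table"), table$n > 0)
  o <- table$a
  e <- (table$a + table$b) * (table$a + table$c) / table$n
  ic_from_counts(o, e)
}

#' Monte-Carlo IC025 (gamma-posterior oracle)
#'
#' Independent check on the closed-form IC025: samples the reporting-rate
#' ratio lambda from the shrinkage posterior Gamma(shape = O + 0.5, rate =
#' E + 0.5) and returns the 2.5th percentile of `log2(lambda)`.
#' Deterministic given `seed`. The closed-form approximation in
#' [ic_from_counts()] is known to sit up to about 0.05 below this exact
#' percentile for moderate O; the two agree as O grows.
#'
#' @param x a [contingency_table], or a list with elements `o` and `e`.
#' @param n_samples number of posterior draws, >= 1e5.
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return the Monte-Carlo IC025 estimate (numeric scalar).
#' @export
ic025_mc <- function(x, n_samples = 1e6, seed = 1L) {
  if (inherits(x, "contingency_table")) {
    o <- x$a
    e <- (x$a + x$b) * (x$a + x$c) / x$n
  } else {
    o <- x$o; e <- x$e
  }
  stopifnot(n_samples >= 1e5, o >= 0, e >= 0)
  with_seed(seed, {
    lam <- rgamma(n_samples, shape = o + 0.5, rate = e + 0.5)
    unname(quantile(log2(lam), 0.025, type = 7))
  })
}

#' The IC025 signal rule
#'
#' A pair is flagged as a potential signal when the lower end of the 95%
#' credibility interval of its Information Component is strictly positive.
#' `ic025 = 0` is not a signal. The ROR lower-bound rule (`ci_low > 1`) is
#' also computed by the pipeline but the signal flag follows IC025.
#'
#' @param result a `disproportionality_result` row (or any list/data.frame
#'   with an `ic025` element), or a bare numeric ic025 value.
#' @return logical; `NA` ic025 values give `FALSE` (not estimable).
#' @export
is_signal <- function(result) {
  ic025 <- if (is.numeric(result)) result else result$ic025
  !is.na(ic025) & ic025 > 0
}

#' Full disproportionality result for one drug(-group)/event pair
#'
#' Builds the 2x2 table and assembles ROR + CI, IC + IC025 and the signal
#' flags into a one-row data.table. Pairs with an empty exposure margin
#' (nobody exposed, or nobody unexposed) yield a structured not-estimable
#' row instead of an error.
#'
#' @inheritParams build_table
#' @param confidence CI level for the ROR.
#' @return one-row data.table with columns `label`, `n_cases`, `ror`,
#'   `ci_low`, `ci_high`, `ror_signal`, `ic`, `ic025`, `signal`,
#'   `corrected`, `estimable`, `n`.
#' @export
disproportionality <- function(store, target_pt, group,
                               roles = c("suspect", "interacting"),
                               confidence = 0.95) {
  group <- as_drug_group(group)
  if (n_total(store) == 0L) return(not_estimable_row(group$name))
  tab <- build_table(store, target_pt, group, roles)
  disprop_row(tab, confidence)
}

disprop_row <- function(tab, confidence = 0.95) {
  if (tab$a + tab$b == 0 || tab$c + tab$d == 0)
    return(not_estimable_row(tab$label, n_cases = tab$a, n = tab$n))
  rr <- ror_with_ci(tab, confidence)
  icv <- information_component(tab)
  data.table(label = tab$label, n_cases = as.integer(tab$a),
             ror = rr$ror, ci_low = rr$ci_low, ci_high = rr$ci_high,
             ror_signal = rr$ci_low > 1,
             ic = icv$ic, ic025 = icv$ic025, signal = is_signal(icv$ic025),
             corrected = rr$corrected, estimable = TRUE, n = as.integer(tab$n))
}

not_estimable_row <- function(label, n_cases = 0L, n = 0L) {
  data.table(label = label, n_cases = as.integer(n_cases),
             ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             ror_signal = FALSE, ic = NA_real_, ic025 = NA_real_,
             signal = FALSE, corrected = FALSE, estimable = FALSE,
             n = as.integer(n))
}
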