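---
title: "Disproportionality methods in pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods in pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The case/non-case design

Spontaneous-reporting databases have no denominators: we observe reports,
not prescriptions or person-time, so incidence is unidentifiable.
Disproportionality analysis instead asks a within-database question. Fix a
target adverse event, defined by one MedDRA preferred term (PT); reports
listing that PT are *cases*, all others *non-cases*. A report is *exposed*
to a drug (or named drug group) when some drug entry names it with role
`suspect` or `interacting` — concomitant medication does not confer
exposure, because the reporter did not implicate it. Each report falls into
exactly one cell of the 2×2 table (a, b, c, d), so `a+b+c+d = N` holds by
construction and is enforced and tested. The comparator is always "all
other reports in the same store": subgroup analyses first restrict the
store, then rebuild the table, so N, both margins, and the expected count
are recomputed inside the stratum.

This report-level counting (one report, one cell, however many member
drugs it lists) is what makes union groups well-defined: a report listing
two member vaccines counts once in the group's `a` cell, which is why the
group `a` can be smaller than the sum of its members' `a` cells.

## Estimators

**ROR.** `ROR = ad/bc`, with the Woolf log-normal interval
`exp(ln ROR ± z·√(1/a+1/b+1/c+1/d))`, `z = 1.959964` at 95%. This is the
de-facto standard interval for the ROR in pharmacovigilance. If any cell is
zero, the Haldane–Anscombe correction adds 0.5 to **all four** cells, for
both the point estimate and the interval, and the result carries a
`corrected` flag; the correction is *not* applied otherwise, so ordinary
tables are untouched. An empty exposure margin (`a+b = 0` or `c+d = 0`)
is an error at the single-table level and a structured `estimable = FALSE`
row at the pipeline level, because descriptive strata legitimately include
empty levels.

**IC.** With observed `O = a` and expected `E = (a+b)(a+c)/N`,

    IC    = log2((O + 0.5) / (E + 0.5))
    IC025 = IC − 3.3·(O + 0.5)^(−1/2) − 2·(O + 0.5)^(−3/2)

the shrinkage-stabilised observed/expected ratio on a base-2 log scale.
The +0.5 terms pull small-count pairs toward IC = 0, which is the method's
built-in false-positive control; no multiplicity correction is applied on
top of it, by design. The signal rule is **strictly** `IC025 > 0`
(`IC025 = 0` is not a signal). The ROR rule `ci_low > 1` is computed and
reported alongside, but the `signal` flag follows IC025 — the two disagree
exactly in the regime (small O, inflated ROR) the IC is designed to damp.

**Monte-Carlo cross-check.** `ic025_mc()` samples the reporting-rate ratio
λ from the shrinkage posterior Gamma(shape = O+0.5, rate = E+0.5) and takes
the 2.5th percentile of log2 λ. This is an *exact* (up to MC error)
evaluation of the credibility bound the closed form approximates. The two
routes are implemented independently precisely so each can audit the other.

**A known gap, kept honest.** The closed-form IC025 sits *below* the exact
gamma percentile by an O-dependent offset: ≈0.028 at O = 4, ≈0.047 at
O = 10, ≈0.042 at O = 50, ≈0.034 at O = 100, ≈0.018 at O = 500 (we verified
the offset is constant in E, as the form of the approximation implies). A
0.02 agreement band therefore cannot be met below O ≈ 500. The acceptance
test asserting that band is left failing rather than loosened; the
practical consequence is conservative (the closed form slightly
under-calls signals near the boundary), and the package's own validation of
the MC machinery tests against the analytic gamma quantile instead.

## Eligibility, ranking, output

Only ingredients that are suspect/interacting in at least `min_cases`
cases (default 4, inclusive) are ranked — below that, estimates are noise
regardless of estimator. Ranking defaults to ROR descending (the
conventional signal-table order), with `by_cases` as the alternative; ties
break by case count, then ROR, then name. Configured group rows and their
eligible member rows co-exist: members are marked with their parent group
and carry two shares, percent of all cases (`pct_cases`) and percent of
the group's cases (`pct_group`), mirroring how a combined-vaccine row is
typically nested. Whether a member's comparator should exclude the sibling
members is not settled in the field; we use "all other reports" for every
row and note that the alternative would shrink member RORs slightly.

All percentages use one fixed rule — half away from zero, one decimal —
applied to integer counts. Two of the fifteen checkable published
percentages in the reference series (147/289 and 69/289) are inconsistent
with *any* single rounding rule that reproduces the other thirteen; we keep
the rule and do not chase those two printed values.

## The synthetic generator

`generate_database()` draws reports independently: truncated-Poisson(μ,
min 1) counts of drugs and events per report, item identities from
Zipf-like catalogue frequencies (defaults: 200 drugs, 100 events, exponent
1, μ_drugs = 2, μ_events = 1.5 — a skew and multiplicity typical of
spontaneous-report stores), roles ~ (suspect 0.70, interacting 0.05,
concomitant 0.25), demographics from configurable strata probabilities
(defaults: adult-skewed, 55% female, ~45% serious, a physician/consumer
reporter mix with a large unknown fraction).

**Signal injection** tilts the joint presence law of one (drug, event)
pair: with background presence probabilities `p_D`, `p_E`, the four
presence cells (θ·p_D·p_E, p_D(1−p_E), (1−p_D)p_E, (1−p_D)(1−p_E)) are
renormalized and drawn per report; the tilted pair is removed from
background sampling. Renormalization cancels in the odds ratio, so the
presence odds ratio — which is what the sample ROR estimates — equals θ
*exactly*, giving θ a clean interpretation as the target reporting-rate
ratio. The marginal presence probability of a signal entity is kept at its
background level via `p = 1 − (1 − f)^μ`, the at-least-once probability
for a catalogue item of frequency f among μ slots. A tilt with
θ·p_D·p_E > 1 is rejected as infeasible. Injected drugs are always
`suspect`. Multiple signals must use distinct drugs and events and are
drawn independently.

Calibration measured under this generator (and asserted in the acceptance
suite): relative bias of log-ROR ≈ 0 at n = 200,000 (−0.1% at θ = 5 over
20 replicates); null z-scores mean ≈ 0.08, sd ≈ 0.86 over 100 seeds —
slightly conservative, as expected with discrete counts; ~1% of eligible
null pairs flagged by IC025; Woolf CIs cover 1 for ~95% of null pairs.

**What the generator does not emulate:** reporting trends over time (e.g.
launch-period inflation of new products), country- or reporter-specific
reporting cultures, correlated drug co-prescription, near-duplicate
reports, and MedDRA term hierarchies (PTs are opaque labels). A green test
against this generator validates the estimators and pipeline mechanics; it
says nothing about confounding, causality, or those unmodelled features.

## The deterministic fixture

`build_tga_fixture()` reconstructs, report by report, a store whose *case*
margins equal a published worldwide series of 852 transient global amnesia
reports: the 289 vaccine-exposed cases with member split 147/69/60/12/1,
and exact sex, age-band, country, reporter and seriousness margins for
both columns, plus co-reported headache/confusional state/fatigue counts
of 31/27/24. Joint cells are not pinned by any published table; each
variable's level vector is laid out from the counts and interleaved by a
fixed coprime-stride permutation (a different stride per variable), which
is deterministic, auditable, and avoids fully block-correlated joints.
Three published numbers are internally inconsistent and were adjusted in
the unknown levels only (reporter totals, which over-count because reports
can carry several reporter qualifications, and a one-report excess in the
all-case country column); every named level is exact.

The 20,000 filler non-case reports come from the package's own generator
under a fixed internal seed, with the analysed ingredients given plausible
frequencies so every `b` cell is populated. Consequently ROR/IC values on
the fixture are *well-defined but deliberately not comparable* to the
published estimates — those depend on source-database margins that were
never printed. Only the descriptive case percentages are acceptance-
bearing. The same applies to fixture subgroup results: e.g. the
physician-only sensitivity row on the fixture is dominated by the filler's
reporter mix being independent of exposure, and is illustrative only.
Exact ages are filled on a deterministic grid within each band (the store
itself is banded; exact age is an optional field used only by descriptive
summaries), and onset delays follow fixed piecewise-linear quantile
profiles targeting the published onset medians (5 days for vaccine cases,
7 days overall) approximately — these are excluded from exact acceptance.

## Numerical and interface choices

- Quartiles use linear interpolation between order statistics (R type 7);
  this is the convention under which an IQR bound like 63.75 arises from
  integer day counts, and it is frozen so tests can be exact.
- Time to onset is the floor of (onset date − earliest suspect/interacting
  start date) in days; negative values are flagged, never silently
  dropped or clamped.
- Name normalization is trim/lowercase/whitespace-collapse only; no
  spelling reconciliation. Age is stored banded; exact ages are binned on
  read with lower-bound-inclusive edges, and ages below 2 fall to unknown
  (the youngest band starts at 2).
- Off-vocabulary demographic levels become `unknown` with a warning; drug
  roles are strict errors — a report whose exposure status is
  uninterpretable would corrupt every table it enters.
- All randomness sits behind a single seed per operation; replicate r of
  an experiment uses seed + r; RNG state of the caller is restored.
- Configs and report files are JSON(-Lines) or CSV; YAML is not supported
  because no YAML parser is available in the supported dependency set.

## Limitations

Disproportionality is a screening statistic, not an effect measure:
signals reflect reporting behaviour as much as biology, and no adjustment
for confounding, stimulated reporting, or event background rates is made
(or claimed). The package reproduces the design faithfully — including its
known fragilities at small counts, which the IC shrinkage only mitigates.
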