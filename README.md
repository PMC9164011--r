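# pvsignal

Case/non-case disproportionality analysis for spontaneous adverse-event
reporting databases — the class of passive pharmacovigilance data collected
by national authorities and pooled internationally. Given individual case
safety reports (drugs with reporter-assigned roles, MedDRA preferred terms,
demographics, seriousness), `pvsignal` answers the screening question: *is
this adverse event reported disproportionately often with this drug,
compared with all other drugs in the database?*

It is written for pharmacoepidemiologists and pharmacovigilance assessors
who need a reproducible, testable pipeline for this design — including a
synthetic database generator with known ground truth, because the real
international databases are access-restricted.

## The statistics

Cases are the reports listing a target preferred term (PT); exposure means
a drug (or drug group) listed as *suspect* or *interacting* (concomitant
listings do not expose). Each report falls in exactly one cell of the 2×2
table

|            | case | non-case |
|------------|------|----------|
| exposed    | a    | b        |
| unexposed  | c    | d        |

with `a+b+c+d = N`, the number of reports in the (possibly stratified)
store. Two estimators are computed per pair:

- **Reporting Odds Ratio** `ROR = (a·d)/(b·c)` with the Woolf (log-normal)
  95% CI `exp(ln ROR ± 1.959964·√(1/a+1/b+1/c+1/d))`; a zero cell triggers
  the Haldane–Anscombe +0.5 correction of all four cells (flagged).
- **Information Component** `IC = log₂((O+0.5)/(E+0.5))` with `O = a`,
  `E = (a+b)(a+c)/N`, and its 2.5th credibility percentile
  `IC025 = IC − 3.3(O+0.5)^{−1/2} − 2(O+0.5)^{−3/2}`. The **signal rule is
  strictly `IC025 > 0`**; the ROR lower-bound rule (`ci_low > 1`) is also
  reported. An exact gamma-posterior Monte-Carlo IC025 (`ic025_mc()`)
  serves as an independent cross-check of the closed form.

Eligibility: only drugs that are suspect/interacting in at least
`min_cases` (default 4) cases are ranked. Subgroup (sex, age band) and
sensitivity (physician-reported-only) analyses recompute every margin
inside the stratum.

## Worked example

The package ships a deterministic reference fixture: 852 transient global
amnesia (TGA) case reports whose descriptive margins reproduce a published
worldwide case series exactly (289 exposed to a COVID-19 vaccine), on top
of 20,000 synthetic background reports.

```r
library(pvsignal)
fx  <- build_tga_fixture()
g   <- covid19_vaccine_group()
cfg <- analysis_config("transient global amnesia", groups = list(g))
st  <- run_disproportionality(fx, cfg)
head(as.data.frame(st), 10)
```

```
                label     parent_group n_cases pct_cases pct_group   ror ic025 signal
 1:         tadalafil             <NA>      17       2.0        NA  3.37  0.70   TRUE
 2:      atorvastatin             <NA>      41       4.8        NA  2.55  0.68   TRUE
 3:        sildenafil             <NA>      17       2.0        NA  2.42  0.31   TRUE
 4:          zolpidem             <NA>      15       1.8        NA  2.29  0.19   TRUE
 5:      enzalutamide             <NA>       6       0.7        NA  2.24 -0.45  FALSE
 6: influenza vaccine             <NA>      23       2.7        NA  2.03  0.22   TRUE
 7:   alendronic acid             <NA>      11       1.3        NA  1.95 -0.18  FALSE
 8:  covid-19 vaccine             <NA>     289      33.9        NA  1.91  0.45   TRUE
 9:       tozinameran covid-19 vaccine     147      17.3      50.9  1.87  0.46   TRUE
10:           azd1222 covid-19 vaccine      69       8.1      23.9  1.45  0.07   TRUE
```

Reading this: the vaccine group accounts for 289 of the 852 TGA cases
(33.9%, `pct_cases`); tozinameran is 50.9% of the group's cases
(`pct_group`); rows with `ic025 > 0` carry `signal = TRUE`. The *case
percentages* are exact reproductions of the published series; the *ROR/IC
values* are not comparable to any published estimate, because the fixture's
non-case background is synthetic (the source database's margins were never
published).

Ground-truth recovery on a fully synthetic database — inject a pair with a
5-fold reporting-rate tilt among 200,000 reports and re-estimate it:

```r
sc <- sim_config(200000, signals = list(list(drug = "drug_030",
                                             event = "event_020", theta = 5)),
                 seed = 42)
db <- generate_database(sc)
disproportionality(db, "event_020", "drug_030")
```

```
      label n_cases  ror ci_low ci_high ic025 signal
1: drug_030     143 4.29   3.61    5.11  1.69   TRUE
```

## Command line

```sh
exec/pvsignal run --reports reports.jsonl --config config.json --out results/
exec/pvsignal descriptives --reports reports.jsonl --config config.json --out results/
exec/pvsignal simulate --config sim.json --out synthetic.jsonl
exec/pvsignal fixture --out fixture.jsonl
```

(`exec/pvsignal` under the installed package directory, or call
`pvsignal::pvsignal_main(c("run", ...))` directly.) Configs are JSON; see
`?pvsignal_main`.

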