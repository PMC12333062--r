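---
title: "Reporting odds ratio signal detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reporting odds ratio signal detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rorsignal)
```

## The problem

Spontaneous adverse-event report databases such as JADER (the Japanese
Adverse Drug Event Report database published by the PMDA) collect
case-keyed reports: each case links patient demographics, the drugs
involved (with an involvement role of suspected, concomitant or
interaction, and an administration route), the adverse events coded as
MedDRA Preferred Terms, and medical history. There is no denominator of
exposed patients, so risk cannot be estimated; what can be estimated is
*disproportionality* — whether a particular event is reported more often
with a particular drug than with everything else in the database.

`rorsignal` implements this analysis end to end for the infusion-reaction
question: do antitumor antibodies that exert antibody-dependent cellular
cytotoxicity (ADCC) — recruiting NK cells and macrophages via their Fc
region to lyse target cells, with attendant cytokine release — show
infusion-reaction signals more often than antibodies without ADCC
activity? Infusion reactions are operationalized as two Preferred Terms:
10051792 (infusion-related reaction) and 10052015 (cytokine release
syndrome).

## The statistic

For one drug against the rest of the analysis universe, the 2×2 table is

|              | event | no event |
|--------------|-------|----------|
| drug         | a     | b        |
| other drugs  | c     | d        |

with margins fixed by the universe totals: `a + c = N_event`,
`a + b + c + d = N_total`. The reporting odds ratio is

$$\mathrm{ROR} = \frac{a/b}{c/d} = \frac{ad}{bc},$$

with the Woolf log-normal 95% interval

$$\exp\!\left(\ln \mathrm{ROR} \pm z_{0.975}
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right),
\qquad z_{0.975} = 1.959964.$$

A **signal** is declared when the lower bound exceeds 1 *strictly* and the
drug has at least two event cases (`a >= 2`). The two-case rule guards
against single-report artifacts; the strict inequality means a bound of
exactly 1 never signals. Hand recomputation with this interval reproduces
every published per-drug ROR and CI in the bundled 25-antibody reference
table to the printed 2 decimal places, which is why Woolf (rather than
exact or score intervals) is the package default and only method.

Per-drug p-values come from the two-sided Fisher exact test under the
small-p-values rule (sum of hypergeometric point probabilities not
exceeding the observed table's). Group detection tables (signal yes/no by
ADCC status or antibody type) are tested with the same rule extended to
2×K tables (Freeman–Halton). Across the per-drug tests of one run,
p-values are adjusted by the Benjamini–Hochberg step-up procedure. Note
that BH adjustment is *not* idempotent as an operator on p-value vectors
(re-adjusting already-adjusted values can inflate them further, e.g.
`(0.01, 0.5) -> (0.02, 0.5) -> (0.04, 0.5)`); adjusted values are reported
once and never re-fed.

## Inclusion rules and counting conventions

Three decisions fix the numbers and were genuinely open:

* **Counting unit is the case, not the drug–event pair.** A drug's report
  total is the number of universe cases listing it as a suspected,
  intravenous drug; a case with both target PTs is one event case. Under
  this reading the published tables satisfy `No IR = AE − IRs` exactly.
* **The disproportionality background is the filtered universe itself**
  (all cases passing the role/route filters), not the raw database.
  Rebuilding the published per-drug tables requires `N_total = 97,567`
  and `N_event = 1,762` — the filtered totals.
* **Group pooling is additive over member drugs**: the pooled `a` and
  `a + b` are sums of the per-drug counts, so a case suspected of two
  member drugs contributes once per drug. This exactly reproduces the
  published ADCC-group table from the per-drug rows (1,142 = the sum of
  the 14 ADCC-positive drugs' event counts). Deduplicated pooling would
  be defensible epidemiology but would not reproduce the published
  construction, and with the default single-suspected-drug synthetic data
  the two coincide.

Drug-name normalization is deliberately minimal — trim, collapse
whitespace, case-fold, optional user synonym map — because no unification
rules for brand/generic/transliterated names are published; real JADER
extracts need a curated synonym map supplied by the analyst. Unknown role
or route vocabulary is preserved but mapped to `other_unknown` with a
warning, so filters remain closed-vocabulary.

## Numerical choices

* **Zero cells** make the ROR undefined; the package reports `NA` with an
  `undefined` flag rather than silently correcting. The Haldane–Anscombe
  +0.5 correction is available behind `continuity = TRUE` and off by
  default: the reference analysis never needed it (every drug has
  `a >= 1`, and the two-case rule gates signals).
* **No internal rounding.** ROR/CI are rounded to 2 decimals and p-values
  to 4 only in `format_signal_results()` and written reports.
* **p-value underflow.** On very large tables the exact p can fall below
  the smallest representable double and becomes 0. The volcano stage
  excludes any point with `p < p_floor` (default 1e-300) with the reason
  `"p underflow"` instead of plotting an infinite ordinate; in the bundled
  reference run exactly one drug (cetuximab, 591 events among 4,799
  reports) is excluded this way.
* **Volcano axes**: abscissa is the natural log of the ROR; the ordinate's
  log base is not dictated by convention in the source tables, so the
  community volcano-plot convention of −log10 was adopted.
* **Exact-test backends.** The 2×2 and 2×K exact tests are computed by
  `stats::fisher.test` (the de-facto reference implementation, and the
  engine behind the EZR GUI widely used for these analyses); the test
  suite verifies both against an independent brute-force
  margin-preserving enumeration oracle to 1e-12 on tables with margins up
  to 30. The 2×K path refuses tables above a grand-total cap (default
  2,000) rather than approximating silently. Where the published
  antibody-type comparison prints two different p-values in different
  places (0.667 and 0.677), the enumeration oracle adjudicates: the exact
  value is 0.6674, so 0.667 is pinned in tests.

## The synthetic-report generator

Real spontaneous-report data cannot be redistributed, so every pipeline
stage is exercised against a seeded generator
(`generator_config()` / `generate_reports()`) that emulates the four-table
layout with known structure:

* Each synthetic case gets **one suspected drug** drawn from the
  configured profiles (shares summing to ≤ 1; the remainder goes to a
  neutral background pool of five intravenous drugs). Multi-drug cases
  are available behind `multi_drug_prob` but are off by default, matching
  the additive pooled-count convention above.
* **Effects are planted on the odds scale**: a drug with multiplier `r`
  gives its cases event probability `r·q/(1 − q + r·q)` at background
  rate `q`, so the drug's population ROR against the background pool is
  exactly `r` and the ROR estimator is the natural parameter. Default
  study conditions in the calibration tests mirror the reference
  database's order of magnitude: background event rate `q = 0.02` (the
  reference universe has 1,762 events in 97,567 cases, about 1.8%), with
  `n = 50,000` cases for effect-recovery runs and `n = 5,000` with
  `q = 0.05` for interval-coverage runs (the latter chosen so per-replicate
  event counts are large enough that the log-normal interval is in its
  working range while 1,000 replicates stay cheap).
* Role noise downgrades a configured fraction of a drug's mentions to
  concomitant; oral-route profiles are generated but must vanish from the
  filtered universe — both are exercised as filter tests.
* A single master seed drives four deterministically derived per-table
  sub-streams, so identical configurations yield byte-identical tables.

What the generator does **not** emulate: realistic demographics, dosing,
outcome severity, reporting-time dynamics (Weber effect), correlated
multi-drug regimens, or MedDRA coding noise. Passing calibration tests
therefore shows the estimator and rules are correct under the stated
sampling model, not that the pipeline is robust to real-world reporting
biases — stimulated reporting, missing denominators and channeling all
remain, as in any disproportionality analysis.

## Calibration properties the suite enforces

* A planted null (`r = 1`) drug's 95% CI covers 1 in 95% ± 3% of 1,000
  seeded replicates.
* A planted `r = 5` at 50,000 cases lies inside the estimate's own 95% CI
  in at least 90% of 100 seeds, and the mean log-ROR across seeds is
  within 3 standard errors of `ln 5`.
* Exact tests agree with the enumeration oracles to 1e-12; BH agrees with
  a hand step-up oracle and is monotone and never decreasing.

## Known limitations

* The ROR is a reporting association, not a risk estimate; no causal or
  incidence claim follows from a signal.
* The BH family is the per-drug tests of one run; if an analysis plan
  involves several runs, the family must be widened by the analyst.
* Concomitant-medication usage percentages sometimes quoted alongside
  such analyses have no reproducible extraction procedure and are out of
  scope here.
* The packaged attribute table (ADCC status, antibody type) is curated
  literature data, shipped as data; the package does not compute ADCC
  status.
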