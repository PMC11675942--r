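---
title: "Disproportionality signal mining for GLP-1 receptor agonist GI adverse events"
author: "glp1pv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal mining for GLP-1 receptor agonist GI adverse events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect voluntary reports of suspected drug harms.
They have no denominator: a report says that a drug and an event were
reported together, not how many patients took the drug. Signal detection on
such data therefore compares the *relative* frequency of a drug-event pair
against its frequency among all other reports -- disproportionality
analysis. `glp1pv` implements this workflow for the gastrointestinal (GI)
safety profile of the four widely used glucagon-like peptide-1 receptor
agonists (GLP-1 RAs): exenatide, liraglutide, dulaglutide and semaglutide.
The class is strongly associated with GI physiology (delayed gastric
emptying is part of its mechanism), which makes within-class comparison the
natural design: each drug is contrasted against the other three pooled.

The package covers the full path from raw report tables to a signal table:

1. **Ingestion** -- a normalized one-row-per-report-drug-event table, or a
   minimal FAERS-style `$`-delimited dialect (`DEMO`/`DRUG`/`REAC`/`OUTC`/
   `INDI`), with drug-name normalization over the US generic and brand
   names.
2. **Selection** -- deduplication (latest case version wins) and a fixed
   filter sequence (primary-suspect role, retained drugs, GI events, US
   reports, exclusion of multi-suspect combination reports, completeness,
   2007--2023 window), each stage recorded in an attrition log.
3. **Counting** -- a 2x2 table per drug x event: `a` reports of the drug
   with the event, `b` its remaining reports, `c`/`d` the same over the
   pooled comparator.
4. **Statistics** -- four methods per pair (below), with positivity flags
   and a combined method count.
5. **Reproduction** -- the per-drug case counts printed by a published
   FAERS analysis of this class are packaged, and
   `reproduce_signal_table()` recomputes its signal table cell by cell.

## The statistics

For a 2x2 table with cells $a,b,c,d$, $N = a+b+c+d$ and expected pair count
$E = (a+b)(a+c)/N$:

* **ROR** $= ad/bc$ with the delta-method interval
  $\exp(\ln \mathrm{ROR} \pm z\sqrt{1/a+1/b+1/c+1/d})$. Signal:
  CI lower bound $> 1$ and $a \ge 3$.
* **PRR** $= \frac{a/(a+b)}{c/(c+d)}$ with variance
  $1/a - 1/(a+b) + 1/c - 1/(c+d)$ on the log scale. Signal:
  $\mathrm{PRR} \ge 2$, $\chi^2 \ge 4$ (Yates-corrected Pearson) and
  $a \ge 3$.
* **Information component**, two variants. The closed-form shrinkage
  variant (the package headline, deterministic):
  $\mathrm{IC} = \log_2\frac{a+0.5}{E+0.5}$, with
  $\mathrm{IC}_{025} = \mathrm{IC} - 3.3(a+0.5)^{-1/2} - 2(a+0.5)^{-3/2}$.
  The prior-based variant places independent Beta posteriors on the pair
  probability and the two margins ($\alpha_1=\beta_1=1$,
  $\alpha=\beta=2$, $\gamma_{11}=1$, $\gamma$ scaled so the prior IC
  expectation is zero) and uses the *exact* log-moments of those posteriors
  (digamma/trigamma) rather than first-order moment approximations; this
  makes the quantity well-defined enough to verify against numerical
  quadrature to $10^{-6}$. Signal: $\mathrm{IC}_{025} > 0$.
* **Adjusted logistic regression** -- per pair, the report-level model
  $\mathrm{logit}\,P(\text{event}) = \beta_0 + \beta_1\,\text{drug} +
  \beta_2\,\text{age}_c + \beta_3\,\text{male}$, maximum likelihood via
  IRLS. Age enters continuous and mean-centered, sex as a male indicator
  with female reference; rows missing either are dropped listwise for this
  method only (the count-based statistics keep them). Signal: $\beta_1 > 0$
  with Wald $p < 0.05$. With no covariates $\beta_1 = \ln \mathrm{ROR}$
  exactly, which the tests assert to $10^{-4}$.

Zero cells: when any cell is 0 the ratio statistics apply the
Haldane-Anscombe +0.5 to all four cells and flag the result
`continuity_corrected`; flagged results never count as exact
reproductions and never fire a signal flag. Complete separation in the
regression is *reported* (`converged = FALSE`, reason `"separation"`),
not silently penalized; a Jeffreys-penalized (Firth) fit is available
behind `firth = TRUE` for users who want finite estimates under
separation.

Confidence intervals use the conventional $z = 1.96$ at the default 95%
level (the value published signal tables in this field are computed with
-- verifiable here because the sparse anal-fissure row, where the standard
error is enormous, reproduces the printed bounds only with 1.96), and the
exact normal quantile at any other level.

## The packaged counts and what "reproduction" means

The fixture (`count_fixture()`) carries the published per-drug GI report
totals (4401 / 4126 / 4075 / 3966; 16,568 in total), the per-event case
counts, and every printed ROR/PRR/IC025/beta value, each cell with a
provenance note. `reproduce_signal_table()` rebuilds all complete rows and
compares, at the printed three-decimal precision, with a 5e-4 tolerance
(printed values are rounded, not truncated).

Not everything in the printed table is arithmetically consistent with its
own counts, and the package flags rather than hides this. The packaged
known-discrepancy rules cover:

* the semaglutide vomiting case count (printed 2298; the row's own ROR of
  1.612 and the published 30.2% share both imply 1198 -- a digit erratum;
  the fixture carries the corrected count for comparator cells, and the
  row itself stays excluded),
* the life-threatening and hospitalization rows, whose printed values
  match each other's recomputation (transposed) for three of the four
  drugs,
* the entire dulaglutide column, which matches recomputation from the
  published totals nowhere (no alternative denominator reconciles it),
* the liraglutide diarrhea cell, which reproduces exactly from the
  dulaglutide count (a transposition),
* all printed PRR confidence limits (they follow no delta-method variance;
  property-tested instead), all IC025 cells (the published BCPNN
  parameterization matches neither standard variant), and all
  regression coefficients (they require the original report-level
  covariates),
* zero-cell rows, whose published continuity handling is not recoverable.

Every other cell -- 207 of them -- must `match`; a mismatch anywhere is a
`tolerance_fail` and `cmd_reproduce_paper()` callers exit nonzero. The
excluded cells appear in the report with status
`excluded_known_discrepancy` and a reason code, never silently.

## The synthetic cohort generator

`synthetic_config()` defaults describe the analyzed cohort: 16,568 reports
split 26.6/24.9/24.6/23.9% over the four drugs, 62% female, age-band
shares 10/19.8/32/38.2% over 18--44/45--54/55--64/65+, reporting years
drawn uniformly from each drug's post-approval study years, 65% consumer
reporters, diabetes as the dominant indication, and the observed
serious-outcome rates. Event baselines default to the pooled observed
event frequencies.

The reporting-rate multiplier $\theta$ is defined on the **odds** scale:
$p = \theta q / (1 - q + \theta q)$ for baseline $q$. This makes the ROR
of the generated 2x2 exactly $\theta$ -- the multiplier is the generative
analogue of what the statistics estimate -- so parameter recovery is a
sharp test at any baseline. (A risk-multiplicative definition
$p = \theta q$ would make the true odds ratio $4.75$ at $q=0.05,
\theta=4$, and "recovery of $\theta$" would be ill-posed.) For small $q$
the two definitions coincide.

Events are drawn independently per report given drug and covariates; real
reports have correlated symptom clusters, so passing tests here validate
the estimators and pipeline, not within-report dependence structure. Other
realities the generator does not emulate: duplicate submissions (injected
only explicitly for deduplication tests), secular reporting trends,
notoriety effects, and missing-data mechanisms other than
missing-completely-at-random.

With `confounding` set, event probabilities become logit-linear in
centered age and sex, and drug assignment can be tilted by age
(`drug_age_bias`, per-drug log-odds per year). In that regime the crude
ROR is biased away from $\theta$ while the adjusted regression recovers
$\ln\theta$ -- the acceptance surface for the adjustment stage. The
packaged scenario uses an age slope of 0.05 per year on the event,
0.3 for male sex, and an assignment tilt of 0.08 per year, chosen once as
a materially confounded design.

## Numerical and design choices

* **Counting unit.** `a` counts *reports* (a report naming the event on
  several rows counts once; its presence in one event's `a` does not
  remove it from another's), because the published per-drug totals are
  report counts and each report can carry several events. Row-level
  counting is available via `unit = "row"`; the two coincide on
  fixture-expanded data.
* **Comparator.** Within-class (the other three drugs pooled) -- the only
  comparator consistent with the published values. A user-built background
  table can be passed to the statistics directly for external-comparator
  analyses; the published class-versus-background figures are not
  reproduced because their background population is unspecified.
* **Combination reports** are defined as reports whose suspect-drug set
  (primary or secondary suspect) contains more than one distinct drug --
  the strictest reading -- and the flag is computed before role filtering
  so secondary suspects still count.
* **Deduplication key**: latest case version per case id (configurable to
  full-record matching); order-invariant and idempotent.
* **Missingness**: only drug, event PT and country are completeness
  requirements by default; demographics may be missing in retained reports
  (the published cohort table shows they were).
* **FAERS ages** convert by code (YR, DEC x10, MON /12, DY /365.25,
  WK /52.1775); out-of-range results become missing.
* **Percent display** uses half-up rounding to one decimal.
* **Problem sizes in the test suite** were chosen to make Monte-Carlo
  error small relative to the asserted tolerances: 50 replicates of
  n = 50,000 per multiplier for recovery (median ln ROR within 0.1 of
  ln theta), 200 replicates of n = 20,000 over six events for CI coverage
  (0.95 plus or minus 0.02), n = 50,000 for the confounded scenario.

## Known limitations

Spontaneous-report disproportionality measures reporting, not incidence or
risk; a positive signal is a hypothesis for pharmacoepidemiologic
follow-up, not proof of causation. The within-class comparator means every
estimate is relative to the other three drugs, and a class-wide effect is
invisible by construction. Published IC025 and regression coefficients
cannot be verified from printed counts alone, and the discrepancies listed
above are in the published table itself, so exact reproduction is bounded
by the source's internal consistency -- which the reproduction report makes
explicit rather than papering over.
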