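---
title: "Methods: two-stage SNP screening, cumulative risk scores and absolute risk"
author: "snpRiskAssess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage SNP screening, cumulative risk scores and absolute risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpRiskAssess)
```

This vignette is the package's own account of the statistical machinery it
implements: the models, their assumptions, the tunable parameters, the
numerical conventions, and what the synthetic-data generator can and cannot
establish. No empirical number is stated here that the test suite or
`scripts/acceptance.R` does not itself compute.

## The study design being modelled

The package targets a two-stage case-control design: a panel of candidate
susceptibility SNPs is screened for association in a *testing set*, the
markers passing the screen are genotyped in an independent *validation
set*, and the confirmed markers are combined — with categorical
reproductive risk factors (age at menarche in three levels: < 15, 15–< 17,
≥ 17 years; age at first live birth in two: < 25, ≥ 25 years) — into
cumulative risk models. The category boundaries are half-open intervals so
the levels partition the axis. The bundled reference inputs are the
published summary tables of such a study in Chinese women (testing set
878 cases / 900 controls, validation set 914 / 967, five confirmed
markers); `publishedGenotypeCounts()` and `publishedScreeningPanel()`
expose them.

A `StudyDataset` is a `SummarizedExperiment` with a `dosage` assay
(markers × subjects, counting copies of each marker's *minor* allele), the
SNP panel in `rowData` and covariates in `colData`. The *risk allele* is
fixed in the panel definition rather than re-estimated per dataset, so its
orientation cannot silently flip between study stages; risk-model code
flips dosage only where the designated risk allele is the major one.

## Exact tests

**Hardy–Weinberg.** The exact conditional test fixes the allele counts and
enumerates all attainable heterozygote counts; the two-sided P-value is the
total conditional probability of heterozygote counts no more probable than
the observed one, capped at 1. It is conventionally computed on controls
and is reported, not used as an exclusion filter (the filtering threshold
is the caller's choice).

**Genotype tables.** The Fisher–Freeman–Halton test enumerates all 2×3
tables with the observed margins and sums the probabilities of tables no
more probable than the observed one ("probability ordering"). Because this
comparison is made between floating-point numbers, a table is counted as
"no more probable" when its probability is within relative `1e-7` of the
observed table's — a tie tolerance that makes the two-sided rule stable
against rounding noise. The Pearson 2-df chi-square is provided as an
alternative; the two agree to printed precision on dense tables and differ
exactly where cells are sparse, which is why the exact test is the default
for screening. Enumeration is vectorised over the two free cells of the
first row and uses `lgamma`, so the cost is quadratic in the margins and
negligible even for tables with thousands of subjects.

## Logistic modelling conventions

Odds ratios come from binomial GLMs fitted by IRLS (`stats::glm.fit`
behind the `fitLogistic()` surface) with a strict convergence tolerance
(`1e-10`, 100 iterations) and two explicit failure modes: non-convergence,
and quasi-complete separation flagged when any non-intercept coefficient
passes |β| > 15 — at that point the Wald machinery is meaningless and the
error names the offending predictor. Confidence intervals are Wald,
`exp(β ± 1.96·se)`, matching the 95% convention of the reference tables;
profile-likelihood intervals are deliberately not used. Genetic codings
expand as: additive (0/1/2 dosage), dominant (carrier indicator),
recessive (minor-homozygote indicator), genotype (two indicators against
the major-homozygote reference). The standard covariate set is age
(continuous), menarche (two indicators, late as reference), menopausal
status (post vs pre) and first live birth (late vs early); every model is
complete-case on its own variables, so denominators shrink per analysis
rather than being imputed.

The stage-2 confirmation rule is: same risk-allele direction in the
validation set (crude allelic OR with a 0.5 continuity correction, so a
zero cell cannot produce an infinite estimate) *and* combined-set exact
P < α. This is the weakest direction-plus-significance reading of
"consistent association" and is the package's fixed convention.

## Cumulative risk models

The counting model adds risk-allele dosages (0–10 over five markers) and,
for the factor version, one point for early menarche and one for late
first birth; an ordinal three-level menarche contribution (2/1/0) sits
behind the `menarche_ordinal` flag because the integer contribution of a
three-level factor to a count is genuinely ambiguous — the binary coding
is the default since it reproduces the conventional bin structure
(0–1, …, ≥ 6 alleles shifting to 0–2, …, ≥ 7 factors, an upward shift of
at most 2).

The weighted score is the linear predictor of the multiplicative model:
per-SNP weights are logs of the combined-set adjusted additive ORs, and
clinical weights are logs of the adjusted category ORs from one logistic
model on the combined set. Quartile grouping uses the linear-interpolation
percentile definition (R's type 7) of the *control* score distribution,
with boundary values assigned upward; both choices are arbitrary where the
convention is unstated, and are fixed for reproducibility. When the score
already contains the clinical factors, the grouped-OR adjustment defaults
to age and menopause only, to avoid adjusting for a variable that is part
of the exposure; passing the full covariate set forces the alternative.

## Absolute risk

The modified Gail chain is: per-allele OR → genotype relative risks
`(1, OR, OR²)` (multiplicative within locus) → risks relative to the
population, `r = rr / Σ f·rr`, using pooled *control* genotype and
category frequencies as the population stand-in (a case-control sample has
nothing closer; external frequencies can be supplied) → combined relative
risk by multiplication across the five SNPs and two factors (independence
across factors is assumed, consistent with the generator's linkage
equilibrium) → projection with piecewise-constant hazards and competing
mortality:

$$AR = \sum_j S_j \, \frac{r h_{1j}}{r h_{1j} + h_{2j}}
       \left(1 - e^{-(r h_{1j} + h_{2j})\Delta_j}\right),
\qquad S_j = \prod_{i<j} e^{-(r h_{1i} + h_{2i})\Delta_i}.$$

Because every factor table satisfies `Σ f·r = 1` (asserted to `1e-10`), the
population-average projected hazard already equals the schedule's
incidence, and no additional attributable-risk deflation is applied — that
is the self-consistent reading of "risk relative to the population".
The relative risk is age-constant (no age interaction is modelled), and
the projection span is a fixed 20–85 years for every subject, i.e. a
65-year risk; a per-subject `age_start` is available for residual-risk
projections.

The bundled hazard schedule is **synthetic**: real registry incidence and
competing-mortality rates are an external input
(`readHazardSchedule()`, per-100,000 units divided by `1e5`). The default
is shaped like an urban East-Asian female breast-cancer incidence curve
(rising to a plateau around age 50) with exponentially increasing
competing mortality, scaled so the population-average 65-year risk is
about 0.07 — a deliberately realistic order of magnitude, not a fit to any
registry. Consequently all absolute-risk checks in the tests are
analytic (closed form vs ODE integration to `1e-8`, monotonicity in `r`
and in competing mortality, the first-order small-hazard limit) or
pattern-based (medians rising across allele-count bins), never comparisons
against published absolute-risk numbers, which depend on the unpublished
registry schedule and individual data.

## Discrimination

AUC is the Mann–Whitney statistic computed from midranks (ties count
half), with DeLong's placement-value variance; the paired test uses the
placement covariance, and a zero variance of the difference (identical
rankings) returns P = 1 with a warning rather than 0/0. Operating points
maximise Youden's J under the rule "positive when score ≥ cutoff", ties
broken toward higher specificity; Youden is an assumption — the
sensitivity/specificity convention behind published operating points is
often unstated. Cross-validation is stratified by case status and reports
one AUC on the pooled held-out scores (lower-variance than averaging
per-fold AUCs, and it matches the single-number reporting convention);
fold assignments that lose a class are re-randomised, at most 10 times.

## The synthetic-data generator

`defaultSimulationConfig()` *is* the emulated study: five independent
markers in HWE at control MAFs (0.12, 0.40, 0.26, 0.34, 0.31) with
combined-set additive ORs (1.25, 1.14, 1.08, 1.33, 1.27); menarche and
first-birth categories at the published combined control frequencies with
crude cross-product ORs derived from the published combined counts (early
menarche 3.118 and normal 1.622 vs late; late first birth 1.868 vs early
— the adjusted values are not published, so the crude ratios are the
defensible default and are config-overridable); stage sizes 878/900 and
914/967. Disease status is drawn from a logistic model — chosen over a
log-linear one because the estimation targets are odds ratios, and at low
prevalence ORs approximate RRs, consistent with the multiplicative
absolute-risk combination. The intercept is solved by bisection so the
marginal prevalence hits its target within `1e-6`; the baseline prevalence
defaults to 0.05, a documented knob with no published counterpart. Age is
drawn from a truncated normal resembling the control distribution and
menopause from an age threshold; neither enters the disease model, because
the emulated design age-matched its controls. Every stochastic operation
takes an explicit seed; there is no hidden global state.

What the generator does *not* emulate: linkage disequilibrium between
markers (the emulated panel was selected for low LD, r² < 0.8),
genotyping error beyond independent missingness, correlation between
clinical factors and age, family history, and age-dependent incidence of
case status (ascertainment is cross-sectional). Passing tests on this
generator therefore establish internal consistency — parameter recovery,
correct null behaviour, the published orderings of model performance —
not concordance with any individual-level dataset.

## Problem sizes and runtime choices

The test suite and acceptance script size their simulations to make
Monte-Carlo error small relative to the tolerance being asserted while
keeping a laptop-scale runtime: 200,000 subjects for AUC and
effect-recovery point checks (AUC standard error ≈ 0.003 at 5%
prevalence), 200 replicates of the full sampled study (1,792 cases /
1,867 controls from populations of 40,000) for CI-coverage checks
(binomial SE on 1,000 coverage indicators ≈ 0.7%), 30,000 subjects for
cross-validation sanity, and exhaustive enumeration up to table totals of
12 (with randomised spot checks to 40) for the exact-test oracles.

## Known limitations

Wald intervals misbehave with very sparse genotype cells (the package
raises separation errors rather than reporting meaningless CIs); the FFH
implementation is specialised to 2- and 3-column tables (the genotype and
category structures of this design) and does not scale to wider tables;
no multiple-testing correction is applied across the panel (the emulated
design applied none — its guard against false positives is the two-stage
replication itself); the absolute-risk model has a single competing
"other mortality" stream and no calendar or cohort effects; and the VCF
reader handles biallelic records and the GT field only. The command-line
surface is intentionally thin: the exported functions, `runPipeline()`
with a YAML config, and this vignette are the interface.
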