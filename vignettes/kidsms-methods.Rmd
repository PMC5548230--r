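---
title: "Scoring, evaluation and cohort-reconstruction methods in kidsms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, evaluation and cohort-reconstruction methods in kidsms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kidsms)
```

## The two rule systems

`kidsms` implements two deterministic clinical rule systems over a shared
patient-visit data model.

**Ghent-2** (the revised Ghent nosology) is the reference standard for
diagnosing Marfan syndrome. Its systemic score awards weighted points to
16 checklist items (maximum 20) and calls systemic involvement at ≥ 7
points. A confirmed diagnosis requires one of six conjunctions:
aortic dilatation/dissection together with ectopia lentis, systemic
involvement, or an FBN1 mutation; or family history together with aortic
dilatation/dissection, ectopia lentis, or systemic involvement.

**Kid-SMS** is a pediatric pre-test probability stratifier over seven
resolved features — SV dilatation, EL, MVP, TVP, PA dilatation, family
history, and "≥ 3 skeletal features" — with eight rules in three ordered
risk bands (very high > high > moderate). A record matching no rule is
negative. The engine records *every* matched rule; the dominated
moderate rules (FH alone, SV alone) are kept because follow-up
recommendations attach to them. The *primary profile* used to partition
a cohort into one row per patient is the first matched rule in published
row order, so a patient with both FH and isolated SV reports FH.

### Exclusivity assumptions in the 20-point checklist

The printed checklist sums to 22 if every row is counted independently,
yet its stated maximum is 20. Two exclusive pairs reconcile this, and we
adopt them as the scoring rule:

* *pectus carinatum* (2) suppresses *pectus excavatum / chest
  asymmetry* (1) — they describe the same anterior chest wall;
* *hindfoot deformity* (2) suppresses *plain pes planus* (1) — "plain"
  flatfoot is the lesser finding of the same region.

With these, and wrist/thumb contributing exactly one of {0, 1, 3}
(both signs 3, exactly one sign 1, never 4), the maximum reachable total
is exactly 20, and awarding is monotone: setting any single item true
never lowers the total (e.g. adding hindfoot deformity to pes planus
changes 1 → 2). Both properties are verified exhaustively over all
2^16 item vectors against an independent brute-force oracle.

### Counting skeletal features

The Kid-SMS "3 skeletal features" criterion counts *distinct present
items* of the 11-item skeletal subset, not Ghent points: wrist + thumb
sign is two features even though it scores three points. Counting points
would make one sign-pair equal three features, which contradicts the
plain reading of "features".

## Absent is not negative

Clinical features that were not assessed are represented as `NA`
("absent") and make every dependent score *uncomputable* — the engines
raise an error naming the field and row rather than assuming the finding
is negative. Silently defaulting missing data to "no finding" would
inflate apparent specificity and corrupt sensitivity estimates in
validation settings, which is precisely where this package is meant to
be used. The CSV serialization preserves the distinction
(`"true"`/`"false"`/empty cell), and round-trip identity is tested
field-for-field. `fbn1_status` is a three-level enum: `not_tested` is
legitimate (genetics are done only when warranted) and *disables* rather
than fails the FBN1 pathway.

## Nomograms and dilatation

Vessel dilatation is resolved per record: a direct `sv_dilated` /
`pa_dilated` flag always wins and the nomogram is then never consulted
(a contract tested with a deliberately poisoned nomogram); otherwise the
Z-score `(observed − expected(BSA)) / SD` is computed from the recorded
diameter and body-surface area, and dilatation is called at `z ≥ 2.0`
(inclusive; configurable). The threshold follows the convention of the
revised Ghent criteria.

Nomogram coefficient sets are configuration, not doctrine. The bundled
SV default is the classical pediatric aortic-root regression of Roman
and colleagues (expected diameter 1.02 + 0.98·BSA cm, residual SD
0.18 cm, admissible BSA 0.2–2.0 m²). Pediatric PA references vary in
parameterization, so the bundled PA default (`pa_synthetic_linear`) is
an explicitly *synthetic* example set; real analyses should load their
preferred reference via `read_nomogram()` (a small YAML schema) or
`nomogram()`. BSA from height/weight is available via the Mosteller and
Du Bois formulas, chosen explicitly, never defaulted silently.

## Diagnostic-performance machinery

* **Confidence intervals** are exact Clopper–Pearson, from beta
  quantiles; for `x = n` the lower bound has the closed form
  `(α/2)^(1/n)`. The choice reproduces, after rounding, every published
  interval of the validation analysis the fixture reconstructs
  (e.g. 24/24 → 0.86, 63/63 → 0.94, 24/43 → 0.40–0.71, 63/82 →
  0.66–0.85), and is cross-checked against `binom.test`. Coverage at
  nominal level is verified by simulation (n = 50, p ∈ {0.05, 0.5,
  0.95}, 10,000 replicates).
* **Fisher's exact test** uses the probability-ordering two-sided
  convention (sum the probabilities of all fixed-margin tables no more
  likely than the observed, with a 1e-7 relative tie tolerance — the
  common software convention; conventions differ, so this is stated).
  It is verified against `stats::fisher.test` and, exhaustively for all
  2×2 tables with total ≤ 30, against a brute-force fixed-margins
  enumerator.
* **Likelihood ratio**: `LR+ = sens/(1 − spec)`, reported as infinite
  at specificity 1. Statistics whose margin is empty are flagged
  undefined rather than propagated as NaN.
* **Rounding** is a property of *printing* only (whole percents,
  2-decimal CI bounds, 1-decimal LR); internal values are never
  pre-rounded, and the key-value report writes unrounded values.
* The unpaired t test offered for quantitative cohort summaries is a
  thin, clearly-labeled wrapper over the classical equal-variance
  `t.test`; it is a reporting convenience, not part of the scoring or
  evaluation contracts.

## Survival comparison

`km_estimate()` is the product-limit estimator with events processed
before censorings at tied times; `logrank_test()` is the standard
unweighted two-sample log-rank (1 df). Both are deliberately small,
direct implementations whose contracts (error on event-free series,
curve export as a plain table) are part of the module surface; the
`survival` package serves as an independent oracle in the tests, never
as the implementation, so the two routes stay distinct. Patients who
never reach an endpoint are censored at age at last visit. One caveat is
inherited from the design being mirrored: the stratification and
diagnosis endpoints are observed on the *same* children, so the
two-sample log-rank treats as independent what is really paired; we
implement the unpaired comparison as described and note the caveat here.

## The synthetic cohort

`fixture_cohort()` deterministically reconstructs a 106-patient
validation cohort from published aggregate counts; no individual-level
data exist for it, so every record is a *minimal realization*: exactly
the manifestations its risk profile requires, plus the minimum extras
that force its assigned Ghent-2 status (e.g. a confirmed SV + 3Skel
patient carries wrist + thumb + pectus carinatum + hindfoot = 7 points;
an unconfirmed one carries three 1-point skeletal items). Construction
is asserted internally: 106 records, 27 eventual diagnoses, 5
FBN1-positive children without diagnosis.

**Reconciling the published counts.** The aggregates this fixture
realizes are not mutually consistent as printed: the follow-up fourfold
table has 24 reference-positive children, while the profile-by-outcome
table's diagnosed column sums to 27, and the accompanying narrative
variously says three or four children were diagnosed during follow-up.
The fixture resolves this in favor of the fourfold tables, which anchor
the headline statistics: computed Ghent-2 status is positive for 21
children at baseline and 24 at follow-up (three conversions, each
already stratified at risk at baseline), and a fixture-only `mfs_final`
column marks three further children (one FH-moderate, two SV-moderate)
as diagnosed after the follow-up evaluation, bringing the outcome
column to 27. The profile-by-outcome summary (`table5_summary()`)
therefore crosses *computed* Kid-SMS profiles with the *stored* final
outcome. The "FBN1-negative" outcome column means "not FBN1-positive":
most of those children were never tested, consistent with
genetics-when-warranted practice.

**Ages** are placed deterministically at bin representatives (0.5, 3.5,
9.5, 15.5, 19 years) hitting the presentation-age bin counts 2/14/33/
53/4; within-bin placement is unknowable from aggregates, so the printed
cohort mean age is deliberately not a target. Assignment is clinically
motivated: children screened early because of family history or isolated
findings occupy the young bins, diagnosed children center in the
school-age bin — which is also why the fixture demonstrates the reported
ordering (mean stratification age < mean diagnosis age) without tuning.
The follow-up visit is placed 2 years after baseline, matching a
2.5-year enrollment window; the sex split is 39 female / 67 male.

**What passing tests show — and don't.** The fixture proves the engines
reproduce the published cross-tabulations and statistics *given* the
published aggregates. It cannot validate Kid-SMS on real children: real
cohorts have correlated manifestations, measurement error in Z-scores,
incomplete assessments and age-dependent penetrance, none of which the
minimal realizations emulate. `random_cohort()` likewise samples
profiles i.i.d. with uniform ages within bins — adequate for property
testing (seed-determinism, distributional correctness by chi-square
goodness-of-fit at n = 10,000, monotonicity, very-high ⇒ Ghent-2), not
for epidemiological simulation.

## Numerical and design choices

* Dilatation threshold inclusive at `z = 2.0`; Kid-SMS uses SV
  *dilatation* only — aortic dissection enters Ghent-2's aorta
  criterion but not Kid-SMS.
* Kid-SMS positivity cutoff for evaluation defaults to *moderate* (the
  score counts as positive as soon as any risk is stratified), matching
  the validation design; configurable in `run_config()`.
* One integer seed governs an entire `random_cohort()` draw through a
  private RNG stream; the global RNG state is untouched.
* Problem sizes in the test suite (exhaustive 2^16 and 2^7 sweeps,
  exhaustive Fisher tables to total 30, 10,000-replicate coverage and
  2,000-replicate log-rank null simulations) were chosen as the smallest
  sizes that make the respective guarantees exhaustive or statistically
  sharp.
* Exit codes of the `exec/kidsms` entry point: 0 success, 1
  usage/config error, 2 data error; logs to stderr, results to files.

## Known limitations

* The fixture's per-record phenotypes are one of many minimal
  realizations consistent with the published aggregates; quantities not
  pinned by those aggregates (exact ages, which specific systemic items
  a child carried) are conventions, not estimates.
* The full adult Ghent-2 decision tree beyond the printed pathway list
  (e.g. Z-threshold stratification by age ≥ 20, MASS-phenotype
  differentials) is out of scope, as is any re-validation of published
  nomogram coefficients.
* The log-rank comparison of paired endpoints is anti-conservative in
  principle; it is provided because it mirrors the validation design,
  with this caveat attached.
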