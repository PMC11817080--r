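---
title: "Methods: stratified pre-conception diagnosis associations with preterm birth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified pre-conception diagnosis associations with preterm birth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ptbphewas)
```

## The problem

Preterm birth (PTB, delivery before 37 completed gestational weeks) has
heterogeneous origins: part of the burden is *medically indicated* — a
clinician initiates early delivery because of maternal or fetal risk — and
part is *spontaneous* (spontaneous labor or membrane rupture, including
PPROM). Risk factors differ sharply between the two, and analyses that pool
them are dominated by the indicated component. `ptbphewas` implements a
phenome-wide association (PheWAS) pipeline that tests every pre-conception
diagnosis, coded as a phecode, for association with preterm delivery in
three arms — indicated vs. term, spontaneous vs. term, and all-PTB vs. term
— together with a synthetic EHR generator that reproduces the statistical
structure such cohorts exhibit, so the whole pipeline can be evaluated
against known ground truth.

## From billing codes to exposures

Diagnosis events enter as dated ICD-9-CM/ICD-10-CM codes. Each code is
mapped to a phecode (a curated grouping of ICD codes into clinically
meaningful phenotypes) and truncated after the first decimal digit, which
coarsens phenotypes to subgroup granularity — "250.21" and "250.23" both
become "250.2". Unmappable codes are dropped (and counted): they fall
outside the tested phenotype universe by design. Events are de-duplicated
at (person, phecode, date) granularity; exposure is later binarized per
pregnancy, so a chronic condition billed at every visit counts once.

The package bundles a small hand-built synthetic map for self-contained use
and also reads community-style map layouts (an `icd9`/`icd10` column plus
`phecode`).

## Pregnancies, outcomes, windows

The start of pregnancy is the delivery date minus the gestational age,
with weeks converted to whole days by rounding (no sub-day convention
exists in routine obstetric data).

Each curated delivery carries a PTB status label. Classification combines
the label with gestational age (GA), term threshold 37 weeks:

| GA < 37 | label | outcome |
|---|---|---|
| yes | medically indicated / termination-iatrogenic | indicated PTB |
| yes | spontaneous / PPROM / PTL with TOCO and TERM | spontaneous PTB |
| yes | "No" | unclassified PTB |
| no | "No" | term |
| no | any preterm-type label | dropped (GA/status mismatch) |

Unclassified PTBs are kept and pooled into the all-PTB arm by default
(`include_unclassified_in_all_ptb`); they belong to neither stratified arm.

Selection excludes, in a fixed tallied order: duplicate delivery records,
non-singleton deliveries, missing GA, missing delivery date,
GA/status mismatches, and — unless the sensitivity toggle
`require_prior_diagnosis = FALSE` is used — pregnancies with no windowed
pre-conception diagnosis.

Exposure windows are half-open intervals ending at conception. For a
person's first recorded pregnancy the window opens at the start of record;
for each later pregnancy it opens `postpartum_exclusion_days` after the
previous delivery. "Six months" is fixed at 183 days: month arithmetic is
calendar-dependent, a day count is deterministic and testable. An event on
the conception date is excluded; an event exactly 183 days after the
previous delivery is included. A pregnancy conceived before its
predecessor's delivery (a data error) gets an empty window and a warning.

## The association model

For each phecode with at least one carrier in an arm, the package fits

$$\operatorname{logit} P(\text{case}) = \beta_0 + \beta_1 x
  + f(\text{age}) + \gamma^\top \text{edu} + \delta^\top \text{ins}$$

where $x$ is binary phecode presence. The reported effect is the adjusted
odds ratio $e^{\beta_1}$ with the 95% Wald interval
$e^{\beta_1 \pm 1.96\,\mathrm{SE}}$ and a two-sided Wald p-value, matching
default GLM reporting; intervals are not adjusted for multiplicity.

Covariate choices:

* **Maternal age** enters through a natural cubic spline basis with 4
  degrees of freedom (knots at quantiles), the standard GLM-compatible
  realization of a smooth age effect inside a linear predictor. The df is
  configurable (`spline_df`). Records missing age (rare in curated delivery
  data) are excluded from regression with a warning — a spline cannot
  absorb a categorical "unknown".
* **Education** (`<12`, `12`, `>12` years) and **insurance**
  (private/non-private) are dummy-coded with explicit `unknown` levels, so
  missingness is a category rather than a dropped record. Reference levels
  are the modal categories (`>12` years, private); this choice affects only
  covariate coefficients, not the exposure OR.
* `use_covariates = FALSE` reduces every model to intercept + presence,
  whose MLE is the closed-form 2×2 cross-product odds ratio — this identity
  is the package's primary numerical oracle.

Fitting goes through iteratively reweighted least squares
(`stats::glm.fit`, convergence tightened to 1e-10) with each per-phecode
fit warm-started from the arm's covariate-only model; results are identical
to cold fits up to convergence tolerance, which the test suite verifies
against the `stats::glm` formula interface.

### Degenerate fits

A zero cell in the phecode × outcome 2×2 table means the ML odds ratio is
undefined (complete separation), so no model is fitted: the result is
flagged, its OR/CI reported as `NA`, and it contributes p = 1 to the arm's
multiplicity correction. Quasi-separation and non-convergence (|log OR| >
15, SE > 1000, or IRLS failure) share the same pathway: the Wald statistic
of such a fit is numerically meaningless and must not outrank valid tests.
Flagged results stay in output tables but are barred from significance.

## Multiplicity and stability

Raw p-values are adjusted per arm with the Benjamini–Hochberg step-up
procedure, with m equal to the number of tested phecodes in the arm.
Significance requires adjusted p strictly below `fdr_alpha` (default 0.05)
and a defined OR; significant-but-undefined results are logged separately.

Because many phecodes are rare, each significant association then passes a
leave-one-carrier-out stability filter (a jackknife-style check): up to
`robustness_iterations` (default 50) refits, each removing one carrier
pregnancy — case or control, chosen uniformly without replacement under the
run seed; when a phecode has fewer carriers than iterations, every carrier
is removed in exactly one iteration, with no padding. Each iteration
replaces only that phecode's p-value in the arm's p-vector and recomputes
BH (refitting all other phecodes' models would change nothing material:
removing one carrier of the tested phecode perturbs other tests only
through a one-row change in the shared control pool). An association is
*robust* only if every iteration stays significant with a defined OR; final
tables report the robustness percentage. The filter is applied to every
significant phecode, not only rare ones — uniform application is simpler
and conservative.

## The synthetic EHR generator

`simulate_cohort()` is first-class, tested code, not a fixture. Its
defaults encode the cohort conditions the pipeline targets:

* ~1.12 pregnancies per person (one with probability 0.88, two with 0.12);
  inter-pregnancy gaps uniform 270–1100 days, so subsequent-pregnancy
  windows are never empty and the generator and the windowing filter agree
  exactly on the interval algebra (a cross-module test asserts every
  generated event falls in exactly one admissible window).
* Baseline outcome mix 91% term / 4.2% spontaneous / 3.9% indicated / 0.9%
  unclassified at zero linear predictor.
* A phecode universe of 300 codes with a two-stratum log-uniform prevalence
  spectrum on [5e-4, 0.08]: 87% of codes drawn below 1% prevalence,
  reproducing the rare-dominated diagnosis frequency distribution of EHR
  cohorts (a single log-uniform over that range would put only ~59% of
  codes below 1%, far less skewed than real diagnosis spectra).
* Covariates: maternal age truncated-normal (mean 34.4, SD 4.92, range
  14–55); education mostly college-level with 7.9% missing; ~93% private
  insurance with 0.4% missing. Covariate → outcome effects default to zero
  (they are a config hook, `covariate_outcome_effects`).
* Diagnosis dates fall off exponentially before conception (mean 1.6
  years), truncated to the admissible window; record length before first
  conception is exponential (mean 2 years, capped at 21.7).

Outcomes are drawn from a four-class multinomial logit with term as
reference, adding each carried phecode's planted per-arm log-OR to the
spontaneous and indicated linear predictors. This construction is chosen
deliberately: conditioned on {arm class, term}, the multinomial logit
reduces exactly to the binary logistic model the pipeline fits, so planted
ORs are conditional effects recoverable without noncollapsibility bias —
which is what makes CI-coverage experiments well-defined.

Gestational age is uniform 37–41 weeks for term and 24–36.9 for preterm
classes; status labels are emitted consistently with the outcome class
(spontaneous outcomes draw among the three spontaneous-type labels,
indicated among the two indicated-type labels, unclassified preterm carries
label "No").

The preset `headline_effects()` plants analogs of essential hypertension
(5% prevalence, indicated OR 6, spontaneous OR 1.5), type 1 diabetes (1%,
OR 11) and type 2 diabetes (2%, OR 6) with no spontaneous effect for the
diabetes analogs — the canonical stratified contrast: strong indicated
signals, a sub-threshold spontaneous one.

**What the generator does not emulate:** correlated comorbidity structure
(exposures are independent across phecodes and pregnancies), diagnosis-code
drift over calendar time, within-person chronic-condition persistence
across pregnancies, confounding (covariates are independent of exposures),
and informative missingness. Passing recovery tests therefore demonstrates
the pipeline's statistical machinery, not robustness to those real-data
complications.

## Problem sizes and numerical choices

The test-suite experiments use sizes at which their properties are
meaningful while staying desk-scale: null-calibration cohorts of 5,000
persons × 300 phecodes over 20 seeds; CI-coverage at 10,000 persons over 50
replicates; headline-pattern replication at 9,500 persons (~10.6k
deliveries, the cohort scale the preset emulates) over 20 seeds. The
spontaneous-arm planted effect (OR 1.5 at ~470 cases against a BH threshold
over 300 tests) is deliberately borderline: it can reach the final table in
occasional seeds, so the "spontaneous arm stays empty" pattern is a
strong-majority property, not a certainty — exactly the behavior expected
of an underpowered true effect under FDR control with a stability filter.

Other fixed numerical choices: Wald p-values are clamped at the smallest
positive double (extreme z underflows to zero, and BH requires p > 0);
phecode ordering is numeric-then-lexical for deterministic output; BH uses
`stats::p.adjust`; weeks-to-days conversion rounds half to even (R's
`round`); the RNG is touched only inside seeded scopes, so simulation calls
leave the caller's RNG stream unchanged.

## Known limitations

* Repeated pregnancies from the same person are analysed as independent
  units (as in the source design); no within-person clustering adjustment.
* Wald intervals misbehave near separation; the flagging heuristics
  (|log OR| > 15, SE > 1000) are pragmatic cutoffs, not likelihood-based
  tests. Profile-likelihood or Firth fits are out of scope.
* The robustness filter's BH recomputation holds other phecodes' p-values
  fixed; the neglected control-pool perturbation is negligible at cohort
  scale but not exactly zero.
* Phecode → organ-system categories cover only the bundled map's codes.
* Race is summarised descriptively but is not a model covariate.
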