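---
title: "Surgical triage of highly myopic cataract: the rule engine and its evaluation framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surgical triage of highly myopic cataract: the rule engine and its evaluation framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyetriage)
library(dplyr)
```

## The clinical problem

Cataract surgery in highly myopic eyes — operationalised here as axial
length (AL) above 26.0 mm — is harder to plan than in ordinary cataract,
because the lens opacity usually coexists with macular pathology
(epiretinal traction, macular retinoschisis, lamellar and macular holes,
foveal retinal detachment, choroidal neovascularization). The clinically
useful output is not a cataract grade but a four-way triage:

| Category | Recommendation |
|---|---|
| 0 | surgery not advised |
| 1 | cataract surgery recommended |
| 2 | retinal surgery recommended |
| 3 | combined cataract–retinal surgery recommended |

`eyetriage` packages three things: (i) a configurable five-step rule
engine that maps one eye's record to one of these categories, (ii) the
evaluation battery used to compare automated graders and human raters
against a gold standard, and (iii) a seeded synthetic-cohort generator so
the entire pipeline is testable without clinical data.

## Input scales

**Visual acuity.** All computations run in logMAR. Snellen fractions are
converted as $\log_{10}(\text{den}/\text{num})$ and rounded to two
decimals by default, so 6/12 is 0.30 (the conventional reporting value)
rather than 0.30103; `rounding = NULL` gives the raw value. The
off-chart categorical acuities use the standard code table: counting
fingers 1.9, hand motion 2.3, light perception 2.7, no light perception
3.0. Eyes are dichotomised at 0.30 logMAR into *good* (< 0.30) and
*poor* (>= 0.30) vision; the boundary is assigned to the poor group,
matching how the grouping is labelled wherever it is reported with an
inequality sign ("$\ge 0.30$").

**Lens grades.** LOCS III: nuclear 1.0–6.0, cortical and posterior
subcapsular 1.0–5.0, at 0.1 resolution. A cataract is *surgically
significant* when the nuclear **or** cortical grade strictly exceeds 3.5;
3.5 exactly is not an indication. PSC grades are carried in the data model
but excluded from the grading evaluation battery.

## The five-step rule engine

`decide()` evaluates at most five steps, in a fixed order; the trace
column records which steps fired for each eye.

1. **Preoperative VA.** Good preoperative vision with no surgically
   mapped OCT finding ends the evaluation: category 0.
2. **Predicted improvement.** The predicted gain, preop minus predicted
   postoperative logMAR, is flagged *meaningful* at >= 0.20 logMAR.
3. **Cataract grading.** The > 3.5 indication above, computed from
   either the automated (`ai`) or the gold grades.
4. **OCT.** Any finding mapped to retinal surgery gives category 3 when
   the cataract is also significant, else category 2.
5. **Axial length.** A significant cataract gives category 1 when the
   gain is meaningful; without meaningful gain, surgery is still offered
   below the 30.0 mm caution threshold but withheld (category 0) in the
   extreme-AL eyes, where the expected benefit is least and the surgical
   risk highest. A non-significant cataract gives category 0.

The published description of this workflow fixes the skeleton — the step
order, the four categories, the > 3.5 grade rule, and the 0.30 logMAR
convention — but not the inner branch predicates, so the engine's default
table is this package's own reconstruction. That is why **every** branch
constant is exposed in `decision_config()`: the step-1 VA gate, the
improvement threshold (0.20 logMAR ~ two Snellen lines, a conventional
"clinically meaningful gain"), the grade threshold, the AL caution
threshold, and the finding-by-finding OCT map (CNV defaults to `none`
because it is usually managed intravitreally, not surgically). None of the
defaults introduced here should be attributed to any specific clinical
source; re-specify them freely:

```{r}
decision_config(grade_threshold = 3.0,
                oct_surgical_map = c(oct_default_map(), cnv = "retinal_surgery"))
```

Structural guarantees, enforced by tests: the engine is total and
deterministic over valid records; raising a grade can never demote an eye
from category 1 to 0; adding a retinal-surgical OCT finding always lands
in {2, 3}; an eye short-circuited at step 1 never needs the VA
prediction, and an eye that does need it fails loudly if the prediction
is missing.

## The evaluation battery

**Grading** (`grading_eval()`, per subtype): Re1.0, the percentage of
absolute AI-vs-gold grade differences <= 1.0 (closed boundary);
ICC(2,1) — two-way random effects, absolute agreement, single measure —
computed from the mean-squares decomposition, chosen because the
AI-versus-gold question is about absolute interchangeability, not mere
consistency (a rater with a constant offset should be penalised); and,
after binarising both graders at the surgical threshold, accuracy /
sensitivity / specificity plus the AUC of the continuous predicted grade
against the gold indication. AUC uses the Mann–Whitney tie convention
(ties count 1/2) and DeLong variance for its confidence interval;
`delong_test()` compares two correlated AUCs measured on the same eyes.
ROC/AUC/DeLong computations are delegated to **pROC**, the standard tool
for this job; the test suite checks them against an exhaustive
pairwise-concordance oracle and a stratified bootstrap.

**VA prediction** (`va_eval()`): MAE, RMSE (always >= MAE, by Jensen),
the share of predictions within ±0.30 logMAR (closed band, with a 1e-9
guard against binary-representation artefacts at the boundary), and
good/poor group sensitivity (denominator: actual group size) and
precision (denominator: predicted group size). An empty denominator
yields `NA`, never a silent zero.

**Agreement** (`cohen_kappa()`, `kappa_from_marginals()`): unweighted
Cohen's kappa on the fixed 4x4 table (rows gold, columns comparator,
categories 0–3). Kappa depends on the table only through its marginals
and diagonal, so published per-category counts plus an agreement count
reconstruct it exactly — `kappa_from_marginals()` does precisely that,
and the property is tested over random tables. Reported kappas are
rounded half-up to 3 decimals (`kappa_reported`); the raw value is kept.
The *special-case* subset — eyes whose gold decision is 0, 2 or 3, i.e.
everything except plain cataract surgery — gets the same statistics on
the full 4-category table (a comparator may still answer 1). Weighted
kappa variants are deliberately out of scope: the reconstruction
evidence supports the unweighted form, and offering near-equivalent
statistics invites accidental misuse.

```{r}
kappa_from_marginals(gold_counts = c(1, 95, 5, 6),
                     comparator_counts = c(1, 96, 2, 8),
                     agree = 103, n = 107)
```

## The synthetic-cohort generator

No per-eye clinical data are distributable, so `simulate_cohort()`
generates cohorts with the statistical structure the evaluation assumes.
Defaults (fixed once, as the package's study conditions):

- **Prevalence** proportional to the internal gold decision marginals
  (1, 95, 5, 6)/107 — triage of a cataract-clinic population is heavily
  dominated by category 1.
- **Gold grades** consistent with the category: cataract-surgical
  categories (1, 3) draw nuclear grades on (3.6, 5.5); the others keep
  both nuclear and cortical at <= 3.5 (grid 0.1).
- **Automated grades** = gold + Gaussian error rounded to the 0.1 LOCS
  step and clipped to the scale. The sigmas invert the published
  operating points Re1.0 = 99.07% (nuclear) and 88.79% (cortical)
  through `calibrate_sigma_re10()`, which solves
  $P(|\mathrm{round}_{0.1}(N(0,\sigma))| \le 1.0) = p$ by bisection
  (note the 1.05 half-step boundary induced by rounding). Clipping at the
  scale ends shrinks errors and biases empirical Re1.0 upward near the
  boundaries; calibration checks therefore restrict to gold grades at
  least 1.05 from both scale ends, where clipping cannot occur.
- **VA prediction error**: predicted = actual + $N(0, \sigma_p)$ with
  $\sigma_p = 0.156\sqrt{\pi/2} \approx 0.1955$ logMAR, so the expected
  MAE is the published internal value 0.156 ($E|N(0,\sigma)| =
  \sigma\sqrt{2/\pi}$).
- **Preoperative/actual postoperative VA** by category: category 0 eyes
  see well preoperatively; cataract-only eyes recover to < 0.30; eyes
  with retinal pathology (2, 3) recover onto (0.30, 1.00) — retinal
  disease caps the benefit.
- **OCT findings**: categories 2/3 draw one surgically mapped finding;
  the rest are mostly `none` with occasional `cnv`.
- **Axial length**: truncated normal, mean 28.5, sd 1.5, strictly above
  26.0 mm — a realistic spread for an AL > 26 mm cohort.
- **Rater decisions**: drawn independently per eye from a per-rater
  row-stochastic 4x4 confusion matrix conditioned on the gold category.
  The default `ai` matrix is a labelled stand-in (true rater-by-gold
  cross-tabulations are not identifiable from marginal summaries):
  near-perfect on category 1, noisier on the special categories.
  Conditional independence given the gold class is the simplest model
  satisfying marginal/kappa calibration; there is no shared eye-difficulty
  random effect, so rater-rater correlation beyond class is not emulated.

One global seed drives named substreams (per field), so cohorts are
byte-reproducible and adding a field never perturbs existing draws.

```{r}
cohort <- simulate_cohort(sim_config(n = 200, seed = 7))
count(cohort, decision_gold)
run_report(cohort)
```

What passing tests on these cohorts shows — and what it does not: the
generator emulates the *marginal* calibration targets (grading error,
VA-prediction error, decision prevalences, per-rater confusion) and the
*deterministic* couplings the rule engine relies on (grades vs category,
OCT vs category). It does not emulate the joint distribution of grades,
acuity and pathology in any real clinic, image-level variability, or
between-site shifts (the kind that degrade external-site performance),
so green tests certify the arithmetic and the engine's logic, not
clinical transportability.

## Numerical choices and degenerate inputs

- Closed comparison boundaries throughout (error <= 1.0 grade,
  |error| <= 0.30 logMAR), each with a 1e-9 absolute guard because 0.1
  and 0.3 are not representable in binary floating point.
- Undefined statistics are explicit `NA`s with a diagnostic where
  useful: sensitivity with no actual positives, ICC below 3 pairs or at
  zero variance, kappa when both raters are constant ($p_e = 1$), the
  DeLong p-value at zero variance with unequal AUCs (identical scores,
  by contrast, give difference 0 and p = 1).
- Reporting precision follows the field's conventions: percentages to 2
  decimals, kappa/ICC/AUC to 3, logMAR metrics to 4, all rounded half-up;
  raw values are always retained, and every reported percentage carries
  its numerator and denominator.
- Problem sizes used by the test suite — cohorts of 10,000 eyes for
  Monte-Carlo recovery checks (3-standard-error bands), 100,000 bootstrap
  resamples for the DeLong oracle — were chosen to make sampling noise
  negligible relative to the tolerances tested.

## Known limitations

- The rule table beyond the published skeleton is a reconstruction;
  conclusions about any specific clinical deployment require configuring
  the engine to that site's agreed predicates.
- Kappa is reported without a confidence interval, and multi-rater
  generalisations (Fleiss, Krippendorff) are out of scope.
- The printed ICC variant behind published grading ICCs is not
  identifiable from summary data; this package fixes ICC(2,1) and
  reports the mean squares so other forms can be derived.
- No image processing: the package starts from tabular per-eye records,
  not from slit-lamp or OCT pixels.
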