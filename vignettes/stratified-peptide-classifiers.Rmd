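---
title: "Stratified urinary-peptide classifiers of rapid CKD progression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified urinary-peptide classifiers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rapid progression of chronic kidney disease — a sustained loss of estimated
glomerular filtration rate (eGFR) of 5 ml/min/1.73 m² per year or more —
is poorly predicted by the two standard clinical markers, baseline eGFR and
urinary albumin excretion (UAE), especially in patients whose eGFR is still
preserved. Urinary peptidomics offers an alternative: capillary
electrophoresis–mass spectrometry quantifies thousands of endogenous urinary
peptides per sample, and multi-peptide support-vector-machine (SVM) panels
summarize them into a single risk score.

`ckdstrata` implements a stratified refinement of that idea as a reusable,
fully tested pipeline: patients are divided into seven baseline-eGFR strata
(≥80, 70–79, 60–69, 50–59, 40–49, 30–39, <30 ml/min/1.73 m²), a peptide
panel is discovered and an SVM subclassifier trained *within* each stratum,
and every subclassifier is validated in the other strata and benchmarked
against albuminuria and the 4-variable Kidney Failure Risk Equation (KFRE).
Because no public cohort with this structure exists, the package ships a
synthetic-cohort generator that emulates the study design; every stage of
the pipeline is exercised and tested against that generator and against
independent oracles.

## Outcome labeling

Each patient contributes a longitudinal eGFR series (at least two visits;
visit times in years from baseline). The slope is the unweighted
ordinary-least-squares regression of eGFR on time — the convention for eGFR
trajectories; the package makes no attempt to model within-patient
correlation (see Limitations). Labels partition the slope axis:

| slope (ml/min/1.73 m²/yr) | label |
|---|---|
| ≤ −5 | rapid progressor (case) |
| (−5, −1.5) | excluded, grey zone |
| [−1.5, +5] | non-rapid progressor (control) |
| > +5 | excluded, implausible rise |

Boundary convention: −5 is rapid (the KDIGO wording "5 … or more" takes
precedence over the stricter ">5" phrasing that also circulates), and −1.5
and +5 are controls (the control interval is read as closed). All four
thresholds are arguments of `classify_progression()`, so other conventions
are one call away. Stratum boundaries assign a boundary eGFR (80, 70, …) to
the higher stratum, matching the "≥80" definition of stratum 1.

## Normalization

Sample-to-sample analytical and urine-dilution variation is corrected
against a set of housekeeping peptides (29 by default) that are detected in
every sample with low variance. `normalize_matrix()` divides each sample by
the mean amplitude of its detected housekeeping peptides, then multiplies
by a common reference level. The reference is a genuine design choice:

* `reference = "unit"` (the default) uses a fixed reference of 1. The
  result is strictly invariant under any per-sample rescaling, idempotent,
  and comparable across cohorts.
* `reference = "grand_mean"` rescales to the cohort's mean housekeeping
  level, which keeps the output on the input's amplitude scale but couples
  the overall level to cohort composition (rescaling one sample perturbs
  every normalized value through the grand mean).

Only the overall scale differs — within-sample ratios, and hence every
rank-based statistic and standardized SVM feature, are identical under
either choice. The reference actually used is recorded in the result's
`normalization` attribute. Zeros encode "not detected", never "abundance
zero": they stay zero under normalization, are excluded from amplitude
means (detection is carried separately as a frequency), and enter rank
tests as the lowest tied values.

## Discovery

Within one stratum, `discover_stratum()` compares every non-housekeeping
peptide between rapid and non-rapid progressors with the two-sided Wilcoxon
rank-sum test — exact for small tie-free samples (combined n ≤ 20), normal
approximation with tie and continuity correction otherwise. Zeros are kept
as lowest ties deliberately: dropping them would discard exactly the
detection-rate signal that the frequency filter targets. P-values are
adjusted across all tested peptides by Benjamini–Hochberg within the
stratum. A peptide is selected when q ≤ α (default 0.05) *and* it is
detected in more than `min_freq` (default 30%) of at least one group —
"at least one group" is our reading of the frequency rule; the
alternative (both groups) is a one-line change and would only make
selection stricter. Optionally, selection also requires *consistent
regulation*: the sign of the case–control median difference must agree in
every cross-validation fold; the term is standard in this field but not
formally defined, and fold-wise sign agreement is our operationalization
(off by default).

The candidate panel for a stratum is the union of a configurable base panel
— a stand-in for the published 273-peptide CKD panel, whose identities and
weights are proprietary and out of scope — and the stratum's selected
peptides, de-duplicated with provenance tags, base panel first, discoveries
in ascending-q order.

## Subclassifier training

`train_svm()` fits a C-classification SVM with a Gaussian RBF kernel
(through `e1071`, the implementation the original workflow also used) on
features `log(amplitude + 1)`, standardized per peptide with training-set
constants; zero (undetected) maps to zero before the transform.
Class weights are inversely proportional to class frequency because
case fractions vary widely across strata. Hyperparameters are selected by
maximizing stratified cross-validated AUC (5 folds by default, seeded fold
assignment) over a small grid — cost ∈ {0.1, 1, 10, 100}, kernel width
γ ∈ {0.1, 1, 10}/d for panel size d (features are standardized, so 1/d is
the variance-scaled default width). On our synthetic benchmark the CV
objective is flat across a much wider grid (held-out AUC varies by < 0.01
between the grid optimum and an extended grid), so the small grid is kept.
The fitted model is stored as explicit support vectors, coefficients and
offset; `score()` evaluates the decision function directly, orients it so
that higher = more case-like, and imputes peptides missing from an input
profile as non-detected (counting them). Models serialize to plain JSON at
full floating-point precision (17 significant digits), so a save/load cycle
reproduces scores to machine precision.

Patients are put in a canonical id order before fold assignment, which
makes training invariant to the order samples arrive in.

### Take-one-out panel reduction

`take_one_out_reduce()` prunes a candidate panel by greedy backward
elimination against cross-validated AUC. Each round evaluates the removal
of every remaining peptide and accepts the best one, *including removals
that cost up to `tolerance` (default 0.002) CV-AUC* — this deliberately
favours smaller panels, since candidate unions are much larger than the
panels such pipelines end up with. Two traces are recorded: the accepted
per-round objective, which may dip within tolerance, and the incumbent-best
objective, which is non-decreasing by construction and is the monotonicity
contract the tests assert. The returned model is the best seen (at equal
objective, the smaller panel), refit on all training data. Hyperparameters
are tuned once on the initial panel and frozen during elimination by
default (`refit_hyperparameters = TRUE` re-tunes per candidate; whether the
original workflow re-tuned is unknowable from its description). Stopping:
no acceptable removal, panel at `min_panel`, or `patience` accepted rounds
without improving the incumbent.

## Evaluation

`roc_auc()` computes the AUC by the pairwise-concordance identity (ties
count ½) with a 95% DeLong confidence interval, and `compare_auc()` the
DeLong test for correlated curves (paired) or a normal test on independent
DeLong variances (unpaired); both run through `pROC`. DeLong is the method
MedCalc-style ROC software defaults to, which is why it is the package's
single CI/compare method. `operating_point()` maximizes the Youden index,
breaking ties toward the lower threshold (higher sensitivity).

`cross_stratum_run()` realizes the study design: for every eligible
training stratum it discovers, builds the panel, trains (optionally with
reduction), then evaluates the model on its own stratum (the grid diagonal
— training-set performance, deliberately optimistic) and on every other
stratum (true validation: strata partition the cohort, so validation
samples are never seen in training, which a test asserts by id-set
disjointness). Per validation stratum it reports the best externally
trained subclassifier — ties prefer the adjacent stratum, mirroring the
observation that transfer degrades with distance in baseline eGFR — next
to three comparators: raw UAE as a univariate score, a base-panel-only SVM
trained on the other strata, and KFRE risk at 2 and 5 years. Strata with a
missing outcome class are skipped with a warning; strata with fewer than
`min_cases` (default 10) cases are evaluated but flagged underpowered
rather than dropped, because the low-eGFR strata of such cohorts are
genuinely small.

## Clinical comparator models

The 4-variable KFRE implements the published risk equation
`risk = 1 − S₀^exp(lp)` with
`lp = −0.2201(age/10 − 7.036) + 0.2467(male − 0.5642) − 0.5567(eGFR/5 − 7.222) + 0.4510(ln ACR − 5.137)`
and baseline survivals 0.9832/0.9365 (2/5 years, North American
calibration) or 0.9878/0.9570 (non-North-American recalibration — the
default here, appropriate for a predominantly European cohort; both ship).
ACR of 0 is floored at 1 mg/g before the log. Where only 24-h UAE is
available, ACR ≈ UAE (mg/g ≈ mg/24 h, i.e. ~1 g urinary creatinine/day) is
the documented approximation; the generator emits ACR directly so the
approximation is testable. CKD-EPI eGFR implements the 2009 creatinine
equation, without the race coefficient by default (available as a flag).
Cox association (`survival::coxph`, Efron ties) reports the hazard ratio
of rapid progression per 1 SD of classifier score by default — the score
scale is always printed with the estimate, since an HR without its scale
is meaningless — with Wald 95% intervals; exactly collinear covariates are
flagged with a warning, never silently dropped.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the joint structure the analysis
assumes. Its defaults *are* the emulated study conditions:

| parameter | default | rationale |
|---|---|---|
| n_patients | 1482 | reference cohort size |
| stratum_weights | 479, 381, 261, 126, 67, 80, 88 (÷1482) | reference stratum occupancy |
| rapid fraction per stratum | 0.269, 0.168, 0.096, 0.127, 0.388, 0.550, 0.432 | reference case fractions |
| slope ranges | rapid U(−12, −5); stable U(−1.5, +5) | uniform over the label intervals |
| visits | U{2..8} (mean 5), uniformly spaced | matches ~4.5 ± 2 data points |
| follow-up | N(2.48, 1.1) rapid / N(3.46, 1.1) stable, ≥ 0.5 y | rapid progressors are observed for less time |
| visit noise | sd 2.5 ml/min/1.73 m² | realistic single-visit eGFR error; yields ~10% grey-zone/rising exclusions |
| amplitudes | log-normal on detection, log-sd 1; per-peptide log-mean N(5, 0.75) | log-normal is the standard model for MS intensities |
| detection | background probability 0.7; housekeeping always detected, log-sd 0.2 | zero-inflation with stable housekeeping peptides |
| planted effects | 15 per stratum, log2 effect 1, sign per peptide; adjacent strata share 50% | stratum-specific biology with neighbour overlap |
| covariate shifts (rapid − stable) | diabetes logit +2.66, age +5.2, SBP +5.7, DBP −0.9, log-UAE +1.85, sex logit −0.08 | direction and approximate magnitude of the emulated cohort's group differences |

Planted effects act multiplicatively on amplitude (2^effect) and, by
default, also shift detection probability on the logit scale (0.5 × log2
effect), because detection-frequency differences are part of the signal the
frequency filter targets. The planted sets are sliding windows over the
peptide pool, so `planted_overlap` controls how much signal adjacent strata
share; `planted_overlap = 1` collapses all windows into one shared set,
which is how a second stratum can serve as a clean held-out sample in the
benchmark below. Two generator details keep the labeling contract exact:
the time-0 visit carries no noise (baseline eGFR *is* the trajectory value
at time 0), and follow-up of declining patients is truncated where the
trajectory would reach the eGFR floor — clinically, kidney failure ends
the observation window; numerically, a noiseless cohort labels identically
to the ground truth, which is asserted by a test.

Every random draw derives from the single master seed through named
per-patient substreams (a 31-bit hash of "patient_i" mixed with the seed),
so cohorts are bit-reproducible and independent of generation order.

The generator provides its own performance ceiling:
`likelihood_ratio_score()` scores profiles with the true log likelihood
ratio of the zero-inflated log-normal model, and `bayes_auc_oracle()`
turns it into the Bayes-optimal AUC on fresh samples (10⁵ per group by
default) — by the Neyman–Pearson lemma no classifier can beat it on data
from the same generator.

**What the generator does not emulate.** Peptides are independent given
group (no correlation structure, no shared proteolytic parents); eGFR visit
errors are independent over time; detection probability is uniform across
background peptides; amplitudes have no batch or drift structure; and
covariates are conditionally independent given the outcome group. Passing
tests therefore show that the machinery recovers planted structure under
the stated noise model — they do not show that real urinary peptidomes
carry such signal.

## Numerical and testing choices

Problem sizes in the test suite were chosen to give each check adequate
power at desk scale: the signal-recovery benchmark uses two strata × 300
patients with 300 peptides and 20 shared planted peptides at log2 effect 1
(rapid fraction ⅓, so ~100 cases per stratum); the discovery FDR check uses
200 fully-null replicates of a 40-patient stratum; DeLong coverage and
paired type-I use 1000 replicates of 100 + 100 binormal scores; Cox
calibration uses 200 replicates at n = 1000 with true HR 2 on the unit
score scale (the score is simulated with population SD 1, so per-unit and
per-SD coincide and the target is exact); the take-one-out contract uses 20
seeded replicates of a 5-informative + 20-noise panel. In that benchmark
the subclassifier is trained on the discovery panel alone: the question is
how close discovery + SVM training come to the generator's information
bound, and padding the panel with the deliberately uninformative stand-in
base peptides would measure the stand-in, not the method (under the null
generator, where discovery selects nothing, the stand-in panel *is* the
model, and its held-out AUC stays at chance). Monte-Carlo oracle
comparisons for tied rank-sum tests allow 3 MC standard errors plus the
probability mass of one lattice atom at the observed statistic, because a
continuity-corrected normal approximation cannot resolve the discrete
permutation distribution more finely than that; tie-free cases are checked
against full enumeration at 10⁻¹².

## Limitations

* The base panel is a stand-in; results with it quantify the pipeline, not
  any published panel.
* "Sustained" decline is operationalized as the fitted slope alone; no
  visit-level persistence criterion is applied.
* Independent visit noise understates slope uncertainty if real eGFR
  errors are autocorrelated.
* The Cox endpoint (diagnosis as rapid progressor at end of follow-up) is
  determined by the same trajectory that defines the time scale; hazard
  ratios on synthetic data are internally consistent but not estimates of
  any real-world effect.
* Competing risks, albuminuria staging (A1–A3), probability calibration of
  SVM scores, and the 8-variable KFRE are out of scope.

## Reproducing the study on synthetic data

```{r}
library(ckdstrata)
report <- run_pipeline(list(
  cohort = cohort_config(seed = 1),  # 1482 patients, reference structure
  base_panel_size = 20, seed = 1
), outdir = "results/run")
report$best_subclassifiers
```

The `analysis/` directory decomposes the same workflow into numbered
scripts (simulate → label → discover → train → validate → risk models)
that write their tables under `results/`, and `scripts/acceptance.R` runs
the end-to-end study plus the Bayes-bound benchmark and writes the headline
numbers as JSON.
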