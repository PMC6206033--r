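# ckdstrata

Stratified urinary-peptide classifiers of rapid chronic kidney disease
(CKD) progression.

## What this package is for

Rapid CKD progression — a sustained eGFR decline of ≥ 5 ml/min/1.73 m² per
year — is poorly predicted by baseline eGFR and albuminuria, especially
while kidney function is still preserved. Urinary peptidomics (CE-MS)
quantifies thousands of endogenous peptides per urine sample, and
multi-peptide SVM panels condense them into a risk score. `ckdstrata`
implements, as a tested and reusable pipeline, the stratified refinement of
that approach: discover a peptide panel and train an SVM subclassifier
*within each baseline-eGFR stratum* (≥80, 70–79, 60–69, 50–59, 40–49,
30–39, <30 ml/min/1.73 m²), validate every subclassifier in the other
strata, and benchmark against albuminuria and the Kidney Failure Risk
Equation (KFRE). It is aimed at biomarker methodologists and biostatisticians
who want to study or extend this class of pipeline; since no cohort with
this structure is public, a synthetic-cohort generator with known ground
truth stands in for the data and makes every stage testable.

## The method

For patient *i* with eGFR series (t, y), the outcome is the OLS slope
β̂ᵢ = Σ(t−t̄)(y−ȳ)/Σ(t−t̄)²: **rapid** if β̂ᵢ ≤ −5, **control** if
−1.5 ≤ β̂ᵢ ≤ +5, excluded otherwise (grey zone / implausible rise).
Peptide amplitudes (0 = not detected) are normalized per sample against 29
housekeeping peptides. Within stratum *s*, each peptide is tested with the
two-sided Wilcoxon rank-sum test (zeros as lowest ties), adjusted by
Benjamini–Hochberg; peptides with q ≤ 0.05 and detection frequency > 30%
in a group join the base panel to form the candidate panel. A C-SVM with
Gaussian RBF kernel K(u,v) = exp(−γ‖u−v‖²) on standardized log(amplitude+1)
features is tuned by cross-validated AUC and pruned by take-one-out
backward elimination (remove the peptide whose removal best preserves CV
AUC; accept drops ≤ 0.002 to favour small panels). Validation reports ROC
AUC with DeLong 95% CIs per train × validation stratum, the best external
subclassifier per stratum, operating points (Youden), comparator AUCs
(albuminuria, base-panel model, 4-variable KFRE at 2 and 5 years:
risk = 1 − S₀^exp(lp), lp linear in age/10, male, eGFR/5, ln ACR), and the
Cox hazard ratio of rapid progression per SD of score.

## Worked example

```r
library(ckdstrata)

cfg <- cohort_config(n_patients = 400, n_peptides = 150, n_housekeeping = 15,
                     n_planted_per_stratum = 10, planted_log2_effect = 1.2,
                     stratum_weights = c(.4, .3, .3, 0, 0, 0, 0),
                     rapid_fraction_per_stratum = rep(0.3, 7), seed = 42)
coh    <- generate_cohort(cfg)
norm   <- normalize_matrix(coh$matrix)
labels <- label_cohort(coh$clinical, coh$trajectories)
table(labels$label)
#> excluded_grey_zone    excluded_rising              rapid             stable
#>                 20                 13                114                253
```

Twenty patients fall in the grey zone (slope between −5 and −1.5) and 13
rise implausibly; both groups are excluded from case–control analysis, as
the labeling rule requires. Discovery in stratum 1 then finds the planted
differential peptides:

```r
disc <- discover_stratum(norm, labels, stratum = 1)
disc
#> discovery_result: stratum 1, 44 cases vs 109 controls, 4/135 peptides selected (alpha 0.05)
top_differential(disc, k = 3)[, c("peptide_id", "q_value", "fold_change", "direction")]
#>   peptide_id      q_value fold_change direction
#> 1   pep_0006 5.395869e-05   1.7268462        up
#> 2   pep_0004 5.141109e-04   3.2822993        up
#> 3   pep_0007 1.528632e-03   0.3947848      down
```

Fold change is the mean detected amplitude in cases over controls, so
pep_0007 (fold change 0.39, "down") is depleted in rapid progressors. A
subclassifier trained on this panel in stratum 1 transfers to the adjacent
stratum:

```r
model <- train_svm(norm, labels[labels$stratum == 1, ],
                   build_candidate_panel(disc), seed = 1, stratum = 1)
model
#> ckd_classifier: 4 peptides, cost 0.1, gamma 0.025, CV AUC 0.876 (stratum 1)

val <- labels[labels$stratum == 2 & labels$label %in% c("rapid", "stable"), ]
roc_auc(score(model, norm, sample_ids = val$patient_id), val$label)
#> AUC 0.816 (95% CI 0.721-0.911), 33 cases / 80 controls
```

The validation AUC of 0.816 means the stratum-1 panel separates rapid from
stable progressors in stratum-2 patients it never saw. Clinical comparators
come from the same package:

```r
kfre_risk(age = 65, sex = "male", egfr = 28, acr = 250)
#>     risk_2yr  risk_5yr
#> 1 0.04412095 0.1491933
```

— a 4.4% two-year and 14.9% five-year estimated risk of kidney failure for
that patient.

## The analysis workflow

`analysis/` decomposes the full study into numbered drivers, each a thin
narrative script over the package that writes its tables under `results/`:

1. `01_simulate_cohort.R` — 1482-patient cohort with the reference stratum
   structure and covariate shifts
2. `02_label_progression.R` — slopes, labels, strata
3. `03_discover_biomarkers.R` — per-stratum differential peptides
4. `04_train_subclassifiers.R` — panels and SVM models (with take-one-out
   reduction in the largest stratum)
5. `05_validate_cross_strata.R` — 7 × 7 AUC grid, best subclassifier and
   comparators per stratum
6. `06_risk_models.R` — KFRE risks and the adjusted Cox hazard ratio

Run them in order with `Rscript analysis/01_simulate_cohort.R` etc.

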