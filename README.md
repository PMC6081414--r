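# icnvar

Temporal variability of dynamic functional connectivity between
intrinsic connectivity networks (ICNs), and a linear-SVM diagnostic
model built on it — an R implementation of a phase-based
dynamic-connectivity pipeline for resting-state fMRI, aimed at
neuroimaging researchers who want network-level dynamic features with
far fewer dimensions than voxel-wise maps.

## The statistic

Conventional inter-network measures are static: functional connectivity
(FC) is the Pearson correlation of two network time-courses, and phase
synchrony (PS) is the phase-locking value
`PLV = |mean_t exp(i Δφ(t))|`. Both summarise alignment, not its
fluctuation. The package's core metric, **inter-ICN variability (VAR)**,
quantifies how *unstable* the phase relation between two networks is,
without sliding windows:

1. extract one time-course per ICN by spatial regression of its template
   map on each volume of the 4D series (the spatial-regression step of
   dual regression);
2. band-pass 0.01–0.1 Hz (zero-phase Butterworth);
3. take each time-course's instantaneous phase `φ(t)` from its analytic
   signal (Hilbert transform);
4. form the pairwise phase difference `Δφ(t) = φ_i(t) − φ_j(t)`;
5. wrap it to (−π, π];
6. report its sample variance over time.

With N = 10 ICNs this yields 45 pairwise features per subject. The
diagnostic model is a linear SVM on

    label = Σ w_1i VAR_i + Σ w_2i IQ_i + w_3 sex + w_4 age + w_5 mFD + b

with label 1 = patient, evaluated by leave-one-out CV and by repeated
stratified 10-fold CV (accuracy, sensitivity, specificity, ROC/AUC).
Signed weights are the discriminative pattern (positive = elevated in
patients); top-10 weight frequencies across CV repeats rank feature
stability. A synthetic two-group cohort generator with planted
differences in pairwise phase dispersion makes every stage testable
without clinical data.

## Worked example

```r
library(icnvar)

cfg <- make_sim_config(n_patients = 30, n_controls = 30, seed = 42)
cohort <- simulate_cohort(cfg)
cohort
#> Synthetic ICN cohort: 30 patients + 30 controls, 235 frames x 10 components (TR 2s)

feats <- cohort_features(cohort, metric = "VAR")
dim(feats$X)
#> [1] 60 51

cv <- loocv(feats$X, feats$y)
cv
#> loocv: accuracy 1.0000, sensitivity 1.0000, specificity 1.0000, AUC 1.0000 (n = 60)

rep_cv <- repeated_kfold(feats$X, feats$y, k = 10, repeats = 20, seed = 42)
head(top_k_frequency(rep_cv, k = 10), 5)
#>     feature count mean_weight
#> 1   MVN-OVN    20  0.08775838
#> 2   MVN-LVN    20  0.09197142
#> 3   MVN-DMN    20  0.07478708
#> 9  MVN-LFPN    20  0.08685898
#> 10  OVN-LVN    20  0.08786683
```

The 51 predictors are the 45 pairwise VAR values plus verbal /
performance / full IQ, sex, age and mean framewise displacement. The
default generator plants a dispersion difference (0.3 vs 0.05 rad) on
the three pairs among components 1–3 (MVN, OVN, LVN), so the cohort
separates cleanly: LOOCV classifies all 60 held-out subjects correctly,
and the planted pairs appear in every repeat's top-10 weight list with
positive mean weights (elevated variability in patients). Pairs that
share one planted component (e.g. MVN-DMN) inherit part of the effect —
phase-difference variance adds per component — which is why they also
rank highly.

For volume-level work, `simulate_templates()` + `simulate_bold()` build
a synthetic 4D NIfTI acquisition and `extract_all()` recovers the
time-courses; `framewise_displacement()` and `exclude_high_motion()`
implement motion QC (subjects with mean FD above 0.5 mm are excluded).

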