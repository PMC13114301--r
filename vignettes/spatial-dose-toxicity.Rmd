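---
title: "Spatial dose features and urinary toxicity after prostate seed brachytherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial dose features and urinary toxicity after prostate seed brachytherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brachytox)
```

## The problem

Permanent low-dose-rate (LDR) prostate brachytherapy delivers its dose from
I-125 seeds implanted throughout the gland.  Whole-organ dose-volume metrics
(prostate D90%, urethra D30%, ...) are kept inside tight planning windows,
which paradoxically makes them poor predictors of which patients go on to
long-term urinary toxicity: the constraint erases inter-patient variability
exactly where clinicians look for it.  What does vary from implant to
implant is the *spatial arrangement* of dose — how the hot and cold regions
sit relative to the urethra, the apex, and the gland periphery.

`brachytox` implements a pipeline that captures this spatial variability and
relates it to a 12-month urinary-symptom endpoint:

1. **TG-43 dosimetry** — total permanent-implant dose on a voxel grid from
   seed positions and air-kerma strength, using the 1-D point-source
   formalism.
2. **48-subzone segmentation** — three partition families of the
   prostate-plus-urethra volume (Base/MidGland/Apex axially in a 1:2:1
   ratio; Anterior/Posterior of the urethral center line; Urethra /
   7–10 mm urethra-near annulus / Peripheral radially) and all their
   pairwise and triple intersections.
3. **Per-zone DVHs and PCA features** — a cumulative DVH per zone on a
   fixed dose axis, compressed to two principal-component scores per zone
   (96 spatial features), plus ten whole-organ, implant and clinical
   indicators (106 columns total).
4. **Outcome labelling** — long-term toxicity means the post-implant IPSS
   failed to return to within 2 points of baseline at any visit inside 12
   months.
5. **Modelling** — min–max scaling, Pearson pruning of collinear columns
   (|r| > 0.9), then sequential backward selection (SBS) wrapped around an
   RBF-kernel SVM scored by repeated stratified shuffle-and-split mean AUC,
   stopped by the one-in-ten rule; feature importance is reported as the
   mean AUC after removing each selected feature.  A univariate Spearman
   screen with orientation-corrected standalone AUCs complements the
   multivariate model.

Because clinical implant records are private, the package ships a
first-class synthetic cohort generator that emulates the study conditions
and plants a known dose–toxicity mechanism, so every stage of the pipeline
— including its ability to *discover* a planted spatial effect — is
testable end to end.

## Dosimetry model and its assumptions

The dose rate at distance $r$ from a seed of air-kerma strength $S_k$ is

$$\dot D(r) = S_k \, \Lambda \, \left(\frac{r_0}{r}\right)^2 g(r)\, \phi_{an}(r), \qquad r_0 = 1\ \mathrm{cm},$$

with the dose-rate constant $\Lambda$, radial dose function $g(r)$ and
anisotropy factor $\phi_{an}(r)$ taken from the published consensus
parameters for the Best Medical 2301 I-125 seed (a generic I-125 set is
selectable).  Total permanent-implant dose is the initial rate times the
mean life $\tau = T_{1/2}/\ln 2$ ($T_{1/2} = 59.4$ d).  Choices worth
knowing about:

* **1-D point source, not 2-D line source.**  Loose seeds have no reliable
  orientation, and the features downstream are radius-scale; the
  anisotropy *factor* is the appropriate average.
* **Minimum-radius clamp** at 1 mm: the voxel containing a seed is assigned
  the dose at 1 mm rather than a singularity.  This touches only that
  voxel.
* **Radial tables** are interpolated linearly in $\log r$ and held constant
  beyond the last node (the geometry factor supplies the inverse-square
  tail).  The compiled superposition kernel interpolates the same tables
  with the same rule, so it agrees with the R-side single-seed function to
  floating-point precision — the test suite asserts a 60-seed implant
  against a pure-R double loop at $10^{-9}$ relative.
* No interseed attenuation, tissue heterogeneity, seed migration, or EBRT
  dose: out of scope by design.

## Geometry conventions

* Voxel membership is by center point: a voxel belongs to the prostate if
  its center lies inside the slice polygon (the polygon of the *nearest*
  contoured slice; contours are 2.5 mm apart, the default grid 1 mm).  The
  urethra is a 7 mm circle around the per-slice urethral center
  (interpolated linearly in z between contours); its voxels are labelled
  whether or not they fall inside the prostate polygon, since the urethra
  participates in all three partition families.
* The axial 1:2:1 split is measured per patient on the contoured z-extent.
  Internal boundaries are half-open: the apex/mid boundary belongs to the
  mid-gland, mid/base to the base.  z increases toward the base (superior).
* Anterior/posterior is decided per slice by the anterior–posterior
  coordinate of the urethral center; a voxel exactly on the line is
  posterior.  Radial boundaries are closed inward: exactly 7 mm is
  urethra, exactly 10 mm is the near annulus.
* The `Prostate` zone includes urethra voxels that overlap the polygon; a
  configuration switch is deliberately *not* offered for excluding them —
  DVH indicators are computed on this inclusive mask, and the near-annulus
  and peripheral zones are unaffected either way.

These conventions make the three families exact partitions of the labelled
voxel set, which the test suite asserts on randomly generated anatomies,
along with composite-equals-intersection and isotropic volume scaling.

## DVH and feature choices

Zone DVHs are cumulative, sampled on a fixed axis of 0–400% of the 110 Gy
prescription in 1% steps (401 nodes).  The fixed axis makes every zone
curve a commensurate vector — a prerequisite for pooling them in PCA — and
400% comfortably covers LDR hot spots.  $D_{x\%}$ is read off the curve as
the largest axis dose still covering $x\%$ of the volume (no sub-bin
interpolation: the uniform-dose step case then returns the exact plateau
dose, and agreement with an exact quantile is within one 1% bin).
Volumes are fractional throughout; only the prostate-volume indicator is in
cc.

Per zone, the cohort's curves are mean-centered (no per-bin
standardization: bins share units) and the first two right singular vectors
give the loadings; signs are fixed so each loading sums non-negatively.
On synthetic cohorts two components explain ~95% of per-zone variance,
which matches what this kind of smooth, monotone curve family admits.
Patients whose zone is empty (possible for small composites in small
glands) are projected to the cohort mean, i.e. scores (0, 0); zones empty
for essentially the whole cohort are dropped with a warning.  Min–max
scaling and the |r| > 0.9 Pearson prune walk the columns in catalogue
order and drop the later member of an offending pair — deterministic, and
it retains individual zones in preference to their composites.

## Modelling choices

* **Shuffle-and-split**: stratified 80/20 splits (the held-out fraction is
  not dictated by the endpoint definition; 0.2 is standard practice and
  configurable), mean test AUC over repeats.  The reference analysis depth
  is 1000 repeats; desk-scale runs in this package's tests use 6–200 and
  state so.  The mean ROC is vertically averaged at a fixed
  false-positive-rate grid (0–1, step 0.01).
* **Decision threshold** for accuracy/sensitivity/specificity is the SVM
  decision boundary (score 0); no threshold tuning.
* **PCA and scaling are fitted once on the full cohort before selection.**
  This mirrors the described architecture (scaling "prior to" selection),
  and it is deliberately leakage-prone: the reported AUC is an in-cohort
  validation estimate, not an external one.  Split-wise refitting was
  considered and rejected for fidelity; the optimism is quantified
  empirically by the label-permutation null in the acceptance suite.
* **Hyperparameters** $(C, \gamma)$ are tuned once on the post-pruning
  feature set by a small global-best particle swarm inside the boxes
  $C \in [0, 100]$ (evaluated from a small positive floor, since $C = 0$
  is degenerate) and $\gamma \in [10^{-5}, 100]$ (searched on a log
  scale), then frozen during SBS.  Re-tuning inside every SBS iteration
  would multiply the fit count by the swarm budget for no demonstrated
  benefit.
* **SBS ties** break to the lowest column index; splits are redrawn each
  iteration from the scheme seed and shared across that iteration's
  candidates (common random numbers), so the trace is exactly reproducible
  from the master seed.
* **One-in-ten rule**: selection stops at $\lfloor n/10 \rfloor$ retained
  features — 8 for an 85-patient cohort, at most 10 for 100 patients.

## The synthetic cohort generator

The generator defines the study conditions; its defaults are fixed, not
tuning knobs:

| Quantity | Default | Why |
|---|---|---|
| Cohort size | 85 | the cohort scale the analysis targets |
| Toxicity prevalence | 0.48 | observed prevalence emulated |
| Prostate volume | lognormal, median 35 cc, sdlog 0.3 | typical implant candidates |
| Prescription | 110 Gy | LDR boost prescription |
| Planning goals | D90% ≥ 100%, V150% < 50%, urethral max < 150% | intraoperative goals enforced by construction |
| Planted effect | log-odds ln 2 per SD of apex urethra-near mean dose | "moderate effect" (OR ≈ 2/SD) concentrated where the analysis should find it |
| Baseline-IPSS effect | −ln 2 per SD | higher baseline symptoms are protective for the *resolution* endpoint |
| Baseline IPSS | discretized gamma (shape 2.2, scale 3.6), clamped 0–30 | right-skewed questionnaire scores, median ≈ 7 |

Anatomies are ellipsoids with mild random axis ratios, sliced at 2.5 mm,
rescaled so the slab-integrated volume hits the drawn target within a few
percent; the urethra runs near the posterior-central axis with a gentle
bow.  Implants follow modified peripheral loading on a 5 mm template
(needles ≥ 7 mm from the urethral center line, full outer ring, alternate
interior slots, seeds ~8 mm apart axially, 0.75 mm placement jitter).
Because dose is linear in air-kerma strength, the compliant strength
window is solved analytically from the unit-strength dose distribution;
draws with an empty window are re-jittered, densifying the loading on
later attempts.  The urethral maximum constraint is evaluated on a
catheter-sized 3 mm planning core — the 7 mm circle is the *zoning*
urethra, far wider than the planning organ, and holding its maximum under
150% would contradict realistic peri-urethral dose levels.

The planted mechanism acts on the *true* zone mean dose, not on PCA
scores, so recovering it through the DVH-PCA features is a genuine test of
the pipeline's discovery claim rather than a circularity.  The latent
toxicity probability is logistic with an intercept calibrated by
root-finding to the prevalence target.  IPSS trajectories rise by 5–15
points to a peak near 3 months and decay back toward baseline with the
resolution time placed on the correct side of the 12-month horizon, so the
labelling rule recovers every latent label exactly — asserted in the
tests.

What the generator does *not* emulate: real contouring variability,
non-ellipsoidal gland shapes, seed migration and edema, EBRT dose, or
correlated questionnaire noise.  Passing tests therefore demonstrate that
the pipeline's machinery is correct and can detect a planted spatial
effect of moderate size at these cohort scales — not that any particular
clinical effect size is recoverable from 85 real patients.

## Problem sizes used in the checks

The test and acceptance runs choose desk-scale sizes: voxel spacing
2.5–3 mm for cohort-level runs (1 mm default for single-patient use),
6–10 shuffle-split repeats inside SBS iterations with 25–200 repeats for
final performance estimates, and the parameter-recovery study at n = 300
with 10 generator seeds against a 2-seed label-permuted null.  The
recovery study restricts the SBS candidate set to the indicators, the nine
individual zones and the apex-region composites (~44 columns post-pruning)
— the wrapper's combinatorial budget grows quadratically in the candidate
count, and this focused design keeps the planted-zone features, their
containing zones and all whole-gland competitors in play.  The
label-permuted null reruns the identical selection procedure.  Both arms
use the default hyperparameters ($C = 1$, $\gamma = 1/p$): running the
swarm tuner inside a permutation null lets it optimize pure noise and
inflates the null AUC by several points while adding little to the signal
arm, which would blur exactly the contrast the study measures.  The tuner
is exercised by its own tests.

Null-calibration checks read the ±0.05 band on standalone AUCs
distributionally: at n = 500 the null rank-AUC has a standard deviation of
about 0.026, so individual features stray outside 0.05 by chance about 5%
of the time; the suite asserts the median and the bulk of the
distribution, plus marginal uniformity of the Spearman p-values.

## Known limitations

* The point-source formalism underestimates anisotropy close to seed ends;
  fine near-urethra features inherit this smoothing.
* Center-point voxel membership makes zone volumes jitter by a voxel layer
  at boundaries; the partition invariants absorb this by construction, but
  very coarse grids (> 3 mm) make small triple composites empty for some
  patients.
* The reported AUC shares splits with the selection loop, as in the
  architecture it mirrors; treat it as internal validation.
* The Spearman screen deliberately applies no multiple-testing correction
  (a Benjamini–Hochberg column is emitted for transparency but drives no
  decision).

## A worked example

```{r example, eval = FALSE}
library(brachytox)

co <- simulate_cohort(cohort_config(n_patients = 85, spacing = 2, seed = 42))
res <- run_pipeline(co, n_repeats = 50, seed = 42, out_dir = "bundle")
print(res)
res$importance
head(res$uva[order(res$uva$p_value), ])
plot(res$fit)   # mean ROC
```
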