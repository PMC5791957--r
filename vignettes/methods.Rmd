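---
title: "Assessing masticatory efficiency from two-coloured chewing-gum scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing masticatory efficiency from two-coloured chewing-gum scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A mixing test quantifies how well a person chews: the patient masticates a
wafer made of two differently coloured chewing-gum layers (here red and
white) for a fixed number of strokes, the flattened bolus is scanned on
both sides, and the degree of colour mixing is measured from the images.
Masticatory performance (MP) is the set of image measurements
characterizing the state of the specimen. Masticatory efficiency (ME) asks
a comparative question: how many chewing strokes would a *healthy
reference person* need to reach a similar degree of mixing? If a
classifier calibrated on a healthy reference population predicts that a
patient's specimen looks like a reference specimen chewed `P` strokes,
while the patient actually applied `T` strokes, then

```
ME = P / T
```

so ME = 0 means no mixing at all, ME = 1 a normal level, and ME > 1 better
than the norm. ME maps onto linguistic tags at 0/25/50/75/100%
("Totally impaired" … "Normal", and "Better than the norm" above 100%);
intermediate values take the nearest level, midpoints rounding up. The
nearest-level rule (rather than tags only at exact anchor values) is a
design choice: reported cohort means such as 0.26 or 0.71 must still carry
a meaningful tag.

The package implements the whole measurement chain twice over: a
**calibration stage** that learns mixing patterns from a reference
population and packages them as a portable MEPAT record, and a **diagnosis
stage** that scores a single new specimen against a MEPAT.

## Synthetic specimens: what the generator emulates

No public image set of masticated two-colour wafers exists, so the package
ships a generator (`generate_specimen()`, `generate_calibration_set()`,
`generate_diagnosis_cohort()`) that emulates the study conditions every
module is exercised under: 80 reference subjects, five specimens each at
0/5/10/15/20 chewing cycles (400 specimens, 800 images), and a 40-patient
pre/post-treatment cohort of 160 specimens at 20 cycles.

Each specimen is an irregular elliptical bolus (a Fourier-perturbed
ellipse; 10–70% of the frame; never touching the border) on a dark
scanner background, imaged from both sides. Mixing follows a saturating
exponential in the stroke count with one per-subject rate parameter:

```
mixing_level(t) = 1 - exp(-subject_rate * t)
```

Any monotone saturating map would serve; the exponential is the simplest
with a single subject parameter. At `t = 0` one face is entirely red and
the other entirely white (the wafer is two stacked layers); for `t > 0`
both faces show the same mixing level with independent patch realizations.
The red/white interleaving is a thresholded smoothed-noise field: the
threshold pins the red area fraction on face A to `1 - mixing/2` and on
face B to `mixing/2` (colour mass is conserved — pooled over both faces
the red fraction is always one half, exactly as for a real wafer), the
patch length scale shrinks linearly with mixing, and a logistic blend
whose softness grows with mixing produces the pink shades of a
half-masticated bolus. A mild per-image illumination gradient (±1.5%) and
additive Gaussian pixel noise (sd 5 of 255) emulate scanner imperfections.

Default parameter choices worth explaining:

* **Mixing rate ~ N(0.04, 0.001) per stroke.** A healthy subject reaches
  mixing 0.55 at 20 cycles and ~0.87 at 50, consistent with the domain
  observation that chewing beyond ~50 cycles adds little further mixing.
  The small between-subject spread reflects the tightly screened young
  dentate reference population; it is what makes near-perfect
  stroke-count classification attainable, as observed on the real data
  the method was developed for.
* **Patch scale 0.7–2.5 px in a 128 px frame.** The bolus then carries
  hundreds of colour patches, so per-specimen histogram statistics are
  stable. (Large patches relative to the bolus would make every summary
  statistic a tiny-sample estimate — visually pretty marbling, but a
  regime in which no classifier, and no clinician, could tell 15 from 20
  cycles.)
* **Near-white (240, 234, 226) rather than a strongly tinted cream.**
  The white face's hue is then dominated by scan noise when unmixed, so
  hue-histogram features start diffuse and concentrate as pink blending
  takes over — matching the monotone behaviour expected of hue-based
  mixture indices.
* **Dark background (grey 60).** An open-lid flatbed scan. It also keeps
  both wafer colours far from the background in L\*u\*v\*, which is the
  contrast regime the segmentation method was designed for; against a
  light-grey lid the white phase becomes nearly equidistant between bolus
  and background and no two-cluster colour partition can be correct.

What the generator does **not** emulate: saliva sheen and specular
highlights, press-flattening optics, dye bleeding, non-elliptical folded
boluses, and scanner colour-profile drift. Tests passing on synthetic data
therefore certify the pipeline's correctness and internal consistency, not
its clinical accuracy on real scans.

## Segmentation: mean shift + distance map + k-means

`segment()` isolates the bolus (ROI) from the background fully
automatically:

1. **Mean-shift filtering** (`mean_shift_filter()`, Rcpp) in CIE-L\*u\*v\*
   with a flat joint kernel (spatial bandwidth 8 px, range bandwidth 12
   L\*u\*v\* units, ≤5 mode-seeking iterations). Noise and texture are
   flattened while colour boundaries sharper than the range bandwidth are
   preserved. The bandwidth defaults suit 300-dpi-like scans and are
   exposed in `segment_params()`.
2. **Distance map** (`distance_map()`): per-pixel distance to the frame
   centre, min–max normalized. The bolus is centred by protocol, so this
   single feature biases clustering to gather the central object even
   when its colours are heterogeneous.
3. **K-means region classification** (`kmeans_region_classify()`): k = 2
   over the per-pixel stack (filtered L, u, v, weighted normalized centre
   distance; each channel z-standardized), 10 restarts under a fixed
   seed. The cluster with the smaller mean centre distance is the ROI
   (ties: the smaller cluster — the bolus is smaller than the
   background). Post-hoc cleanup keeps only the connected component
   containing the frame centre and fills interior holes (the bolus is a
   solid object; a wafer patch whose colour sided with the background
   cluster is still bolus).

A segmentation-failure error is raised when the two clusters' mean
colours are closer than 4 L\*u\*v\* units (a background-only frame), or on
degenerate constant images. The ablation variants (`km`, `ms_km`,
`dm_km`) are exposed for comparison; on generator fixtures the full
pipeline dominates plain k-means.

## Feature extraction: MP = 121 features

ROI pixels from both faces are pooled (`pool_roi_pixels()`), converted to
twelve channels — R, G, B; CIE L\*, u\*, v\* (D65, hand-implemented per the
CIE definitions); H, S, I (arccos hue variant, radians, hue masked where
undefined); normalized Rn, Gn, Bn — and summarized by ten extraction
models per channel plus the circular variance of hue:

| code | statistic |
|------|-----------|
| Mp, Vp | mean and population variance of the pixel values |
| Vh | population variance of the 256 raw histogram bin counts |
| Sh | count-weighted Fisher–Pearson skewness of the histogram |
| Gh, Eh | histogram energy Σp² and entropy −Σp·log₂p (bits) |
| Nh | number of peaks (prominence ≥ 1% of total count) |
| V1, V2 | heights of the two tallest peaks (V2 = 0 if absent) |
| P2 | bin index of the 2nd peak (−1 if absent) |

Histograms use 256 equal-width bins over fixed per-channel ranges, so bin
counts are comparable across specimens. Peak detection smooths the counts
with a (1, 2, 1)/4 kernel before finding strict local maxima and computes
topographic prominence; the 1% prominence floor suppresses scan-noise
jitter. "Variance of the histogram" operates on raw counts, not
probabilities — reported magnitudes of order 10⁶–10⁷ for hue-histogram
variances on real data are only consistent with count variances.
`CVOH = 1 − R̄` (one minus the mean resultant length of the hue angles) is
the classical single-number mixture index. The feature registry
(`mfc_registry()`) is data-driven: `<model><channel>` codes plus `CVOH`,
121 in all.

## Relevancy-based feature selection

Every feature is scored against the stroke count (`select_features()`):
Spearman's ρ, and γ = the number of stroke-class pairs separated by
one-way ANOVA followed by Bonferroni-corrected pooled-variance pairwise
t-tests (γ = 0 when the omnibus test is not significant). The relevancy
score combines them as

```
q = ( |rho| + (gamma / C(n,2))^2 ) / 2
```

with n the number of stroke classes; features with q < 0.5 are discarded.
The printed source formula is typographically garbled; this reconstruction
is adopted because γ/C(n,2) is the natural normalization of the pair
count, the trailing 2 reads as a halving that maps the score into [0, 1],
and the 0.5 discard threshold then sits mid-scale. The formula is isolated
in `q_score()` so it can be revised in one place. Optional standardized
PCA of the kept features (`pca_reduce()`) is provided for comparison; the
cascade trains on the bare kept features by default, as that performed at
least as well in the original study.

## The MLP binary cascade

Samples are split 40/30/30 into Training, Validation and Testing groups,
stratified by stroke class (`split_dataset()`). One split is drawn per
calibration run and shared by all stages: a per-training-execution
re-split would leave no common held-out group on which the assembled
cascade's global score is honest. Kept features are z-standardized with
Training-Group statistics.

Per stroke class, a one-vs-rest multilayer perceptron (k inputs, h
logistic hidden units, one logistic output) is trained for every h in a
sweep of ⌈k/3⌉..k (10 evenly spaced values by default; the full
every-integer sweep is available) with 3 seeded restarts per h. Training
(`src/mlp.cpp`) is batch iRprop⁻ on class-weighted cross-entropy with L2
decay 10⁻³, in chunks of 100 epochs; after each chunk the Validation-Group
MCC is checked and training stops once it stops improving (patience 2) —
early stopping against overfitting. Resilient propagation was chosen
because its cost is linear in the weight count, which keeps the h ≤ k
sweep tractable at k ≈ 100 on a single CPU; the weight layout matches the
classical R MLP implementation, against which the package's forward pass
is cross-checked in the tests.

Each trained network is scored by its Matthews correlation coefficient on
the Testing Group; the best (h, restart) wins the stage, and a stage is
*suitable* only if that MCC strictly exceeds 0.95. Calibration fails
loudly if any class lacks a suitable stage. Suitable stages, ordered by
ascending stroke count, form the binary cascade: a new MP vector is
queried stage by stage (output threshold 0.5) and takes the stroke count
of the first stage that fires; if none fires the specimen is UNCLASSIFIED
— surfaced as such, never coerced to ME = 0. Training is stochastic by
design; the best-of-many selection under the MCC gate is the mechanism
that tames that randomness, and all seeds are recorded.

## MEPAT files

`write_mepat()`/`read_mepat()` serialize the calibration artefact — test
food (TF), experimental settings (ES), selected features with their
relevancies and standardization (CH), the cascade's weight matrices (CLS),
operator metadata (OP), performance block (PER), plus a UUID and
timestamps — as UTF-8 XML validated against the shipped XSD
(`inst/extdata/mepat.xsd`). The schema is this package's own dialect of
the six-block structure; interoperability with other implementations is
not claimed. Weights are written as decimal text with 17 significant
digits, so a deserialized cascade reproduces bit-identical predictions,
and writing is canonical: write → read → write is byte-identical.

## Diagnosis, agreement, and the z-score baseline

`diagnose()` runs a single-test diagnosis: segmentation with the MEPAT's
stored parameters, extraction of only the CH features, cascade
classification, ME = P/T with its tag. T must be one of the calibrated
cycle counts (the clinical protocol uses T = 20, the largest calibrated
count; behaviour at uncalibrated T is undefined by the method, so it is
refused). `repeat_agreement()` computes Cohen's κ between repeated
measurements; `summarize_patients()` takes the maximum ME over a
patient's repeated tests.

The comparison baseline (`fit_zscore_model()`, `zscore_classify()`) is
the classical single-feature approach: per-class mean and sample sd of
one MP feature from the Training Group, z = (mp − mean_T)/sd_T,
pre-classification into class T when |z| ≤ 0.25 (boundary inclusive), and
final assignment to the class with the smallest |z| (ties to the smaller
stroke count — the conservative ME). On overlapping classes it trails the
multivariate cascade, which is the point of the comparison.

## Numerical and degenerate-input choices

* Hue is radians in [0, 2π); achromatic pixels have undefined hue and are
  excluded from all H statistics (never imputed); an all-achromatic ROI
  raises an error from `cvoh()`.
* Normalized RGB of the black pixel is defined as (⅓, ⅓, ⅓).
* MCC with any zero denominator factor is 0 (standard convention); an
  all-zero confusion matrix is an error.
* K-means on a constant image raises a segmentation failure; cluster ties
  on mean centre distance resolve to the smaller cluster.
* P2/V2 sentinels (−1 and 0) when fewer than two histogram peaks exist.
* A constant feature has ρ = 0 (flagged degenerate) and γ = 0.
* All randomness funnels through per-run seeds; generation, segmentation,
  feature extraction and diagnosis are bit-reproducible, and trained
  cascades are reproducible given the run seed.

## Problem sizes used by the shipped checks

The packaged test-and-acceptance runs use the generator defaults above:
a 400-specimen calibration (80 subjects × 5 cycle counts, 128×128 px
frames, reduced h-sweep of 10 values × 3 restarts) and a 160-specimen
diagnosis cohort (40 patients × 2 phases × 2 repeats). Unit tests run the
same code paths at smaller sizes (64 px frames, 12 subjects). The
relevancy and cascade machinery is additionally exercised on planted
feature tables where ground truth is known by construction.

## Known limitations

* Synthetic realism bounds what the tests certify (see above); no claim
  is made about accuracy on real scans without a real calibration.
* The segmentation appendix of the original method is not public; the
  distance-map definition (distance to frame centre) and mean-shift
  kernel here are documented substitutes consistent with its published
  description, not a verbatim reimplementation.
* The exact formulas behind the original "energy/skewness/peaks"
  extraction models and the tenth model are not public; standard
  definitions are used and the registry keeps them swappable.
* Single-hidden-layer MLPs only; no GPU; no alternative architectures.
* MEPAT "upload date" is metadata only — no synchronization workflow.
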