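---
title: "Methods and design choices in matriscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in matriscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matriscope)
```

`matriscope` packages four measurement workflows used when studying KRT5+
airway basal cells on fibrotic extracellular matrix: collagen-organisation
scoring of 2D images, single-cell migration analytics, relative qPCR
quantification (2^−ΔΔCT), and differential matrisome proteomics. This
vignette explains the models behind each workflow, the parameters that
matter, the synthetic-data generators that stand in for real acquisitions,
and the numerical decisions taken where conventions were genuinely open.

## Collagen texture

### Density and segmentation

Collagen density is defined as the percentage of tissue pixels covered by
segmented collagen. Segmentation thresholds intensities within the tissue
mask; the default method is Otsu's criterion, with a fixed-quantile
alternative (`segment_collagen(method = "quantile")`) whose resulting
density is invariant to global intensity rescaling. The published analyses
used a commercial surface tool whose threshold settings are not public, so
the method is configurable and recorded in the output provenance columns.

### GLCM features

The grey-level co-occurrence matrix p(i, j) collects the joint distribution
of quantized grey levels for pixel pairs at chosen offsets. Open conventions
were fixed as follows:

* **Quantization**: min–max within the tissue mask to **64 levels** by
  default. 64 balances grey-level resolution against count sparsity in
  typical image sizes; requesting more levels than an integer image can
  represent is an error.
* **Offsets**: distance 1 pixel at 0°, 45°, 90° and 135°, symmetrised and
  accumulated over directions — the common rotation-tolerant convention.
* **Masking**: pixel pairs with either member outside the tissue mask are
  excluded rather than zero-coded, to avoid manufacturing artificial
  homogeneity at tissue borders.
* **Entropy base**: log₂ (bits), recorded in the output (`entropy_base`
  column), since plugin conventions differ.

The five features (contrast, entropy, correlation, IDM, ASM) follow the
standard second-order definitions; correlation is flagged undefined when a
marginal standard deviation is zero (e.g. constant images). The vectorised
implementation is pinned to a brute-force double-loop oracle over all pixel
pairs in the test suite.

### Structure-tensor coherency

Gradients are taken by central differences after Gaussian smoothing
(`gradient_sigma`, default 1 px); the tensor components are averaged over
the tissue mask (an optional Gaussian window `window_sigma` can pre-smooth
the component maps). Coherency is the normalised eigenvalue anisotropy, and
the reported orientation is the fibre direction — perpendicular to the
dominant gradient — in degrees from the image x-axis, range (−90°, 90°],
with y pointing down (image convention). Flat images return coherency 0
with an undefined-orientation flag. The one-pixel image border, where
central differences degenerate, is excluded from the average.

## Migration analytics

### Filtering and metrics

The filter defaults reproduce the published tracking settings: tracks with
12 or fewer frames are deleted; only cells present at every frame of the
experiment window are kept; any instantaneous step faster than 100 μm/s
(floating debris) rejects the track; gaps up to 3 missing frames are closed
by linear interpolation, and larger gaps split the track. Interpolated
points are flagged and *included* in path length — whether the original
analyses excluded them is not recoverable, so the simpler convention was
chosen and documented. Elapsed time for speed uses first-to-last timestamps
rather than frame count × nominal interval, to tolerate timestamp jitter.

Class boundaries read the published wording literally: sessile = [0, 30)
μm, motile = [30, 90] μm ("up to 90" taken as inclusive), highly motile =
(90, ∞) μm; both thresholds are arguments.

### MSD and the PRW model

The default MSD estimator measures squared displacement **from the track
origin**, matching trackers that report MSD as squared distances from the
beginning of the track; the overlapping time-averaged estimator is provided
(`method = "time_averaged"`) and clearly labelled non-default. The
from-origin estimator is unbiased but high-variance at long lags; the
time-averaged one is the better input for parameter fitting, and the test
suite uses it for PRW recovery.

The persistent random walk is the standard motility null. It is simulated
as an Ornstein–Uhlenbeck velocity process with RMS speed S and persistence
time P, whose ensemble MSD follows the Fürth form
2S²P[τ − P(1 − e^(−τ/P))]. Integration uses Euler substepping with 10
internal steps per frame; at the default frame interval (5 min) and
persistence (20 min) the discretisation bias is well inside the recovery
tolerance verified by the tests. `fit_prw()` fits the Fürth form by
weighted least squares with weights 1/MSD², since the sampling error of an
ensemble MSD scales with its magnitude; with exact Fürth input the fit is
exact regardless of weighting. A fitted P beyond the observation window is
flagged ballistic.

### SuperPlot inference

Cell-level measurements are averaged per biological replicate, and the
one-way ANOVA with Tukey's test runs on the donor means, never on pooled
cells; a guard in the tests asserts the donor-level n. Conditions with
fewer than 2 donors skip inference with a warning.

## The 2^−ΔΔCT workflow

CT values above the cut-off (default 35 cycles) and undetermined values are
set **to** the cut-off — the vendor-style convention; the alternative
(dropping them) changes denominators silently, so censoring is explicit and
flagged. ΔCT subtracts the arithmetic mean CT of the configured
housekeeping genes per sample; which housekeeping genes an instrument's
software auto-selected for a given run is not recoverable, so explicit
configuration is required. Fold change is the ratio of group means of
2^−ΔCT (the printed ratio-of-normalised-expression form); per-gene
inference is a pooled-variance two-sample t-test on the 2^−ΔCT values
themselves, not on ΔCT. The volcano default classifies at fold change ≥ 2
or ≤ 0.5 with p < 0.05; the published legend's wording ("log fold change
>2 or <2") is internally contradictory, so the threshold is exposed as an
argument with fold 2 as the default reading.

## Differential matrisome abundance

Mass-spectrometry abundance is multiplicative, so fold changes are
differences of group means of log2 abundance and the one-way ANOVA also
runs on log2 values; the linear-scale abundance ratio is reported
alongside. Benjamini–Hochberg adjustment is applied across all tested
proteins; significance requires both |log2 fc| ≥ log2(2) and adjusted
p < 0.05. Proteins with fewer than 2 finite values in any group are not
tested (no imputation by default); zero-variance proteins get p = 1 with a
flag. Normalisation options are total-sum and median-ratio scaling, both
rank-preserving within samples. The bundled matrisome reference is a small
synthetic fixture (named as such); real analyses supply a full reference
CSV in the same two-column format.

## Shared statistics

* **PCA**: rows (features) centred and unit-variance scaled; missing
  entries filled by iterative low-rank SVD imputation, rank min(5, dims−1),
  relative tolerance 1e-6 — the named convention of the web tool used in
  the field is not parameterised publicly, so these values are this
  package's own documented defaults; numeric parity with that tool is not
  promised.
* **Prediction ellipses** use the prediction (not confidence) form: with
  probability `coverage` a *new* observation from the group falls inside.
  The radius uses the small-sample F-based factor
  2(n+1)(n−1)/(n(n−2)) · F(coverage; 2, n−2).
* **Clustering**: 1 − Pearson correlation distance with average linkage
  (UPGMA); inputs are ordered lexicographically by label before clustering
  so leaf order is reproducible under ties.
* **Spearman**: rho on mid-ranks; the two-tailed p is exact by full
  permutation enumeration for n ≤ 9 and t-approximate above — n = 9 is
  where enumeration (362,880 permutations) stops being worth the cost.
* **Normality gate**: the D'Agostino–Pearson omnibus K² from the
  z-transformed skewness and kurtosis; p > 0.05 recommends the parametric
  branch. The transforms need n ≥ 8, below which the gate abstains rather
  than guessing.

## What the generators emulate — and what they do not

* `sim_fiber_image()` renders anti-aliased straight chords with von Mises
  orientations (sampled on the doubled angle, the axial-data construction)
  over Gaussian background noise, additive with clipping so overlaps do not
  double-count coverage. Ground-truth coverage is the exact fraction of
  pixels whose noiseless signal exceeds half the fibre intensity. It does
  **not** emulate photon statistics, fibre curvature, bundling, 3D
  projection or spectral bleed-through of real SHG imaging — so passing
  texture tests shows the *estimators* are correct, not that real tissue
  values are reproduced.
* `sim_tracks()` mixes confined movers (positional OU process whose
  stationary RMS radial distance equals `confinement_radius`, default 10
  μm, relaxation 30 min) with PRW movers. The oscillatory "sessile"
  phenotype has no published quantitative model, so the confinement radius
  is this package's choice, set well below the 30 μm class boundary. The
  intermediate motile class uses a scaled PRW speed
  (`motile_speed_factor`, default 0.3). Defaults follow the study design:
  12-h experiments at 5-min frames (145 points), RMS speed 1 μm/min,
  persistence 20 min, localisation noise 0.2 μm. No cell shape, contact
  interactions or matrix remodelling are simulated.
* `sim_ct_plate()` and `sim_abundance_table()` are additive
  Gaussian-on-log-scale models (CT noise 0.2 cycles; log2 dispersion 0.3;
  3 replicates per group, matching the study's donor counts) with known
  spiked effects; they do not model amplification efficiency, plate
  effects, or missing-not-at-random dropout.

Every generator is a pure function of its arguments including the seed;
per-item sub-streams ensure that growing n leaves earlier items unchanged.

## Problem sizes and determinism

The test suite verifies the Monte-Carlo claims at the sizes it states: 200
random images for the GLCM oracle, 20 seeds for isotropy calibration, 500
tracks for Brownian-slope and PRW recovery, 100 random track sets for the
filter oracle, 1,000 draws for BH and Tukey calibration. The bundled demo
pipeline (`inst/extdata/demo-config.yaml`) runs all four stages on small
synthetic inputs and is hash-stable given its seed — these sizes are the
package's chosen trade-off between statistical resolution and a test suite
that stays fast enough to run habitually.

## Known limitations

* Real-tissue values from the motivating study (pixel-, track- and
  spectrum-level data) are not reproducible here; the package validates
  estimator correctness and calibration on synthetic ground truth.
* The GLCM implementation targets 2D single-channel images; there is no 3D
  texture support.
* PRW fitting assumes a shared frame interval across tracks and a
  reasonably sampled persistence time (P between one frame and the
  observation window); outside that range the ballistic flag fires.
* The ANOVA used per protein is the classic fixed-effects one-way layout;
  proprietary variants in commercial proteomics software (and their
  normalisation) are intentionally not imitated, only documented
  alternatives are offered.
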