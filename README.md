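# matriscope

Quantitative analytics for studies of airway basal cells (KRT5+) interacting
with fibrotic extracellular matrix. In idiopathic pulmonary fibrosis (IPF),
basal cells accumulate in remodelled, collagen-rich regions of the distal
lung, and their behaviour is shaped by the matrix they sit on. Four
measurement workflows recur in this field, and `matriscope` implements all of
them as tested, composable R functions:

1. **Collagen organisation from 2D greyscale images** (e.g. second harmonic
   generation microscopy): collagen density (% of tissue covered), the
   five classic grey-level co-occurrence matrix (GLCM) texture features, and
   structure-tensor fibre coherency/orientation.
2. **Single-cell migration analytics** from tracked time-lapse positions:
   gap closing, the published filtering rules, per-track speed and
   straightness ratio, ensemble mean squared displacement (MSD),
   persistent-random-walk (PRW) fitting, motility classification and
   contingency testing, and SuperPlot-style donor-level inference.
3. **Relative qPCR quantification** (the 2^−ΔΔCT workflow): CT cut-off,
   housekeeping normalisation, fold changes, per-gene t-tests and volcano
   classification.
4. **Differential matrisome proteomics** from protein abundance tables:
   matrisome annotation, normalisation, per-protein one-way ANOVA with
   Benjamini–Hochberg control.

A synthetic-data generator produces ground-truthed fibrous images, cell-track
mixtures, CT plates and abundance tables, so the whole stack is testable
end-to-end with no microscopy or proteomics downloads.

## The statistics at the core

- **GLCM features.** From the joint probability p(i, j) that pixel pairs at a
  given offset have quantized grey levels (i, j):
  contrast = Σ (i−j)² p(i,j); entropy = −Σ p log₂ p (bits);
  correlation = Σ (i−μᵢ)(j−μⱼ) p / (σᵢσⱼ); IDM = Σ p / (1 + (i−j)²);
  ASM = Σ p². Pairs with either pixel outside the tissue mask are excluded.
- **Coherency.** With the structure tensor
  J = [⟨fₓ²⟩ ⟨fₓf_y⟩; ⟨fₓf_y⟩ ⟨f_y²⟩] averaged over the tissue,
  coherency = (λ_max − λ_min)/(λ_max + λ_min) ∈ [0, 1]; the dominant fibre
  direction is perpendicular to the dominant gradient direction.
- **Migration.** Straightness (directionality) ratio = start-to-end
  displacement / path length (1 = straight, 0 = returns to origin);
  MSD(τ) = mean |r(t₀+τ) − r(t₀)|²; a PRW fit uses the Fürth form
  MSD(τ) = 2S²P[τ − P(1 − e^(−τ/P))] for speed scale S and persistence P.
  Filtering follows the published tracking settings: tracks with ≤ 12 frames
  deleted, full 12-h duration required, steps faster than 100 μm/s rejected,
  gap closing up to 3 frames. Displacement thresholds 30/90 μm define
  sessile / motile / highly motile classes.
- **ΔΔCT.** 2^−[CT(GOI) − CT(avg HKG)] = 2^−ΔCT per sample; fold change is
  the ratio of group means of 2^−ΔCT, i.e. 2^−ΔΔCT. CT cut-off 35.
- **Differential abundance.** log2 fold change of group means of log2
  abundance; one-way ANOVA p; Benjamini–Hochberg step-up across proteins;
  significant iff |log2 fc| ≥ 1 and adjusted p < 0.05 (thresholds
  configurable).

## Worked example

```r
library(matriscope)

# a ground-truthed fibrous image: 30% coverage, fibres concentrated at 30 deg
img <- sim_fiber_image(image_size = 128, target_coverage = 0.3,
                       mean_orientation = 30, orientation_kappa = 8, seed = 42)
img
#> <fibrous_image> 128 x 128 px (1 um/px)
#>   ground truth: coverage 0.311, orientation 30.0 deg, kappa 8.00, 19 fibres

round(image_feature_panel(img)[, 1:9], 3)
#>   density_pct mean_intensity contrast entropy correlation   idm   asm coherency
#> 1      31.396         63.278  239.317   6.141       0.817 0.515 0.119     0.935
#>   orientation_deg
#> 1          33.901
```

The measured density (31.4%) matches the generator's ground-truth coverage
(31.1%), and the structure tensor recovers both the imposed anisotropy
(coherency 0.94 for a concentrated field) and the mean fibre orientation
(33.9° vs 30° imposed).

```r
# a qPCR plate with two spiked genes: MMP2 at CT shift -2.5, SPARC at +2
plate <- sim_ct_plate(genes = c("ACTB", "B2M", "RPLP0", "MMP2", "SPARC", "TIMP1"),
                      housekeeping = c("ACTB", "B2M", "RPLP0"),
                      group_delta_ct_shift = c(MMP2 = -2.5, SPARC = 2),
                      ct_noise_sd = 0.2, seed = 42)
ddct_workflow(plate)[, c("gene", "fold_change", "log2_fc", "p", "classification")]
#>    gene fold_change log2_fc      p classification
#>    ACTB      1.0770  0.1071 0.6642             ns
#>     B2M      0.8844 -0.1771 0.3611             ns
#>   RPLP0      1.0723  0.1007 0.2818             ns
#>    MMP2      7.0962  2.8270 0.0000             up
#>   SPARC      0.2542 -1.9758 0.0000           down
#>   TIMP1      1.0296  0.0420 0.8936             ns
```

A CT shift of −2.5 cycles corresponds to a true fold change of 2^2.5 ≈ 5.7;
with measurement noise of 0.2 cycles the workflow estimates 7.1 and classifies
the gene as upregulated, while the unshifted genes stay near fold change 1.

An end-to-end demo (simulate → analyse → report across all four workflows)
runs from the bundled config:

```r
cfg <- system.file("extdata", "demo-config.yaml", package = "matriscope")
run_pipeline(cfg, "demo-out")
pipeline_report("demo-out")
```

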