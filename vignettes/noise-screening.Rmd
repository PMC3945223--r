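---
title: "Screening for phenotype genes from single-cell noise: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for phenotype genes from single-cell noise: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisescreen)
```

## The idea

Genetically identical cells differ: a cell that happens to express a protein
above the population mean tends to stay above it for about one cell
generation, and cells likewise have persistent individual behaviours. If a
protein contributes to a phenotype such as motility, this slow
*individuality* in the protein should co-vary with the individuality in the
phenotype across cells of the same clone. `noisescreen` screens tagged-protein
clones for exactly this signal: it pools every tracked cell at every frame,
correlates protein features with motility features, and asks whether the
association is stronger than expected when the protein trace of one cell is
paired with the motility trace of another.

The screen's statistical engine makes three assumptions worth stating
explicitly:

1. **Pooling is informative because individuality is slow.** Frames of the
   same cell are far from independent; the effective sample size of a pooled
   correlation is governed by the number of cells and the individuality
   correlation time, not by the number of rows. All calibration is therefore
   done by permuting whole cell traces, never single frames.
2. **Cells within a field of view (FOV) share systematic effects**
   (illumination, focus, local density). The permutation null re-pairs
   traces *within* FOVs so that these batch effects are present in the null
   exactly as in the data.
3. **Associations are monotone.** Only linear (Pearson) and rank (Spearman)
   correlation are used; requiring both to exceed the threshold with the
   same sign guards against pathologies of either statistic alone.

## Protein features

Each cell image patch is background-subtracted (negative pixels clipped to
zero and counted), then quantized to 64 gray levels by linear min–max
rescaling of the in-mask intensities; a constant patch maps to level 0. The
gray-level co-occurrence matrix (GLCM) counts horizontally adjacent pixel
pairs with **both** pixels inside the cell mask — boundary pairs that would
mix cell and background are excluded — and is accumulated symmetrically
(each pair counted in both orders, the standard Haralick convention), with
an ordered mode available. From the normalised matrix `p(i, j)`:

- **contrast** `sum (i - j)^2 p(i, j)` — 0 for a constant image, large for
  punctate or sharply varying protein distributions;
- **texture correlation**
  `sum (i - mu_i)(j - mu_j) p(i, j) / (sigma_i sigma_j)` — the linear
  dependency of neighbouring gray levels, in [-1, 1], undefined when a
  marginal standard deviation is 0 (propagated as missing data, not as 0);
- optional **homogeneity** and **energy**.

**Protein level** is the summed in-mask fluorescence: the total amount of
tagged protein, which is less sensitive to outlier pixels than mean or
median intensity.

Design points that the method itself does not pin down, decided here once:

- *Quantization is per image* (min–max within the mask). No global
  calibration across movies is assumed; correlations are computed within
  clones, where per-image scaling only removes an irrelevant gain.
- *Rotation averaging* (`patch_features(rotations = 4)`) averages the
  texture features over the four 90° rotations of the patch. Horizontal-only
  GLCMs are already nearly isotropic for cell images; the averaged and
  unrotated values rank patches almost identically (checked by simulation in
  the test suite), so `rotations = 1` is the default.

## Motility features

- **Velocity**: Euclidean displacement of the cell centroid between
  consecutive frames, in µm per frame interval (the 20-min frame spacing is
  metadata, not folded into units).
- **Angle change**: the unsigned angle in [0°, 180°] between the
  displacement into frame *i* and the displacement out of it, assigned to
  the middle frame. Persistent motion gives low values. If either
  displacement is zero the angle is undefined (`NA`): a stationary cell has
  no direction, and scoring it 0 would fabricate persistence.
- **Aspect ratio**: major/minor axis of the second-moment ellipse of the
  mask, available as a shape control.
- Series are computed within maximal runs of consecutive frames; a tracking
  gap splits the series rather than bridging it.

## The screen

For each protein all (cell, frame) rows are pooled and the six comparisons
(level, contrast, texture) × (velocity, angle change) are computed with
Pearson and Spearman correlation, deleting missing values pairwise per
comparison (a row with undefined texture still contributes to the level
comparisons). Comparisons with fewer than `min_points` (default 50)
complete pairs are ignored.

**Null model.** Within every FOV the protein traces are reassigned to
motility traces by a random *derangement* (no cell keeps its own trace —
with two cells this is the swap), preserving frame alignment; single-cell
FOVs are dropped with a warning. Ten permuted datasets per protein give the
null distribution for each comparison and statistic.

**Candidate rule.** A comparison passes at threshold 0.15 when
`|R_Pearson| >= 0.15`, `|R_Spearman| >= 0.15`, and the two signs agree; a
protein is a candidate when any comparison passes. Sign agreement is not
strictly implied by "both statistics exceed the threshold", but mixing
signs would accept proteins with no coherent association, so it is part of
the rule here.

**FDR.** For each comparison, the estimate is the mean per-permutation
count of proteins passing the dual rule on permuted data, divided by the
count of real proteins passing it. Using the per-permutation mean keeps the
numerator an expectation over nulls of the same size as the data (rather
than pooling all permutations). The estimate is undefined when there are no
real hits and is capped at 1 (on pure-null data the ratio can fluctuate
above 1). Multiplicity across the six comparisons is handled by this
permutation FDR itself — the null is permuted per comparison — not by an
additional Bonferroni step.

**FOV robustness.** "The correlation holds in most FOVs" is implemented as:
for some passing comparison, strictly more than `majority_fraction`
(default 0.5) of the evaluable FOVs (those with at least `min_points`
pairs) individually show a Pearson correlation of the pooled sign with
`|R| >=` threshold. With fewer than two evaluable FOVs robustness is
undefined and the candidate is retained with an `NA` flag by default
(configurable). Both the majority fraction and the per-FOV threshold are
exposed because "most" is a judgement call.

**Enrichment.** Candidate lists are tested against annotation categories
(e.g. known-motility, subcellular localization; one primary localization
per gene) with the exact upper-tail hypergeometric probability
`P(X >= k)`; only over-representation is tested and p-values are reported
raw. Because a candidate can pass on several protein features, the feature
breakdown reports both an inclusive tally (a protein counts under every
feature it passes on) and an exclusive one (multi-feature proteins count
only as multi-measure).

## The synthetic-data generator

The generator exists so that every decision rule above can be tested
against known ground truth. Its defaults encode the study conditions: 4
FOVs × 15 cells per clone, 72 frames at 20-minute spacing (24 h), and
individuality lasting about one cell generation.

**Individuality.** Protein level and motility each get a slow component
modelled as a stationary Ornstein–Uhlenbeck process on the frame grid
(AR(1) with mixing coefficient `exp(-dt/tau)`, `tau` = 20 h) plus white
frame noise, scaled so the marginal variance is 1 and the slow component
contributes `individuality_var_frac` (default 0.4) of it. The trace
autocorrelation is then `frac * exp(-lag/tau)`, the simplest stationary
process with a tunable correlation time. The magnitude of slow versus fast
variance is not something the screen's method fixes; 0.4 was chosen once as
a realistic middle ground that reproduces a permutation-null spread
comparable to the reference analysis, and is not tuned per test.

**Coupling.** A planted positive draws the protein slow component as
`u_f = rho * u_m + sqrt(1 - rho^2) * w` with `u_m` the motility
individuality path and `w` an independent path — a linear combination of
independent stationary AR(1) processes with the same coefficient is again
stationary AR(1), so the two processes hold cross-correlation `rho` at
*every* frame. (Coupling only the initial conditions would decay as
`exp(-2t/tau)` and the pooled correlation would not reach its nominal
value.) The resulting pooled level~velocity correlation tends to
`rho * sqrt(frac_p * frac_m)` — e.g. 0.2 for `rho = 0.5` with fractions
0.4 — which is the oracle the tests check. Coupling is planted at the
individuality level because that is the signal the screen exploits.

**Motility.** Trajectories are persistent random walks: step lengths are
`speed_mean + speed_sd * (slow + fast)` (default 10 ± 3 µm/frame, clipped
at 0), and the heading turns between steps by a wrapped-normal angle whose
dispersion is `1/sqrt(turn_kappa * v/v_ref)` — fast cells turn less, which
produces the negative velocity/angle-change correlation observed in
migrating cells; `turn_kappa = 0` gives exactly uniform (isotropic)
turning. The turn out of a step is damped by that step's own speed so the
angle change assigned to frame *i* co-varies with the velocity at frame
*i*. `turn_kappa = 2` gives a pooled velocity–angle correlation of about
-0.2, a realistic magnitude with an unmistakable sign.

**Batch effects.** Each FOV draws an additive `N(0, 0.1)` offset applied to
protein features and a multiplicative `exp(N(0, 0.1))` factor on speed —
modest but non-ignorable systematic differences that create exactly the
within-FOV dependence motivating the within-FOV permutation.

**Patches.** Synthetic cells are a smooth radial intensity dome inside a
disk mask with sharp Gaussian puncta on top and 2% pixel noise. The dome
matters: quantization is per-image min–max, so a perfectly flat cell would
be rescaled pure noise — maximally rough — whereas a real "homogeneous"
cell is dominated by its smooth body. With the dome, spotless cells are
low-contrast and contrast grows with `n_spots * spot_amplitude`, as
intended.

**What the generator does not emulate** — and hence what passing tests do
not demonstrate about real data: cell divisions, deaths and tracking errors
(tracks are gapless unless truncation is switched on); segmentation noise
in masks; nucleo-cytoplasmic translocation events; heavy-tailed intensity
noise and bleaching drift; density-dependent motility and cell–cell
contact. The screen's robustness to those must come from the upstream
tracking software and from the FOV-robustness filter.

## Numerical choices and degenerate inputs

- Undefined values (zero-displacement angles, constant-image texture,
  constant-feature correlations) are explicit `NA`s that propagate into
  pairwise deletion; they are never silently replaced by 0.
- The texture correlation is clamped to [-1, 1] against floating-point
  overshoot; GLCM probabilities sum to 1 within 1e-12 by construction.
- Derangements are drawn by rejection sampling (expected < e draws for any
  FOV size; the two-cell case is deterministic).
- All generators are pure functions of (configuration, seed); the pipeline
  derives per-clone and per-permutation sub-seeds from one master seed, and
  reruns are byte-identical.
- Tests and the acceptance script run the screen at the study's native
  scale — 50–100 clones of 60 cells × 72 frames for calibration and
  recovery checks, thousands of cells for closed-form oracles — sizes
  chosen so the whole suite completes in a few minutes on one core.

## Known limitations

- Only monotone association is screened; a protein whose level relates to
  motility non-monotonically (e.g. optimum at intermediate expression) will
  be missed, as will couplings much faster than a cell generation.
- The FDR estimator is a ratio of counts; with very few real hits it is
  coarse, and with none it is undefined rather than 0.
- The printed false-negative behaviour of any such screen is substantial:
  a coupling of 0.3 with individuality fractions of 0.4 sits near the
  detection threshold (expected pooled R ≈ 0.12 < 0.15).
- Enrichment assumes one primary annotation per gene and tests categories
  independently.
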