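---
title: "Methods: navigational-affordance RSA on synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: navigational-affordance RSA on synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package computes

`navrsa` studies how the *navigational affordances* of a visual scene --
the directions in which an observer could walk, starting from the
bottom-center of the image -- could be encoded by populations of visual
responses. Because the empirical ingredients of such a study (stimulus
photographs, rater norming data, multi-run fMRI response patterns, a
pre-trained scene-classification network) are large and external, every
input here is produced by a synthetic generator with known ground truth,
and every downstream claim is tested against that ground truth.

The analysis chain is:

1. **Affordance model.** A rater path map is summed along one-degree
   angular bins radiating from the bottom-center origin, giving a 180-bin
   histogram over $[0^\circ, 180^\circ)$. The raw histogram is smoothed by
   penalized least squares in the discrete cosine basis with a
   generalized-cross-validation (GCV) penalty, then z-scored across bins.
2. **RDMs.** Representational dissimilarity matrices use squared Euclidean
   distances, $d_{ij} = \lVert x_i - x_j \rVert^2$, because they sum
   linearly -- the property multiple-regression RSA needs. On patterns
   z-scored across features (sample-SD convention) the identity
   $d_{ij} = 2(p-1)(1 - r_{ij})$ holds exactly, with $r$ the Pearson
   correlation and $p$ the feature count.
3. **Inference.** Spearman correlations between vectorized RDMs
   (off-diagonal upper triangle only); bootstrap standard errors by
   subsampling 90% of conditions without replacement, jointly across RDMs;
   permutation tests that permute one RDM's rows and columns by a single
   condition permutation, with $p = (\#\{R_{perm} \ge R_{test}\} + 1)/(N+1)$;
   Bonferroni correction; and a noise ceiling equal to the mean
   subject-to-group RDM correlation (subject included in the group mean --
   that is the quantity computed, not a leave-one-out variant).
4. **Commonality analysis.** For a target RDM regressed on predictors
   $X_1, X_2$ (OLS with intercept, raw distance vectors -- $R^2$ is
   scale-invariant so standardization would not change any reported value):
   $\gamma_1 = R^2_{12} - R^2_2$, $\gamma_{12} = R^2_1 + R^2_2 - R^2_{12}$,
   and the shared-variance percentage
   $SV = 100\,\gamma_{12}/(\gamma_{12} + \gamma_1)$, the share of $X_1$'s
   explained variance that is common with $X_2$. $\gamma_{12}+\gamma_1$
   equals $R^2_1$ algebraically, so $SV$ is undefined (and flagged) when
   $X_1$ explains nothing.
5. **In-silico experiments** on a small feedforward convolutional network:
   stimulus filtering (grayscale; Fourier-domain Gaussian high/low-pass at
   0.1 and 0.0075 cycles/pixel; cardinal and oblique 3x3 contour-energy
   kernels), horizontal-slice occlusion (41-px slices, stride 5 at the
   227-px reference size), occlusion-based receptive-field mapping (11x11
   random-value occluder, stride 3, absolute activation discrepancies),
   segmentation at 10% of the smoothed peak, t-SNE embedding of unit
   response profiles with silhouette-selected k-means, and navigability
   classification (minimum-distance and leave-one-out shrinkage LDA) with
   a unit-resampling null.

## The synthetic generators: what they emulate, and what they do not

**Scenes** are single-vanishing-point indoor views: textured floor and
wall planes, a dark floor--wall junction, bright door rectangles at the
planted opening azimuths, and brighter walkable path wedges on the floor.
The angular convention is fixed once for the whole package: angles are
measured at the bottom-center origin with 0 degrees pointing right and
90 degrees straight up the image. Setting `door_luminance` equal to the
wall luminance or `path_contrast = 0` removes, respectively, the
wall-borne or floor-borne affordance cues -- this is how the slice
experiment's "signal only in the lower half" construction is planted.
Rendering is deterministic; scenes are not photorealistic and contain no
clutter, objects, or lighting variation.

**Rater paths** are straight rays from the origin at a noisy draw around a
ground-truth azimuth, rasterized with anti-aliased bilinear weights,
normalized to unit mass per rater, superposed, and blurred with a small
mass-conserving Gaussian (sigma 2 px, reflected at the border) to mimic
mouse-trajectory spread. Raters are assigned to azimuths round-robin, so
an even rater count splits mass exactly across planted directions. Real
path-tracing data would contain curved paths, speed variation and
rater-specific biases; none of that is modeled, so passing recovery tests
says the *binning and smoothing machinery* is correct, not that the model
describes human norming behavior. A Monte-Carlo fact worth knowing: at
100 raters and 5 degrees of angular noise the smoothed histogram's peaks
localize the planted azimuths to within about 3 degrees (not 1-2; the
mode of a kernel-smoothed density over ~50 draws per direction jitters),
and exact localization holds at zero noise.

**Voxel cohorts** plant a target RDM exactly: classical MDS of the target
(eigenvalues below $10^{-10}$ of the maximum truncated) gives coordinates
$U\Lambda^{1/2}$; these are mapped into voxel space through a frame
$Y$ with $YY^\top = \Lambda$, equal column norms (Givens balancing) and a
mirrored $[Z, -Z]/\sqrt{2}$ sign structure. Consequently the noiseless
patterns have (a) squared-Euclidean RDM exactly equal to the target,
(b) identical variance in every voxel, and (c) zero mean across voxels for
every condition. Run-level i.i.d. Gaussian noise is added on top. The
construction needs `n_voxels >= 2 * rank`, slightly stronger than the
rank bound, because of the mirrored pairs.

An analytical point that shaped the pipeline: the full normalization
chain for raw fMRI patterns (z-score each voxel across conditions within
run; average runs; z-score each condition across voxels) maps *any*
pattern set to the geometry of angles seen from the condition centroid --
column z-scoring centers the centroid at the origin and row z-scoring
then divides each condition by its distance from it. For real scanner
data those steps remove gain and baseline nuisance and the residual
radial distortion is the accepted price; for the calibrated synthetic
cohorts (no gain structure, equal voxel variances by construction) the
distortion is pure loss, and no generator can plant a generic RDM through
it (only "spherical" RDMs survive). The pipeline therefore computes
synthetic-cohort subject RDMs from run-averaged raw patterns, while
`normalize_fmri()` implements and tests the full chain for fMRI-style
input. With that choice, a zero-noise cohort reproduces the planted
affordance RDM with Spearman $\rho = 1$ and recovery decays monotonically
with noise.

**Labelled activation sets** give a sparse informative subset of units
class-separated means ($\pm$ effect/2, unit noise SD), each informative
unit with its own random response polarity. Polarity matters: a
common-polarity shift is exactly the component that z-scoring across
units removes, so a single-polarity construction is invisible to the
minimum-distance classifier by design, not by failure. Defaults
(`n_units = 2000`, `n_informative = 50`, `effect_size = 2`) emulate a
high-dimensional convolutional layer in which affordance-informative
units are a small fraction -- with a dense informative fraction every
random 50-unit subset saturates and the resampling percentile becomes
degenerate.

## The mini network

The network is a configurable stack of valid convolutions, rectification,
local max pooling, local response normalization
($b = a/(k + \alpha \sum a^2)^{\beta}$ over a channel neighborhood;
$k = 2$, $\alpha = 10^{-4}$, $\beta = 0.75$, $n = 5$ -- the standard
constants of the architecture family it imitates) and dense layers.
The default desk-scale configuration is three convolution blocks (max
pooling and normalization after the first two) and one dense block on
64x64 grayscale input; it preserves the hierarchy the experiments probe
while a forward pass costs ~5 ms. Weights are seeded Gaussians scaled by
$1/\sqrt{\text{fan-in}}$ and quantized to float32 at build time so that
the float32 on-disk weight store round-trips bit exactly. Inputs of other
sizes are rescaled bilinearly. The network is untrained: analyses that
depend on *trained* feature detectors (e.g. the specific visual motifs of
real unit clusters) are out of reach, and the per-layer PCA reduction
(45 components, capped at the available rank) is applied to it just as it
would be to a trained model, because low-variance units otherwise dilute
the distances. Any object mapping an image batch to named activation
matrices can replace the network through `activation_adapter()`, which is
also how a pre-trained model's activations would be plugged in.

## Numerical choices

- **Smoother.** Orthonormal DCT-II basis (reflective boundaries);
  attenuation $1/(1 + s\lambda_k^2)$ with $\lambda_k$ the
  second-difference eigenvalues; $s$ selected by GCV over 61 log-spaced
  points in $[10^{-6}, 10^{6}]$. No robust reweighting iterations: the
  synthetic histograms have no outlier structure, and exact numerical
  agreement with any particular published smoother implementation is not
  claimed.
- **Angular binning.** Bin $k$ covers $[k, k+1)$ degrees; origin-row
  pixels go to bins 0/179 by horizontal sign; the origin pixel is
  excluded. Pixels whose angle is an exact bin edge (the diagonals) sit
  in the right-hand bin, which is why mirror-symmetry checks exclude
  them.
- **z-scores** use the sample ($n-1$) denominator everywhere, making the
  distance/correlation proportionality constant exactly $2(p-1)$.
- **Zero-variance features** (dead voxels/units) are dropped with a
  message, never imputed; degenerate normalized histograms are encoded as
  all-zeros with a flag so RDM construction stays total; SV with
  $R^2_1 = 0$ is flagged undefined rather than returned as NaN.
- **Ties.** Spearman uses average ranks; the minimum-distance classifier
  breaks exact distance ties toward the alphabetically first label (with
  a message); discrepancy-map peak ties break toward the lowest row, then
  column.
- **LDA.** Pooled covariance with Ledoit-Wolf shrinkage toward the scaled
  identity; the intensity is estimated once per unit subset on the full
  data and reused across leave-one-out folds (fold statistics themselves
  are exact sufficient-statistic downdates; re-estimating the intensity
  inside every fold is quadratically more work and does not measurably
  change it). Equal class priors: the design is balanced, and
  training-proportion priors would systematically vote against each
  held-out image, whose class is always the training minority.
  Cross-validated accuracies at null carry a small (~1 point)
  self-exclusion pessimism and replicate variance above binomial; chance
  calibration is therefore asserted on means over replicates.
- **Slice positions** advance by the stride and append one flush-bottom
  position when the last regular position misses the bottom row, so both
  the 38-position regular grid and the 39th flush position are available
  (227/41/5 geometry). Slice occluders are mid-gray to minimize spurious
  edge energy.
- **Clustering.** t-SNE (perplexity $\min(15, (n-1)/3)$, exact mode at
  these sizes) followed by k-means with 20 restarts over $k = 2..10$;
  the silhouette criterion picks $k$, with a fallback to $k = 1$ when the
  best silhouette is below 0.25 (the silhouette is undefined at $k = 1$,
  so the rule needs an explicit floor). Identical unit responses are
  flagged degenerate instead of embedded.
- **Permutation p-values** use the $(+1)/(N+1)$ convention, so the
  smallest attainable p is $1/(N+1)$; resampling-null percentiles use the
  strictly-less rank, which reproduces the "99th percentile with one
  exceedance in 5000" convention.

## Problem sizes

The end-to-end pipeline default is 20 scenes, 8 subjects x 2 runs x 60
voxels, 500 bootstrap/permutation/resampling iterations, a 64x64-input
network, receptive-field mapping on 64x64 renders with an 11x11/stride-3
occluder, and classification over 100 images x 2000 units -- chosen so a
full run completes in well under a minute on one core and is exactly
reproducible from its seed (stochastic stages derive child seeds from the
master seed). Per-operation defaults are larger (5000 iterations) and are
what a standalone analysis would use.

## Known limitations

- The untrained network's "receptive fields" reflect random filters; the
  clustering machinery is validated on planted response families, not on
  semantically meaningful motifs.
- The rater-path model is a stand-in; no claim is made about the
  statistics of real norming data beyond what the binning machinery
  requires.
- The fMRI noise model is i.i.d. Gaussian at the run level; no
  autocorrelation, voxel covariance or session drift is modeled, so noise
  ceilings here quantify the generator's noise parameter, not scanner
  realism.
- Headline empirical values from studies of real data (specific
  correlations, classification accuracies, shared-variance percentages)
  depend on real stimuli, real brains and trained weights; nothing here
  reproduces them, and the test suite deliberately asserts properties and
  planted-truth recovery instead.
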