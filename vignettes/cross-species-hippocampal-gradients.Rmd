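---
title: "Methods: cross-species hippocampal connectivity gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species hippocampal connectivity gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippograd)
```

## The analysis problem

The hippocampus can be analytically unfolded into a two-dimensional
flatmap whose intrinsic axes — anterior-posterior (AP, the long axis) and
distal-proximal (PD, the short axis, running from the subicular complex
toward the dentate gyrus) — are geometrically matched across primate
species. On that shared coordinate system, resting-state functional
coupling between hippocampal vertices and cortical parcels can be compared
quantitatively between species. `hippograd` implements the full analysis
chain:

1. **Connectivity**: per-subject Fisher-z correlation matrices between
   hippocampal vertex and cortical parcel time series, after global-mean
   regression; group averages per species.
2. **Gradients**: normalized-angle affinity kernels and diffusion-map
   embedding of connectivity matrices, giving hippocampal gradients,
   cortico-cortical gradients, and a *joint* two-species embedding in
   which the cortical parcels of both species are stacked as items over
   their shared hippocampal fingerprint space.
3. **Gradient matching**: LASSO feature selection and univariate OLS fits
   of the joint gradient against cortico-cortical gradient maps, with
   spin-test spatial permutation nulls and a threshold-Dice combination
   analysis over map pairs and triplets.
4. **Dual regression**: the two binned hippocampal axis regressors are
   projected through the concatenated cortex + hippocampus data in two
   least-squares stages, producing per-subject cortical AP and PD coupling
   maps, which in turn act as coordinates for reprojecting cortical
   locations into the 2D hippocampal space; species are compared per
   region with exact two-sample Kolmogorov-Smirnov tests on subject-level
   ROI means.
5. **Homology index**: per-parcel median correlation of hippocampal
   connectivity fingerprints with the other species' parcels inside a
   geodesic searchlight around the registered location, summarized per
   cortical network.
6. **Subfield metrics**: categorical subfield flatmaps reduced to per-row
   extent profiles, compared by mean row-wise cosine, with relative
   subfield size ratios and percentage change between species.

Everything runs end-to-end on synthetic two-species data with planted
structure (`simulate_two_species()`), so every stage can be validated
against a known ground truth.

## The synthetic generator

The generator is a latent-factor model chosen to reproduce the statistical
structure the pipeline is designed to detect, with one factor per cortical
network plus two hippocampal axis factors.

* **Axis factors.** Hippocampal loadings are `2*ap_coord - 1` and
  `2*pd_coord - 1` — the AP and PD axes themselves. Cortical parcels load
  on the same factors through smooth unit-sphere maps
  (`axis_coupling_sd * z` and `axis_coupling_sd * x`), which are the
  planted cortical axis-coupling maps that dual regression should recover.
* **Network factors.** Network `k` couples to the hippocampus with a
  Gaussian bump along the AP axis centred at the network's mean polar
  angle divided by pi: networks tile the cortical sphere from pole to
  pole, and their preferred hippocampal positions sweep the long axis in
  step. This makes the first hippocampal gradient an AP gradient, as in
  real data. Cortical parcels load on network factors through a soft
  spatial membership kernel in polar angle (`membership_sigma`, default
  0.25 rad), dominated by the parcel's own network but mixing smoothly
  into neighbouring networks.
* **Species divergence.** The two species share all loadings except that
  one network's hippocampal coupling row is attenuated by
  `(1 - divergence)` in species B. The default divergent network is the
  most anterior-coupled one — the stand-in for the default-mode network,
  whose cross-species reconfiguration is the scientific contrast of
  interest.

The soft membership kernel deserves a note, because a harder design (each
parcel loading only on its own network) looks simpler. With hard loadings,
hippocampal fingerprints are step functions of cortical position: two
neighbouring parcels on opposite sides of a network border can have
uncorrelated or even anti-correlated fingerprints. A searchlight homology
index computed on such data is then systematically depressed wherever
searchlights straddle borders — for *identical* generative processes in
the two species — which contradicts the basic requirement that
species-contrast statistics sit at their null value under exchangeable
species. Real connectivity transitions are smooth at parcel scale, and the
soft kernel reproduces that. With it, the network-mean homology spread
under exchangeable species (divergence 0) is below 0.1 across seeds, while
an attenuated network still drops far below the rest (gap ≈ 0.25-0.3 at
divergence 0.8).

Latent scores are drawn independently per subject and species (different
individuals), optionally AR(1)-correlated in time (default 0: white, since
scanner TR and autocorrelation are irrelevant to the statistics under
test), and empirically centred and whitened within subject. The whitening
makes sample second moments match the planted ones exactly at finite
length, so noiseless exchangeable species produce *identical* mean
connectivity matrices rather than merely similar ones.

Default study conditions: 200 parcels and 7 networks per species, a
32 x 16 flatmap (512 vertices), 10 subjects per species, 600 time points,
observation noise SD 1, divergence 0.8, `network_coupling` 2 and
`axis_coupling_sd` 0.5. The coupling amplitudes were set so that
connectivity estimation noise at T = 600 does not re-introduce spatially
structured attenuation of fingerprint correlations; at these settings the
first hippocampal gradient correlates with the planted AP loading at
|r| ≈ 0.98 and dual regression recovers the planted cortical axis maps at
|r| ≈ 0.998.

What the generator does *not* emulate: haemodynamics, motion and scanner
noise spectra, volumetric geometry, hemispheres (the pipeline is
hemisphere-agnostic and runs per labelled structure), and any genuine
cross-species misregistration — the parcel correspondence is the identity,
standing in for a myelin-based surface registration that is consumed, not
computed, by the homology module. Passing tests therefore demonstrate the
*statistical machinery*, not robustness to real acquisition artefacts.

## Key parameters and numerical choices

* **Fisher z clipping.** Correlations are clipped to `|r| <= 1 - 1e-7`
  before `atanh`, keeping self-correlations finite.
* **Affinity sparsification.** Before the normalized-angle kernel, the
  smallest 90% of entries in each fingerprint row are zeroed
  (`sparsity = 0.9`, configurable), mirroring the common default of
  gradient-embedding toolboxes. The kernel is
  `1 - acos(cosine)/pi`, symmetrized, with unit diagonal.
* **Diffusion embedding.** Degree normalization with `alpha = 0.5`,
  row-normalization to a Markov operator, eigendecomposition via the
  symmetric conjugate; the trivial constant eigenvector is dropped and
  components are scaled by `lambda/(1 - lambda)` (automatic diffusion
  time). A dense solver is used up to 2000 items and a subspace-iteration
  solver (Ritz-residual tolerance 1e-10) above; the two routes agree to
  1e-6 on component values in tests. Sign convention: each component is
  flipped so its largest-magnitude element is positive. Disconnected
  affinity graphs are rejected with the component sizes listed.
* **LASSO penalty.** `penalty = 0.1` on the scikit-learn `Lasso(alpha)`
  scale, i.e. the objective `(1/2n) RSS + penalty * ||b||_1` with
  standardized inputs; fitted by glmnet along a short warm-start path.
  Maps are rank-gaussianized (`qnorm((rank - 0.5)/n)`, average ranks for
  ties) before any regression; OLS fits use the gaussianized maps too, for
  consistency between the two fit types.
* **Spin test.** Uniform SO(3) rotations (QR of a Gaussian matrix with
  sign fix and determinant correction) applied to the *candidate* map's
  coordinates, nearest-neighbour re-assignment, two-sided add-one p-value
  `(1 + #{|r_null| >= |r_obs|})/(n_perm + 1)`. Rotating the candidate
  rather than the target is symmetric in expectation; multiple candidates
  are Bonferroni-corrected (the conservative default when the correction
  procedure is otherwise unspecified).
* **Dice thresholding.** Binarization keeps strictly-greater-than-quantile
  elements (ties at the quantile excluded); combinations of candidate maps
  use the union of their binary masks; the threshold grid is 0.70-0.95 in
  steps of 0.05.
* **Axis design.** 16 AP bins and 8 PD bins; bin `i` of `B` carries
  `-1 + 2i/(B - 1)`, assigned by nearest coordinate when row counts do not
  divide evenly. Axis columns are mean-centred within the hippocampal
  block (a no-op for balanced bins), which makes the design exactly
  orthogonal; cortical elements stay 0.
* **Reprojection.** Each axis map is linearly rescaled so its 10th and
  90th percentiles map to 0 and 1, with outside values clipped —
  winsorized rescaling, so extreme vertices influence neither the fit nor
  the display range. The reprojection is invariant to positive affine
  transforms of the maps.
* **KS comparison.** The subject-level summary for a region is the mean
  reprojected coordinate of its elements along the chosen axis; with 10
  subjects per species this gives an exact two-sample p-value. The default
  correction count is (#ROIs x #axes).
* **Homology searchlight.** Distances are great-circle on the registration
  sphere, not chords. The radius is a required, never hard-coded setting;
  the synthetic default of 0.45 rad yields roughly 8-15 neighbours at 200
  parcels. The median is over signed correlations. Parcels with
  zero-variance fingerprints or empty searchlights are flagged missing and
  excluded from network means with a warning.
* **Subfield similarity.** Rows of the extent profile are compared by
  cosine distance `1 - cos`; the reported similarity is
  `1 - mean(distance)`. Note this is algebraically identical to the mean
  row-wise cosine, so the two natural readings of a "similarity metric"
  derived from mean cosine distance coincide and there is nothing to
  choose between. Profiles with unequal row counts are aligned by linear
  interpolation onto the smaller count.

## Interface

The package is a library in the Bioconductor style: the exported functions
are the interface, `run_config()` + `run_pipeline()` provide the
end-to-end driver with validated configuration and provenance sidecars,
and TSV/JSON are the on-disk formats (17-significant-digit TSV tables
round-trip doubles bit-exactly). Flatmap maps can be exported as PNG heat
maps at grid resolution; surface-mesh formats are out of scope here, and
no shell entry point is shipped.

## Validation strategy and problem sizes

The test suite validates each operation against independent oracles:
closed forms where they exist, brute-force loops for aggregations, a dense
non-symmetric eigendecomposition of the explicit transition matrix for the
embedding (100 random connected affinities up to n = 50, component
correlation > 0.999), exact linear-algebra identities for dual regression,
and calibration simulations for the inferential tools (spin-test type-I
rate on 200 smooth null map pairs; KS false-positive rate over 200
exchangeable-species simulations; LASSO single-predictor selection over
100 draws). Planted-recovery checks run at the default study conditions;
the multi-seed checks (divergent-network detection, null calibrations) use
20-200 seeds at sizes chosen so the full suite completes in about a
minute on one CPU. `scripts/acceptance.R` recomputes the headline
quantities from scratch at the default conditions.

## Known limitations

* The homology index presumes the searchlight radius is small relative to
  the scale of genuine fingerprint variation; at radii approaching the
  inter-network distance it conflates divergence with spatial remapping.
* The joint embedding aligns species through matrix concatenation only; no
  Procrustes or other alignment variants are provided.
* The spin test assumes maps live on a full sphere; masked or hemispheric
  maps would need a masked-rotation variant.
* The KS regional comparison tests location differences of ROI means; it
  is blind to within-ROI redistribution that leaves the mean unchanged.
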