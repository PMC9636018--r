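---
title: "Spatial null models for comparing brain maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial null models for comparing brain maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinmaps)
```

## The problem

Scalar brain maps — cortical thickness, receptor binding, metabolic
uptake, functional gradients — are spatially smooth: neighbouring vertices
carry nearly identical values. When two such maps are correlated across
thousands of vertices, the effective number of independent observations is
orders of magnitude smaller than the vertex count, so a parametric test or
an i.i.d. permutation test treats redundant samples as evidence and
produces wildly inflated significance. The remedy is to test the observed
similarity against surrogate maps that *preserve the spatial
autocorrelation* of the data while destroying its specific topography.
`spinmaps` implements three families of such surrogates and the
comparison workflow around them.

## Data model

A hemisphere is a triangulated unit sphere (`spherical_mesh`); maps are
per-vertex values with a validity mask (`scalar_map`), where `mask =
FALSE` encodes the medial wall or other missingness, stored as NaN on
disk (GIFTI / NIFTI) and excluded from every statistic. Volumes are
`volume_grid`s whose valid voxels have world coordinates through the
affine. Distances are Euclidean chords on the unit sphere everywhere —
chord distance is monotone in geodesic distance on a sphere, cheap, and
sufficient for nearest-neighbour queries, variogram binning and smoothing
kernels; a geodesic option would change none of the statistics
qualitatively and is left as an extension. Hemispheres are processed as
separate meshes; whole-brain maps are (left, right) concatenations.

## The spin permutation

For vertex data the null model applies a random rotation `R` to the mesh
coordinates `V` and re-indexes the map so that every vertex receives the
value of the nearest rotated vertex (`V_rot = V R`). Rotations are drawn
Haar-uniformly over SO(3) by QR decomposition of a Gaussian matrix with
sign correction; the sampled angle distribution is testable against the
closed-form Haar density `(1 - cos t) / pi`. The opposite hemisphere uses
the conjugated rotation `F R F` with `F = diag(-1, 1, 1)`: reflection
about the mid-sagittal plane, which preserves the anterior–posterior axis
so left and right surrogates stay anatomically congruent. (The phrase
"mirrored across the anterior–posterior axis" admits a second reading —
a half-turn *about* that axis — but the sagittal conjugation is the
standard realization and is what we implement.)

Vertices whose assigned source vertex is masked become `NA` in the
surrogate: data are neither invented nor silently dropped, and the
comparison stage uses pairwise-complete locations identically for the
observed and surrogate statistics. Ties in every nearest-neighbour query
resolve to the lowest index, making all outputs deterministic.

Because the permutation induced by a rotation depends only on the mesh,
`spin_indices()` precomputes an index matrix that any number of analyses
on that mesh can reuse; `spin_vertex()` accepts it directly, and
ensembles are content-addressed (`cache_key`) so cached and fresh results
can be verified identical.

### Parcellated variants

For parcel-level data the parcel values are projected to vertices, spun,
and re-aggregated by the vertex mean (mode would be the alternative for
label-valued data; the package aggregates continuous values only). The
three strategies differ in their treatment of parcels whose rotated
sources land on the medial wall: `discard` leaves a parcel `NA` when every
contributing vertex is missing; `ignore` removes medial-wall vertices
from the mesh before rotating, so missingness never arises; `nearest`
fills an `NA` parcel from the nearest parcel (centroid chord distance)
that has data. Donors are the originally non-missing parcels — filling is
not chained, so results do not depend on the order in which missing
parcels are visited.

## Variogram-matching surrogates

Volumes have no sphere to rotate, so the generative route is the default
there: permute the valid values (destroying autocorrelation), then smooth
and rescale to reintroduce it, emitting

    y = |beta|^(1/2) * x'_sm + |alpha|^(1/2) * z,   z ~ N(0, 1)

where `x'_sm` is the permuted map smoothed by a Gaussian kernel over the
distance structure and `alpha`, `beta` come from a least-squares fit
between the empirical variograms of the original and the smoothed
permuted data. The empirical variogram uses 25 bins spanning distances up
to the 0.25 quantile of pairwise distances by default; spaces with more
than 10^4 locations have their pairs subsampled (seeded, 10^5 pairs by
default) — an explicit approximation knob.

Two numerical choices matter here, and both were made after the naive
version demonstrably failed:

* **The fit is variance-constrained.** A plain ordinary-least-squares fit
  of `gamma_orig ~ beta * gamma_sm + alpha` often returns a slightly
  negative intercept, and the `|alpha|^(1/2)` in the transform then turns
  a negative nugget into *positive* noise variance, visibly inflating the
  short-distance bins. Moreover the final step — rescaling each surrogate
  to the source mean and variance, which is what makes surrogate moments
  exactly comparable — multiplies the whole variogram by
  `var(x) / var(y)`, spoiling the fit whenever the OLS solution implies a
  variance different from the source's. We therefore minimize the same
  residual subject to `beta * var_sm + alpha = var_orig` and
  `0 <= alpha <= var_orig`: the nugget stays physical and the rescaling
  becomes a no-op in expectation. On ico4 Gaussian-field sources this
  roughly halves the mean bin-wise deviation between source and surrogate
  variograms.
* **The candidate kernel ladder is dense.** The smoothing scale is chosen
  per surrogate by residual sum of squares over a candidate set,
  defaulting to {2, 5, 10, 15, 20, 30}% of the maximum pairwise distance.
  A sparser ladder (e.g. {2, 5, 10, 20}%) leaves a gap exactly where
  smooth cortical maps live; since selection is by fit quality, a denser
  ladder is strictly better and costs only memory for the precomputed
  kernels. Both the ladder and the bin settings are user-configurable.

A degenerate surrogate (zero-variance smoothed permutation at every
candidate scale) raises a numerical error naming the surrogate index
rather than silently emitting noise.

## Moran spectral randomization

The third family works in the eigenbasis of the doubly centered spatial
weight matrix (Moran eigenvector maps). The map's coefficients in that
basis are mixed by random orthogonal rotations *within groups of
near-equal eigenvalues* (relative tolerance `1e-8`; on symmetric meshes
these groups are the degenerate harmonic subspaces, elsewhere they
degenerate to random sign flips). Group-wise mixing preserves the squared
coefficient mass per eigenvalue, hence the map's variance exactly and its
Moran's I up to the grouping tolerance, while randomizing the
topography. Weights come from `build_weights()`: binary triangulation
adjacency or union-symmetrized k-NN inverse distance; both symmetric,
zero-diagonal, and checked for connectivity.

## The comparison workflow

`compare_maps()` computes the similarity statistic (Pearson's r by
default; any pure function of two equal-length vectors can be substituted)
on the observed pair and on each surrogate substituted for the nulled map
(the source map by default, matching the usual workflow of spinning the
source), and returns the two-sided permutation p-value with the add-one
estimator `(1 + #{|null| >= |obs|}) / (1 + n_null)`, which never returns
zero. `compare_many()` runs one source against many targets: each pair is
first brought into a common space by the lower-resolution rule — the
higher-resolution map (by valid-vertex count; ties favour the first
argument) is resampled down by nearest neighbour so no data are ever
artificially upsampled — then nulls are generated (or fetched from cache)
in the comparison space, and p-values are corrected across targets with
Benjamini–Hochberg (the conventional realization of false-discovery-rate
correction; correction is applied per source-map family). Defaults follow
the conventions of the field: 1,000 surrogates, spin tests for surface
spaces, variogram matching for volumetric spaces. Surface-to-volume
resampling of continuous data is refused outright rather than
approximated.

Resolution, for the lower-resolution rule, is operationalized as the
valid-location count; mean inter-vertex spacing would be the alternative
for meshes of very different uniformity, but for the near-uniform
icosphere family and the standard neuroimaging templates the two orders
agree.

## Synthetic data, and what the tests do and do not show

Every statistical claim in the package is exercised on seeded synthetic
data; nothing requires a download. `sample_grf()` draws white Gaussian
noise and smooths it with a Gaussian kernel (truncated at three times its
scale) over chord distances, standardizing to mean 0, variance 1:
autocorrelation grows monotonically with the smoothing scale.
`sample_grf_pair()` mixes a shared smoothed field with an independent one
using weights `(r, sqrt(1 - r^2))`, giving pairs whose expected
correlation is exactly `r` with identical autocorrelation structure.
`sample_medial_wall()` masks a spherical cap around a random vertex;
`sample_parcellation()` builds chord-distance Voronoi parcels around
random centres. Study conditions used throughout the test suite: ico4
meshes (2,562 vertices), smoothing scale 0.3 (chord units on the unit
sphere), 300 surrogates per test, 200 independent pairs for type-I
calibration, 100 pairs at true r = 0.6 for power.

These generators emulate the *second-order* structure of real cortical
maps — smoothness, masked medial wall, parcel structure — but not their
asymmetries: no cortical folding geometry, no heavy-tailed or bimodal
value distributions, no spatially varying (non-stationary)
autocorrelation, and hemispheric symmetry is exact rather than
approximate. Passing calibration here therefore shows the null models are
correct for stationary Gaussian fields on a sphere; on real data with
non-stationary autocorrelation the spin test is known to remain valid
(it permutes the actual map) while generative surrogates match only the
stationary summary they fit.

## Reproducibility

Every random quantity flows through one seeded generator
(Mersenne-Twister with inversion sampling) inside a scope that restores
the caller's RNG state; child seeds are derived from the master seed, so
every ensemble, file and results table is bit-identical across reruns
with the same seed and configuration — including cache-hit paths, which
are verified by content digest. The command-line layer (`simulate`,
`nulls`, `compare`) logs its resolved configuration, writes JSON
provenance (framework, seed, n_null, digests) next to every output, and
uses exit codes 0 / 2 / 3 / 4 for success / usage / format / numerical
failure.

## Known limitations

* Dense distance, kernel and eigenvector matrices limit meshes to roughly
  ico5–ico6 (10⁴ locations) in memory; beyond that the variogram
  machinery subsamples pairs, but smoothing kernels and Moran bases would
  need sparse implementations.
* The spatial lag model sometimes listed alongside these frameworks is
  not implemented; the framework enum is extensible.
* Label (parcellation) resampling is strict nearest-neighbour; barycentric
  or area-weighted resampling of continuous data is out of scope.
* GIFTI support covers the scalar/geometry/label subset of the format
  used for cortical surface data (ASCII, Base64, gzip-Base64 encodings;
  float32/float64/int32/uint8 types), not the full specification.
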