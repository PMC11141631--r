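---
title: "Quantifying collective cellular alignment: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collective cellular alignment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellnematics)
```

## The problem this package addresses

Cultured myoblasts (and many other elongated cell types) behave collectively
like a two-dimensional nematic: each cell defines an axis of elongation, not
a direction, and neighboring cells align. On mechanically anisotropic
substrates this local alignment can grow into millimetre-scale order, driven
first by collective polarization of proliferating cells and later by
correlated cell–matrix flows during fusion. Quantifying that process takes a
pipeline: extract an orientation field from microscopy images, summarize
its order and spatial structure, measure collective flow by particle image
velocimetry (PIV), follow single-cell migration through nuclear tracking,
and find the half-integer topological defects where order breaks down. This
package implements that pipeline, together with a synthetic-data generator
that makes every stage testable with no external data.

All angles are in degrees. Nematic (axial) angles live in `(-90, 90]` and
are identified modulo 180; migration and velocity directions live in
`(-180, 180]`. Images are matrices indexed `[row, col]`, `x` is the column
coordinate, and the substrate director is assumed pre-rotated to 0 degrees.

## Orientation fields

`structure_tensor()` computes Gaussian-derivative gradients (scale 1 px),
forms the tensor products, and smooths them with a Gaussian window whose
scale is the analysis `sigma` (10 px for myotube-scale texture at 10x, 20 px
at 20x; of order the feature width in general). The orientation is the
eigenvector of the *smaller* eigenvalue — the structure direction,
perpendicular to the dominant gradient: `theta = 0.5 atan2(-2 Jxy, Jyy -
Jxx)`. Coherency, the eigenvalue contrast in `[0, 1]`, measures how
well-defined the local axis is. The eigenvector convention is locked by a
stripe-recovery test rather than by bit-level comparison with any particular
implementation, since only the window scale is a published setting; the
derivative kernel is a free choice and correctness is defined by recovering
known textures to within 1 degree.

`sample_grid()` reduces the pixel map to a lattice (grid 100 or 50 px for
order statistics; 5 px for defect work) using the coherency-weighted
doubled-angle mean per cell, masking cells whose mean coherency falls below
the 25% gate. Doubled-angle averaging is used everywhere an axial mean is
needed: arithmetic means of axial angles are ill-defined at the
±90-degree wrap.

## Order statistics

The 2D orientation-order parameter of a set of vectors is

S = | < 2 cos²(θ − θ̄) − 1 > |,

with θ̄ the doubled-angle circular mean of the set. With that reference, S
equals the doubled-angle resultant length exactly — the package computes the
difference form and the tests verify the closed-form identity to 1e-12.
S is 1 for perfect alignment, 0 for isotropy, and about n^(-1/2) for n
independent angles. `local_order_map()` applies the same statistic to
sliding 4x4-vector windows (windows straddling the border are dropped, not
padded), and `spatial_disorder()` reports the percentage of windows with
S < 0.5.

The spatial autocorrelation of an angle lattice is

C(d) = 2 < cos²(θ(r) − θ(r+d)) > − 1,

averaged over all unmasked pairs of grid points with the same separation d
(masked vectors are excluded pairwise, never imputed). The correlation
length ξ is the x-intercept of an ordinary least-squares line through the
first 10 points of C(d), converted to micrometres by the pixel size. If the
slope is non-negative or the intercept extrapolates past the largest sampled
distance, ξ is clamped to that distance and flagged degenerate — a uniform
field has no finite correlation length and the flag, not a number, is the
result.

**Distance classes.** Pairs are grouped by their *exact* Euclidean
separation, keyed on the integer dy² + dx², so grouping involves no
floating-point tolerance; on a square lattice the d = 1 class is exactly the
4-neighbour pairs (a 0/90 checkerboard gives C(1) = −1, an identity the
tests pin down). A variant that rounds distances to the nearest multiple of
the grid spacing is available (`binning = "grid"`); it merges the sqrt(2)
diagonals into the d = 1 class and changes ξ by a few percent on smooth
fields. Exact classes are the default because the averaging brackets are
defined over pairs "with the same distance".

Velocity fields reuse this machinery verbatim: vector angles are wrapped to
the nematic range before entering C(d), so the velocity correlation length
ξ_vv is the same construction applied to flow directions. A signed variant
(correlating full directions rather than axes) is available in
`flow_statistics(mode = "signed")` but is not the default.

## PIV

`piv_multipass()` chains windowed FFT cross-correlation passes coarse to
fine (the published settings are, e.g., 600/300, 300/150, 150/75 px
window/step; the synthetic tests use geometrically similar but smaller
windows), with each pass's median-smoothed field interpolated onto the next
lattice as an integer predictor. Within a window the correlation is
zero-mean normalized and divided by the per-lag overlap area — without that
normalization the zero-padding taper drags subpixel peaks toward zero by up
to 0.2 px. The peak is refined by a 3-point Gaussian fit per axis (parabolic
fallback when a log is undefined), windows with a correlation peak ratio
below 1.2 are flagged invalid, and the outermost ring of vectors is always
flagged: the original workflow rejected boundary artifacts by hand, which is
not reproducible, so the rejection is automated as "drop the ring". Frames
contaminated by global stage shifts (after medium changes) are supplied
explicitly as `artifact_frames` and dropped from both the speed and ξ_vv
series. Window deformation is deliberately omitted: the flows of interest
are a few micrometres per hour, far below the window scale.

Subpixel precision is rated on speckle (tracer-like) image pairs from
`gen_speckle_image()`, which have sharp isotropic correlation peaks; on
those the recovery bias is below 0.05 px and the RMS below 0.2 px across
shifts of 0.1–8 px at window 64. Filament textures have broad anisotropic
correlation peaks along the filament direction and no estimator of this
family reaches that precision on them at small windows; integer-pixel
recovery still holds there and is tested separately.

## Tracking and migration

Nuclei are detected by multi-scale Laplacian-of-Gaussian blob detection with
quadratic subpixel refinement; the detected scale maps to a Gaussian-FWHM
equivalent diameter and detections outside 6–30 um are excluded, mirroring
the nuclear size gate of the original workflow (whose trained-network
detector is out of scope here). The scale sweep extends 40% beyond the gate
so oversized blobs are found at their true scale and rejected rather than
clipped into range. Linking is greedy mutual-nearest-neighbour under a
maximum displacement, with no gap closing — the fixtures are non-crossing by
construction, and external track tables (including TrackMate-style exports)
can be ingested directly through `read_tracks_csv()`.

Cell density is detections per mm². Because replicate cultures reach
confluence at slightly different raw times, `align_time_series()` shifts
each movie's clock so the smoothed density peak sits at t_a = 36 h, which
places confluence near t_a = 0 h; the returned offset is applied to all
companion series. A series still rising at its last point is flagged: its
offset is then only a lower bound.

Migration steps give speeds (um/h) and full-circle directions.
`normalized_directional_migration()` histograms directions into 18 bins of
20 degrees and divides the summed frequency of the two bins flanking the
director by the isotropic expectation, 2/18 = 11.111%. A ratio of 1 means no
directional preference; 9 is the maximum (every step in the flanking bins);
a step exactly along the director falls in the left-flanking bin. Division
axes are folded to the nematic range and binned at 20 degrees, a vertical
axis landing in the (70, 90] boundary bin.

## Defects

The winding number of a director field along a closed loop is the sum of
consecutive angle differences, each wrapped to `(-90, 90]`, divided by 360;
on clean fields it is an exact multiple of 1/2. `detect_defects()` evaluates
loop windings as box sums of unit *plaquette* charges — each elementary
lattice cell carries an exactly half-integer charge, and the winding of any
loop equals the sum of the plaquette charges it encloses. Working with the
charged plaquettes directly is therefore equivalent to scanning
`tensorSize`-sized loops (the published parameters, tensorSize 20 and
minDist 30 grid units, are the defaults) while localizing cores to a single
cell. Candidates within `minDist` merge by single linkage; a cluster
reports its net charge and its charge-weighted centroid, and clusters whose
net charge is not ±1/2 (tight annihilating pairs) are dropped. Defect
detection should run on ungated fields (`min_coherency = 0`): the cores are
singular, so the coherency gate would mask exactly the signal.

`lic_render()` visualizes a field by averaging a white-noise texture along
streamlines traced 20 unit steps each way with direction-sign continuity; a
second pass seeded with the first output lengthens the streaks, and rank
histogram equalization raised to power 1.5 deepens the contrast. The power
transform is a display choice (the referenced rendering code does not
publish its exact transform); nothing quantitative depends on it.

## Circular statistics

`watson_wheeler()` implements the large-sample uniform-scores test for
homogeneity of k angular samples: pooled circular ranks give scores
β = 2π·rank/N, and W = Σ 2(C_i² + S_i²)/n_i is referred to χ² with 2(k−1)
degrees of freedom. Axial data are doubled onto the circle first (a flag
disables this; doubling is the default for axial inputs). Rank ties are
broken by a seeded 1e-6-degree jitter and the seed is reported. Groups
smaller than 10 are rejected rather than approximated — the intended inputs
are orientation fields with thousands of entries. Simulation places the
type-I error at 0.05 ± 0.02 and the null p-value distribution
indistinguishable from uniform.

## The synthetic world

The generator module states the world the pipeline is tested in:

* `gen_correlated_field()` draws two unit-variance Gaussian noise fields
  (the doubled-angle components), smooths each with an isotropic Gaussian of
  the requested scale, and takes half the argument of the result — valid
  nematic angles by construction, with ξ empirically monotone in the
  smoothing scale (the map is calibrated by measurement, not assumed;
  `analysis/03_correlation_length.R` writes the calibration table).
* `gen_defect_field()` builds θ = Σ k_i·atan2(y−y_i, x−x_i) analytically,
  so winding numbers have exact ground truth.
* `gen_filament_image()` renders anti-aliased segments at the local field
  angle plus 3 degrees of jitter — below the structure-tensor tolerance, so
  texture error does not mask field error.
* `gen_displaced_pair()` uses an exact Fourier phase shift for constant
  flows and Catmull–Rom resampling for varying ones.
* `gen_growth_tracks()` combines deterministic logistic growth (default
  carrying capacity 4000 cells/mm², the plateau the cultures reached) with a
  biased persistent random walk: the next direction is the angle of
  `persistence·u_prev + bias·u_director + noise`. Bias 0 is isotropic;
  infinite bias puts every step exactly along the director (directional
  ratio exactly 9). Speed decays linearly with crowding from a 15 um/h
  base — the order of magnitude seen in proliferating myoblast cultures —
  and cells that walk out of the field leave the movie while newcomers
  enter elsewhere, so every recorded step is a true motility step. Default
  growth rate 0.05/h and initial density 10% of capacity were chosen once
  so that a 120-hour movie spans sparse growth through plateau; they are
  conveniences of the synthetic world, not claims about any particular
  cell line.

What the generator does *not* emulate: fusion into multinucleated myotubes,
substrate mechanics, intensity noise and illumination drift, or cell-cell
exclusion (except in the dedicated non-crossing tracking fixtures). A green
test therefore establishes algorithmic correctness on data with the assumed
statistical structure, not robustness to every imaging artifact.

## Numerical choices and degenerate inputs

* Gaussian filtering uses dense banded operator matrices with
  renormalized-truncation boundaries; derivative operators are made exactly
  zero-sum over their local support so constant regions produce exactly zero
  gradient (otherwise border rows leak signal and flat image halves acquire
  spurious coherency).
* Structure-tensor energies below an absolute floor tied to the intensity
  scale are masked; a constant image is fully masked with zero coherency.
* The autocorrelation uses direct lag enumeration up to 1200 lattice points
  and zero-padded FFTs beyond; both compute identical sums and the direct
  path is verified against an O(N²) brute-force oracle to 1e-12.
* C(0) is set to its identity value 1 after accumulation.
* Histograms with an empty gated sample, all-masked order fields, curves
  with fewer than two classes, coincident division pairs, and sub-minimum
  Watson–Wheeler groups are errors, not silent NAs.
* All generator randomness flows through explicit seeds and the caller's
  RNG state is restored afterwards.

## Known limitations

The PIV estimator has no window deformation and loses subpixel precision on
strongly anisotropic textures; the blob detector is a classical stand-in for
a trained network and assumes roughly Gaussian nuclei; linking has no gap
closing, merging, or lineage logic; defect detection reports static
configurations only (no tracking of annihilation events); and the
Watson–Wheeler implementation relies on the large-sample χ² approximation
throughout.
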