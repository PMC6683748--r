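---
title: "Demultiplexing barcoded CLEM samples: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demultiplexing barcoded CLEM samples: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clemux)
```

## The problem

Correlative light-electron microscopy (CLEM) of pooled samples trades
per-sample sample preparation for a demultiplexing problem: many cell
populations are stained with distinct *combinations* of fluorophore-lectin
conjugates (a binary barcode over the available fluorescent channels),
pooled into a single EM block, sectioned, and imaged once. Each channel is
either present or absent on a given cell's wall, and the all-absent
combination is excluded because it cannot be told apart from a staining
failure, so $n$ channels address $2^n - 1$ populations — 7, 15 and 31 for
3, 4 and 5 channels. `clemux` implements the computational side of such an
experiment end to end:

1. **Cell detection** in the medium-magnification EM overview, from a
   pixel-class map (`detect_cells()`).
2. **LM↔EM registration** from user-picked landmark pairs
   (`fit_affine()`).
3. **Per-cell intensity measurement** through dilated outline masks
   (`build_masks()`, `measure_intensities()`).
4. **Barcode demultiplexing** by two-step normalization, k-means and
   Hungarian cluster-pattern matching (`classify_cells()`).
5. **Coordinate export** to SerialEM Navigator files for automated
   high-resolution acquisition (`add_acquisition_points()`).
6. **Stereological morphometry** of organelle profiles
   (`volume_fraction()`, `surface_to_volume()`).

A synthetic-data generator (`render_sample()`, `slice_spheres()`) replaces
the microscope so that every stage is testable against known ground truth.

## Cell detection

The EM overview is assumed pre-classified into four pixel classes
(0 background/resin, 1 well-preserved cell, 2 hole where a cell detached,
3 dark debris), either as an integer label raster or as per-class
probabilities (argmax-converted). The cell class is smoothed by a
morphological opening and closing (disc radius `smoothing_radius_px`,
default 3 px), connected blobs are labelled, and each blob is split by
marker-based watershed: markers are local maxima of the Euclidean distance
transform, suppressed so that no two markers are closer than
`marker_separation_um` (default 1.5 µm, about one yeast cell radius) and so
that two maxima joined by a ridge with no intervening valley deeper than
1 px seed a single object (otherwise elongated plateaus would fragment).
Label assignment from the markers uses seeded region growing on the
distance transform.

Objects are gated on area (default 3–80 µm², bracketing yeast cross
sections) and on circularity $4\pi A / P^2$ (default minimum 0.6), with the
perimeter measured on the traced 8-connected outline polygon. Those
thresholds are package defaults, not community constants — the gates are
fully configurable and every rejected object is returned with an
explanatory flag (`excluded_size`, `excluded_shape`, `edge_touching`)
rather than dropped, so a user can audit the gating. Edge-touching objects
are excluded from `ok` because partial profiles bias both area and
intensity. Ids are assigned in raster order of the centroids, making the
output independent of the labelling order of the underlying library.

## Registration and measurement masks

The LM and EM frames are related by a 2D affine map fitted by least
squares to 3 or more non-collinear control-point pairs; 5–10 spread
landmarks are ample in practice, and residuals are reported per point with
a warning (not an error) above a configurable RMS threshold. Coordinates
are 0-based pixel centers, $(x, y) = (\text{column}, \text{row})$,
everywhere in the package.

Measurement masks are built from the EM-derived outlines transformed into
the LM frame. The default mask is the **dilated outline band** (dilation
0.2 µm, clipped 1 px into the interior): the conjugate stains the cell
wall, which lies on and just outside the EM-derived outline, so a band
hugging the outline captures the ring while excluding the unstained
interior, whose pixels would otherwise dominate the median. A
`style = "filled"` alternative (fill, then dilate) is available for stains
that fill the whole profile. Pixels claimed by more than one mask, and
pixels falling on holes or debris (warped into the LM frame), are removed
from *every* claimant — dropping shared pixels is unbiased and keeps masks
pairwise disjoint by construction. The per-cell, per-channel statistic is
the median of the masked pixels, which is insensitive to the occasional
bright speck of aggregated stain.

## Barcode determination

Raw medians $I_i^c$ are normalized in two steps. Step 1 puts channels on a
common scale using statistics across cells:

$$N_i^c = \frac{I_i^c - \min_j I_j^c}{Q_3(I^c) - Q_1(I^c)}$$

with quartiles by linear interpolation between order statistics (R type 7;
the convention matters only at the third decimal but is fixed for
reproducibility). The interquartile range is used instead of the min–max
range because it characterizes the distribution shape without depending on
outliers; the literal minimum is kept as the location reference for
fidelity to the established procedure, with a robust-percentile switch
(`min_prob`) off by default. A channel with zero IQR carries no
information and is reported by name as an error. Step 2 removes the
per-cell staining level, which varies strongly between cells but is highly
correlated across channels:

$$F_i^c = \frac{N_i^c}{\max_{c'} N_i^{c'}}$$

so every classifiable cell has maximum exactly 1; cells whose maximum is
not positive are flagged `unclassifiable` and excluded from clustering.

Cells are clustered in $F$-space by Euclidean k-means with
$k = |\text{patterns in use}|$, k-means++ initialization, 50 restarts and a
mandatory seed. Each pattern's ideal $F$-vector is its own bit vector (its
maximal channel is 1), and clusters are matched one-to-one to patterns by
the Hungarian assignment minimizing total centroid–ideal distance; a
bijection is required for barcodes to be well defined, and the assignment
is deterministic (ties break by pattern binary order). Calls farther from
their centroid than the 95th percentile of within-cluster distances are
flagged `low_confidence` — an audit flag, not an exclusion. The whole
chain is invariant to affine rescaling of any raw channel and to row
order.

The non-interactive counterpart of visual quality control is
`qc_report()`: a per-cell thumbnail gallery (all LM channels plus the EM
crop, grouped by assigned pattern) and a calls CSV, with an override table
(`exclude` / `reassign:<pattern>`) standing in for interactive correction.

## Navigator export

Selected cells are appended to a SerialEM Navigator autodoc file as point
items with the acquire flag set. The parser keeps every line verbatim, so
read–write round trips are byte-identical (up to newline normalization)
and keys the package does not interpret survive for the acquisition
software. Pixel-to-stage conversion follows
$\text{stage} = \text{raw} + M\,(p - \text{center})$ with $M$ the map's
scale matrix in stage micrometers per pixel; because image rows grow
downward while stage Y conventionally grows upward, the pixel y-offset is
negated by default (`y_flip`), a per-installation convention flag under
which the round-trip identity holds either way.

## Stereological morphometry

Organelle cross sections are measured by the user as ellipses
($D_1$ major, $D_2$ minor diameter), giving area $A = \pi D_1 D_2 / 4$ and
circumference by Ramanujan's approximation
$C = \pi[3(a+b) - \sqrt{(3a+b)(a+3b)}]$, $a = D_1/2$, $b = D_2/2$, which is
exact for circles and within 0.02% of the arc-length integral for aspect
ratios up to 5. The volume fraction uses the Delesse principle with
measured areas in place of point counts, $V_r = \sum v / \sum u$ over
paired per-cell organelle ($v$) and cell ($u$) cross-section areas, with
the sampling-theory ratio-estimator standard error

$$\mathrm{SE} = V_r\sqrt{\frac{k}{k-1}\left[\frac{\sum u^2}{(\sum u)^2} +
\frac{\sum v^2}{(\sum v)^2} - \frac{2\sum uv}{\sum u \sum v}\right]}.$$

The cross term is negative: positive $u$–$v$ correlation must reduce the
ratio's variance, and $v \propto u$ must give SE $= 0$ (the bracket is
snapped to zero when cancellation leaves only rounding residue). This form
is validated in the test suite against a 2,000-replicate bootstrap of the
ratio. Surface-to-volume is estimated from profile boundary length per
profile area: the classical relation $S_V = (4/\pi) B_A$ restricted to the
organelle phase gives $S/V = (4/\pi) \sum C / \sum A$. The quantity is
dimensionally 1/length, which forces circumference over area; the $4/\pi$
constant is included by default with `include_constant = FALSE` for the
bare ratio, since published figures do not always state which convention
they plot.

## The synthetic-data generator

`render_sample()` emulates the paired microscope output with known ground
truth. Cells are circles with a bright wall ring; the ring intensity of
cell $i$ in channel $c$ is

$$b_i \cdot \text{bit}_c \cdot (1 + \varepsilon_{ic}) + \text{background},$$

where $b_i \sim \text{log-normal}(\sigma = 0.3)$ is the shared per-cell
brightness (labelling varies per cell but is correlated across channels),
$\varepsilon_{ic} \sim N(0, 0.10)$ is per-cell-per-channel staining
heterogeneity (the "channel CV"), and additive Gaussian pixel noise at 10%
of the local signal models the camera. Staining heterogeneity is not
quantified in the literature; $\sigma = 0.3$ is a tunable, deliberately
generous guess. The EM frame is related to the LM frame by a configurable
similarity transform (default scale 8, rotation 7°, auto-translation),
mimicking medium-magnification EM pixels of ~12.5 nm against LM pixels of
~100 nm; the class map contains the same cells plus hole and debris
distractor blobs, and exact landmark pairs are emitted for the
registration stage. Rendering is a pure function of (configuration, seed).

What the generator does *not* model: optics (PSF, chromatic shift),
section compression, spectral bleed-through, stain aggregates, or
non-circular cells. Passing tests therefore demonstrate the correctness of
the algorithms under the stated noise model, not performance on real
micrographs — on real data the interesting failure modes are registration
drift, segmentation errors on touching or damaged cells, and dim or
aggregated staining, which is why every stage emits flags and the QC
gallery exists. `simulate_intensities()` is the image-free path of the
same intensity model, used to benchmark the classifier at population
sizes (e.g. 15 patterns × 100 cells) where rendering full frames would be
pointlessly expensive.

`slice_spheres()` validates the stereology: spherical cells of log-normal
radius (default mean 2 µm, CV 0.1) contain non-overlapping organelle
spheres (Poisson count, mean 1.5; log-normal radius, mean 0.25 µm) placed
uniformly; each cell is cut by a plane whose offset is uniform over the
cell's diameter. A cell is *hit* by the section with probability
proportional to its radius, as a random section through a slab would hit
it; without this size-biased sampling the areal ratio converges to a
$1/(2R)$-weighted fraction rather than the true volume fraction whenever
radii vary. Cells whose plane misses every organelle still contribute a
cell profile with $v = 0$. The simulator returns the exact population
volume fraction and surface-to-volume for comparison.

## Numerical choices and problem sizes

* Quantiles: type 7 (linear interpolation) throughout.
* k-means: k-means++ seeding, 50 restarts, best total within-SS kept;
  duplicate-center failures are retried within the restart budget.
* Hungarian assignment: $O(k^3)$ potentials/augmenting-path
  implementation, verified against brute-force enumeration for small $k$.
* Affine fit: QR least squares; collinearity detected by rank of the
  design matrix; inversion guarded at $|\det| > 10^{-12}$.
* Degenerate inputs become flags (`unclassifiable`, `excluded_outside`,
  `empty_mask`), not errors; genuinely contradictory inputs (zero-IQR
  channel, k exceeding cells, orphan measurement ids) are errors naming
  the offender.
* The test suite and the acceptance script run the full rendered pipeline
  at 7 patterns × 2–3 cells in a 400 px LM frame (EM ≈ 3,600 px), the
  classifier benchmark at 15 × 100 cells, and the stereology benchmark at
  10,000 cells with a 2,000-replicate bootstrap at $k \approx 170$ —
  sizes chosen to exercise every code path at comfortable desk-scale
  runtimes while keeping Monte-Carlo error well inside the asserted
  tolerances.

## Known limitations

* Binary staining levels only; graded intensities and spectral unmixing
  are out of scope.
* No deformable registration; a single global affine is assumed adequate
  across a grid square.
* Class maps come from an external pixel classifier; training it is out
  of scope, and only TIFF input (labels or probabilities) is supported.
* Organelle profiles are user-measured ellipses; automatic organelle
  segmentation in EM images is out of scope.
* The Navigator writer targets the version-2 autodoc dialect and the
  minimal point-item subset required for automated acquisition.
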