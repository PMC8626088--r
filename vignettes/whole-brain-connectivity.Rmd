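---
title: "Quantifying whole-brain inputs and outputs from labeled volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying whole-brain inputs and outputs from labeled volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Viral tracing experiments label two complementary faces of a neuron
population's connectivity. Anterograde tracers (e.g. AAV-driven fluorophores
expressed in a Cre-defined population) fill the population's axons, so a
whole-brain fluorescence volume carries the population's *outputs* as bright
tubular structures. Retrograde monosynaptic tracers (modified rabies virus)
label the somata of *input* neurons presynaptic to the population. After
both kinds of volumes are registered to a common annotation atlas, the
scientific quantities of interest are per-region connectivity profiles: the
proportion of total projection volume, or of total input-neuron count, that
falls in each atlas region, with the injection site excluded; and the
comparisons built on those profiles (correlations between populations,
per-region ANOVA across groups, output-to-input reciprocity ratios,
clustering of samples).

`tracemapr` implements this quantification chain end to end: per-section
signal detection, connectivity validation of the detected signal by fast
marching from the injection site, soma detection, atlas aggregation, and
the group statistics. Because the real imaging volumes are terabyte-scale
and not redistributable, the package also contains a synthetic-data module
that generates toy brains with planted, known connectivity, so that every
stage is testable at desk scale. Registration is assumed done upstream:
all volumes entering the pipeline share the atlas geometry (a plain affine
coordinate transform is provided for point sets, but no image registration).

# Signal detection

Detection runs independently per coronal section (the first array axis), on
volumes assumed resampled to isotropic spacing:

1. **Background estimation.** The initial estimate is the per-section
   median gray level; the section is clipped to it from above (elementwise
   `min`), then smoothed by ten sequential convolutions with a uniform
   9×9 averaging template, reflecting at borders. The `min` step makes the
   estimate insensitive to sparse bright signal, which is exactly the
   regime of axonal label: thin bright structures on a smooth background.
   The median as initial scalar is a robustness choice; it is configurable
   (`detection_params()`).
2. **Subtraction**: `max(I - B, 0)`.
3. **Gaussian filtering** with a truncated, renormalized 5×5 kernel,
   sigma 1 px by default (only the kernel size is canonical; sigma is a
   conventional choice, exposed as a parameter).
4. **Thresholding.** A global per-section threshold comes from Yen's
   maximum-correlation criterion on a 256-bin histogram of the filtered
   section, *clipped to a predetermined range*. A pixel is foreground only
   if it exceeds both this clipped threshold and `background_multiplier`
   (default 4) times its local background estimate.

The clip range deserves emphasis. Yen's criterion picks the split that
maximizes a correlation functional over the histogram; on a section that is
almost entirely background (most sections of a whole brain), the criterion
splits the *noise* distribution and lands far below any useful value. The
clip range is therefore not a cosmetic guard but the mechanism by which
dataset-level knowledge ("label is at least this bright") enters the
segmentation. When no floor is given, the package defaults to the filtered
section's 95th percentile — a weak, data-driven floor. The synthetic study
in this package fixes its predetermined range to `[100, Inf)` gray units:
half the nominal label amplitude (200), comfortably above the background
gradient plus noise ceiling (~70). With the weak default instead, detection
still finds all signal (the 4×B term carries it) but keeps a 1–1.5-voxel
blur ring around tubes; with the study floor, the voxel-level F1 against
planted tubes rises from ~0.8 to ~0.99.

# Connectivity validation by fast marching

Detection is local, so detached bright specks survive it. The validation
stage removes signal that is not plausibly connected to the injection site:

1. The binary mask is pooled into **10 µm signal-density cells** (density =
   detected voxels / voxels in the cell).
2. Density becomes a **speed field** `F = density + eps` (`eps = 1e-3`).
   The affine law keeps empty space traversable — paths through empty cells
   are possible but slow, which is what lets the later confidence measure
   distinguish them — while dense corridors are fast.
3. The eikonal equation `|grad T| · F = 1` is solved outward from the
   injection-site cells by **multistencils fast marching**: second-order
   upwind differences on the axis-aligned stencil plus the three in-plane
   diagonal stencils, first-order fallback where second-order upwind
   neighbors are not yet finalized, and a priority-queue front. Because
   second-order differences straddle the non-smooth source point, cells in
   a radius-4 ball around each seed are initialized analytically
   (straight-ray time with the endpoint-mean slowness) — the standard cure
   for near-source error in accurate fast-marching implementations. On a
   41³ uniform-speed grid the solver is within 2.5% of the exact Euclidean
   solution everywhere beyond 5 cells from the seed.
4. Every signal-bearing cell is **back-tracked** down the arrival-time
   gradient (trilinear interpolation of per-cell central differences,
   step 0.5 cells). With a 1000× speed contrast between corridor and empty
   space, interpolated arrival times explode within half a cell of a
   corridor wall, and a pure gradient step can appear uphill from inside
   the corridor; when that happens the tracker takes one discrete
   steepest-descent step to the lowest-T neighboring cell, which provably
   decreases T (every finite non-seed cell has a smaller-T 26-neighbor by
   upwind construction), then resumes gradient descent. Back-tracking
   therefore cannot stall anywhere T is finite.
5. **Path confidence** is the fraction of back-tracked points lying in
   foreground cells (density above `foreground_density_threshold`,
   default 0.05). Points inside seed cells count as foreground: a path is
   penalized for the empty space it crosses, not for arriving. At
   whole-brain scale this is a no-op (the injection site is the densest
   labeled tissue); at toy scale, where complete paths are only a handful
   of points, it prevents genuine 3-point paths from being quantized to
   confidence 2/3. Cells whose path fails to reach a seed or has
   confidence below `confidence_cutoff` (default 0.8) have their mask
   voxels cleared. An optional override mask (the stand-in for manual
   inspection) is applied last.

Validation never adds voxels, and on its own output it is a fixed point.

## Why the solver is checked two ways

The solver is held to the exact solution on uniform speed (above). It is
*also* compared with an independent 26-neighbor Dijkstra oracle (edge cost
= length × mean slowness of the endpoints) on smooth random speed fields.
That comparison needs care: the graph metric itself overestimates continuum
distances by up to ~13% in skew directions (for displacement (1,2,4) the
cheapest 26-step path costs √3+√2+2 = 5.146 against a true √21 = 4.583),
and on rough i.i.d. fields Dijkstra additionally tunnels through lucky
cells. A *less* accurate first-order axis-stencil solver shares the graph's
directional bias and would appear to agree better. The oracle check
therefore asserts agreement in the mean (< 10% mean relative deviation on
smooth fields, observed ~8%) and bounds the tail by the oracle's own
certified worst-case inflation; pointwise agreement beyond that is not a
property an accurate solver can have.

# Soma detection

Dedicated sphere-fitting soma localizers are external tools in the original
workflow; here a transparent stand-in operates on the detection mask:
26-connected components are size-filtered to `[0.2, 5] × (4/3)πr³` voxels
(r = nominal soma radius, default 3 µm), oversized components are split by
a watershed flood seeded at local intensity maxima, each accepted component
yields its intensity-weighted centroid, and centroids closer than the
minimum separation (default 2r) are merged keeping the brighter. The
detector makes no claim of equivalence with sphere-fitting methods; its
job is to be accurate on well-separated, roughly spherical somata, which
it is (recall and precision 1.0 on the synthetic study at signal-to-noise
ratio 20). Somata are assigned to regions by voxel lookup under the
half-open voxel-box convention and flagged for exclusion when inside the
injection mask.

# Quantification

Output profiles count validated foreground voxels per *analysis region*
(raw atlas labels are collapsed upward to the first ancestor flagged as an
analysis region; labels with no flagged ancestor pool into "Others"; label
0 is the non-annotated area). Voxels inside the hand-drawn injection mask
are excluded from numerator and denominator. At 1 µm isotropic resampling,
a voxel count *is* a volume in µm³. Input profiles count non-excluded
somata per region. Both normalize to sum to one.

The output/input ratio per region uses the published category boundaries:
ratio < 0.25 input-biased, 0.25 ≤ ratio ≤ 4 balanced, ratio > 4
output-biased; the boundaries are read as inclusive into "balanced"
because the biased categories are printed with strict inequalities. Zero
input with positive output is reported as `Inf` (output-biased); zero/zero
is undefined.

# Group statistics

- **Correlation**: Pearson r between sample profile vectors; zero-variance
  profiles yield flagged `NA` entries.
- **Per-region ANOVA**: classic one-way ANOVA through `stats::aov`,
  followed by Tukey HSD (`stats::TukeyHSD`, Tukey–Kramer standard errors
  under imbalance). The all-equal degenerate case is reported as
  `F = 0, p = 1`. No correction is applied *across* regions beyond the
  within-region Tukey adjustment — a deliberate mirror of the original
  reporting, and a known limitation.
- **Clustering**: average-linkage agglomeration on correlation distance
  `1 − r`.
- **Bootstrap support** re-implements the multiscale bootstrap: columns
  (regions) are resampled with replacement at sizes `round(r·p)` for
  scales r in 0.5…1.4; each replicate is reclustered and each reference
  node is checked for reappearance (same spanned item set). BP is the
  appearance fraction at scale 1. AU comes from the probit fit: the line
  `qnorm(1 − BP(r)) ≈ v√r + c/√r` is fit by least squares and
  `AU = 1 − Φ(v − c)`. Nodes never observed get AU 0 with a flag; nodes
  at ceiling in every scale get AU 1. The AU implementation is flagged
  experimental: it uses an unweighted fit, not the full maximum-likelihood
  machinery of the reference R package.

# The synthetic-data module

The generator emulates what the pipeline consumes, not how microscopes
work:

- **Atlas**: an ellipsoidal brain partitioned into Voronoi regions around
  farthest-point-sampled sites (cells of a convex body are convex, hence
  contiguous; farthest-point sites keep region sizes comparable so every
  region can host somata for any seed). The central region is the
  injection region.
- **Axons**: biased random walks from the injection centroid toward a
  target region drawn per axon from the configured target fractions, with
  isotropic direction jitter (`tortuosity`, default 0.15), rasterized as
  tubes. Two terminal modes exist because two test regimes need different
  geometry. In `"centroid"` mode (default) all axons to a region collapse
  into one compact bundle — a sparse corridor network, the right backdrop
  for testing removal of isolated noise. Overlapping tubes are counted
  once, so in this mode deposited volume saturates and does *not* track
  axon counts. In `"region"` mode each axon homes on a uniformly drawn
  point inside its target region; tubes fan out, volume stays roughly
  proportional to axon count, and group differences in target preference
  survive into the voxel fractions (this mode drives the group-comparison
  workflow under `analysis/`).
- **Ground truth** output fractions are recomputed from the planted tube
  voxels per region (injection region and non-annotated space excluded,
  renormalized) — the generator's own bookkeeping, not the requested
  fractions, so recovery tests measure the pipeline, not the generator's
  sampling noise.
- **Somata**: spheres placed uniformly inside each requested region,
  rejecting placements whose guard ball crosses the region boundary or
  comes within 3 radii of an accepted soma (the spec of the experiment
  requires only 2 radii — non-overlap; the wider default emulates sparsely
  distributed neurons and is configurable).
- **Background and noise**: a per-section linear gradient (amplitude 20
  gray units) plus i.i.d. Gaussian noise (sigma 10), clipped at zero.
  Gaussian rather than Poisson noise is a deliberate simplification: the
  detection chain is intensity-threshold-based, and a single-parameter
  noise model is enough to exercise it.
- **Noise blobs** (`plant_noise_blobs()`): small bright spheres scattered
  with cell-scale clearance from real signal and from each other, for the
  validation-removal scenario. Isolation matters: specks packed densely
  enough to fill adjacent 10 µm cells form their own percolating
  "foreground" network and are (correctly, by the method's definition) no
  longer removable as unconnected noise.

## Study conditions

The canonical synthetic study used by the tests and the acceptance script:
100³ voxels at 1 µm, 8 regions, 200 axons of tube radius 3 voxels, signal
amplitude 200, noise sigma 10 (SNR 20), background gradient 20, injection
mask radius 6 µm, 100 isolated noise blobs, detection clip floor 100,
validation at density threshold 0.05 and confidence cutoff 0.8. The tube
radius is chosen for geometric self-consistency with the density
threshold: a radius-2 tube split across cell boundaries yields per-cell
densities near 0.03, i.e. planted signal would not even qualify as
foreground under the density definition, and the validation test would
measure thresholding accidents rather than connectivity. Radius 3 keeps
worst-case on-tube densities near 0.07.

Under these conditions, across five seeds: recovered output fractions are
within 0.04 of the planted fractions per region (Pearson r > 0.99), ~94%
of true tube voxels are retained while >95% of noise-blob voxels are
removed, and soma recall/precision are 1.0 with exact per-region
proportions.

## What passing these tests does and does not show

The generator's tubes are straight-ish, its noise is Gaussian and
stationary, its background is linear, its somata are perfect spheres, and
its atlas has no misregistration. Passing the synthetic recovery tests
shows the chain is internally correct — each stage recovers what the
previous stage's model says is there. It does not show robustness to
autofluorescence structure, striping or vignetting artifacts, registration
error, densely packed or irregular somata, or fiber bundles of varying
caliber — all properties of real data that the original workflow handles
with manual checking steps, represented here only by the override-mask and
accept/reject hooks.

# Numerical choices and degenerate inputs

- All convolutions reflect at borders (edge-repeating reflection).
- Yen's criterion breaks ties toward the lower gray level; a single-valued
  section is flagged degenerate and produces an empty mask.
- The marching heap uses lazy deletion; arrival times are doubles.
- Back-tracking stops on: seed entry (success), step budget (default 10×
  the grid diagonal / step size), or no downhill progress by either the
  gradient or the discrete fallback step (failure).
- Boundary density cells use their actual voxel counts.
- Empty detection masks give an empty soma list (not an error); an empty
  injection mask is an error; profiles with zero total signal or zero
  remaining somata are degenerate-profile errors.
- Analysis scale: the tests and acceptance script run the full study at
  100³ voxels with five seeds, the workflow demo at 60³ with four samples;
  both sizes were chosen so the complete chain (including 10 mean-filter
  passes over every section and a bootstrap with thousands of replicates)
  runs comfortably on a single CPU.

# Known limitations

- The pipeline consumes pre-registered volumes; registration error is out
  of scope and untested.
- Terminal boutons and fibers of passage are not distinguished — outputs
  are labeled-voxel volume, as in the source workflow.
- AU values are experimental (see above); BP is the primary support
  measure.
- The NRRD codec covers attached-header raw encoding only (the formats the
  pipeline itself writes); exotic NRRD variants should be converted
  upstream.
- The soma detector is a stand-in and is only validated on well-separated
  spherical somata.
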