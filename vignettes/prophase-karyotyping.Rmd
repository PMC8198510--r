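---
title: "Methods: 3D karyotyping of prophase chromosomes and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D karyotyping of prophase chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(karyo3d)
```

`karyo3d` turns a 3D intensity stack of a single late-prophase nucleus into
a quantitative 3D karyotype: 46 segmented chromosomes, each measured,
assigned a chromosome number, homolog label and cytogenetic group, and
placed in the radial and neighborhood organization of the nucleus. This
vignette documents the models and estimators behind each stage, the
tunable parameters, the design choices made where several constructions
were defensible, and what the synthetic validation does and does not
demonstrate.

## The imaging model and the three contrast bands

Serial block-face scanning electron microscopy of heavy-metal-stained
chromatin produces an aligned 16-bit stack with strongly anisotropic
voxels: fine in-plane sampling (11 × 11 nm by default) and coarser serial
sectioning (25 nm). Condensed prophase chromosomes appear as bright,
rod-shaped bodies: each of the two parallel sister chromatids carries a
brighter axial core, with intensity falling off toward the chromatid
surface and a dimmer nucleoplasm background around it.

Segmentation works by band thresholding at three published 16-bit contrast
intervals:

| band   | min    | max    | selects                                      |
|--------|--------|--------|----------------------------------------------|
| narrow | 38,445 | 41,264 | the bright chromatid axial core              |
| medium | 37,596 | 43,832 | the chromosome envelope tracking DNA content |
| wide   | 37,498 | 41,346 | a slightly dimmer outer envelope             |

Bounds are inclusive on both ends (the source material states only
minima/maxima, so the closed convention was chosen; at 16-bit depth the
difference is negligible). Note that the wide preset is *not* an interval
superset of the medium preset — its maximum is lower — so envelope nesting
is only guaranteed between narrow and medium; `karyo3d` asserts
narrow ⊂ medium and treats the wide band as a third, independent level.

Thresholded masks are labeled by 3D connected components. The default
connectivity is 26: with anisotropic voxels, merged sister chromatids can
touch diagonally across slices, and 6-connectivity would fragment them.
Components smaller than the voxel volume of a 0.2 µm sphere are discarded
(far below any chromosome at any supported resolution, far above noise
specks); survivors are renumbered by descending voxel count. No automatic
splitting of touching chromosomes happens by default — a count other than
46 is reported, and a seeded-watershed splitter (`split_touching()`, via
EBImage) is available behind a flag.

Optional denoising is an edge-preserving bilateral filter applied
independently per x–y slice (`denoise_inplane()`), because pixel noise in
block-face imaging is in-plane and filtering across the coarser z axis
would blur section boundaries. Defaults: spatial radius 2 voxels, range sd
300 intensity units (about twice the default simulated noise).

## Morphometry

**Volume** is the voxel count times the physical voxel volume; **DNA
content** divides the volume by the packing density of the chromatin
protein–DNA complex, 5.80 nm³ per base pair, and by 10⁶ to give Mbp. This
conversion is exact and is also used, inverted, to size the synthetic
chromosomes, so the validation closes the loop on it.

**The skeleton** (`skeleton_longest_path()`) is a smooth principal curve,
not a topological thinning. The object's voxel cloud is rotated into its
principal-component frame; the two transverse coordinates are regressed on
the axial coordinate with quadratic polynomials; the fitted curve is
sampled densely. Each voxel's axial position is the arc length of the
curve at the voxel's own axial coordinate, and the tip-to-tip length is
the span of those positions. This construction was chosen after more
conventional alternatives failed on merged chromatid pairs: a
farthest-point geodesic path through the voxel graph measures the
*geodesic diameter*, which for a wide two-chromatid object includes a
lateral corner-to-corner component and can double back along the sister
chromatid, inflating lengths by 20–40% on short chromosomes. Projection
spans are immune to both effects: a corner voxel projects to the same
axial position as an on-axis voxel. The cost is generality — the quadratic
drift model follows the gentle bows the generator produces (≤ 20° total
curvature) and real prophase chromosomes' curved morphologies, but not
hairpin folds. The geodesic length of a straight analytic cylinder is
recovered within one voxel diagonal; a single-voxel object has length 0.

**The centromere** is the constriction separating the p and q arms. It is
localised on the *cross-section area profile*: every voxel contributes its
volume at its axial arc position through a Gaussian kernel (bandwidth 0.75
of the largest voxel pitch), giving a smooth area-per-unit-length profile
whose square root is an equivalent-circle radius. The minimum of this
profile inside the central 14–86% of the arc, refined by parabolic
interpolation when it is interior, is the centromere; the shorter side is
the p arm. Two choices deserve comment:

* *Why an area profile rather than the distance transform along the
  skeleton?* The local EDT radius along a centerline threading a chromatid
  pair dips wherever the curve passes between the sisters, creating false
  constrictions. The cross-section area is a property of the object, not
  of where the curve threads, and both chromatids constrict at the same
  arc position, so their dips add.
* *Why 14–86% and not a wider or narrower window?* The window must exclude
  the telomeric taper of the rounded chromatid ends (which extends about
  one chromatid radius, up to ~20% of the shortest chromosome) yet reach
  acrocentric centromeres whose canonical index is 16–19. At 14% the
  worst-case clipping error for a packaged acrocentric index is under 5
  centromere-index points; a 20% edge would make acrocentric centromeres
  structurally undetectable.

A profile whose relative depth within the window is below 8% is flagged
unreliable (`ci_reliable = FALSE`); if a canonical index is supplied it is
used as a fallback. The p/q *volume* split assigns each voxel to an arm by
its axial coordinate — a curvature-aware version of cutting with a plane
orthogonal to the skeleton at the centromere. **Diameter** is twice the
mean distance-transform radius along the skeleton; for a chromatid pair
this reports the thickness of a single chromatid (the curve rides one
chromatid's ridge), which is the morphologically meaningful quantity; for
a solid cylinder it equals the true diameter within a voxel.

All measurements are equivariant under voxel rescaling: scaling the
spacing by *s* multiplies lengths by *s* and volumes by *s³* exactly.

## Identification as a linear assignment problem

Visual scatter-plot karyotyping — ranking objects by volume and length
against centromere index — is formalised as optimal bipartite matching.
For a 46,XY template (46,XX selectable) the 46 slots carry reference
values: percent of genome by Mbp, and canonical centromere index. Measured
objects carry volume-percent, length-percent and measured index. Each
feature is standardised to zero mean and unit variance *on its own side*,
which removes affine mismatch between measured geometry and reference Mbp
(chromosome length is affine, not proportional, in DNA content because of
the end caps). The cost of assigning object *i* to slot *j* is

  w_v |z_vol(i) − z_ref(j)| + w_l |z_len(i) − z_ref(j)| + w_c |z_ci(i) − z_ci(j)|

with defaults w_v = w_l = 1 and w_c = 0.5 (the index is the noisiest
feature). The exact optimum is found with the Hungarian algorithm in
O(n³); an infinitesimal (object, slot)-ordered perturbation makes
tie-breaking deterministic. Homolog `a` of each pair is the larger-volume
object.

On the noiseless phantom the assignment recovers every chromosome number
at the reference seed. Across arbitrary seeds, occasional swaps occur
within {9, 10, 12} — these chromosomes differ by as little as 0.4% in DNA
content and a few centromere-index points, and the same ambiguity within
group C is a documented feature of real karyotyping. Under 5% multiplicative
volume noise, group-level classification remains at or near 46/46 while
within-group-C numbering may permute.

`validate_assignment()` regresses measured volume on assigned reference
Mbp: the slope estimates the DNA packing density (5.80×10⁶ nm³/Mbp on the
phantom, R² > 0.99) and objects deviating more than 25% from the fitted
line are flagged.

## Spatial organization

The nucleus center is the voxel-weighted centroid of all chromosome mass
(the phantom and typical stacks have no segmented envelope; an explicit
nuclear mask can replace it upstream). Each chromosome's radius is the
distance of its centroid from that center. Radii are binned into five
equal-width regions labeled center → periphery; the outermost bin is
closed. Radius is regressed on chromosome volume and on gene density
(protein-coding genes per Mbp from the packaged reference table) by
ordinary least squares, with R² the squared Pearson correlation.

Two chromosomes are neighbors when their surfaces come within `cutoff_nm`
of each other. Surfaces are represented by boundary voxel centers, which
sit up to one voxel inside the true surface, so the test allows one voxel
diagonal on top of the cutoff — touching objects are neighbors at any
cutoff, including 0. The published criterion is visual ("closer
proximity") with no stated cutoff; the default of 250 nm is of the order
of one chromatid radius and is surfaced in every report so it can be
varied. The matrix is symmetric with an empty diagonal and
monotone in the cutoff, and the export order follows the karyotype
(1a, 1b, …, 22b, X, Y).

## The synthetic nucleus

The generator emulates the geometry the pipeline is built for, with known
ground truth:

* **Nucleus**: a 7.2 µm sphere, centered on a coarse anisotropic grid
  (44 × 44 × 100 nm by default, so a full phantom builds in seconds; the
  acquisition-resolution 11 × 11 × 25 nm grid is selectable).
* **Chromosomes**: for each of the 46 slots, two parallel capsule-shaped
  sister chromatids (radius 230 nm, axes 1.5 radii apart so the pair is
  merged over a wide contact zone, total width ≈ 0.8 µm) share a common
  centerline with a random bow of up to 20°. A Gaussian radius waist
  (factor 0.7, half-width 18% of the chromatid length, capped at 250 nm)
  marks the centromere, positioned so the realized short-arm fraction
  equals the canonical centromere index. The chromatid length is solved
  analytically from the target volume `Mbp × 10⁶ × 5.80 nm³` using exact
  merged-pair cross-section and cap formulas, so the rendered medium-band
  volume matches reference DNA content within a few percent. Homolog
  volumes differ by a pair-level jitter of 0.5–3% ('a' is generated first
  and larger), so pairs are near-identical but never equal and the
  identification stays well-posed.
* **Placement**: seeded random initial positions (largest chromosome
  first), then pairwise repulsive relaxation over the exact centerline
  segment geometry: the enforced centerline separation is annealed upward
  in stages to the full threshold `2r + clearance`, with violating pairs
  translated and torqued apart along their minimum-distance vector and
  wall violations pushed back inside. Pure sequential rejection sampling
  — the naive construction — jams far below the required 18% chromatin
  volume fraction, which is why the relaxation exists; it packs all 46
  chromosomes in seconds at any seed tried, with automatic re-seeded
  restarts as a safety net. The inter-chromosome clearance (135 nm)
  exceeds one voxel diagonal, so distinct chromosomes can never merge
  under 26-connectivity, and a positive `radial_bias` adds a
  gene-density-proportional centripetal drift during the early relaxation
  stages, reproducing gene-density-dependent radial organization
  (regression slope negative in ≥ 9/10 seeds at β = 4; at β = 0 the slope
  is weakly positive, as for a volume-excluded uniform packing).
* **Rendering**: intensity falls off quadratically from 41,000 at the
  chromatid axis to 37,550 at the surface and continues into a thin
  sub-threshold halo down to the 33,000 background, so the three contrast
  bands carve nested envelopes (narrow < medium ≤ wide per object) and the
  medium band recovers ≈ 98.5% of each solid. The published "almost
  double" wide-band volume of real data is *not* emulated — with a
  monotone falloff and the printed wide interval, the wide envelope is
  only a thin shell larger than the medium one, and the package treats the
  wide band as qualitative. Gaussian noise (sd 150 by default) is added
  last; its ±30σ range cannot bridge the background-to-band gap.
* **Truth**: per object — chromosome, homolog, exact voxel volume of its
  label, tip-to-tip length and arm lengths from the realized geometry
  (including the hemispherical end caps the renderer produces), centromere
  index, centroid and radius. Identical `(config, seed)` give bit-identical
  stacks, labels and truth tables.

### What the phantom validates — and what it cannot

Passing the recovery suite (volume and length within 10%, centromere
index within 5 points, exact identification, 46/46 segmentation) shows the
*estimators* are correct and well-calibrated on geometry that matches
their assumptions: rod-shaped, gently curved, well-separated chromosomes
with a single constriction and clean band structure. Real SBFSEM data add
effects the generator deliberately omits: charging and curtaining
artifacts, slice-to-slice registration error, touching chromosomes,
nucleoli and membrane signal, staining heterogeneity, and chromosomes with
folded arms. Segmentation of real data will typically need the denoiser,
possibly the watershed splitter, and manual review of the reported object
count; the identification and spatial stages are agnostic to the upstream
source.

## Numerical and engineering choices

* Voxel storage is column-major `(x, y, z)` with 1-based indices; the
  physical position of voxel (i, j, k) is `((i−½)s_x, (j−½)s_y, (k−½)s_z)`
  nm. All reported geometry is in nm, nm³ and Mbp.
* The distance transform is the exact anisotropic squared-Euclidean
  transform (per-axis lower-envelope passes), computed per object on a
  padded crop.
* Component labeling, EDT, the bilateral filter, the phantom renderer,
  point/segment minimum distances and the Hungarian solver are small C++
  kernels; everything else is plain R.
* Problem sizes used throughout validation: the coarse 44 × 44 × 100 nm
  grid (~2.3 M voxels per nucleus), one full 46,XY nucleus plus one
  9-chromosome nucleus as shared fixtures, and ten biased placements for
  the radial-organization check.
* Degenerate inputs: empty karyotypes yield an all-background stack and
  empty truth table; single-voxel objects have zero length and an
  unreliable centromere; constant-intensity stacks pass through the
  denoiser unchanged; a flat radius profile falls back to the canonical
  index only when one is supplied, and is flagged either way.

## Known limitations

* Haplotype (maternal/paternal) assignment is out of scope; homolog labels
  a/b order by volume only.
* Aneuploid or rearranged karyotypes are not modeled; the assignment
  assumes a complete 46,XY or 46,XX template (partial nuclei are possible
  behind `allow_partial`).
* Lengths of strongly folded chromosomes would be underestimated by the
  quadratic principal curve; the skeleton is tuned for late-prophase
  morphology.
* The wide contrast band is reported but carries no quantitative claims.
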