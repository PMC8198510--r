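# karyo3d

3D karyotyping of human prophase chromosomes from volume electron microscopy
stacks.

At late prophase, the 46 chromosomes of a human nucleus are condensed,
discrete bodies with paired parallel sister chromatids — compact enough that
a serial block-face scanning electron microscopy (SBFSEM) stack of a single
nucleus can be segmented into all 46 individual chromosomes, identified,
and mapped in 3D nuclear space. `karyo3d` implements that analysis as a
reproducible pipeline for R, aimed at microscopists and genome-organization
researchers working with volume-EM (or comparable 3D) stacks of condensed
chromatin:

1. **Segmentation** — in-plane bilateral denoising, band thresholding at
   three 16-bit contrast levels (narrow 38445–41264, the bright chromatid
   axial core; medium 37596–43832, the envelope whose volume tracks DNA
   content; wide 37498–41346), and 3D connected-component labeling on
   anisotropic voxel grids.
2. **Morphometry** — per object: volume; tip-to-tip length along a
   principal-curve skeleton with p/q arm split at the centromeric
   constriction; centromere index `CI = 100·p/(p+q)` by length and by
   volume; mean diameter from the 3D distance transform; DNA content via
   the packing density of the chromatin fiber,
   `DNA [Mbp] = V [nm³] / 5.80 / 10⁶`.
3. **Identification** — measured objects are matched to the 24-type
   reference karyotype (sizes in Mbp, canonical centromere indices, gene
   densities) by solving a 46×46 linear assignment problem over
   standardized volume-percent, length-percent and centromere-index
   features; objects inherit chromosome numbers, homolog labels a/b and the
   cytogenetic groups A–H. A least-squares fit of measured volume against
   reference Mbp recovers the 5.80 nm³/bp conversion as its slope and
   flags volume outliers.
4. **Spatial analysis** — radial position of every chromosome relative to
   the chromatin center of mass, five equal-width radial regions
   (center … periphery), regressions of radius on volume and on gene
   density, and a symmetric chromosome neighborhood matrix from
   surface-to-surface distances.

Because no public SBFSEM stack of a prophase nucleus exists, the package
includes a first-class **synthetic nucleus generator**: 46 paired-chromatid
chromosome solids, sized from reference DNA content, packed into a 7.2 µm
sphere by annealed repulsive relaxation and rendered as a 16-bit stack with
a bright axial core, graded intensity falloff and optional noise — with a
voxel-exact ground-truth table. Every stage of the pipeline is validated
against this ground truth.

## Worked example

```r
library(karyo3d)

# simulate a noiseless nucleus at the coarse working resolution
phantom <- generate_phantom(phantom_config(noise_sd = 0, seed = 42))

# segment with the medium contrast band
labels <- segment_stack(phantom$stack, "medium")
attr(labels, "n_objects")
#> [1] 46

# measure, identify, validate
morph  <- measure_chromosomes(labels)
assign <- assign_karyotype(morph)
print(assign)
#> karyotype_assignment: 46 object(s), complete, total cost 4.199, groups: ABCDEFGH
#>    object_id chrom_id homolog group assignment_cost
#> 1          1        1       a     A          0.0699
#> 2          2        2       a     A          0.0692
#> 3          3        1       b     A          0.2054
#> ...

validate_assignment(assign, morph)
#> volume ~ Mbp: slope 5.8e+06 nm^3/Mbp, intercept -1.75e+06, R^2 = 0.9989
#> no volume outliers

# radial organization and neighborhood map
sp <- spatial_report(labels, morph, assign, cutoff_nm = 250)
print(sp)
#> spatial_report: 46 chromosomes, nucleus center (3788, 3661, 3815) nm
#>   radius ~ volume:       R^2 = 0.133 (slope -5.77e-07)
#>   radius ~ gene density: R^2 = 0.000 (slope 1.93)
#>
#>                 center    center-intermediate           intermediate
#>                      0                      4                      7
#> periphery-intermediate              periphery
#>                     19                     16
```

The 46 labeled objects are the full 46,XY karyotype; the assignment covers
all eight cytogenetic groups; the volume-versus-Mbp slope recovers the DNA
packing density used to size the phantom (5.80×10⁶ nm³/Mbp) with R² ≈ 0.999;
and the spatial report places every chromosome in one of five radial
regions with its neighbor list.

A thin command line interface chains the same stages:

```sh
inst/cli/karyo3d run-all --out results/run1 --seed 42 --noise-sd 0
```

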