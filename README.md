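# coatsitu

Tools for determining the structure and organisation of vesicle coat
protein lattices **inside cells** from cryo-electron tomograms.

Membrane coats (of which the COPI/COPII/clathrin family is the
archetype) assemble as lattices of symmetric repeat units on budding
vesicles. Determining their native structure from cellular tomograms —
without any external reference — requires a chain of specialised
computation on top of the tomograms and per-vesicle annotations
(center, membrane-to-membrane diameter, Golgi-region and
luminal-density labels):

* **Reference-free subtomogram averaging** of the coat repeat unit:
  particles seeded on the annotated vesicle spheres (out-of-plane
  orientation from the surface normal, in-plane angle random), two
  vesicle-granular half-sets processed independently, iterative masked
  alignment driven only by the azimuthally asymmetric coat density,
  centering and C3-symmetrized refinement of the emergent three-fold
  feature, cross-correlation filtering and 17.7 nm overlap removal.
* **Gold-standard resolution**: Fourier shell correlation between the
  half-maps under a soft membrane-excluding cylindrical mask, with
  mask correction by phase randomization,
  `FSC_corr = (FSC_masked − FSC_rand)/(1 − FSC_rand)` beyond the
  randomization shell; threshold crossing (0.143 by default) with
  linear interpolation. Postprocessing divides by a radial CTF-sum
  weight, low-passes to the determined resolution, and sharpens with a
  B-factor of −2000 Å².
* **Lattice and linkage analysis**: per-vesicle lattice maps, linkage
  templates derived from exemplar pairs (quaternion mean after C3
  canonicalization), and an automated search that compares every
  neighbour pair's relative rigid transform with the template under
  all 3 × 3 in-plane symmetry branches.
* **Coat completeness**: a 13-slice central slab divided into eight
  45° sectors of the coat annulus; occupied sectors give the angular
  completeness, and the coated fraction of the vesicle population
  estimates the coated fraction of the vesicle lifetime under
  steady-state sampling.
* **Membrane thickness**: leaflet peak–peak distance (explicitly not
  absolute bilayer thickness) from radially straightened averages,
  with a 750-replicate bootstrap; 20 × 20 box averaging for planar
  cisternal membranes; vesicle diameter measurement from radial
  density profiles.

All conventions follow the classic tomography toolboxes: ZXZ Euler
angles `R = Rz(psi) Rx(theta) Rz(phi)` with `phi` the in-plane
rotation, MRC2014 volumes (x fastest, 0-based voxel coordinates),
tab-separated particle/vesicle tables with an optional RELION-style
STAR export.

Because cellular tomograms are large and not redistributable, the
package ships a first-class synthetic-scene generator
(`simulate_scene()`): coated and uncoated vesicles with two-leaflet
Gaussian bilayers of controllable peak separation, three-fold
Gaussian-blob coat motifs planted on spherical caps (a budding-scar
gap is always present) or as exact linkage-transform lattices,
Gaussian noise and an optional missing wedge — each scene carrying its
full ground truth. The entire pipeline is validated against these
scenes; see the methods vignette
(`vignettes/coatsitu-methods.Rmd`) for the models, parameter choices
and what the synthetic validation does and does not demonstrate.

## Worked example

Render a synthetic vesicle (56 nm membrane-to-membrane diameter,
40 Å leaflet separation, 6.84 Å voxels), then measure it back:

```r
library(coatsitu)

v <- render_vesicle(diameter_nm = 56, leaflet_separation = 40,
                    voxel_size = 6.84)
v
#> volume3d: 124 x 124 x 124 voxels, 6.84 A/voxel, range [0, 1]

m <- measure_vesicle_diameter(v, (dim(v) - 1) / 2)
m$diameter_nm
#> 56.03

r_out <- 56 * 10 / 2 / 6.84
st <- straighten_radial(v, (dim(v) - 1) / 2,
                        radial_range = c(r_out - 12, r_out + 6))
profile_and_peaks(st)
#> membrane_profile: leaflet peaks at 41.9 / 82.0 A, separation 40.12 A

subs <- replicate(8, v, simplify = FALSE)
bootstrap_thickness(subs, (dim(v) - 1) / 2,
                    radial_range = c(r_out - 12, r_out + 6),
                    n_reps = 750, seed = 1)
#> bootstrap_result: separation 39.64 A (bootstrap 39.64 +/- 0.00 A, 750 reps, 0 failed)
```

The measured diameter is within 0.03 nm of the planted value; the
straightened profile recovers the 40 Å leaflet separation to 0.12 Å;
and the bootstrap of identical noise-free inputs has, as it must,
zero spread (the 0.5 Å offset of the bootstrap point estimate comes
from the 25 Å low-pass applied before profiling, which slightly
rounds the two leaflet peaks towards each other).

For the full pipeline, `simulate_scene()` + `run_ab_initio()` takes a
vesicle-annotated tomogram to half-set averages, a refined particle
table and per-stage correlation logs; `build_lattice_map()` +
`search_linkages()` then count linkage occurrences, and
`sector_completeness()` / `bootstrap_thickness()` produce the
population statistics. A thin command-line wrapper with
`simulate`, `align`, `fsc`, `completeness` and `thickness` subcommands
is installed at `inst/scripts/coatsitu`.

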