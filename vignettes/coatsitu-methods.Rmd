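---
title: "In situ coat structure analysis: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In situ coat structure analysis: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(coatsitu)
```

# Scope

`coatsitu` implements the computational half of an in-situ structural
study of vesicle coat lattices: given cryo-electron tomograms and
per-vesicle annotations (center, membrane-to-membrane diameter, region
and luminal-density labels), it determines the coat repeat unit by
reference-free subtomogram averaging with an independent half-set
protocol, estimates resolution by mask-corrected phase-randomized
Fourier shell correlation, analyses the lattice organisation by
rigid-transform pattern matching, quantifies coat completeness with a
sector statistic, and measures bilayer leaflet separation from
radially straightened averages with bootstrap errors.

Real cellular tomograms are not shipped; a synthetic-scene generator
(`simulate_scene()`) renders ground-truth-annotated stand-ins so every
stage can be validated quantitatively. This vignette records the
models, the tunable parameters, the numerical choices and what the
synthetic validation does and does not demonstrate.

# Conventions

* **Euler angles.** ZXZ with angles `(phi, psi, theta)` and
  composition `R = Rz(psi) Rx(theta) Rz(phi)` — the convention of the
  classic tomography toolboxes. `phi` is the in-plane rotation about
  the particle's local z-axis; `psi`/`theta` encode the out-of-plane
  direction. At the gimbal degeneracy (`theta` = 0 or 180) `psi` is
  reported as 0 and the in-plane rotation carried by `phi`. Whether
  any particular upstream package orders its ZXZ axes identically is
  not guaranteed; the convention here is documented, self-consistent
  and round-trip tested to 1e-9.
* **Coordinates.** 0-based voxel indices, positions at voxel centers,
  right-handed axes in the MRC order (x fastest). Voxel sizes in
  Angstrom. Particle tables are tab-separated text with a fixed
  header; a RELION-style STAR export is provided for viewers.
* **Randomness.** Every stochastic operation takes an explicit seed
  and restores the caller's RNG state; nothing touches the global
  stream as a side effect.

# The synthetic scene generator

`scene_pars()` fixes the study conditions:

* vesicle diameters are drawn from a normal population with mean 56 nm
  and SD 6 nm (the late-bud/vesicle population the pipeline is aimed
  at), floored at 20 nm;
* the working pixel size defaults to 13.68 Å (the twice-binned scale
  at which subtomograms are extracted in the original protocol; the
  unbinned object pixel is 3.42 Å);
* membranes are two concentric Gaussian leaflet shells (σ = 1.2
  voxels) whose radial maxima are `leaflet_separation` apart, with the
  outer maximum at the annotated membrane-to-membrane radius; only the
  peak–peak distance is a measurement target, so any two-peak model
  suffices and Gaussians make the analytic oracle trivial. Default
  separations rise from *cis* (35 Å) through *medial/trans* (40 Å) to
  *trans*/TGN (45 Å), emulating the reported thickening gradient; the
  paper prints these values only graphically, so the ladder is a
  generator choice, documented here, not a measured quantity;
* the coat unit is an abstract three-lobed C3 Gaussian-blob motif
  (hub, three lobes, three off-azimuth satellites that break six-fold
  ambiguity), not an atomic model — the pipeline's correctness is
  geometric. Blob widths are kept at or above two voxels of the
  working scale so the motif survives trilinear resampling;
* coats cover a spherical cap (`coat_coverage`, default 0.65); the
  complement is the budding-scar gap, which is mandatory — complete
  coats must be requested explicitly (`plant_coat(allow_complete =
  TRUE)`);
* the triad center sits `coat_height` (default 50 Å) above the outer
  leaflet peak, and triads are spaced `triad_spacing` apart. The
  default spacing is 22 nm: it must exceed the 17.7 nm overlap-removal
  threshold by enough margin that the irregularity of a Fibonacci cap
  (nearest neighbours down to ~0.87 of nominal) never pushes genuine
  neighbours below the threshold. Neither the in-situ spacing nor the
  coat height is quantified in the source study; both are generator
  choices made once for testability;
* Gaussian white noise is added last (`noise_sd`, relative to the
  signal peak), and an optional missing wedge zeroes the unsampled
  Fourier region (off by default — wedge handling is inherited from
  upstream reconstruction in the real protocol and is not part of the
  validated claims).

## Two coat-planting modes

A single placement mode cannot both cover a cap evenly and realize
exact linkage transforms, because Fibonacci points are not related by
any fixed rigid transform. `plant_coat()` therefore has two modes:

* **cap** (scene default): a Fibonacci lattice restricted to the cap,
  random in-plane angles. Planted counts equal the closed-form
  cap-area count `round(coverage · 4πr²/spacing²)`; neighbour
  transforms vary with local geometry.
* **lattice**: breadth-first growth by applying linkage-pattern
  transforms exactly. The default patterns are pure rotations about
  axes through the coat-sphere center, so chains stay exactly on the
  sphere with outward-normal orientation, and every planted edge
  reproduces its template to machine precision — the substrate for
  the zero-jitter pattern-search tests.

# Reference-free averaging

The alignment engine (`align_iterate()`) scans local rotation grids
(in-plane angles crossed with an out-of-plane cone) and finds, per
rotation, the translation at the maximum of the masked normalized
cross-correlation, computed over all shifts by FFT with 3-point
parabolic subvoxel interpolation; the in-plane angle is refined the
same way from the per-angle peak correlations. Three design elements
matter on membrane-bound lattices, and all three are exposed:

* **The mask excludes the membrane.** A soft cylindrical mask in the
  reference frame covers one coat motif and is rotated together with
  the reference (masks are axially symmetric, so one resampling per
  cone tilt suffices). Correlating under a mask that includes the
  membrane lets the spherically symmetric shell dominate the score and
  the motif never locks.
* **Only azimuthally asymmetric density is correlated**
  (`flatten_reference = TRUE` in the driver). The membrane and lumen
  are invariant under rotation about the particle normal; subtracting
  the azimuthal mean of the reference removes them from the model, so
  the search cannot converge onto the membrane-consistent degenerate
  solution that otherwise outscores the true lattice.
* **Radial shift constraint.** The coat lies on a sphere whose radius
  is annotated; the shift component along the particle's outward
  normal is bounded per pass (`radial_lo`/`radial_hi`), while lateral
  search stays free. Without the bound, particles slide radially onto
  the bright leaflets.

`run_ab_initio()` composes the full protocol per independent half-set
(half-sets are split at vesicle granularity, so no particle can
contribute to both half-maps):

1. **Seeding.** Directions on a dense Fibonacci lattice are sampled
   through a low-pass-filtered copy of the tomogram over a shell just
   outside each annotated membrane sphere; greedy maxima with a
   minimum separation become seeds, oriented along the outward normal
   with random in-plane angles (`seed_coat_peaks()`). This is
   template-free: on a coated vesicle the coat triads *are* the maxima
   of the smoothed coat shell. The classic alternative — evenly spaced
   surface seeds (`sphere_seed_points()`, 10 nm spacing) followed by
   emergent alignment — is implemented and exported, but with an
   abstract Gaussian-blob motif the emergence from laterally random
   positions is bistable (membrane- and interpolation-locked
   attractors are self-consistent and outscore the sparse true
   lattice), so the driver seeds at density peaks. On real data with
   a strong low-resolution motif both initialisations are viable.
2. **Bootstrap emergence.** The starting reference is the single
   strongest seed particle's subvolume — no external structure — and
   one full-circle in-plane round aligns all particles against it.
3. **Refinement and centering.** After re-deriving normals at the
   refined positions, local passes refine against the growing average
   (references are built from the best-correlating half of the
   particles so unconverged seeds cannot pollute them). The emergent
   three-fold feature is brought to the box center — laterally by the
   closed-form relation between the flattened self-rotation
   correlation peak `u` and the axis offset `s0` (`u = (R − I)s0`),
   axially by the centroid of azimuthally asymmetric power — and the
   centering shift is composed analytically into the particle
   parameters so the subsequent search only polishes.
4. **Symmetrized refinement, pruning, fine passes.** C3 is applied to
   rebuilt references; overlapping particles are removed greedily
   (best correlation first) at the 17.7 nm threshold; the low-score
   tail is dropped by a two-means split of the final correlation
   distribution (falling back to the fixed keep-fraction when the
   split is ambiguous); final passes add a small out-of-plane cone
   search and end with a fine in-plane polish after normals are
   re-derived once more.
5. **Half registration.** The two half references are registered by
   in-plane rotation and shift, the transform is composed into the
   half-2 particle parameters, and half 2 is re-refined against the
   common orientation, so the two half-maps are directly comparable by
   FSC.

An ab initio solution is defined only modulo a global in-plane
rotation and a common local-frame offset (the emergent reference's
arbitrary azimuth and residual centering). Validation against ground
truth therefore estimates and removes this global transform before
computing per-particle errors; the per-particle residuals are the
meaningful recovery statistics.

# Resolution estimation

`fsc()` computes per-shell normalized cross-spectral correlation
(shell width one Fourier voxel). `phase_randomized_fsc()` implements
the gold-standard mask correction: phases of both half-maps are
randomized beyond `rand_start` (Hermitian-symmetrically, with
independent derived seeds per half), the masked FSC is recomputed, and
`(FSC_masked − FSC_rand)/(1 − FSC_rand)` is applied beyond
`rand_start` plus a two-shell buffer; shells where `FSC_rand` is
within 1e-6 of 1 are flagged undefined rather than corrected.
`resolution_at()` reports the first threshold crossing with linear
interpolation in frequency, at 0.143 by default (the source study does
not state its threshold; 0.5 is also reported). Post-processing
divides by a user-supplied radial CTF-sum weight (floored), low-passes
to the determined resolution, and sharpens with a B-factor of −2000 Å²
— in that fixed order.

Half-map FSC is evaluated under the membrane-excluding cylindrical
mask, as in the source protocol: the two halves average different
vesicles, whose membrane radii legitimately differ, so unmasked
high-frequency agreement is not expected even for perfect coat
alignment.

# Lattice and linkage analysis

Relative transforms between neighbouring triads are compared to
pattern templates under all 3 × 3 in-plane symmetry branch
combinations and both pair orderings; a pair matches when the geodesic
rotation residual and Euclidean translation residual of its best
branch are within the tolerances (defaults 15° / 30 Å — the source
gives none; counts are always reported alongside the tolerances used,
and overlapping matches across patterns are visible because matches
are reported per pattern). `derive_pattern()` averages exemplar pairs
after canonicalizing them into a single C3 branch (sign-aligned
quaternion mean) and rejects exemplar sets whose scatter exceeds 30°
or half the translation norm. Linkage subvolume averaging follows the
half-set protocol with in-plane-only iterative alignment from a
randomized third Euler angle, the half-1 result low-passed to 55 Å as
the half-2 starting reference.

# Completeness and thickness

Completeness is judged in a 13-slice central slab with an 8-sector
mask over the coat annulus; a sector is occupied when its mean
exceeds the background mean plus two background SDs (the original
assessment was visual; the explicit criterion is exposed, and a
manual-override column can be carried in the table). The statistic is
quantized to 45° sectors, which systematically overestimates
mostly-complete and underestimates mostly-incomplete coats — planted
extents are recovered within one sector. The coated fraction of
vesicles estimates the coated fraction of the vesicle lifetime under
steady-state sampling (42 coated / 103 uncoated ≈ 0.29, "about one
third").

Thickness is the leaflet peak–peak distance only — explicitly not an
absolute bilayer thickness, which is confounded by CTF, charging and
orientation effects; no operation converts it. Averages are low-passed
to 25 Å and sharpened at −2000 Å² before profiling. Spherical averages
are straightened by radial orthographic resampling (trilinear, grid
spacing one voxel of arc at the membrane radius, elevation restricted
to a 55° cone to avoid polar distortion); profiles are lateral means
per radius with 3-point parabolic peak interpolation. The bootstrap
(default 750 replicates, seeded) resamples the subtomogram set with
replacement and repeats the full measurement; because filtering,
straightening and averaging are all linear, the per-subtomogram
straightened profiles are computed once and each replicate profile is
their resampled mean — mathematically identical to re-running the
chain, with only the non-linear peak measurement redone per
replicate. Failed replicates (fewer than two peaks) are excluded and
counted; beyond 20% failures the result is flagged unreliable. Planar
cisternal membranes are measured from 20 × 20 boxes along a traced
bilayer, aligned vertically by 1D correlation to the running average.

# Problem sizes used in the validation suite

The test and acceptance runs are sized for a single CPU: ab initio
recovery uses a four-vesicle noise-free scene (~75 planted triads,
~198 × 198 × 99 voxels at 13.68 Å), the diameter-population check
renders 267 vesicles at 6.84 Å, the bootstrap check runs the full 750
replicates on small boxes, and pattern-search scenes stay below 200
triads so the brute-force oracle remains exact. These sizes are
choices of the package's validation design; all operations accept
larger inputs.

# What the synthetic validation does not show

The generator omits CTF modulation, dose-dependent filtering, crowded
cytoplasm, neighbouring organelles, intracisternal arrays and
non-spherical (budding-neck) membrane geometry; noise is white and
Gaussian. Passing the recovery suite therefore demonstrates the
geometric and statistical correctness of the pipeline — conventions,
bookkeeping, search, symmetry handling, estimators — not robustness to
every imaging artifact of real cellular tomograms. The missing wedge
is modelled (optionally) in the generator but wedge-compensated
scoring is deliberately not enabled in the validated default path.

# Known limitations

* The alignment engine is exhaustive-local, not gradient-based; its
  angular accuracy is bounded by the finest grid step plus the
  rotation–shift coupling of the motif (~atan(position error / lobe
  radius)).
* `search_linkages()` is O(edges × branches) in pure R; for the
  lattice sizes of single-tomogram studies (hundreds of triads) this
  is seconds, but it is not engineered for millions of pairs.
* Multi-class classification, CTF refinement, local-resolution maps
  and anisotropic FSC are out of scope.
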