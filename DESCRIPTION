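Package: coatsitu
Title: In Situ Membrane Coat Analysis by Subtomogram Averaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining the structure and organisation of vesicle
    coat protein lattices inside cells from cryo-electron tomograms.
    Implements reference-free subtomogram averaging with sphere-seeded
    initialisation, independent half-set processing and C3 symmetrisation;
    gold-standard resolution estimation by mask-corrected phase-randomized
    Fourier shell correlation; lattice-map construction and rigid-transform
    linkage pattern search; sector-based coat-completeness statistics; and
    bilayer leaflet-separation measurement from radially straightened
    averages with bootstrap errors. A synthetic-scene generator renders
    coated vesicles with controllable bilayer geometry so the whole
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr, jsonlite, yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
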