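Package: sigmaqsar
Title: QSAR and Pharmacophore Geometry of Sigma-1 Receptor Piperidine Ligands
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the computational arm of a sigma-1 receptor
    structure-activity study of 1,4-disubstituted piperidines: transformation
    of possibly-censored radioligand Ki values to the pKi (log-affinity)
    scale, selectivity ratios, multilinear QSAR on molecular surface-area
    descriptors with exhaustive descriptor-subset search and leave-one-out
    validation, Shrake-Rupley solvent-accessible and van der Waals surface
    areas, grid-based van der Waals volumes and point-charge dipole moments
    computed on seeded distance-geometry conformers minimized with a classical
    force field, and Gund-style pharmacophore distance measurement (aryl
    centroid, basic nitrogen, secondary-site oxygen) with classification
    against published ranges. Ships the study's literature-transcribed
    binding and descriptor tables as plain-text fixtures together with a
    synthetic-data generator emulating their statistical structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
SystemRequirements: OpenBabel (the 'obabel' and 'obenergy' executables on PATH)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
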