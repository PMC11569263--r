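Package: hydrogate
Title: Pore Geometry, Hydration and Imaging Metrics for Ion Channel
    Gating Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis layer for hydrophobic-gating studies of
    hexameric ion channels such as Orai1. Reads multi-model PDB or XYZ
    trajectory frames and computes HOLE-style slice-wise maximal-sphere
    pore-radius profiles, axial water histograms inside pore-centred
    cylinders, solvation-shell water counts, side-chain rotation angles and
    charged-moiety distances, Calpha triangle areas, torsions and
    Kabsch-superposed per-helix RMSDs, with replica aggregation (mean and
    standard deviation of the mean). Also provides Roseman-scale sliding
    window hydropathy profiles, pixel-wise three-cube sensitized-emission
    FRET efficiency with bleed-through calibration and ratio gating, NFAT
    nucleus/cytosol translocation scoring, and seeded synthetic-data
    generators (pseudo-hexameric channels with planted water densities and
    side-chain orientations; microscopy images with planted FRET
    efficiencies and translocation ratios) that make every stage testable
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
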