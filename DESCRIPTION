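Package: stapr
Title: Structural Aggregation Propensity of Protein Structures and
    Proteome-Scale Aggregation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes a spatial, solvent-exposure-corrected aggregation
    propensity score (STAP) on protein 3D structures from per-residue
    intrinsic aggregation propensities aggregated over 10 Angstrom spheres,
    the length-normalized linear sequence score Na4vSS, and the structural
    supersaturation index SSI.  Provides the proteome-scale statistical
    layer that relates these scores to protein abundance, length, operon
    membership, essentiality, subcellular location, surface amino-acid
    composition and oligomeric state (rank tests, quartile stratification,
    operon dispersion, fold enrichment), together with a synthetic-data
    generator for coarse-grained globular structures and annotated proteome
    tables with planted effects, so the whole pipeline can be exercised and
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
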