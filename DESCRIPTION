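Package: tfscope
Title: Comparative Transcription-Factor Variant Binding and Chromatin Search Kinetics
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for comparing DNA-binding profiles of a
    transcription factor and its disease-associated variants, and for
    quantifying their chromatin search kinetics from single-molecule
    tracking. Implements Jaccard footprinting over peak sets, partitioning
    of targets into lost/retained/off-target (A/B/C) subsets, GREAT-style
    basal-plus-extension peak-to-gene assignment, rank-based 8-mer E-scores
    from protein-binding-microarray intensities with motif-class and
    flanking-base analysis, spot detection and nearest-neighbour trajectory
    linking, a three-state (bound/slow/fast) jump-distance kinetic model,
    dwell-time survival analysis with bi-exponential fits, jump-angle
    anisotropy and confinement metrics, and seed-deterministic synthetic
    data generators for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
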