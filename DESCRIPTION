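Package: divpart
Title: Divergence Partitioning and Refugial-Origin Tests for Clade-Structured Sequence Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylogeographic divergence-partition analysis of
    multi-locus sequence alignments: uncorrected p-distances with pairwise
    deletion, per-group diversity statistics (segregating sites, nucleotide
    diversity, haplotype number and diversity) with resampling
    standardization for unequal sample sizes, distance-based AMOVA Phi-ST
    with permutation significance, permutation tests comparing between-clade
    and within-clade mean distances, and tests classifying peripheral
    ("northern") localities as in-situ glacial-refugium lineages versus
    postglacial colonists from southern refugia. Includes a Jukes-Cantor
    clade-structured sequence simulator with known ground truth for
    calibration and power analysis, and a pipeline driver with
    reproducibility manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
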