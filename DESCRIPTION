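Package: fruitmap
Title: Bulked-Segregant Mutation Mapping, Selection Tests and Fruit
    Growth Morphometrics for EMS Mutant Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping ethyl-methanesulphonate (EMS) induced
    mutations by bulked segregant analysis of phenotype-pooled
    sequencing data, including a Mendelian pool-frequency model for
    recessive traits, splice-acceptor-loss consequence prediction,
    McDonald-Kreitman selection tests with the direction-of-selection
    (DoS) statistic and a covariate-matched empirical null,
    0-fold/4-fold site degeneracy counting, fruit shoulder-index
    morphometrics, lineage-based cell growth anisotropy from tracked
    polygons, and psi-K-X-[D/E] SUMOylation motif scanning.  Every
    input can be produced by built-in synthetic-data generators so the
    whole pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    Biostrings,
    vcfR,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    yaml
Config/testthat/edition: 3
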