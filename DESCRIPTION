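Package: wgpmap
Title: BAC Physical Map Construction from Whole-Genome-Profiling Fingerprints
    with Radiation Hybrid Map Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@wgpmap.org",
           role = c("aut", "cre"))
Description: Constructs BAC-based physical maps of large plant chromosomes from
    whole-genome profiling (WGP) sequence-tag fingerprints: Sulston-score clone
    overlap scoring, stepwise contig assembly with Q-clone splitting, minimal
    tiling path selection, contamination screening by tag-origin votes,
    radiation hybrid (RH) map construction under an equal-retention haploid
    breakage model, contig anchoring and ordering with synteny support,
    deletion-bin mapping, and comparative gene-order analysis against reference
    chromosomes. Includes a ground-truthed synthetic-data generator emulating an
    arm-sorted BAC library, WGP tags, an irradiation panel and deletion stocks,
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    data.table,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
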