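Package: coralaDNA
Title: Ancient Coral Holobiont DNA Simulation, Authentication and
    Population Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for working with ancient DNA recovered from fossil
    coral skeletons and their associated microbial communities. Simulates
    partial-UDG ("UDG-half") libraries with terminal cytosine-deamination
    damage, merges paired-end reads with quality-consensus arithmetic,
    builds per-position misincorporation profiles and scores read groups
    against three damage-authentication criteria, places sparse
    pseudohaploid ancient samples into modern genetic variation via
    projection PCA with chromosome-block jackknife uncertainty and f4
    statistics with weighted block-jackknife Z scores, and compares
    microbial presence/absence between sample groups with an exact
    overlap test.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    S4Vectors,
    jsonlite,
    yaml,
    graphics,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR
Config/testthat/edition: 3
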