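Package: sedaDNA
Title: Authentication, Taxonomic Profiling and Geochronology for
    Sedimentary Ancient DNA
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for shotgun sedimentary ancient DNA (sedaDNA) studies:
    lowest-common-ancestor taxonomic assignment of competitively mapped
    reads within an identity window, positional cytosine-deamination
    damage modelling with likelihood-ratio authentication (D-max and
    lambda-LR), abundance/sample-depth/replicate filter cascades with
    proportion normalization, reference-genome validation statistics for
    marine metagenome-assembled genomes (mean read ANI, breadth-of-coverage
    ratio, coverage evenness, ANI elbow selection), harmonized comparison
    of DNA, macrofossil and pollen records, and geochronological
    calculators (DNA thermal age by Arrhenius integration, depurination
    fragment-length survival, and 26Al/10Be simple burial dating with
    Monte-Carlo uncertainty propagation). A synthetic-data module generates
    every input the pipeline consumes so the whole workflow can be
    exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
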