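Package: debloom
Title: Detecting and Removing Room-Temperature Storage Blooms from
    Microbiome Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fecal samples shipped or stored at room temperature accumulate
    reads from a small set of fast-growing bacteria ("blooms"), distorting
    the compositional profile of 16S rRNA amplicon data. debloom identifies
    candidate bloom sub-OTUs (exact sequence variants) from paired
    storage-study fold changes and cross-study frequency comparisons,
    removes exact sequence matches to a bloom list from any feature table
    with full read accounting, and evaluates the effect of nested filtering
    depths on alpha-diversity group tests (Kruskal-Wallis), Bray-Curtis
    ordination, and cross-study distances. A compositional count simulator
    with planted blooms and a planted age-richness effect supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    biomformat,
    rhdf5,
    vegan,
    optparse,
    yaml,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
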