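Package: clonalscope
Title: Clonal Population Structure of Mixed-Ploidy Microsatellite Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for mixed-ploidy (diploid/triploid)
    multilocus microsatellite genotypes of clonally propagating microbes,
    built around the population structure of the wine spoilage yeast
    Brettanomyces bruxellensis.  Provides genotype table input/output with
    microplate-control normalization, putative-ploidy inference,
    nearest-reference genetic-group assignment, allele-presence PCA with a
    minimum spanning tree and a 2N-constrained randomization control,
    clonal diversity statistics (genotype richness, Shannon and inverse
    Simpson indices, evenness/equitability) with percentile bootstrap
    confidence intervals, clone detection with winery persistence and
    great-circle dispersal distance classes, vintage-binned temporal group
    dynamics, and a fully ground-truthed synthetic genotype simulator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    igraph,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
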