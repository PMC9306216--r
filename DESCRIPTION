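Package: vitacap
Title: Microbial B and K2 Vitamin Biosynthesis Capability and Abundance Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A branch-aware knowledge base of B and K2 (menaquinone) vitamin
    biosynthesis pathways, a genome-level de novo biosynthesis capability
    classifier with a cobalamin producer/consumer typology, a metagenome
    abundance profiler (TPM to KEGG orthology to functional role to pathway to
    taxon), and the group-comparison statistics used for regional and dietary
    contrasts (Bray-Curtis ordination, permutation AMOVA, rank-sum tests,
    LEfSe-style LDA effect sizes), together with a synthetic-data generator
    that plants machine-readable ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
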