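Package: RMcontext
Title: Gene-Neighborhood Analysis of Restriction-Modification Systems
    Around Two-Component-Like Anchor Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative gene-neighborhood analysis in bacterial
    genome cohorts. Extracts anchor-centered synteny windows from annotated
    gene tables, measures co-localization (linkage) between ortholog groups,
    tests enrichment of restriction-modification (R-M) domains around anchors
    against a pseudogenome permutation null, builds directed 5'->3' domain
    co-occurrence networks weighted by genus counts, and classifies
    histidine-kinase-like proteins into domain-architecture groups with
    phyletic summaries. Includes a synthetic cohort generator with planted
    linkage and R-M enrichment for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    xml2
biocViews: ComparativeGenomics, Annotation, Network, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
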