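Package: gsnet
Title: Construction and Analysis of Multi-Edge Gene Set Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds networks whose nodes are curated gene sets (pathways, GO
    terms, chromosome loci, enzyme substrate sets) and whose edges encode
    statistically significant pairwise relationships: co-membership (shared
    genes), linkage (excess molecular-interaction edges between the unique
    members of two sets), and co-enrichment (joint overrepresentation across
    compendia of experimentally derived gene lists). All three builders share
    a one-sided Fisher's exact test kernel with Benjamini-Hochberg control.
    Also provides GO DAG parsing with annotation propagation and informative
    term filtering, density-guided recursive graph bisection for module
    detection, degree-preserving edge-swap null models for comparing network
    statistics, chromosome-locus contact and enrichment analyses,
    context-specific enrichment network overlays, and seeded synthetic data
    generators with planted structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    xml2
Config/testthat/edition: 3
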