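Package: gofam
Title: Phylogenetic Functional Annotation, GO-Slim Construction and
    Gene-List Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for functional classification of gene families in an
    evolutionary context: parsing and traversal of Gene Ontology graphs
    restricted to is_a and part_of relations; event-labeled gene family
    trees (Newick/NHX) with subfamily assignment at duplication nodes and
    pairwise ortholog inference; propagation of curated gain/loss function
    events along tree branches to descendant genes (IBA annotations);
    automatic GO-slim construction from branch-level annotation usage with
    descendant-closure counting; multiple-sequence-alignment quality
    diagnostics for detecting poorly aligned or wrongly merged families;
    and gene-list overrepresentation (Fisher's exact, binomial) and
    value-based enrichment (Mann-Whitney U) tests with
    Benjamini-Hochberg FDR or Bonferroni correction. Deterministic
    synthetic-data generators make every component testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
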