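Package: meshenrich
Title: MeSH-Term Gene Set Enrichment from Literature-Derived Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a gene-to-MeSH (Medical Subject Headings) association
    database from MeSH tree-structure files and literature link tables
    (mesh2pubmed, gene2pubmed), scores query gene sets for MeSH-category
    over-representation with an upper-tail hypergeometric test under
    citation-count stringency filters, relates result genes to Gene
    Ontology aspects, KEGG pathways and protein interaction partners, and
    renders Z-score expression heatmaps and dotplots from probe-level
    microarray CSV files. Includes a seeded synthetic-fixture generator
    emitting every supported input dialect with planted statistical
    structure, and a command-line interface covering the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    grid,
    igraph,
    jsonlite,
    pheatmap,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
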