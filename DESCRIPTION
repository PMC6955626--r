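Package: metabonet
Title: Reconstruction of Seed-Anchored Gene-Metabolite Networks from KEGG
    Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds directed gene-metabolite networks around seed genes
    from pathway files in the KGML (KEGG Markup Language) dialect.
    Pathways are parsed, merged and deduplicated into a single directed
    network whose gene nodes are classified as metabolic (attached to a
    reaction) or signaling (gene-gene relations only). The network is
    then reduced by a filtering cascade: graph distance from the seed
    genes, tissue expression of gene nodes, and structural pruning of
    disconnected nodes and enzymes linked to fewer than two metabolites.
    Expression, survival-prognosis and urine-detectability annotations
    are joined onto nodes, and the result is exported as node/edge
    tables, SIF and GraphML for Cytoscape. A synthetic-data module
    generates toy pathways (a urea-cycle analog linked to a pyrimidine
    biosynthesis chain through a shared carbamoyl-phosphate analog) and
    random pathway/annotation sets with known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
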