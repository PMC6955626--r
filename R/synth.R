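# Synthetic pathways and annotation tables with known ground truth.
# Identifiers are deliberately fictional analogs ("cpd:CX001", "gsy:CPS1x"):
# the fixtures emulate the *structure* of KEGG/HPA/HMDB inputs, not their
# content, and make no claim of database fidelity.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the random pathway/annotation generators
#'
#' @param n_compounds,n_genes Pool sizes for compound and gene identifiers.
#' @param n_reactions Number of reactions per generated pathway.
#' @param p_reversible Probability a reaction is reversible.
#' @param n_relations Number of gene-gene (`PPrel`) relations.
#' @param n_pathways Number of pathways to generate.
#' @param frac_expressed,frac_prognostic,frac_urine Fractions in \[0, 1\]
#'   of genes given positive expression, genes given a significant
#'   (p < 0.001) prognosis record, and metabolites given a urine record.
#' @param seed Integer RNG seed; the same configuration always produces
#'   identical output, and the global RNG state is left untouched.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_compounds = 12L, n_genes = 8L, n_reactions = 10L,
                         p_reversible = 0.2, n_relations = 2L,
                         n_pathways = 2L, frac_expressed = 0.75,
                         frac_prognostic = 0.25, frac_urine = 0.5,
                         seed = 1L) {
  stopifnot(n_compounds >= 0, n_genes >= 0, n_reactions >= 0,
            n_relations >= 0, n_pathways >= 1,
            p_reversible >= 0, p_reversible <= 1,
            frac_expressed >= 0, frac_expressed <= 1,
            frac_prognostic >= 0, frac_prognostic <= 1,
            frac_urine >= 0, frac_urine <= 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate random, structurally valid pathways
#'
#' Each pathway draws reactions with 1-2 substrates, 1-2 products and one
#' catalysing gene from shared compound/gene pools (so compounds recur
#' across pathways and merging is exercised), plus `n_relations` random
#' `PPrel` gene-gene relations. Everything satisfies the KGML invariants
#' and serializes to parseable KGML.
#'
#' @param config A [synth_config()].
#' @return A list of `kegg_pathway` objects, deterministic under
#'   `config$seed`.
#' @export
random_pathways <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_reactions > 0 && (config$n_compounds < 1 || config$n_genes < 1)) {
    stop("infeasible configuration: reactions need compounds and genes",
         call. = FALSE)
  }
  if (config$n_relations > 0 && config$n_genes < 2) {
    stop("infeasible configuration: relations need at least two genes",
         call. = FALSE)
  }
  compounds <- sprintf("cpd:CR%03d", seq_len(config$n_compounds))
  genes <- sprintf("gsy:GR%03d", seq_len(config$n_genes))
  with_seed(config$seed, {
    lapply(seq_len(config$n_pathways), function(p) {
      random_one_pathway(sprintf("synrw%02d", p), compounds, genes, config)
    })
  })
}

random_one_pathway <- function(pid, compounds, genes, config) {
  entry_id <- 0L
  nid <- function() { entry_id <<- entry_id + 1L; entry_id }
  used_c <- character(0); used_g <- character(0)
  rx <- list()
  for (i in seq_len(config$n_reactions)) {
    ns <- sample(1:2, 1); np <- sample(1:2, 1)
    subs <- sample(compounds, min(ns, length(compounds)))
    prods <- sample(setdiff(compounds, subs),
                    min(np, length(compounds) - length(subs)))
    if (!length(prods)) prods <- sample(compounds, 1)
    g <- sample(genes, 1)
    used_c <- union(used_c, c(subs, prods)); used_g <- union(used_g, g)
    rx[[i]] <- list(name = sprintf("rn:RR%03d", i), substrates = subs,
                    products = prods, gene = g,
                    reversible = runif(1) < config$p_reversible)
  }
  rel <- list()
  for (i in seq_len(config$n_relations)) {
    pair <- sample(genes, 2)
    used_g <- union(used_g, pair)
    rel[[i]] <- pair
  }

  c_ids <- setNames(vapply(used_c, function(x) nid(), 0L), used_c)
  rx_of_gene <- lapply(setNames(nm = used_g), function(g) {
    unlist(lapply(rx, function(r) if (r$gene == g) r$name else NULL))
  })
  g_ids <- setNames(vapply(used_g, function(x) nid(), 0L), used_g)

  entries <- c(
    lapply(used_c, function(cid) list(
      entry_id = unname(c_ids[cid]), kind = "compound", kegg_ids = cid,
      label = cid, component_ids = integer(0), reaction_names = character(0))),
    lapply(used_g, function(gid) list(
      entry_id = unname(g_ids[gid]), kind = "gene", kegg_ids = gid,
      label = gid, component_ids = integer(0),
      reaction_names = as.character(rx_of_gene[[gid]] %||% character(0)))))

  reactions <- lapply(seq_along(rx), function(i) {
    r <- rx[[i]]
    list(reaction_id = nid(), names = r$name, reversible = r$reversible,
         substrate_refs = unname(c_ids[r$substrates]),
         product_refs = unname(c_ids[r$products]),
         gene_refs = unname(g_ids[r$gene]))
  })
  relations <- lapply(rel, function(pair) {
    list(entry1 = unname(g_ids[pair[1]]), entry2 = unname(g_ids[pair[2]]),
         relation_type = "PPrel", subtypes = "activation")
  })
  pw <- structure(list(pathway_id = pid, title = paste("random pathway", pid),
                       entries = entries, reactions = reactions,
                       relations = relations),
                  class = "kegg_pathway")
  validate_pathway(pw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate annotation tables with controlled fractions
#'
#' Builds the three annotation layers for an existing network:
#' `floor(frac_expressed * n_genes)` genes get a positive hepatocyte
#' expression value (the rest 0); every gene gets a prognosis row, of
#' which `floor(frac_prognostic * n_genes)` have p < 0.001 (the rest
#' well above); `floor(frac_urine * n_metabolites)` metabolites get
#' urine-detectability booleans.
#'
#' @param network A `metabo_network`.
#' @param config A [synth_config()]; only the fractions and seed are used.
#' @return A list with data frames `expression`, `prognosis`, `biofluid`.
#' @export
random_annotations <- function(network, config) {
  stopifnot(inherits(network, "metabo_network"), inherits(config, "synth_config"))
  genes <- sort(network$nodes$node_id[network$nodes$kind != "metabolite"])
  mets <- sort(network$nodes$node_id[network$nodes$kind == "metabolite"])
  with_seed(config$seed + 1L, {
    n_expr <- floor(config$frac_expressed * length(genes))
    expressed <- sample(genes, n_expr)
    expression <- data.frame(
      gene_id = genes, tissue = "hepatocytes",
      value = ifelse(genes %in% expressed, round(runif(length(genes), 1, 100), 1), 0),
      stringsAsFactors = FALSE)

    n_prog <- floor(config$frac_prognostic * length(genes))
    significant <- sample(genes, n_prog)
    prognosis <- data.frame(
      gene_id = genes,
      direction = sample(PROGNOSIS_DIRECTIONS, length(genes), replace = TRUE),
      logrank_p = ifelse(genes %in% significant,
                         runif(length(genes), 1e-12, 9e-4),
                         runif(length(genes), 0.01, 1)),
      stringsAsFactors = FALSE)

    n_ur <- floor(config$frac_urine * length(mets))
    in_urine <- sample(mets, n_ur)
    biofluid <- data.frame(
      metabolite_id = mets[mets %in% in_urine],
      in_normal_urine = sample(c(TRUE, FALSE), n_ur, replace = TRUE),
      in_abnormal_urine = sample(c(TRUE, FALSE), n_ur, replace = TRUE),
      stringsAsFactors = FALSE)
    list(expression = expression, prognosis = prognosis, biofluid = biofluid)
  })
}

toy_kgml_urea <- function() {
  paste0(
'<?xml version="1.0" encoding="UTF-8"?>
<pathway name="path:synpw1" title="Urea cycle (toy analog)">
  <entry id="1" name="cpd:CX001" type="compound"><graphics name="carbamoyl-P*"/></entry>
  <entry id="2" name="cpd:CX002" type="compound"><graphics name="ornithine*"/></entry>
  <entry id="3" name="cpd:CX003" type="compound"><graphics name="citrulline*"/></entry>
  <entry id="4" name="cpd:CX004" type="compound"><graphics name="argininosuccinate*"/></entry>
  <entry id="5" name="cpd:CX005" type="compound"><graphics name="arginine*"/></entry>
  <entry id="6" name="cpd:CX006" type="compound"><graphics name="urea*"/></entry>
  <entry id="7" name="gsy:OTCx" type="gene" reaction="rn:RX01"><graphics name="OTCx"/></entry>
  <entry id="8" name="gsy:ASS1x" type="gene" reaction="rn:RX02"><graphics name="ASS1x"/></entry>
  <entry id="9" name="gsy:ASLx" type="gene" reaction="rn:RX03"><graphics name="ASLx"/></entry>
  <entry id="10" name="gsy:ARG1x" type="gene" reaction="rn:RX04"><graphics name="ARG1x"/></entry>
  <reaction id="11" name="rn:RX01" type="irreversible">
    <substrate id="1"/><substrate id="2"/><product id="3"/>
  </reaction>
  <reaction id="12" name="rn:RX02" type="irreversible">
    <substrate id="3"/><product id="4"/>
  </reaction>
  <reaction id="13" name="rn:RX03" type="irreversible">
    <substrate id="4"/><product id="5"/>
  </reaction>
  <reaction id="14" name="rn:RX04" type="irreversible">
    <substrate id="5"/><product id="2"/><product id="6"/>
  </reaction>
</pathway>
')
}

toy_kgml_pyrimidine <- function() {
  paste0(
'<?xml version="1.0" encoding="UTF-8"?>
<pathway name="path:synpw2" title="De novo pyrimidine biosynthesis (toy analog)">
  <entry id="1" name="cpd:CX000" type="compound"><graphics name="glutamine*"/></entry>
  <entry id="2" name="cpd:CX001" type="compound"><graphics name="carbamoyl-P*"/></entry>
  <entry id="3" name="cpd:CX010" type="compound"><graphics name="aspartate*"/></entry>
  <entry id="4" name="cpd:CX011" type="compound"><graphics name="carbamoyl-aspartate*"/></entry>
  <entry id="5" name="cpd:CX012" type="compound"><graphics name="dihydroorotate*"/></entry>
  <entry id="6" name="cpd:CX013" type="compound"><graphics name="orotate*"/></entry>
  <entry id="7" name="gsy:CPS1x" type="gene" reaction="rn:RX10"><graphics name="CPS1x"/></entry>
  <entry id="8" name="gsy:CADx" type="gene" reaction="rn:RX11 rn:RX12"><graphics name="CADx"/></entry>
  <entry id="9" name="gsy:DHODHx" type="gene" reaction="rn:RX13"><graphics name="DHODHx"/></entry>
  <entry id="10" name="gsy:SIGx" type="gene"><graphics name="SIGx"/></entry>
  <reaction id="11" name="rn:RX10" type="irreversible">
    <substrate id="1"/><product id="2"/>
  </reaction>
  <reaction id="12" name="rn:RX11" type="irreversible">
    <substrate id="2"/><substrate id="3"/><product id="4"/>
  </reaction>
  <reaction id="13" name="rn:RX12" type="irreversible">
    <substrate id="4"/><product id="5"/>
  </reaction>
  <reaction id="14" name="rn:RX13" type="irreversible">
    <substrate id="5"/><product id="6"/>
  </reaction>
  <relation entry1="10" entry2="8" type="PPrel">
    <subtype name="activation" value=""/>
  </relation>
</pathway>
')
}

toy_tables <- function() {
  list(
    expression = data.frame(
      gene_id = c("gsy:CPS1x", "gsy:CADx", "gsy:OTCx", "gsy:ASS1x",
                  "gsy:ASLx", "gsy:ARG1x", "gsy:DHODHx", "gsy:SIGx"),
      tissue = "hepatocytes",
      value = c(120.5, 35.1, 80.2, 60, 0, 45.3, 0, 12.7),
      stringsAsFactors = FALSE),
    prognosis = data.frame(
      gene_id = c("gsy:CPS1x", "gsy:CADx", "gsy:OTCx", "gsy:ASS1x", "gsy:SIGx"),
      direction = c("favorable", "unfavorable", "favorable",
                    "unfavorable", "unfavorable"),
      logrank_p = c(6.93e-05, 1.72e-11, 0.005, 0.001, 0.2),
      stringsAsFactors = FALSE),
    biofluid = data.frame(
      metabolite_id = c("cpd:CX000", "cpd:CX002", "cpd:CX006", "cpd:CX013"),
      in_normal_urine = c(TRUE, TRUE, TRUE, FALSE),
      in_abnormal_urine = c(TRUE, FALSE, TRUE, TRUE),
      stringsAsFactors = FALSE))
}

toy_manifest <- function() {
  list(
    seeds = c("gsy:CADx", "gsy:CPS1x"),
    shared_compound = "cpd:CX001",
    # merged network, before any filtering
    merged = list(n_metabolites = 11L, n_metabolic_genes = 7L,
                  n_signaling_genes = 1L, n_nodes = 19L, n_edges = 20L),
    # undirected distance of every node from the nearest seed
    distances = c(
      "gsy:CPS1x" = 0L, "gsy:CADx" = 0L,
      "cpd:CX000" = 1L, "cpd:CX001" = 1L, "cpd:CX010" = 1L,
      "cpd:CX011" = 1L, "cpd:CX012" = 1L, "gsy:SIGx" = 1L,
      "gsy:OTCx" = 2L, "gsy:DHODHx" = 2L,
      "cpd:CX002" = 3L, "cpd:CX003" = 3L, "cpd:CX013" = 3L,
      "gsy:ASS1x" = 4L, "gsy:ARG1x" = 4L,
      "cpd:CX004" = 5L, "cpd:CX005" = 5L, "cpd:CX006" = 5L,
      "gsy:ASLx" = 6L),
    after_distance = list(n_metabolites = 8L, n_metabolic_genes = 4L,
                          n_signaling_genes = 1L, n_nodes = 13L, n_edges = 13L),
    after_expression = list(n_metabolites = 8L, n_metabolic_genes = 3L,
                            n_signaling_genes = 1L, n_nodes = 12L, n_edges = 11L),
    final = list(n_metabolites = 7L, n_metabolic_genes = 3L,
                 n_signaling_genes = 1L, n_nodes = 11L, n_edges = 11L),
    final_nodes = sort(c("cpd:CX000", "cpd:CX001", "cpd:CX002", "cpd:CX003",
                         "cpd:CX010", "cpd:CX011", "cpd:CX012",
                         "gsy:CPS1x", "gsy:CADx", "gsy:OTCx", "gsy:SIGx")))
}

#' The packaged toy fixture: urea cycle linked to pyrimidine biosynthesis
#'
#' Two small fixed pathways with fully hand-enumerated ground truth: a
#' four-reaction cycle modeled on the urea cycle (ornithine
#' transcarbamylase-, argininosuccinate synthase-, lyase- and
#' arginase-like genes) and a linear chain modeled on de novo pyrimidine
#' biosynthesis (carbamoyl-phosphate synthetase-, CAD- and
#' dihydroorotate-dehydrogenase-like genes plus one purely signaling
#' gene). The two pathways share a single connector compound, a
#' carbamoyl-phosphate analog, which is how the real urea cycle and
#' pyrimidine biosynthesis are biochemically linked. The seed genes are
#' the carbamoyl-phosphate synthetase analog and the CAD analog.
#'
#' All identifiers are fictional (`cpd:CX...`, `gsy:...x`). The manifest
#' records hand-enumerated node/edge counts at every pipeline stage, the
#' undirected seed distance of every node, and the final node list; tests
#' re-derive these with independent brute-force oracles.
#'
#' @return A list with elements `pathways` (two `kegg_pathway` objects),
#'   `tables` (`expression`, `prognosis`, `biofluid` data frames),
#'   `seeds` and `manifest`.
#' @export
make_toy_fixture <- function() {
  pathways <- list(parse_kgml(toy_kgml_urea()), parse_kgml(toy_kgml_pyrimidine()))
  manifest <- toy_manifest()
  list(pathways = pathways, tables = toy_tables(),
       seeds = manifest$seeds, manifest = manifest)
}

#' Materialize the toy fixture on disk
#'
#' Writes the two KGML files, the three annotation TSVs and a plain-text
#' key/value manifest into `dir`.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_toy_fixture <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- make_toy_fixture()
  paths <- c(
    synpw1 = file.path(dir, "synpw1.kgml"),
    synpw2 = file.path(dir, "synpw2.kgml"),
    expression = file.path(dir, "expression.tsv"),
    prognosis = file.path(dir, "prognosis.tsv"),
    biofluid = file.path(dir, "biofluid.tsv"),
    manifest = file.path(dir, "manifest.txt"))
  writeLines(toy_kgml_urea(), paths["synpw1"], sep = "")
  writeLines(toy_kgml_pyrimidine(), paths["synpw2"], sep = "")
  tb <- fx$tables
  tb$biofluid$in_normal_urine <- tolower(tb$biofluid$in_normal_urine)
  tb$biofluid$in_abnormal_urine <- tolower(tb$biofluid$in_abnormal_urine)
  write_tsv(tb$expression, paths["expression"])
  write_tsv(tb$prognosis, paths["prognosis"])
  write_tsv(tb$biofluid, paths["biofluid"])

  m <- fx$manifest
  kv <- c(
    paste0("seeds=", paste(m$seeds, collapse = ",")),
    paste0("shared_compound=", m$shared_compound),
    unlist(lapply(c("merged", "after_distance", "after_expression", "final"),
                  function(stage) {
                    sprintf("%s.%s=%d", stage, names(m[[stage]]),
                            unlist(m[[stage]]))
                  })),
    sprintf("distance.%s=%d", names(m$distances), m$distances),
    paste0("final_nodes=", paste(m$final_nodes, collapse = ",")))
  writeLines(kv, paths["manifest"])
  invisible(paths)
}

#' Path to the installed copy of the toy fixture
#'
#' @param file Optional file name inside the fixture directory.
#' @return A file path under the package's `extdata/toy`.
#' @export
toy_fixture_path <- function(file = "") {
  system.file("extdata", "toy", file, package = "metabonet", mustWork = FALSE)
}
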