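NODE_KINDS <- c("metabolite", "metabolic_gene", "signaling_gene")
EDGE_TYPES <- c("substrate_to_gene", "gene_to_product", "gene_to_gene")

# fixed node-attribute schema filled by the annotate_* functions; NA = absent
ATTR_COLS <- c("expression_value", "prognosis", "prognosis_p",
               "urine_normal", "urine_abnormal")

empty_nodes <- function() {
  data.frame(node_id = character(0), kind = character(0), label = character(0),
             expression_value = numeric(0), prognosis = character(0),
             prognosis_p = numeric(0), urine_normal = logical(0),
             urine_abnormal = logical(0), stringsAsFactors = FALSE)
}

empty_edges <- function() {
  d <- data.frame(source = character(0), target = character(0),
                  edge_type = character(0), stringsAsFactors = FALSE)
  d$provenance <- list()
  d
}

new_metabo_network <- function(nodes, edges, seed_ids) {
  net <- structure(list(nodes = nodes, edges = edges,
                        seed_ids = sort(unique(seed_ids))),
                   class = "metabo_network")
  sort_network(net)
}

sort_network <- function(net) {
  n <- net$nodes
  net$nodes <- n[order(n$kind, n$node_id), , drop = FALSE]
  rownames(net$nodes) <- NULL
  e <- net$edges
  e$provenance <- lapply(e$provenance, function(p) sort(unique(p)))
  net$edges <- e[order(e$source, e$target, e$edge_type), , drop = FALSE]
  rownames(net$edges) <- NULL
  net
}

#' Build a merged gene-metabolite network from pathways
#'
#' Converts one or more parsed pathways into a single directed network of
#' metabolite and gene nodes. Pathways are merged and deduplicated: each
#' distinct compound identifier and each distinct gene identifier becomes
#' exactly one node, however many pathways or entries mention it, and
#' duplicate edges are collapsed with their provenance lists merged.
#'
#' For every reaction and every gene catalysing it, each substrate yields a
#' `substrate_to_gene` edge (metabolite to gene) and each product a
#' `gene_to_product` edge (gene to metabolite); reversible reactions
#' additionally yield the mirrored edges. `PPrel` and `GErel` relations
#' yield one `gene_to_gene` edge from `entry1` to `entry2`; `PCrel`
#' relations yield a gene-to-metabolite edge typed `gene_to_product`;
#' `ECrel` and `maplink` relations produce no edges (the compound coupling
#' behind an `ECrel` is already explicit through the reaction edges).
#' Group entries are expanded to their member genes; `map` and `ortholog`
#' entries never become nodes. Self-loop edges are dropped with a warning.
#'
#' Gene nodes attached to at least one reaction anywhere in the input are
#' classified `metabolic_gene`; genes appearing only in relations are
#' `signaling_gene`. Compounds are `metabolite`.
#'
#' @param pathways A list of `kegg_pathway` objects (or a single one).
#' @param seed_ids Character vector of seed gene identifiers (namespaced,
#'   e.g. `"hsa:1373"`); each must occur as a gene in at least one pathway.
#' @return An object of class `metabo_network`: a list with a `nodes`
#'   data frame (`node_id`, `kind`, `label` plus the annotation columns,
#'   `NA` until filled), an `edges` data frame (`source`, `target`,
#'   `edge_type` and a `provenance` list column of
#'   `"<pathway_id>:<reaction or relation id>"` strings), and `seed_ids`.
#' @examples
#' pw <- parse_kgml(paste0(
#'  '<pathway name="path:syn1" title="t">',
#'  '<entry id="1" name="cpd:S" type="compound"/>',
#'  '<entry id="2" name="cpd:P" type="compound"/>',
#'  '<entry id="3" name="gsy:G" type="gene" reaction="rn:R1"/>',
#'  '<reaction id="4" name="rn:R1" type="irreversible">',
#'  '<substrate id="1"/><product id="2"/></reaction></pathway>'))
#' net <- build_network(list(pw), seed_ids = "gsy:G")
#' network_summary(net)
#' @export
build_network <- function(pathways, seed_ids) {
  if (inherits(pathways, "kegg_pathway")) pathways <- list(pathways)
  if (!length(pathways)) stop("empty pathway list", call. = FALSE)
  stopifnot(all(vapply(pathways, inherits, TRUE, "kegg_pathway")))
  seed_ids <- as.character(seed_ids)

  node_kind <- character(0)   # node_id -> kind (genes start as signaling)
  node_label <- character(0)
  edges <- list()             # key -> list(source, target, type, prov)

  add_edge <- function(src, tgt, type, prov) {
    if (src == tgt) {
      warning("dropping self-loop edge at ", src, call. = FALSE)
      return(invisible())
    }
    key <- paste(src, tgt, type, sep = "\r")
    cur <- edges[[key]]
    if (is.null(cur)) {
      edges[[key]] <<- list(source = src, target = tgt, edge_type = type,
                            provenance = prov)
    } else {
      edges[[key]]$provenance <<- union(cur$provenance, prov)
    }
  }

  for (pw in pathways) {
    ent_by_id <- setNames(pw$entries,
                          vapply(pw$entries, function(e) as.character(e$entry_id), ""))

    # expand an entry id to the gene ids it stands for (through groups)
    genes_of <- function(eid) {
      e <- ent_by_id[[as.character(eid)]]
      if (is.null(e)) return(character(0))
      if (e$kind == "gene") return(e$kegg_ids)
      if (e$kind == "group") {
        return(unique(unlist(lapply(e$component_ids, genes_of))))
      }
      character(0)
    }
    compounds_of <- function(eid) {
      e <- ent_by_id[[as.character(eid)]]
      if (is.null(e) || e$kind != "compound") return(character(0))
      e$kegg_ids
    }
    register <- function(ids, kind, label) {
      for (id in ids) {
        if (!id %in% names(node_kind)) {
          node_kind[id] <<- kind
          node_label[id] <<- if (length(ids) == 1L) label else id
        } else if (kind == "metabolic_gene" && node_kind[[id]] == "signaling_gene") {
          node_kind[id] <<- "metabolic_gene"
        }
      }
    }

    for (e in pw$entries) {
      if (e$kind == "compound") register(e$kegg_ids, "metabolite", e$label)
      if (e$kind == "gene") register(e$kegg_ids, "signaling_gene", e$label)
    }

    for (r in pw$reactions) {
      prov <- sprintf("%s:%d", pw$pathway_id, r$reaction_id)
      subs <- unique(unlist(lapply(r$substrate_refs, compounds_of)))
      prods <- unique(unlist(lapply(r$product_refs, compounds_of)))
      gene_ids <- unique(unlist(lapply(r$gene_refs, genes_of)))
      for (g in gene_ids) {
        node_kind[g] <- "metabolic_gene"
        for (s in subs) add_edge(s, g, "substrate_to_gene", prov)
        for (p in prods) add_edge(g, p, "gene_to_product", prov)
        if (r$reversible) {
          for (p in prods) add_edge(p, g, "substrate_to_gene", prov)
          for (s in subs) add_edge(g, s, "gene_to_product", prov)
        }
      }
    }

    for (i in seq_along(pw$relations)) {
      rel <- pw$relations[[i]]
      prov <- sprintf("%s:rel%d", pw$pathway_id, i)
      if (rel$relation_type %in% c("PPrel", "GErel")) {
        for (g1 in genes_of(rel$entry1)) {
          for (g2 in genes_of(rel$entry2)) add_edge(g1, g2, "gene_to_gene", prov)
        }
      } else if (rel$relation_type == "PCrel") {
        # protein-compound: orient gene -> metabolite whichever side holds it
        g <- genes_of(rel$entry1); m <- compounds_of(rel$entry2)
        if (!length(g)) { g <- genes_of(rel$entry2); m <- compounds_of(rel$entry1) }
        for (gi in g) for (mi in m) add_edge(gi, mi, "gene_to_product", prov)
      }
      # ECrel and maplink intentionally yield no edges
    }
  }

  missing <- setdiff(seed_ids,
                     names(node_kind)[node_kind != "metabolite"])
  if (length(missing)) {
    stop("seed gene(s) absent from all pathways: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  ids <- names(node_kind)
  nodes <- data.frame(node_id = ids, kind = unname(node_kind[ids]),
                      label = unname(node_label[ids]), stringsAsFactors = FALSE)
  nodes$label[is.na(nodes$label) | !nzchar(nodes$label)] <-
    nodes$node_id[is.na(nodes$label) | !nzchar(nodes$label)]
  nodes$expression_value <- NA_real_
  nodes$prognosis <- NA_character_
  nodes$prognosis_p <- NA_real_
  nodes$urine_normal <- NA
  nodes$urine_abnormal <- NA

  if (length(edges)) {
    edf <- data.frame(
      source = vapply(edges, `[[`, "", "source"),
      target = vapply(edges, `[[`, "", "target"),
      edge_type = vapply(edges, `[[`, "", "edge_type"),
      stringsAsFactors = FALSE)
    edf$provenance <- unname(lapply(edges, `[[`, "provenance"))
    rownames(edf) <- NULL
  } else {
    edf <- empty_edges()
  }

  new_metabo_network(nodes, edf, seed_ids)
}

#' Summarise node and edge counts of a network
#'
#' @param network A `metabo_network`.
#' @return A named list with `n_metabolites`, `n_metabolic_genes`,
#'   `n_signaling_genes`, `n_nodes` and `n_edges`.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "metabo_network"))
  k <- network$nodes$kind
  list(n_metabolites = sum(k == "metabolite"),
       n_metabolic_genes = sum(k == "metabolic_gene"),
       n_signaling_genes = sum(k == "signaling_gene"),
       n_nodes = nrow(network$nodes),
       n_edges = nrow(network$edges))
}

#' Induced subgraph on a set of node ids
#'
#' Keeps the given nodes and every edge whose two endpoints are both kept.
#' Seed ids absent from `keep_ids` are dropped from the seed set as well.
#'
#' @param network A `metabo_network`.
#' @param keep_ids Character vector of node ids to retain.
#' @return A `metabo_network`.
#' @export
subset_network <- function(network, keep_ids) {
  stopifnot(inherits(network, "metabo_network"))
  nodes <- network$nodes[network$nodes$node_id %in% keep_ids, , drop = FALSE]
  e <- network$edges
  e <- e[e$source %in% nodes$node_id & e$target %in% nodes$node_id, , drop = FALSE]
  new_metabo_network(nodes, e, intersect(network$seed_ids, nodes$node_id))
}

#' Compare two networks for equality
#'
#' Field-for-field comparison of the node set (ids, kinds, labels and all
#' annotation attributes), edge set (endpoints, types and provenance,
#' order-insensitive) and seed ids.
#'
#' @param a,b `metabo_network` objects.
#' @return `TRUE` or `FALSE`.
#' @export
network_equal <- function(a, b) {
  a <- sort_network(a); b <- sort_network(b)
  isTRUE(all.equal(a$nodes, b$nodes, check.attributes = FALSE)) &&
    identical(a$edges[c("source", "target", "edge_type")],
              b$edges[c("source", "target", "edge_type")]) &&
    identical(a$edges$provenance, b$edges$provenance) &&
    identical(a$seed_ids, b$seed_ids)
}

as_igraph <- function(network, directed = TRUE) {
  igraph::graph_from_data_frame(
    network$edges[c("source", "target")],
    directed = directed,
    vertices = network$nodes["node_id"])
}

#' @export
print.metabo_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(paste0("metabo_network: %d nodes (%d metabolites, ",
                     "%d metabolic genes, %d signaling genes), %d edges\n"),
              s$n_nodes, s$n_metabolites, s$n_metabolic_genes,
              s$n_signaling_genes, s$n_edges))
  cat(sprintf("  seeds: %s\n", paste(x$seed_ids, collapse = ", ")))
  invisible(x)
}
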