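# Independent oracles and small constructors shared across test files.

# Brute-force all-pairs shortest path (Floyd-Warshall dynamic programming),
# written against the definition only; never calls the package's distance
# code or igraph.
oracle_seed_distances <- function(network, mode = "undirected") {
  ids <- network$nodes$node_id
  n <- length(ids)
  A <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(A) <- 0
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    A[e$source[i], e$target[i]] <- 1
    if (mode == "undirected") A[e$target[i], e$source[i]] <- 1
  }
  for (k in seq_len(n)) {
    A <- pmin(A, outer(A[, k], A[k, ], `+`))
  }
  seeds <- network$seed_ids
  d_out <- apply(A[seeds, , drop = FALSE], 2, min)  # seed -> node
  d_in <- apply(A[, seeds, drop = FALSE], 1, min)   # node -> seed
  d <- switch(mode,
    undirected = d_out,  # A was symmetrized above
    directed_out = d_out,
    directed_in = d_in,
    directed_either = pmin(d_out, d_in))
  out <- rep(NA_integer_, length(d))
  out[is.finite(d)] <- as.integer(d[is.finite(d)])
  setNames(out, ids)[ids]
}

# Build a metabo_network directly from flat node/edge descriptions,
# bypassing the KGML route, for hand-crafted topology tests.
make_net <- function(node_ids, kinds, edges, seeds,
                     edge_types = NULL) {
  nodes <- metabonet:::empty_nodes()
  for (i in seq_along(node_ids)) {
    nodes <- rbind(nodes, data.frame(
      node_id = node_ids[i], kind = kinds[i], label = node_ids[i],
      expression_value = NA_real_, prognosis = NA_character_,
      prognosis_p = NA_real_, urine_normal = NA, urine_abnormal = NA,
      stringsAsFactors = FALSE))
  }
  if (is.null(edge_types) && nrow(edges)) {
    kind_of <- setNames(kinds, node_ids)
    edge_types <- apply(edges, 1, function(r) {
      if (kind_of[r[1]] == "metabolite") "substrate_to_gene"
      else if (kind_of[r[2]] == "metabolite") "gene_to_product"
      else "gene_to_gene"
    })
  }
  if (nrow(edges)) {
    edf <- data.frame(source = edges[, 1], target = edges[, 2],
                      edge_type = edge_types, stringsAsFactors = FALSE)
    edf$provenance <- replicate(nrow(edf), "test:1", simplify = FALSE)
  } else {
    edf <- metabonet:::empty_edges()
  }
  metabonet:::new_metabo_network(nodes, edf, seeds)
}

# Random seeded network via the package's own generator; seeds picked
# deterministically among the gene nodes present.
random_network <- function(seed, n_seeds = 2L, ...) {
  cfg <- synth_config(seed = seed, ...)
  pws <- random_pathways(cfg)
  gene_ids <- sort(unique(unlist(lapply(pws, function(pw) {
    unlist(lapply(pw$entries, function(e) if (e$kind == "gene") e$kegg_ids))
  }))))
  build_network(pws, head(gene_ids, n_seeds))
}

# Row-shuffled copy of a network (same sets, different in-memory order),
# built without the canonical sorting constructor.
shuffle_network <- function(network, seed = 42L) {
  set.seed(seed)
  net <- network
  net$nodes <- net$nodes[sample(nrow(net$nodes)), , drop = FALSE]
  rownames(net$nodes) <- NULL
  if (nrow(net$edges)) {
    net$edges <- net$edges[sample(nrow(net$edges)), , drop = FALSE]
    rownames(net$edges) <- NULL
  }
  net$seed_ids <- sample(net$seed_ids)
  net
}

empty_network <- function() {
  net <- make_net("gsy:G", "metabolic_gene",
                  matrix(character(0), ncol = 2), "gsy:G")
  subset_network(net, character(0))
}
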