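DISTANCE_MODES <- c("undirected", "directed_out", "directed_in", "directed_either")

#' Filtering-cascade configuration
#'
#' Collects every threshold of the network reduction cascade in one place.
#'
#' @param max_steps Maximum graph distance (in edges) from the nearest seed
#'   gene; nodes further away are discarded. Default 3, the cutoff beyond
#'   which merged pathway networks become too entangled to read.
#' @param distance_mode How distance is measured: `"undirected"` (default;
#'   "steps away" irrespective of edge direction), `"directed_out"`
#'   (seed to node along edge direction), `"directed_in"` (node to seed),
#'   or `"directed_either"` (minimum of the two directed distances).
#' @param expression_threshold A gene counts as expressed when its tissue
#'   expression value is strictly greater than this. Default 0.
#' @param prognosis_alpha Log-rank p-value below which a gene's survival
#'   direction is taken as a prognosis label. Default 0.001.
#' @param min_metabolite_neighbors Minimum number of distinct metabolite
#'   neighbours a metabolic gene must keep to stay in the network; a gene
#'   touching a single metabolite cannot represent a complete reaction.
#'   Default 2.
#' @param prune_to_fixpoint Re-apply the structural pruning rules until
#'   nothing changes (default `TRUE`); `FALSE` runs a single pass.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(max_steps = 3L,
                          distance_mode = "undirected",
                          expression_threshold = 0,
                          prognosis_alpha = 0.001,
                          min_metabolite_neighbors = 2L,
                          prune_to_fixpoint = TRUE) {
  distance_mode <- match.arg(distance_mode, DISTANCE_MODES)
  stopifnot(max_steps >= 0, expression_threshold >= 0,
            prognosis_alpha > 0, prognosis_alpha <= 1,
            min_metabolite_neighbors >= 0)
  structure(list(max_steps = as.integer(max_steps),
                 distance_mode = distance_mode,
                 expression_threshold = expression_threshold,
                 prognosis_alpha = prognosis_alpha,
                 min_metabolite_neighbors = as.integer(min_metabolite_neighbors),
                 prune_to_fixpoint = isTRUE(prune_to_fixpoint)),
            class = "filter_config")
}

#' Graph distance of every node from the nearest seed
#'
#' Computes, for each node, the length in edges of the shortest path
#' to/from the nearest seed gene. Unreachable nodes get `NA`, the
#' "unreachable" sentinel.
#'
#' @param network A `metabo_network` with at least one seed.
#' @param mode One of `"undirected"`, `"directed_out"`, `"directed_in"`,
#'   `"directed_either"`; see [filter_config()].
#' @return A named integer vector over all node ids; seeds map to 0 and
#'   unreachable nodes to `NA`.
#' @export
compute_seed_distances <- function(network, mode = "undirected") {
  stopifnot(inherits(network, "metabo_network"))
  mode <- match.arg(mode, DISTANCE_MODES)
  if (!length(network$seed_ids)) stop("network has no seed genes", call. = FALSE)

  g <- as_igraph(network, directed = TRUE)
  dist_for <- function(igraph_mode) {
    d <- igraph::distances(g, v = network$seed_ids, mode = igraph_mode)
    apply(d, 2, min)
  }
  d <- switch(mode,
    undirected = dist_for("all"),
    directed_out = dist_for("out"),
    directed_in = dist_for("in"),
    directed_either = pmin(dist_for("out"), dist_for("in")))
  d <- d[network$nodes$node_id]
  out <- rep(NA_integer_, length(d))
  out[is.finite(d)] <- as.integer(d[is.finite(d)])
  names(out) <- network$nodes$node_id
  out
}

#' Drop nodes further than a step budget from every seed
#'
#' Returns the induced subgraph on nodes whose seed distance is at most
#' `max_steps`. Seeds are always retained; unreachable nodes (distance
#' `NA`) are always removed, as are all edges incident to removed nodes.
#'
#' @param network A `metabo_network`.
#' @param distances Named distance vector from [compute_seed_distances()],
#'   covering every node of `network`.
#' @param max_steps Non-negative integer cutoff.
#' @return A `metabo_network`.
#' @export
filter_by_distance <- function(network, distances, max_steps = 3L) {
  stopifnot(inherits(network, "metabo_network"), max_steps >= 0)
  missing <- setdiff(network$nodes$node_id, names(distances))
  if (length(missing)) {
    stop("distance map does not cover node(s): ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  }
  d <- distances[network$nodes$node_id]
  keep <- (!is.na(d) & d <= max_steps) | network$nodes$node_id %in% network$seed_ids
  subset_network(network, network$nodes$node_id[keep])
}

#' Remove gene nodes not expressed in the target tissue
#'
#' Gene nodes (metabolic and signaling) whose expression value is at or
#' below the threshold, or which have no expression record at all, are
#' removed together with their incident edges. Metabolite nodes are never
#' touched by this filter.
#'
#' @param network A `metabo_network`.
#' @param expression Data frame with columns `gene_id`, `tissue`, `value`
#'   (see [read_expression_table()]).
#' @param threshold Expressed means `value > threshold`. Default 0.
#' @param tissue Optional tissue name to subset `expression` rows first.
#' @return A `metabo_network`; the removal report (gene ids removed and
#'   why) is attached as attribute `"filter_report"`.
#' @export
filter_unexpressed <- function(network, expression, threshold = 0, tissue = NULL) {
  stopifnot(inherits(network, "metabo_network"), is.data.frame(expression))
  if (!is.null(tissue)) expression <- expression[expression$tissue == tissue, ]
  is_gene <- network$nodes$kind %in% c("metabolic_gene", "signaling_gene")
  gene_ids <- network$nodes$node_id[is_gene]
  val <- setNames(expression$value, expression$gene_id)[gene_ids]
  no_row <- is.na(val) & !gene_ids %in% expression$gene_id
  removed <- gene_ids[is.na(val) | val <= threshold]
  out <- subset_network(network, setdiff(network$nodes$node_id, removed))
  attr(out, "filter_report") <- list(
    removed = removed,
    reason = ifelse(removed %in% gene_ids[no_row], "no_expression_record",
                    "below_threshold"))
  out
}

#' Structural pruning of the filtered network
#'
#' Applies the two structural rules of the cascade: (a) every node with no
#' undirected path to any seed is removed; (b) every metabolic gene with
#' fewer than `min_metabolite_neighbors` distinct metabolite neighbours
#' (undirected) is removed. Signaling genes and metabolites are exempt
#' from rule (b) but subject to rule (a). With `to_fixpoint = TRUE`
#' (default) the rules are re-applied until the output satisfies both
#' simultaneously, since each rule's removals can create new violations
#' of the other.
#'
#' @param network A `metabo_network` with at least one seed remaining.
#' @param min_metabolite_neighbors Rule (b) threshold, default 2.
#' @param to_fixpoint Iterate to a fixed point (default) or run one pass.
#' @return A `metabo_network`.
#' @export
prune_structure <- function(network, min_metabolite_neighbors = 2L,
                            to_fixpoint = TRUE) {
  stopifnot(inherits(network, "metabo_network"))
  if (!length(network$seed_ids)) stop("network has no seed genes", call. = FALSE)
  repeat {
    before <- nrow(network$nodes)
    network <- prune_once(network, min_metabolite_neighbors)
    if (!to_fixpoint || nrow(network$nodes) == before) break
  }
  network
}

prune_once <- function(network, min_metabolite_neighbors) {
  nodes <- network$nodes
  # (a) undirected reachability from any seed
  g <- as_igraph(network, directed = FALSE)
  reach <- unique(unlist(lapply(network$seed_ids, function(s) {
    names(igraph::subcomponent(g, s, mode = "all"))
  })))
  keep_a <- nodes$node_id %in% reach

  # (b) metabolic genes need >= k distinct metabolite neighbours
  kind_of <- setNames(nodes$kind, nodes$node_id)
  e <- network$edges
  nb <- rbind(data.frame(a = e$source, b = e$target, stringsAsFactors = FALSE),
              data.frame(a = e$target, b = e$source, stringsAsFactors = FALSE))
  nb <- nb[kind_of[nb$b] == "metabolite", , drop = FALSE]
  met_nb <- tapply(nb$b, nb$a, function(x) length(unique(x)))
  count_of <- function(id) if (id %in% names(met_nb)) met_nb[[id]] else 0L
  under <- vapply(nodes$node_id, count_of, 0L) < min_metabolite_neighbors
  fail_b <- nodes$kind == "metabolic_gene" & under
  # with no metabolites left there is no reaction to represent and rule (b)
  # is vacuous (e.g. a seeds-only network after a 0-step distance filter)
  if (!any(nodes$kind == "metabolite")) fail_b[] <- FALSE

  bad_seed <- nodes$node_id[fail_b & nodes$node_id %in% network$seed_ids]
  if (length(bad_seed)) {
    stop("degenerate input: seed metabolic gene(s) ",
         paste(bad_seed, collapse = ", "), " have fewer than ",
         min_metabolite_neighbors, " metabolite neighbours", call. = FALSE)
  }
  subset_network(network, nodes$node_id[keep_a & !fail_b])
}
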