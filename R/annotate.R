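PROGNOSIS_DIRECTIONS <- c("favorable", "unfavorable")

resolve_aliases <- function(ids, alias) {
  if (is.null(alias)) return(ids)
  stopifnot(is.data.frame(alias), ncol(alias) >= 2)
  map <- setNames(as.character(alias[[2]]), as.character(alias[[1]]))
  hit <- ids %in% names(map)
  ids[hit] <- map[ids[hit]]
  ids
}

join_report <- function(matched, unmatched) {
  list(n_records = length(matched) + length(unmatched),
       n_matched = length(matched),
       n_unmatched = length(unmatched),
       unmatched_ids = unmatched)
}

#' Attach tissue expression values to gene nodes
#'
#' Joins an expression table onto the network by exact identifier match
#' (optionally through an alias map); each matched gene node gains the
#' `expression_value` attribute. Metabolite nodes are untouched and no
#' node or edge is ever added or removed. Record ids with no matching
#' node are collected in the join report rather than silently dropped.
#'
#' @param network A `metabo_network`.
#' @param records Data frame with columns `gene_id`, `tissue`, `value`.
#' @param tissue Optional tissue name; rows for other tissues are ignored.
#' @param alias Optional two-column data frame mapping record identifiers
#'   (e.g. gene symbols) to node ids; matching is exact, never fuzzy.
#' @return The annotated network, with attribute `"join_report"` holding
#'   `n_records`, `n_matched`, `n_unmatched` and `unmatched_ids`.
#' @export
annotate_expression <- function(network, records, tissue = NULL, alias = NULL) {
  stopifnot(inherits(network, "metabo_network"), is.data.frame(records))
  stopifnot(all(c("gene_id", "tissue", "value") %in% names(records)))
  if (!is.null(tissue)) records <- records[records$tissue == tissue, , drop = FALSE]
  ids <- resolve_aliases(as.character(records$gene_id), alias)

  key <- paste(ids, records$tissue)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    vals <- tapply(records$value, key, function(v) length(unique(v)))
    conflict <- dup[vals[dup] > 1]
    if (length(conflict)) {
      stop("conflicting duplicate expression rows for: ",
           paste(conflict, collapse = ", "), call. = FALSE)
    }
  }

  is_gene <- network$nodes$kind %in% c("metabolic_gene", "signaling_gene")
  node_ids <- network$nodes$node_id
  hit <- ids %in% node_ids[is_gene]
  idx <- match(ids[hit], node_ids)
  network$nodes$expression_value[idx] <- records$value[hit]
  attr(network, "join_report") <- join_report(ids[hit], unique(ids[!hit]))
  network
}

#' Attach survival-prognosis labels to gene nodes
#'
#' Each gene with a record gains `prognosis_p` (the log-rank p-value) and
#' `prognosis`, which is the record's direction (`"favorable"` or
#' `"unfavorable"`) if and only if `logrank_p < alpha` (strict
#' inequality), and `"none"` otherwise. Genes without a record keep their
#' attributes absent.
#'
#' @param network A `metabo_network`.
#' @param records Data frame with columns `gene_id`, `direction`,
#'   `logrank_p`.
#' @param alpha Significance cutoff in (0, 1]; default 0.001.
#' @param alias Optional alias map as in [annotate_expression()].
#' @return The annotated network with a `"join_report"` attribute.
#' @export
annotate_prognosis <- function(network, records, alpha = 0.001, alias = NULL) {
  stopifnot(inherits(network, "metabo_network"), is.data.frame(records))
  stopifnot(all(c("gene_id", "direction", "logrank_p") %in% names(records)))
  stopifnot(alpha > 0, alpha <= 1)
  bad <- setdiff(unique(records$direction), PROGNOSIS_DIRECTIONS)
  if (length(bad)) {
    stop("unknown prognosis direction(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$logrank_p <= 0 | records$logrank_p > 1)) {
    stop("logrank_p values must lie in (0, 1]", call. = FALSE)
  }
  ids <- resolve_aliases(as.character(records$gene_id), alias)
  is_gene <- network$nodes$kind %in% c("metabolic_gene", "signaling_gene")
  node_ids <- network$nodes$node_id
  hit <- ids %in% node_ids[is_gene]
  idx <- match(ids[hit], node_ids)
  network$nodes$prognosis_p[idx] <- records$logrank_p[hit]
  network$nodes$prognosis[idx] <- ifelse(records$logrank_p[hit] < alpha,
                                         records$direction[hit], "none")
  attr(network, "join_report") <- join_report(ids[hit], unique(ids[!hit]))
  network
}

#' Attach urine-detectability flags to metabolite nodes
#'
#' Metabolite nodes with a record gain boolean attributes `urine_normal`
#' and `urine_abnormal` (detectable in normal/abnormal urine). Gene nodes
#' are untouched; a record whose id collides with a gene node is an error,
#' since that indicates crossed identifier namespaces.
#'
#' @param network A `metabo_network`.
#' @param records Data frame with columns `metabolite_id`,
#'   `in_normal_urine`, `in_abnormal_urine` (logical).
#' @return The annotated network with a `"join_report"` attribute.
#' @export
annotate_biofluid <- function(network, records) {
  stopifnot(inherits(network, "metabo_network"), is.data.frame(records))
  stopifnot(all(c("metabolite_id", "in_normal_urine", "in_abnormal_urine")
                %in% names(records)))
  ids <- as.character(records$metabolite_id)
  if (anyDuplicated(ids)) {
    stop("duplicate metabolite ids in biofluid table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  kind_of <- setNames(network$nodes$kind, network$nodes$node_id)
  clash <- ids[!is.na(kind_of[ids]) & kind_of[ids] != "metabolite"]
  if (length(clash)) {
    stop("biofluid record id(s) collide with gene nodes: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  hit <- ids %in% network$nodes$node_id
  idx <- match(ids[hit], network$nodes$node_id)
  network$nodes$urine_normal[idx] <- as.logical(records$in_normal_urine[hit])
  network$nodes$urine_abnormal[idx] <- as.logical(records$in_abnormal_urine[hit])
  attr(network, "join_report") <- join_report(ids[hit], unique(ids[!hit]))
  network
}

#' Read the three annotation tables
#'
#' Tab-separated files with a header row: expression
#' (`gene_id`, `tissue`, `value`), prognosis (`gene_id`, `direction`,
#' `logrank_p`) and biofluid (`metabolite_id`, `in_normal_urine`,
#' `in_abnormal_urine`, booleans serialized as `true`/`false`).
#'
#' @param path Path to the TSV file.
#' @return A data frame with the expected columns and types.
#' @name annotation_tables
NULL

#' @rdname annotation_tables
#' @export
read_expression_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "tissue", "value") %in% names(d)))
  d$value <- as.numeric(d$value)
  d
}

#' @rdname annotation_tables
#' @export
read_prognosis_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "direction", "logrank_p") %in% names(d)))
  d$logrank_p <- as.numeric(d$logrank_p)
  d
}

#' @rdname annotation_tables
#' @export
read_biofluid_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite_id", "in_normal_urine", "in_abnormal_urine")
                %in% names(d)))
  d$in_normal_urine <- tolower(as.character(d$in_normal_urine)) == "true"
  d$in_abnormal_urine <- tolower(as.character(d$in_abnormal_urine)) == "true"
  d
}
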