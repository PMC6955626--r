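# Cytoscape-oriented writers. All output is UTF-8, Unix newlines, tab
# delimited, rows canonically sorted, so identical networks give
# byte-identical files. Absent attributes export as empty strings.

fmt_num <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) {
    if (is.na(v)) "" else format(v, scientific = NA, trim = TRUE, digits = 15)
  }, ""))
}

fmt_bool <- function(x) ifelse(is.na(x), "", ifelse(x, "true", "false"))
fmt_chr <- function(x) ifelse(is.na(x), "", x)

node_table <- function(network, distances = NULL) {
  n <- sort_network(network)$nodes
  d <- if (is.null(distances)) rep(NA_integer_, nrow(n)) else
    unname(distances[n$node_id])
  data.frame(
    node_id = n$node_id, label = n$label, kind = n$kind,
    is_seed = fmt_bool(n$node_id %in% network$seed_ids),
    distance = ifelse(is.na(d), "", as.character(d)),
    expression_value = fmt_num(n$expression_value),
    prognosis = fmt_chr(n$prognosis),
    prognosis_p = fmt_num(n$prognosis_p),
    urine_normal = fmt_bool(n$urine_normal),
    urine_abnormal = fmt_bool(n$urine_abnormal),
    stringsAsFactors = FALSE)
}

edge_table <- function(network) {
  e <- sort_network(network)$edges
  data.frame(
    source = e$source, target = e$target, edge_type = e$edge_type,
    provenance = vapply(e$provenance, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
}

write_tsv <- function(d, path) {
  con <- file(path, open = "wb")  # binary keeps \n on every platform
  on.exit(close(con))
  writeLines(c(paste(names(d), collapse = "\t"),
               if (nrow(d)) do.call(paste, c(unname(d), sep = "\t"))),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write the node table
#'
#' One row per node with the fixed column order `node_id`, `label`,
#' `kind`, `is_seed`, `distance`, `expression_value`, `prognosis`,
#' `prognosis_p`, `urine_normal`, `urine_abnormal`; rows sorted by
#' (kind, node_id). Absent attributes are empty fields. Output is
#' deterministic: the same network always yields a byte-identical file.
#'
#' @param network A `metabo_network`.
#' @param path Output file path.
#' @param distances Optional named distance vector (pre-prune values are
#'   conventionally reported); `NA`/missing exports as empty.
#' @return The path, invisibly.
#' @export
write_node_table <- function(network, path, distances = NULL) {
  stopifnot(inherits(network, "metabo_network"))
  write_tsv(node_table(network, distances), path)
  invisible(path)
}

#' Write the edge table
#'
#' One row per edge with columns `source`, `target`, `edge_type`,
#' `provenance` (semicolon-joined), sorted by (source, target,
#' edge_type).
#'
#' @param network A `metabo_network`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_edge_table <- function(network, path) {
  stopifnot(inherits(network, "metabo_network"))
  write_tsv(edge_table(network), path)
  invisible(path)
}

#' Write a SIF (Simple Interaction Format) file
#'
#' One line per edge: `source<TAB>edge_type<TAB>target`, sorted.
#'
#' @param network A `metabo_network`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "metabo_network"))
  e <- sort_network(network)$edges
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(e)) {
    writeLines(paste(e$source, e$edge_type, e$target, sep = "\t"),
               con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

GRAPHML_NODE_KEYS <- list(
  label = "string", kind = "string", is_seed = "boolean",
  expression_value = "double", prognosis = "string",
  prognosis_p = "double", urine_normal = "boolean",
  urine_abnormal = "boolean")
GRAPHML_EDGE_KEYS <- list(edge_type = "string", provenance = "string")

#' Write the network as GraphML
#'
#' Emits a plain GraphML document carrying every node attribute (kind,
#' label, seed flag and the annotation layers) as typed keys, so that
#' [read_graphml()] reconstructs an identical network. Absent attributes
#' are omitted rather than written as empty data.
#'
#' @param network A `metabo_network`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "metabo_network"))
  net <- sort_network(network)
  n <- net$nodes
  esc <- xml_escape
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  for (k in names(GRAPHML_NODE_KEYS)) {
    lines <- c(lines, sprintf(
      '  <key id="%s" for="node" attr.name="%s" attr.type="%s"/>',
      k, k, GRAPHML_NODE_KEYS[[k]]))
  }
  for (k in names(GRAPHML_EDGE_KEYS)) {
    lines <- c(lines, sprintf(
      '  <key id="%s" for="edge" attr.name="%s" attr.type="%s"/>',
      k, k, GRAPHML_EDGE_KEYS[[k]]))
  }
  lines <- c(lines, '  <graph id="G" edgedefault="directed">')
  datum <- function(key, value) {
    sprintf('      <data key="%s">%s</data>', key, esc(value))
  }
  for (i in seq_len(nrow(n))) {
    lines <- c(lines, sprintf('    <node id="%s">', esc(n$node_id[i])),
               datum("label", n$label[i]),
               datum("kind", n$kind[i]),
               datum("is_seed", if (n$node_id[i] %in% net$seed_ids) "true" else "false"),
               if (!is.na(n$expression_value[i]))
                 datum("expression_value", fmt_num(n$expression_value[i])),
               if (!is.na(n$prognosis[i])) datum("prognosis", n$prognosis[i]),
               if (!is.na(n$prognosis_p[i]))
                 datum("prognosis_p", fmt_num(n$prognosis_p[i])),
               if (!is.na(n$urine_normal[i]))
                 datum("urine_normal", fmt_bool(n$urine_normal[i])),
               if (!is.na(n$urine_abnormal[i]))
                 datum("urine_abnormal", fmt_bool(n$urine_abnormal[i])),
               "    </node>")
  }
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    lines <- c(lines,
               sprintf('    <edge source="%s" target="%s">',
                       esc(e$source[i]), esc(e$target[i])),
               datum("edge_type", e$edge_type[i]),
               datum("provenance", paste(e$provenance[[i]], collapse = ";")),
               "    </edge>")
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a network back from GraphML
#'
#' Inverse of [write_graphml()]: reconstructs the `metabo_network`
#' including kinds, labels, seed set, annotation attributes and edge
#' provenance.
#'
#' @param path Path to a GraphML file written by [write_graphml()].
#' @return A `metabo_network`.
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  get_data <- function(node) {
    d <- xml2::xml_find_all(node, "./g:data", ns)
    setNames(xml2::xml_text(d), xml2::xml_attr(d, "key"))
  }
  node_els <- xml2::xml_find_all(doc, ".//g:graph/g:node", ns)
  nodes <- empty_nodes()
  seeds <- character(0)
  for (el in node_els) {
    dat <- get_data(el)
    id <- xml2::xml_attr(el, "id")
    row <- data.frame(
      node_id = id,
      kind = unname(dat[["kind"]]),
      label = unname(dat[["label"]]),
      expression_value = if ("expression_value" %in% names(dat))
        as.numeric(dat[["expression_value"]]) else NA_real_,
      prognosis = if ("prognosis" %in% names(dat))
        unname(dat[["prognosis"]]) else NA_character_,
      prognosis_p = if ("prognosis_p" %in% names(dat))
        as.numeric(dat[["prognosis_p"]]) else NA_real_,
      urine_normal = if ("urine_normal" %in% names(dat))
        dat[["urine_normal"]] == "true" else NA,
      urine_abnormal = if ("urine_abnormal" %in% names(dat))
        dat[["urine_abnormal"]] == "true" else NA,
      stringsAsFactors = FALSE)
    nodes <- rbind(nodes, row)
    if (identical(unname(dat[["is_seed"]]), "true")) seeds <- c(seeds, id)
  }
  edge_els <- xml2::xml_find_all(doc, ".//g:graph/g:edge", ns)
  if (length(edge_els)) {
    edges <- data.frame(
      source = xml2::xml_attr(edge_els, "source"),
      target = xml2::xml_attr(edge_els, "target"),
      edge_type = vapply(edge_els, function(el) {
        unname(get_data(el)[["edge_type"]])
      }, ""),
      stringsAsFactors = FALSE)
    edges$provenance <- lapply(edge_els, function(el) {
      p <- get_data(el)[["provenance"]]
      if (is.null(p) || !nzchar(p)) character(0) else strsplit(p, ";", fixed = TRUE)[[1]]
    })
  } else {
    edges <- empty_edges()
  }
  new_metabo_network(nodes, edges, seeds)
}
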