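#' Run the full network-reconstruction pipeline
#'
#' Executes the reconstruction cascade in fixed order: build the merged
#' network from the pathways, compute seed distances, drop nodes beyond
#' the step budget, join the three annotation layers (expression,
#' prognosis, biofluid), remove genes not expressed in the target tissue,
#' prune disconnected nodes and under-connected metabolic genes, and
#' export. Annotation precedes the expression filter so that the removed
#' genes are annotated in the run report, mirroring a workflow in which
#' an annotated node table is filtered by hand.
#'
#' Node distances reported in the exports are the values computed before
#' filtering; pruning does not trigger recomputation, so a single
#' "calculate then filter" pass stays reproducible.
#'
#' @param pathways List of `kegg_pathway` objects, or character paths to
#'   KGML files.
#' @param seeds Character vector of seed gene ids.
#' @param expression,prognosis,biofluid Annotation tables as data frames
#'   or TSV paths (see [annotation_tables]); any of them may be `NULL`,
#'   which skips that annotation layer (and, for `expression`, the
#'   expression filter).
#' @param config A [filter_config()].
#' @param tissue Optional tissue to subset the expression table.
#' @param out_dir Optional output directory; when given, the node table
#'   (`node_table.tsv`), edge table (`edge_table.tsv`), SIF
#'   (`network.sif`), GraphML (`network.graphml`) and a plain-text run
#'   report (`run_report.txt`) are written there. On any stage failure
#'   partial outputs are removed.
#' @return A list of class `metabonet_run` with elements `network` (the
#'   final `metabo_network`), `distances` (pre-filter distance map),
#'   `report` (class `metabonet_report`) and `files` (named paths or
#'   `NULL`).
#' @examples
#' fx <- make_toy_fixture()
#' run <- run_pipeline(fx$pathways, fx$seeds,
#'                     expression = fx$tables$expression,
#'                     prognosis = fx$tables$prognosis,
#'                     biofluid = fx$tables$biofluid)
#' run$report
#' @export
run_pipeline <- function(pathways, seeds,
                         expression = NULL, prognosis = NULL, biofluid = NULL,
                         config = filter_config(), tissue = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "filter_config"))
  if (!length(seeds)) stop("at least one seed gene id is required", call. = FALSE)

  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)  # no partial outputs on failure
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  as_table <- function(x, reader) {
    if (is.null(x) || is.data.frame(x)) x else reader(x)
  }

  stages <- list()
  joins <- list()
  removed <- list()
  note <- function(name, net) {
    stages[[name]] <<- network_summary(net)
  }

  net <- stage("build", {
    if (is.character(pathways)) pathways <- lapply(pathways, read_kgml)
    build_network(pathways, seeds)
  })
  note("build", net)

  distances <- stage("distances", compute_seed_distances(net, config$distance_mode))

  net2 <- stage("distance_filter",
                filter_by_distance(net, distances, config$max_steps))
  removed$distance_filter <- setdiff(net$nodes$node_id, net2$nodes$node_id)
  note("distance_filter", net2)

  expression <- as_table(expression, read_expression_table)
  prognosis <- as_table(prognosis, read_prognosis_table)
  biofluid <- as_table(biofluid, read_biofluid_table)

  net3 <- stage("annotate", {
    n <- net2
    if (!is.null(expression)) {
      n <- annotate_expression(n, expression, tissue = tissue)
      joins$expression <- attr(n, "join_report")
    }
    if (!is.null(prognosis)) {
      n <- annotate_prognosis(n, prognosis, alpha = config$prognosis_alpha)
      joins$prognosis <- attr(n, "join_report")
    }
    if (!is.null(biofluid)) {
      n <- annotate_biofluid(n, biofluid)
      joins$biofluid <- attr(n, "join_report")
    }
    n
  })
  note("annotate", net3)

  net4 <- if (is.null(expression)) net3 else {
    stage("expression_filter",
          filter_unexpressed(net3, expression,
                             threshold = config$expression_threshold,
                             tissue = tissue))
  }
  removed$expression_filter <- setdiff(net3$nodes$node_id, net4$nodes$node_id)
  note("expression_filter", net4)

  net5 <- stage("prune",
                prune_structure(net4, config$min_metabolite_neighbors,
                                config$prune_to_fixpoint))
  removed$prune <- setdiff(net4$nodes$node_id, net5$nodes$node_id)
  note("prune", net5)

  report <- structure(list(stages = stages, joins = joins, removed = removed,
                           config = config),
                      class = "metabonet_report")

  files <- NULL
  if (!is.null(out_dir)) {
    stage("export", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      files <- c(node_table = file.path(out_dir, "node_table.tsv"),
                  edge_table = file.path(out_dir, "edge_table.tsv"),
                  sif = file.path(out_dir, "network.sif"),
                  graphml = file.path(out_dir, "network.graphml"),
                  report = file.path(out_dir, "run_report.txt"))
      written <- files
      write_node_table(net5, files[["node_table"]], distances = distances)
      write_edge_table(net5, files[["edge_table"]])
      write_sif(net5, files[["sif"]])
      write_graphml(net5, files[["graphml"]])
      writeLines(format_report(report), files[["report"]])
    })
  }

  structure(list(network = net5, distances = distances, report = report,
                 files = files),
            class = "metabonet_run")
}

format_report <- function(report) {
  out <- character(0)
  for (s in names(report$stages)) {
    cc <- report$stages[[s]]
    out <- c(out, sprintf("%s.%s=%d", s, names(cc), unlist(cc)))
  }
  for (j in names(report$joins)) {
    jr <- report$joins[[j]]
    out <- c(out,
             sprintf("join.%s.n_records=%d", j, jr$n_records),
             sprintf("join.%s.n_matched=%d", j, jr$n_matched),
             sprintf("join.%s.n_unmatched=%d", j, jr$n_unmatched),
             sprintf("join.%s.unmatched_ids=%s", j,
                     paste(sort(jr$unmatched_ids), collapse = ",")))
  }
  for (r in names(report$removed)) {
    out <- c(out, sprintf("removed.%s=%s", r,
                          paste(sort(report$removed[[r]]), collapse = ",")))
  }
  out
}

#' @export
print.metabonet_report <- function(x, ...) {
  cat("pipeline run report\n")
  for (s in names(x$stages)) {
    cc <- x$stages[[s]]
    cat(sprintf("  %-18s %3d nodes (%d met / %d metab.genes / %d sig.genes), %d edges\n",
                s, cc$n_nodes, cc$n_metabolites, cc$n_metabolic_genes,
                cc$n_signaling_genes, cc$n_edges))
  }
  for (j in names(x$joins)) {
    jr <- x$joins[[j]]
    cat(sprintf("  join %-12s %d records: %d matched, %d unmatched\n",
                j, jr$n_records, jr$n_matched, jr$n_unmatched))
  }
  invisible(x)
}

#' @export
print.metabonet_run <- function(x, ...) {
  cat("metabonet pipeline run\n\nfinal network:\n")
  print(x$network)
  cat("\n")
  print(x$report)
  if (!is.null(x$files)) {
    cat("\nfiles:\n")
    for (f in x$files) cat("  ", f, "\n", sep = "")
  }
  invisible(x)
}
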