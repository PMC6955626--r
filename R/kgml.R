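#' @importFrom stats setNames
#' @importFrom utils read.delim head
NULL

ENTRY_KINDS <- c("gene", "compound", "map", "group", "ortholog")
RELATION_TYPES <- c("ECrel", "PPrel", "GErel", "PCrel", "maplink")

#' Parse a KGML pathway document
#'
#' Reads one pathway written in the KGML XML dialect (the format KEGG uses
#' to describe a pathway as `entry`, `reaction` and `relation` elements)
#' into a validated in-memory pathway record.
#'
#' Entries of type `gene`, `compound`, `map`, `group` and `ortholog` are
#' recognised; an entry naming several genes in its `name` attribute is
#' kept as a single entry carrying the full identifier list (splitting into
#' per-gene nodes happens during network construction). Namespace prefixes
#' such as `"hsa:"` and `"cpd:"` are preserved verbatim so identifiers stay
#' unambiguous across modules. `graphics` children are used only for the
#' display label; all other layout information is discarded. Genes are
#' linked to the reactions they catalyse through the entry `reaction`
#' attribute, as in KGML proper.
#'
#' @param xml_text A single string containing a complete KGML document,
#'   or a path to a file holding one.
#' @return An object of class `kegg_pathway`: a list with elements
#'   `pathway_id`, `title`, `entries`, `reactions` and `relations`.
#'   Each entry has `entry_id`, `kind`, `kegg_ids`, `label`,
#'   `component_ids` and `reaction_names`; each reaction has
#'   `reaction_id`, `names`, `reversible`, `substrate_refs`,
#'   `product_refs` and `gene_refs` (entry ids); each relation has
#'   `entry1`, `entry2`, `relation_type` and `subtypes`.
#' @examples
#' pw <- parse_kgml(paste0(
#'   '<pathway name="path:syn001" title="Toy">',
#'   '<entry id="1" name="cpd:C00169" type="compound"/></pathway>'))
#' length(pw$entries)
#' @seealso [write_kgml()], [build_network()]
#' @export
parse_kgml <- function(xml_text) {
  stopifnot(is.character(xml_text), length(xml_text) == 1L)
  doc <- tryCatch(
    xml2::read_xml(xml_text),
    error = function(e) stop("KGML parse error: ", conditionMessage(e), call. = FALSE)
  )
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "pathway") {
    stop("KGML parse error: root element is <", xml2::xml_name(root),
         ">, expected <pathway>", call. = FALSE)
  }

  pathway_id <- sub("^path:", "", xml2::xml_attr(root, "name", default = ""))
  title <- xml2::xml_attr(root, "title", default = "")
  if (!nzchar(pathway_id)) {
    stop("KGML validation error: pathway has no name attribute", call. = FALSE)
  }

  known_children <- c("entry", "reaction", "relation")
  child_names <- xml2::xml_name(xml2::xml_children(root))
  unknown <- setdiff(unique(child_names), known_children)
  if (length(unknown)) {
    warning("ignoring unknown KGML element(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }

  entries <- lapply(xml2::xml_find_all(root, "./entry"), parse_kgml_entry)
  names(entries) <- vapply(entries, function(e) as.character(e$entry_id), "")
  if (anyDuplicated(names(entries))) {
    stop("KGML validation error: duplicate entry id ",
         names(entries)[duplicated(names(entries))][1L], call. = FALSE)
  }

  reactions <- lapply(xml2::xml_find_all(root, "./reaction"), parse_kgml_reaction)
  relations <- lapply(xml2::xml_find_all(root, "./relation"), parse_kgml_relation)

  # attach catalysing genes: gene entries name their reactions, as in KGML
  for (i in seq_along(reactions)) {
    hit <- vapply(entries, function(e) {
      e$kind == "gene" && length(intersect(e$reaction_names, reactions[[i]]$names)) > 0
    }, logical(1))
    reactions[[i]]$gene_refs <- unname(vapply(entries[hit], `[[`, 0L, "entry_id"))
  }

  pw <- structure(
    list(pathway_id = pathway_id, title = title,
         entries = unname(entries), reactions = reactions, relations = relations),
    class = "kegg_pathway")
  validate_pathway(pw)
  pw
}

parse_kgml_entry <- function(node) {
  id <- as.integer(xml2::xml_attr(node, "id"))
  kind <- xml2::xml_attr(node, "type", default = "")
  if (is.na(id)) stop("KGML validation error: entry without numeric id", call. = FALSE)
  if (!kind %in% ENTRY_KINDS) {
    stop("KGML validation error: unknown entry kind '", kind,
         "' for entry ", id, call. = FALSE)
  }
  ids <- strsplit(trimws(xml2::xml_attr(node, "name", default = "")), "\\s+")[[1]]
  ids <- ids[nzchar(ids)]
  gr <- xml2::xml_find_first(node, "./graphics")
  label <- if (inherits(gr, "xml_node")) {
    lab <- xml2::xml_attr(gr, "name", default = "")
    sub(",.*$", "", lab)  # KGML graphics names list aliases; keep the first
  } else ""
  if (!nzchar(label)) label <- if (length(ids)) ids[[1]] else paste0("entry", id)
  comp <- as.integer(xml2::xml_attr(xml2::xml_find_all(node, "./component"), "id"))
  rx <- strsplit(trimws(xml2::xml_attr(node, "reaction", default = "")), "\\s+")[[1]]
  list(entry_id = id, kind = kind, kegg_ids = ids, label = label,
       component_ids = comp, reaction_names = rx[nzchar(rx)])
}

parse_kgml_reaction <- function(node) {
  id <- as.integer(xml2::xml_attr(node, "id"))
  nm <- strsplit(trimws(xml2::xml_attr(node, "name", default = "")), "\\s+")[[1]]
  type <- xml2::xml_attr(node, "type", default = "irreversible")
  list(reaction_id = id,
       names = nm[nzchar(nm)],
       reversible = identical(type, "reversible"),
       substrate_refs = as.integer(
         xml2::xml_attr(xml2::xml_find_all(node, "./substrate"), "id")),
       product_refs = as.integer(
         xml2::xml_attr(xml2::xml_find_all(node, "./product"), "id")),
       gene_refs = integer(0))
}

parse_kgml_relation <- function(node) {
  type <- xml2::xml_attr(node, "type", default = "")
  if (!type %in% RELATION_TYPES) {
    stop("KGML validation error: unknown relation type '", type, "'", call. = FALSE)
  }
  list(entry1 = as.integer(xml2::xml_attr(node, "entry1")),
       entry2 = as.integer(xml2::xml_attr(node, "entry2")),
       relation_type = type,
       subtypes = xml2::xml_attr(xml2::xml_find_all(node, "./subtype"), "name"))
}

validate_pathway <- function(pw) {
  ids <- vapply(pw$entries, `[[`, 0L, "entry_id")
  kind_of <- setNames(vapply(pw$entries, `[[`, "", "kind"), as.character(ids))
  for (e in pw$entries) {
    if (e$kind %in% c("gene", "compound") && length(e$kegg_ids) == 0L) {
      stop("KGML validation error: ", e$kind, " entry ", e$entry_id,
           " has no identifier", call. = FALSE)
    }
    bad <- setdiff(e$component_ids, ids)
    if (length(bad)) {
      stop("KGML validation error: group entry ", e$entry_id,
           " references missing entry ", bad[1L], call. = FALSE)
    }
  }
  for (r in pw$reactions) {
    refs <- c(r$substrate_refs, r$product_refs)
    if (length(r$substrate_refs) == 0L || length(r$product_refs) == 0L) {
      stop("KGML validation error: reaction ", r$reaction_id,
           " lacks a substrate or product", call. = FALSE)
    }
    bad <- setdiff(refs, ids)
    if (length(bad)) {
      stop("KGML validation error: reaction ", r$reaction_id,
           " references missing entry ", bad[1L], call. = FALSE)
    }
    wrong <- refs[kind_of[as.character(refs)] != "compound"]
    if (length(wrong)) {
      stop("KGML validation error: reaction ", r$reaction_id,
           " substrate/product ", wrong[1L], " is not a compound entry",
           call. = FALSE)
    }
  }
  for (rel in pw$relations) {
    bad <- setdiff(c(rel$entry1, rel$entry2), ids)
    if (length(bad)) {
      stop("KGML validation error: relation references missing entry ",
           bad[1L], call. = FALSE)
    }
  }
  invisible(pw)
}

#' Serialize a pathway back to KGML
#'
#' Writes the same KGML dialect [parse_kgml()] reads, so that
#' `parse_kgml(write_kgml(pw))` reproduces `pw` field for field. Layout
#' (`graphics`) information is reduced to the display label.
#'
#' @param pathway A `kegg_pathway` object.
#' @param path Optional file path; when `NULL` the XML is returned as a
#'   single string.
#' @return The KGML text, invisibly when written to `path`.
#' @export
write_kgml <- function(pathway, path = NULL) {
  stopifnot(inherits(pathway, "kegg_pathway"))
  esc <- xml_escape
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<pathway name="path:%s" title="%s">',
            esc(pathway$pathway_id), esc(pathway$title)))
  for (e in pathway$entries) {
    attrs <- sprintf(' id="%d" name="%s" type="%s"',
                     e$entry_id, esc(paste(e$kegg_ids, collapse = " ")), e$kind)
    if (length(e$reaction_names)) {
      attrs <- paste0(attrs, sprintf(' reaction="%s"',
                                     esc(paste(e$reaction_names, collapse = " "))))
    }
    body <- sprintf('    <graphics name="%s"/>', esc(e$label))
    if (length(e$component_ids)) {
      body <- c(body, sprintf('    <component id="%d"/>', e$component_ids))
    }
    lines <- c(lines, sprintf("  <entry%s>", attrs), body, "  </entry>")
  }
  for (r in pathway$reactions) {
    lines <- c(lines,
      sprintf('  <reaction id="%d" name="%s" type="%s">',
              r$reaction_id, esc(paste(r$names, collapse = " ")),
              if (r$reversible) "reversible" else "irreversible"),
      sprintf('    <substrate id="%d"/>', r$substrate_refs),
      sprintf('    <product id="%d"/>', r$product_refs),
      "  </reaction>")
  }
  for (rel in pathway$relations) {
    lines <- c(lines,
      sprintf('  <relation entry1="%d" entry2="%d" type="%s">',
              rel$entry1, rel$entry2, rel$relation_type),
      if (length(rel$subtypes)) sprintf('    <subtype name="%s" value=""/>',
                                        esc(rel$subtypes)),
      "  </relation>")
  }
  lines <- c(lines, "</pathway>")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Read a KGML file from disk
#'
#' @param path Path to a KGML file.
#' @return A `kegg_pathway` object; see [parse_kgml()].
#' @export
read_kgml <- function(path) {
  if (!file.exists(path)) stop("no such KGML file: ", path, call. = FALSE)
  parse_kgml(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' @export
print.kegg_pathway <- function(x, ...) {
  kinds <- table(factor(vapply(x$entries, `[[`, "", "kind"), levels = ENTRY_KINDS))
  cat(sprintf("KGML pathway %s (%s)\n", x$pathway_id, x$title))
  cat(sprintf("  entries: %d (%s)\n", length(x$entries),
              paste(sprintf("%s %d", names(kinds), kinds), collapse = ", ")))
  cat(sprintf("  reactions: %d, relations: %d\n",
              length(x$reactions), length(x$relations)))
  invisible(x)
}
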