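# Ontology handling: OBO parsing, descendant closures, subgraph pruning
# under an anchor term, and focus-term gene selection.
#
# The graph is stored as a terms table plus typed child->parent edges,
# with adjacency lists both ways for traversal.

#' Parse an OBO 1.2/1.4 flat file
#'
#' Loads all `[Term]` stanzas, excluding obsolete terms. `is_a` edges are
#' always kept; `relationship: part_of` edges optionally. Trailing `!`
#' comments on edge targets are stripped. The graph must be acyclic and
#' every edge endpoint known.
#'
#' @param path OBO file.
#' @param include_part_of Also treat `part_of` as a subsumption edge
#'   (default FALSE: the conservative is_a-only reading).
#' @return An `"ontology"` list: `terms` (data.frame `id`, `name`,
#'   `namespace`), `edges` (data.frame `child`, `parent`, `type`), and
#'   adjacency lists `children`, `parents` keyed by term id.
#' @export
parse_obo <- function(path, include_part_of = FALSE) {
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) stop("no [Term] stanzas in ", path)
  ends <- c(stanza_starts[-1] - 1L, length(lines))
  terms <- list(); edges <- list()
  for (s in term_starts) {
    e <- min(ends[stanza_starts >= s][1], length(lines))
    block <- lines[(s + 1L):e]
    getv <- function(key) sub(paste0("^", key, ": "), "",
                              grep(paste0("^", key, ": "), block, value = TRUE))
    if (any(grepl("^is_obsolete: true", block))) next
    id <- getv("id")[1]
    if (is.na(id) || !length(id)) next
    terms[[length(terms) + 1L]] <- data.frame(
      id = id,
      name = if (length(getv("name"))) getv("name")[1] else NA_character_,
      namespace = if (length(getv("namespace"))) getv("namespace")[1]
                  else NA_character_,
      stringsAsFactors = FALSE)
    for (p in getv("is_a"))
      edges[[length(edges) + 1L]] <- data.frame(
        child = id, parent = .strip_obo_comment(p), type = "is_a",
        stringsAsFactors = FALSE)
    if (include_part_of) {
      rel <- getv("relationship")
      rel <- rel[grepl("^part_of ", rel)]
      for (p in sub("^part_of ", "", rel))
        edges[[length(edges) + 1L]] <- data.frame(
          child = id, parent = .strip_obo_comment(p), type = "part_of",
          stringsAsFactors = FALSE)
    }
  }
  terms <- do.call(rbind, terms)
  if (anyDuplicated(terms$id)) stop("duplicate term ids in ", path)
  edges <- if (length(edges)) do.call(rbind, edges)
    else data.frame(child = character(), parent = character(),
                    type = character(), stringsAsFactors = FALSE)
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(unknown))
    stop("edge endpoint(s) not defined as terms: ",
         paste(unknown, collapse = ", "))
  g <- structure(list(terms = terms, edges = edges,
                      parents = split(edges$parent, edges$child),
                      children = split(edges$child, edges$parent)),
                 class = "ontology")
  cyc <- .find_cycle(g)
  if (!is.null(cyc))
    stop("ontology contains a cycle: ", paste(cyc, collapse = " -> "))
  g
}

.strip_obo_comment <- function(x) sub("\\s*!.*$", "", x)

# Kahn's algorithm; returns NULL if acyclic, else ids on a cycle
.find_cycle <- function(graph) {
  ids <- graph$terms$id
  outdeg <- vapply(ids, function(i)
    length(graph$parents[[i]]), integer(1))  # edges child->parent
  names(outdeg) <- ids
  rev_adj <- graph$children  # parent -> children
  queue <- ids[outdeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (c in rev_adj[[v]]) {
      outdeg[c] <- outdeg[c] - 1L
      if (outdeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (seen == length(ids)) NULL else names(outdeg)[outdeg > 0L]
}

#' @export
print.ontology <- function(x, ...) {
  cat("Ontology graph:", nrow(x$terms), "terms,", nrow(x$edges), "edges (",
      paste(unique(x$edges$type), collapse = ", "), ")\n")
  invisible(x)
}

#' Descendants of an anchor term
#'
#' All terms from which the anchor is reachable by child-to-parent
#' (subsumption) edges, including the anchor itself — the terms
#' "subtended by" the anchor.
#'
#' @param graph An [parse_obo()] ontology.
#' @param anchor Term id.
#' @return Character vector of term ids.
#' @export
descendants <- function(graph, anchor) {
  if (!anchor %in% graph$terms$id) stop("unknown anchor term: ", anchor)
  seen <- character(0)
  queue <- anchor
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    queue <- c(queue, graph$children[[v]])
  }
  seen
}

#' Ancestors of a term (transitive parents, term included)
#' @param graph An ontology.
#' @param term Term id.
#' @return Character vector of term ids.
#' @export
ancestors <- function(graph, term) {
  if (!term %in% graph$terms$id) stop("unknown term: ", term)
  seen <- character(0)
  queue <- term
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    queue <- c(queue, graph$parents[[v]])
  }
  seen
}

#' Prune an enriched term set under an anchor
#'
#' Keeps, in input order, only those enriched terms that lie in the
#' subgraph subtended by the anchor (i.e. are the anchor or one of its
#' descendants).
#'
#' @param enriched Character vector of term ids.
#' @param graph An ontology.
#' @param anchor Anchor term id.
#' @return The pruned character vector.
#' @export
prune_enriched <- function(enriched, graph, anchor) {
  missing <- setdiff(enriched, graph$terms$id)
  if (length(missing))
    stop("enriched term(s) not in graph: ", paste(missing, collapse = ", "))
  enriched[enriched %in% descendants(graph, anchor)]
}

#' Genes transitively annotated to a focus term
#'
#' Genes directly annotated to the focus term or to any of its
#' descendants (equivalently: annotated to the focus after true-path
#' propagation).
#'
#' @param annotations A named list gene -> character vector of term ids
#'   (direct annotations are fine), or a two-column data.frame
#'   (`gene`, `term`).
#' @param graph An ontology.
#' @param focus Focus term id.
#' @return Character vector of gene ids.
#' @export
genes_for_term <- function(annotations, graph, focus) {
  if (!focus %in% graph$terms$id) stop("unknown focus term: ", focus)
  ann <- as_annotation_list(annotations)
  desc <- descendants(graph, focus)
  names(ann)[vapply(ann, function(t) any(t %in% desc), logical(1))]
}

#' Coerce annotations to the named-list form
#' @param annotations Named list or two-column data.frame (`gene`,
#'   `term`).
#' @return Named list gene -> term ids.
#' @export
as_annotation_list <- function(annotations) {
  if (is.data.frame(annotations)) {
    stopifnot(all(c("gene", "term") %in% names(annotations)))
    lapply(split(annotations$term, annotations$gene), unique)
  } else {
    annotations
  }
}

#' Read a two-column gene/term annotation TSV
#' @param path TSV with columns gene, term (no header required; a header
#'   line starting with "gene" is skipped).
#' @return Data.frame with columns `gene`, `term`.
#' @export
read_annotations <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE,
                   col.names = c("gene", "term"), comment.char = "#")
  df[df$gene != "gene", , drop = FALSE]
}
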