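# Hypergeometric term enrichment with Benjamini-Yekutieli correction,
# cross-contrast merging, and gene-set (pathway) over-representation.
# Over-representation only (one-sided upper tail), matching SEA
# semantics; depletion is not reported.

#' Propagate annotations up the ontology (true-path rule)
#'
#' Closes each gene's term set under ancestors, so a gene annotated to a
#' term is annotated to every term subsuming it. Idempotent. Annotations
#' to unknown terms are dropped with a warning.
#'
#' @param annotations Named list or two-column data.frame (see
#'   [as_annotation_list()]).
#' @param graph An [parse_obo()] ontology.
#' @return Named list gene -> propagated term ids, with attribute
#'   `propagated = TRUE`.
#' @export
propagate_annotations <- function(annotations, graph) {
  ann <- as_annotation_list(annotations)
  known <- graph$terms$id
  # memoized ancestor closure per term
  cache <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (!is.null(cache[[t]])) return(cache[[t]])
    r <- ancestors(graph, t)
    cache[[t]] <- r
    r
  }
  dropped <- character(0)
  out <- lapply(ann, function(terms) {
    bad <- setdiff(terms, known)
    if (length(bad)) dropped <<- union(dropped, bad)
    terms <- intersect(terms, known)
    unique(unlist(lapply(terms, anc), use.names = FALSE))
  })
  if (length(dropped))
    warning("annotation(s) to unknown term(s) skipped: ",
            paste(dropped, collapse = ", "))
  attr(out, "propagated") <- TRUE
  out
}

#' Benjamini-Yekutieli adjustment
#'
#' FDR control under arbitrary dependence; wraps
#' `stats::p.adjust(method = "BY")` after validating the inputs.
#'
#' @param p P-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
by_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BY")
}

#' Singular enrichment analysis (SEA)
#'
#' Per-term over-representation of a study gene list against a universe:
#' upper-tail hypergeometric \eqn{P(X \ge k)} for every term annotating
#' at least `min_k` study genes, corrected across all tested terms
#' (Benjamini-Yekutieli by default). Annotations must be propagated for
#' DAG-consistent results; a direct-annotation list is accepted when
#' `graph` is supplied (it is propagated internally).
#'
#' @param study Character vector of study gene ids (deduplicated with a
#'   warning); must be a subset of the universe.
#' @param universe Character vector of universe gene ids; defaults to
#'   all genes in the annotations.
#' @param annotations Propagated named list (or anything
#'   [propagate_annotations()] accepts when `graph` is given).
#' @param graph Optional ontology used to propagate unpropagated
#'   annotations.
#' @param adjust `"BY"` (default) or `"BH"`.
#' @param fdr_threshold Threshold stored in the `enriched` column
#'   (default 0.05).
#' @param min_k Minimum study genes annotated for a term to be tested
#'   (default 1).
#' @return A data.frame sorted by p-value: `term`, `k`, `n`, `K`, `N`,
#'   `p_value`, `fdr`, `enriched`.
#' @export
sea <- function(study, universe = NULL, annotations, graph = NULL,
                adjust = c("BY", "BH"), fdr_threshold = 0.05, min_k = 1L) {
  adjust <- match.arg(adjust)
  if (anyDuplicated(study)) {
    warning("duplicate study genes deduplicated")
    study <- unique(study)
  }
  if (!is.null(graph) && !isTRUE(attr(annotations, "propagated")))
    annotations <- propagate_annotations(annotations, graph)
  ann <- as_annotation_list(annotations)
  if (is.null(universe)) universe <- names(ann)
  universe <- unique(universe)
  off <- setdiff(study, universe)
  if (length(off))
    stop("study gene(s) not in universe: ", paste(off, collapse = ", "))
  ann <- ann[intersect(names(ann), universe)]
  N <- length(universe)
  n <- length(study)
  term_genes <- .invert_annotations(ann)
  rows <- lapply(names(term_genes), function(t) {
    tg <- term_genes[[t]]
    k <- sum(study %in% tg)
    if (k < min_k) return(NULL)
    K <- length(tg)
    data.frame(term = t, k = k, n = n, K = K, N = N,
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      fdr = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$fdr <- if (adjust == "BY") by_adjust(res$p_value)
             else p.adjust(res$p_value, method = "BH")
  res$enriched <- res$fdr < fdr_threshold
  res <- res[order(res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "adjust") <- adjust
  attr(res, "fdr_threshold") <- fdr_threshold
  res
}

.invert_annotations <- function(ann) {
  if (!length(ann)) return(list())
  long <- data.frame(
    gene = rep(names(ann), lengths(ann)),
    term = unlist(ann, use.names = FALSE), stringsAsFactors = FALSE)
  lapply(split(long$gene, long$term), unique)
}

#' Merge per-contrast enrichment results (cross-comparison)
#'
#' Builds the term-by-contrast matrix of FDR values over the union of
#' tested terms (NA where a term was not tested for a contrast) plus
#' summary counts of terms enriched in all, in a majority, and in
#' exactly one contrast.
#'
#' @param results Named list (>= 2) of [sea()] tables, one per contrast.
#' @param fdr_threshold Enrichment call threshold for the summary
#'   (default 0.05).
#' @return A list with `fdr` (matrix), `enriched` (logical matrix) and
#'   `summary` (`shared_by_all`, `shared_by_majority`, `unique` counts).
#' @export
cross_compare <- function(results, fdr_threshold = 0.05) {
  if (length(results) < 2L) stop("need at least two contrasts")
  if (is.null(names(results)))
    names(results) <- paste0("contrast", seq_along(results))
  terms <- sort(unique(unlist(lapply(results, `[[`, "term"))))
  fdr <- matrix(NA_real_, length(terms), length(results),
                dimnames = list(terms, names(results)))
  for (j in seq_along(results)) {
    r <- results[[j]]
    fdr[match(r$term, terms), j] <- r$fdr
  }
  enr <- !is.na(fdr) & fdr < fdr_threshold
  n_enr <- rowSums(enr)
  list(fdr = fdr, enriched = enr,
       summary = c(shared_by_all = sum(n_enr == ncol(fdr)),
                   shared_by_majority = sum(n_enr > ncol(fdr) / 2),
                   unique = sum(n_enr == 1L)))
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (set name, description, then member genes,
#'   tab-separated).
#' @return Named list of gene-id vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in ", path)
  if (any(lengths(sets) == 0L)) stop("empty gene set(s) in ", path)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' Write a GMT gene-set collection
#' @param sets Named list of gene-id vectors.
#' @param path Output path.
#' @param descriptions Optional descriptions (default the set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Pathway (gene-set) over-representation
#'
#' The same hypergeometric machinery as [sea()] applied to a gene-set
#' collection: for each set, k = study genes in the set (after
#' restricting sets to the universe), tested when k >= 1.
#'
#' @param genes Study gene list (nonempty).
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param universe Universe gene ids.
#' @param adjust `"BY"` (default) or `"BH"`.
#' @param fdr_threshold Enrichment call threshold (default 0.05).
#' @return A data.frame sorted by p-value: `set`, `k`, `n`, `K`, `N`,
#'   `p_value`, `fdr`, `enriched`; attribute `adjust` records the
#'   correction used.
#' @export
pathway_enrich <- function(genes, collection, universe,
                           adjust = c("BY", "BH"), fdr_threshold = 0.05) {
  adjust <- match.arg(adjust)
  if (!length(genes)) stop("empty gene list")
  genes <- unique(genes)
  universe <- unique(universe)
  genes_u <- intersect(genes, universe)
  if (!length(genes_u))
    stop("gene list has no overlap with the universe")
  N <- length(universe)
  n <- length(genes_u)
  rows <- lapply(names(collection), function(s) {
    sg <- intersect(collection[[s]], universe)
    k <- sum(genes_u %in% sg)
    if (k < 1L) return(NULL)
    data.frame(set = s, k = k, n = n, K = length(sg), N = N,
               p_value = phyper(k - 1, length(sg), N - length(sg), n,
                                lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(set = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      fdr = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$fdr <- if (adjust == "BY") by_adjust(res$p_value)
             else p.adjust(res$p_value, method = "BH")
  res$enriched <- res$fdr < fdr_threshold
  res <- res[order(res$p_value, res$set), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "adjust") <- adjust
  res
}
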