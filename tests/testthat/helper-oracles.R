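# Independent oracles and shared fixture builders for the test suite.
# Every oracle deliberately uses a different algebraic route than the
# implementation it checks.

# Likelihood-ratio statistic of a 2x2 table via the entropy
# decomposition 2*(sum o*log(o) - sum_rows - sum_cols + N log N)
# (contrast with the cell-wise o*log(o/e) form used in the package).
g_oracle <- function(ra, aa, rb, ab) {
  o <- c(ra, aa, rb, ab)
  xlx <- function(x) sum(ifelse(x == 0, 0, x * log(x)))
  n <- sum(o)
  2 * (xlx(o) - xlx(c(ra + aa, rb + ab)) - xlx(c(ra + rb, aa + ab)) +
         xlx(n))
}

# Upper-tail hypergeometric by exhaustive enumeration of all C(N, n)
# draws from a universe with K marked elements.
hyper_tail_enum <- function(N, K, n, k) {
  draws <- combn(N, n)
  marked <- seq_len(K)
  hits <- colSums(matrix(draws %in% marked, nrow = n))
  mean(hits >= k)
}

# Benjamini-Yekutieli by direct evaluation of the step-up formula.
by_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- m * cm / seq_len(m) * p[o]
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- m / seq_len(m) * p[o]
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# --- ontology helpers -------------------------------------------------

# Write an OBO file for a term/edge specification and parse it.
make_ontology <- function(ids, edges, obsolete = character(0),
                          include_part_of = FALSE) {
  path <- tempfile(fileext = ".obo")
  con <- file(path, "w")
  writeLines(c("format-version: 1.2", ""), con)
  for (id in ids) {
    writeLines(c("[Term]", paste0("id: ", id), paste0("name: term ", id),
                 "namespace: biological_process"), con)
    if (id %in% obsolete) writeLines("is_obsolete: true", con)
    for (p in edges$parent[edges$child == id])
      writeLines(paste0("is_a: ", p, " ! x"), con)
    writeLines("", con)
  }
  close(con)
  parse_obo(path, include_part_of = include_part_of)
}

# Random DAG: node i > 1 gets 1-2 parents among earlier nodes.
random_dag_edges <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n))
  ch <- list()
  for (i in 2:n) {
    np <- sample(1:2, 1)
    for (p in sample(ids[seq_len(i - 1)], min(np, i - 1)))
      ch[[length(ch) + 1]] <- data.frame(child = ids[i], parent = p,
                                         stringsAsFactors = FALSE)
  }
  list(ids = ids, edges = do.call(rbind, ch))
}

# Reachability oracle: can `from` reach `to` following child->parent
# edges? Depth-first search with an explicit stack over the raw edge
# list (independent of the package's adjacency-list BFS).
can_reach <- function(edges, from, to) {
  stack <- from
  seen <- character(0)
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v == to) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(edges$parent[edges$child == v], stack)
  }
  FALSE
}

# --- gene/effect helpers ----------------------------------------------

# Build one random multi-exon gene model on a random genome chunk, with
# an ATG start and codon-multiple CDS. Returns list(gene, genome).
random_gene_fixture <- function(gene_id = "g1", chrom = "chr1",
                                strand = sample(c("+", "-"), 1),
                                n_exons = sample(1:3, 1),
                                genome_len = 3000) {
  genome <- setNames(paste(sample(c("A", "C", "G", "T"), genome_len,
                                  replace = TRUE), collapse = ""), chrom)
  ex_len <- 3 * sample(15:40, n_exons, replace = TRUE)
  introns <- if (n_exons > 1) sample(30:80, n_exons - 1, replace = TRUE)
             else integer(0)
  starts <- 100 + cumsum(c(0, head(ex_len, -1) + introns))
  ends <- starts + ex_len - 1
  cds <- data.frame(start = starts, end = ends,
                    phase = c(0, cumsum(head(ex_len, -1)) %% 3))
  if (strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
  gene <- list(gene_id = gene_id, transcript_id = paste0(gene_id, ".t"),
               chrom = chrom, strand = strand,
               start = min(cds$start), end = max(cds$end), cds = cds,
               complete = TRUE)
  # plant the start codon
  if (strand == "+") {
    substr(genome[[chrom]], cds$start[1], cds$start[1] + 2) <- "ATG"
  } else {
    e <- cds$end[1]
    substr(genome[[chrom]], e - 2, e) <- "CAT"
  }
  list(gene = gene, genome = genome)
}

# CDS sequence of a model from a genome, 5'->3' of the transcript.
extract_cds <- function(gene, genome) {
  segs <- gene$cds[order(gene$cds$start), , drop = FALSE]
  s <- paste(substring(genome[[gene$chrom]], segs$start, segs$end),
             collapse = "")
  if (gene$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

# Full-CDS translation oracle: mutate the genome, re-extract and
# translate the whole CDS, and classify by diffing the proteins.
effect_oracle <- function(gene, genome, chrom, pos, ref, alt) {
  segs <- gene$cds[order(gene$cds$start), , drop = FALSE]
  in_cds <- any(pos >= segs$start & pos <= segs$end)
  splice <- FALSE
  if (!in_cds && nrow(segs) > 1) {
    for (i in seq_len(nrow(segs) - 1)) {
      if (pos %in% c(segs$end[i] + 1:2, segs$start[i + 1] - 2:1))
        splice <- TRUE
    }
  }
  if (!in_cds) {
    if (splice) return("splice_site")
    if (pos >= gene$start && pos <= gene$end) return("intronic")
    return("intergenic")
  }
  if (nchar(ref) != nchar(alt))
    return(if (abs(nchar(ref) - nchar(alt)) %% 3 != 0) "frameshift"
           else "inframe_indel")
  mut <- genome
  substr(mut[[chrom]], pos, pos + nchar(ref) - 1) <- alt
  tr <- function(g) {
    s <- extract_cds(gene, g)
    as.character(Biostrings::translate(Biostrings::DNAString(s)))
  }
  p_ref <- tr(genome); p_alt <- tr(mut)
  cds_alt1 <- substr(extract_cds(gene, mut), 1, 3)
  if (cds_alt1 != "ATG" && substr(extract_cds(gene, genome), 1, 3) == "ATG")
    return("start_lost")
  if (identical(p_ref, p_alt)) return("synonymous")
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
  aar <- substr(p_ref, d[1], d[1]); aaa <- substr(p_alt, d[1], d[1])
  if (aaa == "*") return("stop_gained")
  if (aar == "*") return("stop_lost")
  "non_synonymous"
}

# --- pooled-variant helpers -------------------------------------------

# Assemble a pool_variants data.frame from per-pool depth/gq lists.
make_variants <- function(chrom, pos, ref = "A", alt = "T",
                          type = "snp", pools, depths, gqs = 99) {
  n <- length(pos)
  df <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                   ref = rep_len(ref, n), alt = rep_len(alt, n),
                   type = rep_len(type, n), stringsAsFactors = FALSE)
  for (p in pools) {
    df[[paste0(p, "_ref")]] <- rep_len(depths[[p]]$ref, n)
    df[[paste0(p, "_alt")]] <- rep_len(depths[[p]]$alt, n)
    df[[paste0(p, "_gq")]] <- rep_len(gqs, n)
  }
  structure(df, pools = pools, n_multiallelic_dropped = 0L,
            class = c("pool_variants", "data.frame"))
}

# --- session-cached synthetic fixtures --------------------------------

.fixture_env <- new.env(parent = emptyenv())

fixtures_once <- function(seed = 1) {
  key <- paste0("fix", seed)
  if (is.null(.fixture_env[[key]])) {
    dir <- file.path(tempdir(), paste0("ontoqtl-fixtures-", seed))
    unlink(dir, recursive = TRUE)
    man <- generate_fixtures(dir, seed = seed)
    .fixture_env[[key]] <- list(dir = dir, manifest = man)
  }
  .fixture_env[[key]]
}

refine_config_for <- function(fx, out_dir, seed = 1) {
  man <- fx$manifest
  pipeline_config(
    vcf = man$files$vcf, gff3 = man$files$gff3, fasta = man$files$genome,
    obo = man$files$obo, annotations = man$files$annotations,
    gmt = man$files$gmt, pools = unlist(man$pools),
    pool_sizes = unlist(man$pool_sizes), out_dir = out_dir, seed = seed)
}

refine_once <- function(seed = 1) {
  key <- paste0("run", seed)
  if (is.null(.fixture_env[[key]])) {
    fx <- fixtures_once(seed)
    cfg <- refine_config_for(fx, file.path(fx$dir, "out"), seed)
    .fixture_env[[key]] <- suppressWarnings(run_refine(cfg, quiet = TRUE))
  }
  .fixture_env[[key]]
}
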