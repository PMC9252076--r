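# Gene models, gene/QTL intersection, and coding-sequence variant-effect
# classification (a compact SnpEff-style classifier).

#' Effect-class to impact mapping
#'
#' Fixed mapping: start_lost / stop_gained / frameshift / splice_site are
#' high impact (gene-inactivating); non_synonymous / inframe_indel /
#' stop_lost are moderate; synonymous low; intronic / intergenic
#' modifier.
#' @export
impact_map <- c(start_lost = "high", stop_gained = "high",
                frameshift = "high", splice_site = "high",
                non_synonymous = "moderate", inframe_indel = "moderate",
                stop_lost = "moderate",
                synonymous = "low",
                intronic = "modifier", intergenic = "modifier")

#' Read gene models from GFF3
#'
#' Loads gene/mRNA/CDS features and keeps one model per gene: the
#' transcript with the longest total CDS. Coordinates stay 1-based
#' inclusive as in GFF3; CDS segments are ordered 5' to 3' along the
#' transcript (descending genomic position on the minus strand).
#'
#' @param path GFF3 file.
#' @return A `"gene_models"` named list; each element has `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `start`, `end` and a `cds`
#'   data.frame (`start`, `end`, `phase`). Models whose CDS length is not
#'   divisible by 3 are kept but flagged (`complete = FALSE`).
#' @export
read_gene_models <- function(path) {
  gff <- rtracklayer::readGFF(path,
                              columns = c("seqid", "type", "start", "end",
                                          "strand", "phase"),
                              tags = c("ID", "Parent"))
  gff <- as.data.frame(gff)
  gff$Parent <- vapply(gff$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  genes <- gff[gff$type == "gene", , drop = FALSE]
  mrnas <- gff[gff$type == "mRNA", , drop = FALSE]
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  orphan <- !(cds$Parent %in% mrnas$ID)
  if (any(orphan)) {
    warning(sum(orphan), " CDS feature(s) without a known mRNA parent; skipped")
    cds <- cds[!orphan, , drop = FALSE]
  }
  models <- list()
  for (gi in seq_len(nrow(genes))) {
    gid <- genes$ID[gi]
    tx <- mrnas[mrnas$Parent == gid, , drop = FALSE]
    if (!nrow(tx)) next
    # longest-CDS transcript
    lens <- vapply(tx$ID, function(t) {
      cc <- cds[cds$Parent == t, , drop = FALSE]
      if (nrow(cc)) sum(cc$end - cc$start + 1L) else 0L
    }, integer(1))
    if (max(lens) == 0L) next
    tid <- tx$ID[which.max(lens)]
    cc <- cds[cds$Parent == tid, , drop = FALSE]
    strand <- as.character(genes$strand[gi])
    cc <- cc[order(cc$start, decreasing = (strand == "-")), , drop = FALSE]
    total <- sum(cc$end - cc$start + 1L)
    models[[gid]] <- list(
      gene_id = gid, transcript_id = tid,
      chrom = as.character(genes$seqid[gi]), strand = strand,
      start = genes$start[gi], end = genes$end[gi],
      cds = data.frame(start = cc$start, end = cc$end,
                       phase = suppressWarnings(as.integer(as.character(cc$phase))),
                       stringsAsFactors = FALSE),
      complete = (total %% 3L == 0L))
  }
  structure(models, class = "gene_models")
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector, one element per sequence.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Intersect gene models with QTL regions
#'
#' A gene overlaps a region when their 1-based inclusive intervals share
#' at least one base. Overlap search uses GenomicRanges.
#'
#' @param regions A [call_regions()] data.frame (may span contrasts).
#' @param genes A `"gene_models"` list.
#' @return A data.frame `gene_id`, `contrast`, `chrom` with one row per
#'   (gene, overlapping region's contrast), deduplicated.
#' @export
intersect_genes <- function(regions, genes) {
  if (!length(genes) || !nrow(regions))
    return(data.frame(gene_id = character(), contrast = character(),
                      chrom = character(), stringsAsFactors = FALSE))
  gchr <- vapply(genes, `[[`, character(1), "chrom")
  orphan <- setdiff(unique(regions$chrom), unique(gchr))
  if (length(orphan))
    warning("region chromosome(s) absent from the gene models: ",
            paste(orphan, collapse = ", "))
  gr_genes <- GenomicRanges::GRanges(
    gchr, IRanges::IRanges(vapply(genes, `[[`, numeric(1), "start"),
                           vapply(genes, `[[`, numeric(1), "end")))
  gr_reg <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start, regions$end))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_reg)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id")[qh],
    contrast = regions$contrast[sh],
    chrom = gchr[qh],
    stringsAsFactors = FALSE)
  unique(out)
}

# 5'->3' genomic positions of all CDS bases of a model
.cds_positions <- function(gene) {
  segs <- gene$cds
  if (gene$strand == "-") {
    unlist(lapply(seq_len(nrow(segs)), function(i) segs$end[i]:segs$start[i]))
  } else {
    unlist(lapply(seq_len(nrow(segs)), function(i) segs$start[i]:segs$end[i]))
  }
}

.comp <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# cache the codon table: repeated `::` access to a lazy-data object is
# costly inside per-variant loops
.codon_cache <- new.env(parent = emptyenv())
.codon_aa <- function(codon) {
  if (is.null(.codon_cache$tab))
    .codon_cache$tab <- Biostrings::GENETIC_CODE
  aa <- .codon_cache$tab[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

#' Classify the effect of one variant on one gene model
#'
#' SNPs inside the coding sequence are translated codon-wise (standard
#' nuclear code, strand- and phase-aware): same amino acid is
#' `synonymous`; disruption of the ATG start codon is `start_lost`; a
#' stop introduced is `stop_gained`; a stop removed is `stop_lost`;
#' otherwise `non_synonymous`. Length-changing variants in the CDS are
#' `frameshift` when the length difference is not a multiple of 3, else
#' `inframe_indel`. A variant within 2 bp of a CDS/intron junction on
#' the intron side is `splice_site`. Inside the gene span but outside
#' the CDS is `intronic`; outside the span, `intergenic`.
#' Multi-nucleotide substitutions are handled codon-wise only when fully
#' contained in one codon; otherwise classified conservatively as
#' `non_synonymous` (flagged in `note`).
#'
#' @param gene One element of a `"gene_models"` list.
#' @param genome Named character vector from [read_genome_fasta()].
#' @param chrom,pos,ref,alt The variant (VCF conventions, 1-based).
#' @return A one-row data.frame: `gene_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `effect`, `impact`, `note`.
#' @export
classify_effect <- function(gene, genome, chrom, pos, ref, alt) {
  res <- function(effect, note = NA_character_)
    data.frame(gene_id = gene$gene_id, chrom = chrom, pos = pos,
               ref = ref, alt = alt, effect = effect,
               impact = unname(impact_map[effect]), note = note,
               stringsAsFactors = FALSE)
  if (!identical(chrom, gene$chrom)) return(res("intergenic"))
  seq <- genome[[chrom]]
  if (is.null(seq)) stop("chromosome ", chrom, " absent from genome")
  obs <- substr(seq, pos, pos + nchar(ref) - 1L)
  if (toupper(obs) != toupper(ref))
    stop("reference mismatch at ", chrom, ":", pos,
         " (genome has ", obs, ", variant says ", ref, ")")

  segs <- gene$cds[order(gene$cds$start), , drop = FALSE]
  vspan <- c(pos, pos + nchar(ref) - 1L)
  in_cds <- any(vspan[1] <= segs$end & vspan[2] >= segs$start)

  # splice windows: 2 bp on the intron side of internal CDS junctions
  if (!in_cds && nrow(segs) > 1L) {
    for (i in seq_len(nrow(segs) - 1L)) {
      don <- segs$end[i] + c(1L, 2L)
      acc <- segs$start[i + 1L] - c(2L, 1L)
      if (pos %in% c(don, acc)) return(res("splice_site"))
    }
  }
  if (!in_cds) {
    if (pos >= gene$start && pos <= gene$end) return(res("intronic"))
    return(res("intergenic"))
  }

  if (nchar(ref) != nchar(alt)) {
    shift <- abs(nchar(ref) - nchar(alt)) %% 3L
    return(res(if (shift != 0L) "frameshift" else "inframe_indel"))
  }

  map <- .cds_positions(gene)
  idx <- match(pos:(pos + nchar(ref) - 1L), map)
  if (anyNA(idx))  # substitution straddling a CDS edge
    return(res("non_synonymous", note = "partially non-coding substitution"))
  codon_i <- (idx - 1L) %/% 3L
  if (length(unique(codon_i)) > 1L)
    return(res("non_synonymous", note = "multi-codon substitution"))
  ci <- codon_i[1]
  cpos <- map[ci * 3L + 1:3]
  codon_ref <- toupper(paste(substring(seq, cpos, cpos), collapse = ""))
  alt_chars <- strsplit(alt, "")[[1]]
  codon_alt_chars <- strsplit(codon_ref, "")[[1]]
  within <- idx - ci * 3L  # 1..3 offsets of substituted bases
  codon_alt_chars[within] <- toupper(alt_chars)
  codon_alt <- paste(codon_alt_chars, collapse = "")
  if (gene$strand == "-") {
    codon_ref <- .comp(codon_ref)
    codon_alt <- .comp(codon_alt)
  }
  aa_ref <- .codon_aa(codon_ref)
  aa_alt <- .codon_aa(codon_alt)
  if (ci == 0L && codon_ref == "ATG" && codon_alt != "ATG")
    return(res("start_lost"))
  if (identical(aa_ref, aa_alt)) return(res("synonymous"))
  if (identical(aa_alt, "*")) return(res("stop_gained"))
  if (identical(aa_ref, "*")) return(res("stop_lost"))
  res("non_synonymous")
}

#' Classify all variants against all gene models
#'
#' Each variant is classified against every gene model on its
#' chromosome; genic calls (anything but intergenic) are reported per
#' gene, and variants hitting no gene get one intergenic row with
#' `gene_id = NA`.
#'
#' @param genes A `"gene_models"` list.
#' @param genome Named character vector from [read_genome_fasta()].
#' @param variants A `"pool_variants"` data.frame (or any data.frame with
#'   `chrom`, `pos`, `ref`, `alt`).
#' @return A data.frame of effects (see [classify_effect()]).
#' @export
classify_variants <- function(genes, genome, variants) {
  gchr <- vapply(genes, `[[`, character(1), "chrom")
  gstart <- vapply(genes, `[[`, numeric(1), "start")
  gend <- vapply(genes, `[[`, numeric(1), "end")
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    # cheap prefilter: gene span padded by 2 bp covers splice windows
    cand <- which(gchr == v$chrom & gstart - 2L <= v$pos & gend + 2L >= v$pos)
    hit <- FALSE
    for (g in cand) {
      e <- classify_effect(genes[[g]], genome, v$chrom, v$pos, v$ref, v$alt)
      if (e$effect != "intergenic") {
        rows[[length(rows) + 1L]] <- e
        hit <- TRUE
      }
    }
    if (!hit)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = NA_character_, chrom = v$chrom, pos = v$pos,
        ref = v$ref, alt = v$alt, effect = "intergenic",
        impact = "modifier", note = NA_character_,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      effect = character(), impact = character(),
                      note = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize variant impacts inside vs outside QTL regions
#'
#' Per-gene effect-class counts plus, for each contrast, whether the gene
#' overlaps a QTL region of that contrast; also returns the global
#' impact-by-location cross-tabulation (a gene counts as "inside" when it
#' overlaps a region of any contrast).
#'
#' @param genes A `"gene_models"` list.
#' @param effects Output of [classify_variants()].
#' @param regions A regions data.frame across contrasts.
#' @return A list with `per_gene` (data.frame of counts and inside-QTL
#'   flags) and `crosstab` (impact x inside/outside matrix of variant
#'   counts).
#' @export
impact_summary <- function(genes, effects, regions) {
  ov <- intersect_genes(regions, genes)
  contrasts <- unique(regions$contrast)
  eff_classes <- names(impact_map)
  gids <- vapply(genes, `[[`, character(1), "gene_id")
  genic <- effects[!is.na(effects$gene_id), , drop = FALSE]
  per_gene <- data.frame(gene_id = gids, stringsAsFactors = FALSE)
  for (ec in eff_classes)
    per_gene[[ec]] <- vapply(gids, function(g)
      sum(genic$gene_id == g & genic$effect == ec), integer(1))
  for (ct in contrasts)
    per_gene[[paste0("in_", ct)]] <-
      gids %in% ov$gene_id[ov$contrast == ct]
  inside_any <- gids %in% ov$gene_id
  genic$inside <- ifelse(inside_any[match(genic$gene_id, gids)],
                         "inside", "outside")
  crosstab <- table(factor(genic$impact,
                           levels = c("high", "moderate", "low", "modifier")),
                    factor(genic$inside, levels = c("inside", "outside")))
  list(per_gene = per_gene, crosstab = crosstab)
}
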