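# Synthetic pooled-BSA data: a two-parent cross segregating for a
# quantitative trait, individuals binned into trait pools, pooled read
# depths drawn per marker, plus toy genome / gene-model / ontology /
# annotation / pathway fixtures with recorded ground truth.

#' Simulation configuration
#'
#' Defaults emulate a heterozygous x doubled-haploid cross phenotyped for
#' a quantitative trait and binned into four trait-ordered pools of
#' 11/8/11/9 individuals, sequenced to ~110x per pool — the scale of a
#' typical four-bulk flowering-time BSA experiment.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param n_markers Total marker count, distributed over chromosomes in
#'   proportion to length.
#' @param causal_chrom,causal_pos Planted causal locus (always included
#'   as a marker).
#' @param recomb_rate Recombination rate in Morgans per Mb (Haldane map
#'   function between adjacent markers). The toy chromosomes compress
#'   whole chromosomes into a few Mb, so the genetic map is compressed
#'   with them: the default 0.25 M/Mb makes a 6 Mb toy chromosome about
#'   150 cM, a realistic chromosome map length.
#' @param pool_sizes Named integer vector, individuals per pool in trait
#'   order (low to high).
#' @param effect Additive trait effect of the causal alternate allele.
#' @param noise_sd Environmental (residual) trait standard deviation.
#' @param mean_depth Mean per-pool read depth per marker (Poisson).
#' @param design `"f1_het_dh"` (segregating-allele dosage Bernoulli(1/2)
#'   per individual) or `"f2"`.
#' @param gq Genotype quality written for every call (default 99).
#' @param miscall_rate Per-read sequencing-error substitution rate
#'   epsilon (default 0).
#' @param censor_threshold Optional trait value above which all
#'   individuals are binned into the last pool regardless of rank
#'   (emulates a right-censored "never scored" pool); default off.
#' @param seed Integer seed driving every stochastic step.
#' @param markers Optional data.frame (`chrom`, `pos`, and optionally
#'   `ref`, `alt`) of extra marker sites merged into the grid.
#' @param markers_only If `TRUE`, `markers` (with `ref` and `alt`) is
#'   the complete marker table: no grid is generated and no random
#'   alleles are drawn, so alleles can be kept consistent with an
#'   external genome sequence. The causal position must be present.
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(chrom_lengths = c(C1 = 6e6, C2 = 4e6),
                       n_markers = 500,
                       causal_chrom = "C1", causal_pos = 3e6,
                       recomb_rate = 0.25,
                       pool_sizes = c(EF = 11, IF = 8, LF = 11, NF = 9),
                       effect = 2, noise_sd = 1,
                       mean_depth = 110,
                       design = c("f1_het_dh", "f2"),
                       gq = 99, miscall_rate = 0,
                       censor_threshold = NULL,
                       seed = 1L, markers = NULL, markers_only = FALSE) {
  design <- match.arg(design)
  stopifnot(causal_chrom %in% names(chrom_lengths),
            causal_pos >= 1, causal_pos <= chrom_lengths[[causal_chrom]],
            mean_depth > 0, length(pool_sizes) >= 2, all(pool_sizes >= 1))
  structure(list(chrom_lengths = chrom_lengths, n_markers = n_markers,
                 causal_chrom = causal_chrom, causal_pos = causal_pos,
                 recomb_rate = recomb_rate, pool_sizes = pool_sizes,
                 effect = effect, noise_sd = noise_sd,
                 mean_depth = mean_depth, design = design, gq = gq,
                 miscall_rate = miscall_rate,
                 censor_threshold = censor_threshold,
                 seed = as.integer(seed), markers = markers,
                 markers_only = markers_only),
            class = "sim_config")
}

#' Simulate a pooled cross with a planted causal locus
#'
#' Each individual inherits a marker haplotype from the segregating
#' parent by a Markov walk along each chromosome (switch probability
#' from the Haldane map function between adjacent markers), so markers
#' are linked to the causal locus through physical distance. The trait
#' is `effect * causal dosage + N(0, noise_sd)`; individuals are ranked
#' by trait and binned into the configured pools (low trait first).
#' Per marker and pool, read depth is Poisson(mean_depth) (floored at 1)
#' and the alternate depth Binomial(depth, pool allele frequency),
#' optionally perturbed by a miscall rate.
#'
#' @param config A [sim_config()].
#' @param vcf_path Optional path; when given, the VCF is written there
#'   (byte-identical across runs with the same config).
#' @return A list: `variants` (a `"pool_variants"` data.frame), `truth`
#'   (causal locus, per-individual genotypes, pool assignments, true
#'   per-pool allele frequencies), and `vcf_path`.
#' @export
simulate_cross <- function(config = sim_config(), vcf_path = NULL) {
  pools <- names(config$pool_sizes)
  n_ind <- sum(config$pool_sizes)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  if (isTRUE(config$markers_only)) {
    stopifnot(all(c("chrom", "pos", "ref", "alt") %in%
                    names(config$markers)))
    map <- config$markers[, c("chrom", "pos", "ref", "alt")]
    map <- map[!duplicated(paste(map$chrom, map$pos)), , drop = FALSE]
    if (!any(map$chrom == config$causal_chrom &
               map$pos == config$causal_pos))
      stop("markers_only requires the causal position among the markers")
    map <- map[order(map$chrom, map$pos), , drop = FALSE]
    rownames(map) <- NULL
    M <- nrow(map)
  } else {
    # marker map: proportional grid per chromosome + causal + extras
    map <- marker_grid(config$chrom_lengths, config$n_markers)
    map <- rbind(map, data.frame(chrom = config$causal_chrom,
                                 pos = config$causal_pos))
    if (!is.null(config$markers))
      map <- rbind(map, config$markers[, c("chrom", "pos")])
    map <- map[!duplicated(paste(map$chrom, map$pos)), , drop = FALSE]
    map <- map[order(map$chrom, map$pos), , drop = FALSE]
    rownames(map) <- NULL
    M <- nrow(map)

    # ref/alt alleles (extras may carry fixed alleles)
    bases <- c("A", "C", "G", "T")
    map$ref <- sample(bases, M, replace = TRUE)
    map$alt <- vapply(map$ref, function(r) sample(setdiff(bases, r), 1L),
                      character(1))
    if (!is.null(config$markers) &&
        all(c("ref", "alt") %in% names(config$markers))) {
      i <- match(paste(config$markers$chrom, config$markers$pos),
                 paste(map$chrom, map$pos))
      map$ref[i] <- config$markers$ref
      map$alt[i] <- config$markers$alt
    }
  }

  # haplotypes: Markov walk along each chromosome
  geno <- matrix(0L, n_ind, M)
  for (cc in unique(map$chrom)) {
    idx <- which(map$chrom == cc)
    p <- map$pos[idx]
    r <- c(NA, 0.5 * (1 - exp(-2 * config$recomb_rate * diff(p) / 1e6)))
    g <- matrix(0L, n_ind, length(idx))
    g[, 1] <- rbinom(n_ind, 1L, 0.5)
    for (j in seq_along(idx)[-1]) {
      sw <- rbinom(n_ind, 1L, r[j])
      g[, j] <- ifelse(sw == 1L, 1L - g[, j - 1L], g[, j - 1L])
    }
    geno[, idx] <- g
  }
  if (config$design == "f2") {
    # second gamete, independent recombination history
    geno2 <- matrix(0L, n_ind, M)
    for (cc in unique(map$chrom)) {
      idx <- which(map$chrom == cc)
      p <- map$pos[idx]
      r <- c(NA, 0.5 * (1 - exp(-2 * config$recomb_rate * diff(p) / 1e6)))
      g <- matrix(0L, n_ind, length(idx))
      g[, 1] <- rbinom(n_ind, 1L, 0.5)
      for (j in seq_along(idx)[-1]) {
        sw <- rbinom(n_ind, 1L, r[j])
        g[, j] <- ifelse(sw == 1L, 1L - g[, j - 1L], g[, j - 1L])
      }
      geno2[, idx] <- g
    }
  }

  causal_i <- which(map$chrom == config$causal_chrom &
                      map$pos == config$causal_pos)[1]
  dosage <- if (config$design == "f2")
    (geno[, causal_i] + geno2[, causal_i]) / 2 else geno[, causal_i]
  trait <- config$effect * dosage + rnorm(n_ind, 0, config$noise_sd)

  ord <- order(trait)
  assignment <- integer(n_ind)
  assignment[ord] <- rep(seq_along(pools), config$pool_sizes)
  if (!is.null(config$censor_threshold))
    assignment[trait > config$censor_threshold] <- length(pools)

  # per-pool allele frequencies (haplotype scale for F1, dosage for F2)
  freq <- matrix(0, length(pools), M, dimnames = list(pools, NULL))
  for (k in seq_along(pools)) {
    members <- which(assignment == k)
    fk <- if (config$design == "f2")
      (colMeans(geno[members, , drop = FALSE]) +
         colMeans(geno2[members, , drop = FALSE])) / 2
    else colMeans(geno[members, , drop = FALSE])
    freq[k, ] <- fk
  }

  eps <- config$miscall_rate
  df <- data.frame(chrom = map$chrom, pos = map$pos,
                   ref = map$ref, alt = map$alt, type = "snp",
                   stringsAsFactors = FALSE)
  for (k in seq_along(pools)) {
    d <- pmax(1L, rpois(M, config$mean_depth))
    f_obs <- freq[k, ] * (1 - eps) + (1 - freq[k, ]) * eps
    a <- rbinom(M, d, f_obs)
    df[[paste0(pools[k], "_ref")]] <- d - a
    df[[paste0(pools[k], "_alt")]] <- a
    df[[paste0(pools[k], "_gq")]] <- config$gq
  }
  variants <- structure(df, pools = pools, n_multiallelic_dropped = 0L,
                        class = c("pool_variants", "data.frame"))
  if (!is.null(vcf_path)) write_pool_vcf(variants, vcf_path)
  list(variants = variants,
       truth = list(causal_chrom = config$causal_chrom,
                    causal_pos = config$causal_pos,
                    genotypes = geno,
                    trait = trait,
                    pool_assignment = setNames(pools[assignment], NULL),
                    true_freq = freq,
                    marker_chrom = map$chrom, marker_pos = map$pos),
       vcf_path = vcf_path)
}

#' Evenly spaced marker grid over a set of chromosomes
#'
#' Markers are distributed over chromosomes proportionally to length, at
#' least two per chromosome.
#'
#' @param chrom_lengths Named lengths in bp.
#' @param n_markers Total marker count.
#' @return A data.frame `chrom`, `pos`.
#' @export
marker_grid <- function(chrom_lengths, n_markers) {
  tot <- sum(chrom_lengths)
  mk <- lapply(names(chrom_lengths), function(cc) {
    L <- chrom_lengths[[cc]]
    m <- max(2L, round(n_markers * L / tot))
    data.frame(chrom = cc,
               pos = round(seq(L / (2 * m), L - L / (2 * m),
                               length.out = m)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, mk)
}

# --- toy fixture construction -----------------------------------------

.random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

# place ATG (strand-aware) at the translation start of a model
.plant_start_codon <- function(genome, gene) {
  chrom <- gene$chrom
  if (gene$strand == "+") {
    s <- gene$cds$start[1]
    substr(genome[[chrom]], s, s + 2L) <- "ATG"
  } else {
    e <- gene$cds$end[1]  # cds ordered 5'->3', first segment has max end
    substr(genome[[chrom]], e - 2L, e) <- "CAT"
  }
  genome
}

# toy ontology: a reproduction branch (anchor > focus > leaves) plus
# unrelated metabolic / stimulus branches; >= 30 terms
.toy_ontology_terms <- function() {
  t <- function(id, name, parents)
    list(id = id, name = name, parents = parents)
  base <- list(
    t("GO:0008150", "biological_process", character(0)),
    t("GO:0032502", "developmental process", "GO:0008150"),
    t("GO:0003006", "developmental process involved in reproduction",
      "GO:0032502"),
    t("GO:0010228", "vegetative to reproductive phase transition of meristem",
      "GO:0003006"),
    t("GO:0048439", "flower morphogenesis", "GO:0003006"),
    t("GO:0048437", "floral organ development", "GO:0003006"),
    t("GO:0048438", "floral whorl development", "GO:0048437"),
    t("GO:0010431", "seed maturation", "GO:0003006"),
    t("GO:0048510", "regulation of timing of transition from vegetative to reproductive phase",
      "GO:0010228"),
    t("GO:2000028", "regulation of photoperiodism, flowering", "GO:0010228"),
    t("GO:0009416", "response to light stimulus", "GO:0050896"),
    t("GO:0050896", "response to stimulus", "GO:0008150"),
    t("GO:0007623", "circadian rhythm", "GO:0050896"),
    t("GO:0008152", "metabolic process", "GO:0008150"),
    t("GO:0009987", "cellular process", "GO:0008150"))
  filler <- lapply(1:18, function(i)
    t(sprintf("GO:7%06d", i), sprintf("toy metabolic process %d", i),
      "GO:0008152"))
  c(base, filler)
}

.write_toy_obo <- function(terms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", "ontology: toy-go", ""), con)
  for (tm in terms) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", tm$id), con)
    writeLines(paste0("name: ", tm$name), con)
    writeLines("namespace: biological_process", con)
    for (p in tm$parents) writeLines(paste0("is_a: ", p, " ! parent"), con)
    writeLines("", con)
  }
}

#' Generate the full synthetic fixture set
#'
#' Writes, under `out_dir`: a toy genome FASTA (matching the simulated
#' chromosomes), a GFF3 with >= 20 multi-exon genes on both strands (a
#' block of genes inside the planted QTL, the rest elsewhere), a toy OBO
#' ontology whose reproduction branch nests a focus term under an anchor
#' term, a direct gene-to-term annotation TSV over a universe of filler
#' genes, a GMT collection in which one circadian-like pathway is
#' enriched among the focus-term genes by construction, and a pooled-BSA
#' VCF from [simulate_cross()] whose markers include planted
#' coding-sequence SNPs: non-synonymous substitutions in the QTL genes
#' and one stop-gain in a gene far outside the QTL. A JSON manifest
#' records every planted truth.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param config Optional base [sim_config()]; its `markers` field is
#'   overridden with the planted coding SNPs.
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
generate_fixtures <- function(out_dir, seed = 1L, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config)) config <- sim_config(seed = seed)
  config$seed <- as.integer(seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 104729L)  # fixture randomness separate from the cross

  genome <- vapply(config$chrom_lengths, function(L) .random_seq(L),
                   character(1))
  names(genome) <- names(config$chrom_lengths)

  # --- gene models: 12 inside the QTL (causal +- 400 kb), 12 outside
  qtl_lo <- config$causal_pos - 4e5
  genes <- list()
  add_gene <- function(id, chrom, anchor5, strand) {
    n_ex <- sample(2:3, 1L)
    ex_len <- 3L * sample(40:90, n_ex, replace = TRUE)   # codon-multiple
    introns <- sample(80:200, n_ex - 1L, replace = TRUE)
    starts <- anchor5 + cumsum(c(0L, head(ex_len, -1) + introns))
    ends <- starts + ex_len - 1L
    cds <- data.frame(start = starts, end = ends,
                      phase = c(0L, cumsum(head(ex_len, -1)) %% 3L),
                      stringsAsFactors = FALSE)
    if (strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
    g <- list(gene_id = id, transcript_id = paste0(id, ".t1"),
              chrom = chrom, strand = strand,
              start = min(cds$start), end = max(cds$end), cds = cds,
              complete = TRUE)
    genes[[id]] <<- g
    genome <<- .plant_start_codon(genome, g)
  }
  for (i in 1:12)
    add_gene(sprintf("GQ%02d", i), config$causal_chrom,
             as.integer(qtl_lo + (i - 1) * 65000 + sample(0:2e4, 1)),
             sample(c("+", "-"), 1))
  out_chroms <- rep(names(config$chrom_lengths), length.out = 12)
  for (i in 1:12) {
    cc <- out_chroms[i]
    span <- config$chrom_lengths[[cc]]
    repeat {   # keep outside genes away from the QTL neighborhood
      a5 <- sample.int(span - 3000L, 1L)
      if (cc != config$causal_chrom ||
          abs(a5 - config$causal_pos) > 1.2e6) break
    }
    add_gene(sprintf("GB%02d", i), cc, a5, sample(c("+", "-"), 1))
  }
  gene_ids <- names(genes)
  qtl_genes <- grep("^GQ", gene_ids, value = TRUE)
  out_genes <- grep("^GB", gene_ids, value = TRUE)

  # --- planted coding SNPs
  plant <- list()
  plant_snp <- function(gene, kind) {
    map <- .cds_positions(gene)
    n_cod <- length(map) %/% 3L
    ci <- sample(2:(n_cod - 2L), 1L)        # avoid start & stop codons
    cpos <- map[(ci - 1L) * 3L + 1:3]
    if (kind == "stop_gained") {
      # force codon TGG (Trp) and mutate third base to A -> TGA (stop)
      tpl <- if (gene$strand == "+") c("T", "G", "G") else c("A", "C", "C")
      for (j in 1:3)
        substr(genome[[gene$chrom]], cpos[j], cpos[j]) <<- tpl[j]
      gp <- cpos[3]
      ref <- substr(genome[[gene$chrom]], gp, gp)
      alt <- if (gene$strand == "+") "A" else "T"
    } else {
      # force codon GAA (Glu); first-base G->C gives CAA (Gln), missense
      tpl <- if (gene$strand == "+") c("G", "A", "A") else c("C", "T", "T")
      for (j in 1:3)
        substr(genome[[gene$chrom]], cpos[j], cpos[j]) <<- tpl[j]
      gp <- cpos[1]
      ref <- substr(genome[[gene$chrom]], gp, gp)
      alt <- if (gene$strand == "+") "C" else "G"
    }
    plant[[length(plant) + 1L]] <<- data.frame(
      gene_id = gene$gene_id, chrom = gene$chrom, pos = gp,
      ref = ref, alt = alt, planted_effect = kind,
      stringsAsFactors = FALSE)
  }
  for (g in qtl_genes) plant_snp(genes[[g]], "non_synonymous")
  stop_gene <- out_genes[which(vapply(out_genes, function(g)
    genes[[g]]$chrom != config$causal_chrom, logical(1)))[1]]
  plant_snp(genes[[stop_gene]], "stop_gained")
  plant <- do.call(rbind, plant)

  # --- ontology / annotations / gene sets
  terms <- .toy_ontology_terms()
  obo_path <- file.path(out_dir, "toy_go.obo")
  .write_toy_obo(terms, obo_path)
  anchor <- "GO:0003006"; focus <- "GO:0010228"
  focus_leaves <- c("GO:0010228", "GO:0048510", "GO:2000028")
  repro_other <- c("GO:0048439", "GO:0048437", "GO:0048438", "GO:0010431")
  background <- c("GO:0008152", "GO:0009987", "GO:0009416", "GO:0007623",
                  sprintf("GO:7%06d", 1:18))

  filler <- sprintf("F%03d", 1:176)
  universe <- c(gene_ids, filler)
  ann <- list()
  annotate <- function(gene, term_ids)
    ann[[length(ann) + 1L]] <<- data.frame(gene = gene, term = term_ids,
                                           stringsAsFactors = FALSE)
  for (g in qtl_genes)
    annotate(g, c(sample(focus_leaves, 1L), sample(repro_other, 1L)))
  for (g in out_genes) annotate(g, sample(background, 2L))
  # a sprinkling of filler genes on the reproduction branch keeps K
  # realistic without drowning the study signal
  for (i in seq_along(filler)) {
    g <- filler[i]
    if (i <= 12) annotate(g, sample(c(focus_leaves, repro_other), 1L))
    annotate(g, sample(background, 2L))
  }
  ann <- unique(do.call(rbind, ann))
  ann_path <- file.path(out_dir, "annotations.tsv")
  write.table(ann, ann_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  circadian <- c(sample(qtl_genes, 5L), sample(filler[1:12], 2L))
  sets <- c(list(PW_CIRCADIAN_PLANT = circadian),
            setNames(lapply(1:5, function(i)
              sample(filler, sample(8:15, 1L))),
              sprintf("PW_TOY_%02d", 1:5)))
  gmt_path <- file.path(out_dir, "pathways.gmt")
  write_gmt(sets, gmt_path,
            descriptions = c("planted circadian-like pathway",
                             rep("background pathway", 5)))

  # --- genome, gene models, cross VCF
  fasta_path <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fasta_path)
  gff_path <- file.path(out_dir, "genes.gff3")
  .write_gff3(genes, gff_path)

  # complete marker table with genome-consistent alleles: grid + causal
  # + planted coding SNPs (planted rows win position clashes)
  grid <- rbind(marker_grid(config$chrom_lengths, config$n_markers),
                data.frame(chrom = config$causal_chrom,
                           pos = config$causal_pos))
  grid <- grid[!duplicated(paste(grid$chrom, grid$pos)), , drop = FALSE]
  grid$ref <- unname(mapply(function(cc, p) substr(genome[[cc]], p, p),
                            grid$chrom, grid$pos))
  grid$alt <- vapply(grid$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1),
    USE.NAMES = FALSE)
  allm <- rbind(plant[, c("chrom", "pos", "ref", "alt")], grid)
  allm <- allm[!duplicated(paste(allm$chrom, allm$pos)), , drop = FALSE]
  config$markers <- allm
  config$markers_only <- TRUE
  vcf_path <- file.path(out_dir, "pools.vcf")
  sim <- simulate_cross(config, vcf_path = vcf_path)

  manifest <- list(
    seed = seed,
    files = list(genome = fasta_path, gff3 = gff_path, obo = obo_path,
                 annotations = ann_path, gmt = gmt_path, vcf = vcf_path),
    pools = names(config$pool_sizes),
    pool_sizes = as.list(config$pool_sizes),
    causal = list(chrom = config$causal_chrom, pos = config$causal_pos),
    qtl_genes = qtl_genes, outside_genes = out_genes,
    stop_gain_gene = stop_gene,
    planted_variants = plant,
    anchor_term = anchor, focus_term = focus,
    focus_terms = focus_leaves, reproduction_terms = c(anchor, focus_leaves,
                                                       repro_other),
    planted_pathway = "PW_CIRCADIAN_PLANT",
    universe_size = length(universe))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

.write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    writeLines(paste(g$chrom, "ontoqtl", "gene", g$start, g$end, ".",
                     g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"), con)
    writeLines(paste(g$chrom, "ontoqtl", "mRNA", g$start, g$end, ".",
                     g$strand, ".",
                     paste0("ID=", g$transcript_id, ";Parent=", g$gene_id),
                     sep = "\t"), con)
    cds <- g$cds[order(g$cds$start), , drop = FALSE]
    ph <- g$cds$phase[order(g$cds$start)]
    for (i in seq_len(nrow(cds)))
      writeLines(paste(g$chrom, "ontoqtl", "CDS", cds$start[i], cds$end[i],
                       ".", g$strand, ph[i],
                       paste0("ID=", g$transcript_id, ".cds", i,
                              ";Parent=", g$transcript_id), sep = "\t"), con)
  }
}
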