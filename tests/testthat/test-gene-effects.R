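write_toy_gff <- function(path) {
  writeLines(c(
    "##gff-version 3",
    # plus-strand 2-exon gene
    "c1\tsrc\tgene\t100\t400\t.\t+\t.\tID=gplus",
    "c1\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=gplus.t1;Parent=gplus",
    "c1\tsrc\tCDS\t100\t199\t.\t+\t0\tID=c1a;Parent=gplus.t1",
    "c1\tsrc\tCDS\t300\t400\t.\t+\t2\tID=c1b;Parent=gplus.t1",
    # minus-strand 2-exon gene
    "c1\tsrc\tgene\t1000\t1400\t.\t-\t.\tID=gminus",
    "c1\tsrc\tmRNA\t1000\t1400\t.\t-\t.\tID=gminus.t1;Parent=gminus",
    "c1\tsrc\tCDS\t1000\t1099\t.\t-\t2\tID=c2a;Parent=gminus.t1",
    "c1\tsrc\tCDS\t1300\t1400\t.\t-\t0\tID=c2b;Parent=gminus.t1",
    # gene with two transcripts: CDS lengths 300 vs 450
    "c1\tsrc\tgene\t2000\t2999\t.\t+\t.\tID=gtwo",
    "c1\tsrc\tmRNA\t2000\t2999\t.\t+\t.\tID=gtwo.t1;Parent=gtwo",
    "c1\tsrc\tCDS\t2000\t2299\t.\t+\t0\tID=c3a;Parent=gtwo.t1",
    "c1\tsrc\tmRNA\t2000\t2999\t.\t+\t.\tID=gtwo.t2;Parent=gtwo",
    "c1\tsrc\tCDS\t2000\t2449\t.\t+\t0\tID=c3b;Parent=gtwo.t2"),
    path)
  path
}

test_that("GFF3 gene models: exon order, strand, longest-CDS transcript", {
  path <- write_toy_gff(tempfile(fileext = ".gff3"))
  gm <- read_gene_models(path)
  expect_setequal(names(gm), c("gplus", "gminus", "gtwo"))
  expect_equal(nrow(gm$gplus$cds), 2L)
  expect_equal(gm$gplus$cds$start, c(100, 300))        # transcription order
  expect_equal(gm$gminus$cds$start, c(1300, 1000))     # 5'->3' on minus
  expect_equal(gm$gtwo$transcript_id, "gtwo.t2")       # longest CDS wins
  expect_true(gm$gtwo$complete)
  # orphan CDS -> warning + skip
  lines <- readLines(path)
  writeLines(c(lines, "c1\tsrc\tCDS\t5000\t5099\t.\t+\t0\tID=x;Parent=ghost"),
             path)
  expect_warning(read_gene_models(path), "without a known mRNA parent")
})

test_that("gene/region intersection uses inclusive coordinates and matches the quadratic oracle", {
  mk_gene <- function(id, chrom, s, e)
    list(gene_id = id, transcript_id = id, chrom = chrom, strand = "+",
         start = s, end = e,
         cds = data.frame(start = s, end = e, phase = 0), complete = TRUE)
  genes <- structure(list(a = mk_gene("a", "c1", 100, 200),
                          b = mk_gene("b", "c1", 100, 200)),
                     class = "gene_models")
  reg <- data.frame(contrast = "X-Y", chrom = "c1", start = 150, end = 300,
                    n_snps = 10L, max_gprime = 3, mean_gprime = 3)
  expect_equal(intersect_genes(reg, genes["a"])$gene_id, "a")
  reg$start <- 201   # adjacent but not overlapping (inclusive arithmetic)
  expect_equal(nrow(intersect_genes(reg, genes["a"])), 0L)
  reg$start <- 200   # single shared base
  expect_equal(nrow(intersect_genes(reg, genes["a"])), 1L)

  set.seed(21)
  rgenes <- structure(lapply(1:50, function(i) {
    s <- sample.int(1e6, 1)
    mk_gene(paste0("g", i), sample(c("c1", "c2"), 1), s, s + sample.int(5e3, 1))
  }), class = "gene_models")
  names(rgenes) <- vapply(rgenes, `[[`, "", "gene_id")
  rreg <- do.call(rbind, lapply(1:5, function(i) {
    s <- sample.int(1e6, 1)
    data.frame(contrast = paste0("ct", i), chrom = sample(c("c1", "c2"), 1),
               start = s, end = s + sample.int(2e5, 1), n_snps = 10L,
               max_gprime = 3, mean_gprime = 3)
  }))
  got <- intersect_genes(rreg, rgenes)
  # quadratic all-pairs oracle
  want <- list()
  for (g in rgenes) for (j in seq_len(nrow(rreg))) {
    if (g$chrom == rreg$chrom[j] &&
        max(g$start, rreg$start[j]) <= min(g$end, rreg$end[j]))
      want[[length(want) + 1]] <- data.frame(gene_id = g$gene_id,
                                             contrast = rreg$contrast[j],
                                             chrom = g$chrom)
  }
  want <- do.call(rbind, want)
  key <- function(d) sort(paste(d$gene_id, d$contrast))
  expect_equal(key(got), key(want))
})

test_that("codon-level SNP classification on the plus strand", {
  fx <- random_gene_fixture("g", "c1", strand = "+", n_exons = 2)
  g <- fx$gene; genome <- fx$genome
  s <- g$cds$start[1]
  # make codon 2 GGA (Gly): GGA->GGG synonymous, GGA->AGA (Arg) missense
  substr(genome[["c1"]], s + 3, s + 5) <- "GGA"
  syn <- classify_effect(g, genome, "c1", s + 5, "A", "G")
  expect_equal(syn$effect, "synonymous")
  expect_equal(syn$impact, "low")
  mis <- classify_effect(g, genome, "c1", s + 3, "G", "A")
  expect_equal(mis$effect, "non_synonymous")
  expect_equal(mis$impact, "moderate")
  # codon 3 TGG (Trp) -> TGA stop_gained
  substr(genome[["c1"]], s + 6, s + 8) <- "TGG"
  sg <- classify_effect(g, genome, "c1", s + 8, "G", "A")
  expect_equal(sg$effect, "stop_gained")
  expect_equal(sg$impact, "high")
  # destroying the start codon
  sl <- classify_effect(g, genome, "c1", s, "A", "C")
  expect_equal(sl$effect, "start_lost")
  expect_equal(sl$impact, "high")
  # reference mismatch is fatal and names the position
  expect_error(classify_effect(g, genome, "c1", s, "G", "C"),
               as.character(s))
})

test_that("splice, intron, intergenic and indel classes", {
  fx <- random_gene_fixture("g", "c1", strand = "+", n_exons = 2)
  g <- fx$gene; genome <- fx$genome
  e1 <- g$cds$end[1]; s2 <- g$cds$start[2]
  at <- function(p) substr(genome[["c1"]], p, p)
  expect_equal(classify_effect(g, genome, "c1", e1 + 1, at(e1 + 1), "N")$effect,
               "splice_site")
  expect_equal(classify_effect(g, genome, "c1", e1 + 2, at(e1 + 2), "N")$effect,
               "splice_site")
  expect_equal(classify_effect(g, genome, "c1", s2 - 1, at(s2 - 1), "N")$effect,
               "splice_site")
  expect_equal(classify_effect(g, genome, "c1", e1 + 3, at(e1 + 3), "N")$effect,
               "intronic")
  expect_equal(classify_effect(g, genome, "c1", 10, at(10), "N")$effect,
               "intergenic")
  # indels inside the CDS
  p <- g$cds$start[1] + 4
  ref2 <- substr(genome[["c1"]], p, p + 1)
  expect_equal(classify_effect(g, genome, "c1", p, ref2,
                               substr(ref2, 1, 1))$effect, "frameshift")
  ref4 <- substr(genome[["c1"]], p, p + 3)
  expect_equal(classify_effect(g, genome, "c1", p, ref4,
                               substr(ref4, 1, 1))$effect, "inframe_indel")
})

test_that("minus-strand SNPs agree with the full-CDS translation oracle", {
  set.seed(33)
  for (rep in 1:8) {
    fx <- random_gene_fixture(strand = "-", n_exons = sample(1:3, 1))
    g <- fx$gene; genome <- fx$genome
    segs <- g$cds[order(g$cds$start), ]
    cds_pos <- unlist(Map(seq, segs$start, segs$end))
    for (p in sample(cds_pos, 12)) {
      ref <- substr(genome[[g$chrom]], p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      got <- classify_effect(g, genome, g$chrom, p, ref, alt)$effect
      want <- effect_oracle(g, genome, g$chrom, p, ref, alt)
      expect_equal(got, want,
                   info = sprintf("rep %d pos %d %s>%s", rep, p, ref, alt))
    }
  }
})

test_that("impact summary reproduces a planted inside/outside pattern", {
  mk_gene <- function(id, s, e)
    list(gene_id = id, transcript_id = id, chrom = "c1", strand = "+",
         start = s, end = e,
         cds = data.frame(start = s, end = e, phase = 0), complete = TRUE)
  genes <- structure(list(gin = mk_gene("gin", 100, 400),
                          gout = mk_gene("gout", 5000, 5300)),
                     class = "gene_models")
  reg <- data.frame(contrast = "EF-NF", chrom = "c1", start = 50, end = 1000,
                    n_snps = 10L, max_gprime = 5, mean_gprime = 4)
  effects <- rbind(
    data.frame(gene_id = "gin", chrom = "c1", pos = 101:108, ref = "A",
               alt = "G", effect = "non_synonymous", impact = "moderate",
               note = NA),
    data.frame(gene_id = "gout", chrom = "c1", pos = 5010, ref = "T",
               alt = "A", effect = "stop_gained", impact = "high",
               note = NA))
  s <- impact_summary(genes, effects, reg)
  expect_equal(s$crosstab["moderate", "inside"], 8L)
  expect_equal(s$crosstab["high", "outside"], 1L)
  expect_equal(sum(s$crosstab) - 9L, 0L)
  pg <- s$per_gene
  expect_true(pg$`in_EF-NF`[pg$gene_id == "gin"])
  expect_false(pg$`in_EF-NF`[pg$gene_id == "gout"])
  expect_equal(pg$non_synonymous[pg$gene_id == "gin"], 8L)
})
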