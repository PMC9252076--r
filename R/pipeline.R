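# End-to-end refinement pipeline: filter -> per-contrast statistics ->
# QTL regions -> gene intersection & effects -> per-contrast SEA ->
# cross-comparison -> anchored pruning -> focus-term zoom -> pathway
# enrichment. Every intermediate artifact is written to the output
# directory together with a run manifest.

#' Assemble a pipeline configuration
#'
#' @param vcf,gff3,fasta,obo,annotations,gmt Input file paths.
#' @param pools Ordered pool labels (trait order, low to high); must
#'   match VCF sample names.
#' @param pool_sizes Named integer vector of individuals per pool (used
#'   by the delta-CI simulation).
#' @param out_dir Output directory.
#' @param seed Integer seed for every stochastic stage.
#' @param filter A [filter_config()].
#' @param smoothing A [smoothing_config()].
#' @param thresholds A [threshold_config()]; the pipeline default turns
#'   the delta-CI gate on, because with pools of ~10 individuals
#'   pool-composition sampling keeps null G' far above the read-noise
#'   scale and the fixed G' cutoff alone is not null-calibrated.
#' @param regions A [region_config()].
#' @param replicates,level Delta-CI simulation settings (default 10000
#'   replicates, two-sided 95%).
#' @param design Cross design tag for the CI simulation.
#' @param anchor,focus Ontology anchor and focus term ids.
#' @param fdr_threshold Enrichment threshold (default 0.05).
#' @param adjust Multiple-testing method, `"BY"` (default) or `"BH"`.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(vcf, gff3, fasta, obo, annotations, gmt,
                            pools, pool_sizes, out_dir,
                            seed = 1L,
                            filter = filter_config(),
                            smoothing = smoothing_config(),
                            thresholds = threshold_config(use_delta_ci = TRUE),
                            regions = region_config(),
                            replicates = 10000, level = 0.95,
                            design = "f1_het_dh",
                            anchor = "GO:0003006", focus = "GO:0010228",
                            fdr_threshold = 0.05, adjust = "BY") {
  structure(list(vcf = vcf, gff3 = gff3, fasta = fasta, obo = obo,
                 annotations = annotations, gmt = gmt,
                 pools = pools, pool_sizes = pool_sizes,
                 out_dir = out_dir, seed = as.integer(seed),
                 filter = filter, smoothing = smoothing,
                 thresholds = thresholds, regions = regions,
                 replicates = replicates, level = level, design = design,
                 anchor = anchor, focus = focus,
                 fdr_threshold = fdr_threshold, adjust = adjust),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys mirror the [pipeline_config()] arguments; nested blocks
#' `filter`, `smoothing`, `thresholds`, `regions` override the
#' corresponding config constructors' defaults.
#'
#' @param path YAML file.
#' @return A `"pipeline_config"` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  req <- c("vcf", "gff3", "fasta", "obo", "annotations", "gmt",
           "pools", "pool_sizes", "out_dir")
  miss <- setdiff(req, names(y))
  if (length(miss))
    stop("pipeline config missing key(s): ", paste(miss, collapse = ", "))
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  args$pool_sizes <- unlist(y$pool_sizes)
  ctors <- c(filter = "filter_config", smoothing = "smoothing_config",
             thresholds = "threshold_config", regions = "region_config")
  for (blk in names(ctors))
    if (!is.null(y[[blk]]) && is.list(y[[blk]]))
      args[[blk]] <- do.call(ctors[[blk]], y[[blk]])
  do.call(pipeline_config, args)
}

#' Validate a pipeline configuration
#'
#' Checks that every referenced file exists and the pool bookkeeping is
#' consistent, before any compute.
#'
#' @param config A `"pipeline_config"`.
#' @return `config`, invisibly; errors on the first problem.
#' @export
validate_pipeline_config <- function(config) {
  for (f in c("vcf", "gff3", "fasta", "obo", "annotations", "gmt")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("pipeline config: missing or nonexistent ", f, " file: ",
           config[[f]] %||% "<unset>")
  }
  if (length(config$pools) < 2L) stop("need at least two pools")
  if (!all(config$pools %in% names(config$pool_sizes)))
    stop("pool_sizes must name every pool")
  invisible(config)
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] stage=%s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage,
                  paste0(...)))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full refinement pipeline
#'
#' Executes filter, per-contrast statistics with simulated delta-CI
#' bounds, QTL region calling, gene intersection and variant-effect
#' classification, per-contrast singular enrichment, cross-contrast
#' comparison, anchored subgraph pruning, focus-term zoom, and pathway
#' enrichment. All intermediates are written under `config$out_dir`,
#' plus a `run_manifest.json` recording seed, parameters, and the gene
#' funnel counts at each stage.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param quiet Suppress progress messages.
#' @return A `"refine_run"` list bundling every stage result.
#' @export
run_refine <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  if (quiet) {
    oldopt <- options(ontoqtl.quiet = TRUE)
    on.exit(options(oldopt))
  }
  log_ <- if (quiet) function(...) invisible() else .log_stage
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outf <- function(...) file.path(config$out_dir, ...)
  log_("init", "seed=", config$seed)

  variants <- .stage("read_variants",
                     read_pool_variants(config$vcf, config$pools))
  contrasts <- enumerate_contrasts(config$pools)
  log_("read_variants", nrow(variants), " records, ",
       nrow(contrasts), " contrasts")

  genes <- .stage("gene_models", read_gene_models(config$gff3))
  genome <- .stage("genome", read_genome_fasta(config$fasta))
  graph <- .stage("ontology", parse_obo(config$obo))
  ann_direct <- .stage("annotations", read_annotations(config$annotations))
  gmt <- .stage("gene_sets", read_gmt(config$gmt))

  per_contrast <- list()
  all_regions <- list()
  for (ci in seq_len(nrow(contrasts))) {
    ct <- contrasts[ci, ]
    flt <- .stage("filter", apply_filters(variants, ct, config$filter))
    st <- .stage("stats",
                 compute_contrast_stats(flt$variants, ct, config$smoothing))
    dmean <- round((st$depth_a + st$depth_b) / 2)
    dgrid <- unique(round(quantile(dmean, probs = seq(0, 1, 0.1))))
    citab <- .stage("delta_ci", simulate_delta_ci(
      config$pool_sizes[[ct$pool_a]], config$pool_sizes[[ct$pool_b]],
      depths = dgrid, design = config$design,
      replicates = config$replicates, level = config$level,
      seed = config$seed + ci))
    st <- flag_candidates(st, config$thresholds, citab)
    reg <- .stage("regions", call_regions(st, config$regions, ct$id))
    write.table(st, outf(paste0("stats_", ct$id, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(citab, outf(paste0("delta_ci_", ct$id, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    per_contrast[[ct$id]] <- list(filter_report = flt$report, stats = st,
                                  ci = citab, regions = reg)
    all_regions[[ct$id]] <- reg
    log_("contrast", ct$id, ": ", nrow(st), " SNPs, ",
         sum(st$flagged), " flagged, ", nrow(reg), " region(s)")
  }
  regions <- do.call(rbind, all_regions)
  rownames(regions) <- NULL
  write_regions_bed(regions, outf("qtl_regions.bed"))
  write.table(regions, outf("qtl_regions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  freports <- do.call(rbind, lapply(per_contrast, function(x)
    data.frame(contrast = x$filter_report$contrast,
               input = x$filter_report$input,
               surviving = x$filter_report$surviving,
               as.list(unlist(x$filter_report$removed)),
               check.names = FALSE, stringsAsFactors = FALSE)))
  write.table(freports, outf("filter_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  effects <- .stage("effects", classify_variants(genes, genome, variants))
  write.table(effects, outf("effects.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  imp <- .stage("impact_summary", impact_summary(genes, effects, regions))
  write.table(imp$per_gene, outf("impact_per_gene.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ov <- intersect_genes(regions, genes)
  nonsyn_genes <- unique(effects$gene_id[effects$effect == "non_synonymous"])
  qtl_gene_ids <- unique(ov$gene_id)
  study_all <- intersect(qtl_gene_ids, nonsyn_genes)
  log_("gene_funnel", length(qtl_gene_ids), " genes in QTLs; ",
       length(study_all), " with non-synonymous SNPs")

  ann_prop <- .stage("propagate",
                     propagate_annotations(ann_direct, graph))
  universe <- names(ann_prop)
  sea_results <- list()
  pruned <- list()
  for (id in names(per_contrast)) {
    reg <- per_contrast[[id]]$regions
    if (!nrow(reg)) next
    study <- intersect(intersect(unique(ov$gene_id[ov$contrast == id]),
                                 nonsyn_genes), universe)
    if (!length(study)) next
    res <- .stage("sea", sea(study, universe, ann_prop,
                             adjust = config$adjust,
                             fdr_threshold = config$fdr_threshold))
    sea_results[[id]] <- res
    write.table(res, outf(paste0("sea_", id, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    pruned[[id]] <- .stage("prune", prune_enriched(
      res$term[res$enriched], graph, config$anchor))
    log_("sea", id, ": ", sum(res$enriched), " enriched term(s), ",
         length(pruned[[id]]), " under anchor")
  }

  comparison <- NULL
  if (length(sea_results) >= 2L) {
    comparison <- .stage("cross_compare",
                         cross_compare(sea_results, config$fdr_threshold))
    write.table(comparison$fdr, outf("sea_cross_comparison.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
  }
  pruned_union <- sort(unique(unlist(pruned)))
  writeLines(pruned_union, outf("pruned_terms.txt"))

  focus_genes <- .stage("zoom",
                        genes_for_term(ann_direct, graph, config$focus))
  final_genes <- intersect(study_all, focus_genes)
  writeLines(final_genes, outf("final_genes.txt"))
  log_("zoom", length(final_genes), " gene(s) after focus-term zoom")

  pathways <- NULL
  if (length(final_genes))
    pathways <- .stage("pathways", pathway_enrich(
      final_genes, gmt, universe, adjust = config$adjust,
      fdr_threshold = config$fdr_threshold))
  if (!is.null(pathways))
    write.table(pathways, outf("pathway_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  funnel <- list(variants_read = nrow(variants),
                 contrasts = nrow(contrasts),
                 contrasts_with_regions =
                   sum(vapply(per_contrast, function(x) nrow(x$regions) > 0,
                              logical(1))),
                 qtl_regions = nrow(regions),
                 genes_in_qtls = length(qtl_gene_ids),
                 genes_nonsyn_in_qtls = length(study_all),
                 enriched_terms_union =
                   length(unique(unlist(lapply(sea_results, function(r)
                     r$term[r$enriched])))),
                 pruned_terms = length(pruned_union),
                 final_genes = length(final_genes))
  manifest <- list(package_version = as.character(utils::packageVersion("ontoqtl")),
                   seed = config$seed,
                   parameters = list(
                     filter = unclass(config$filter),
                     window_width = config$smoothing$window_width,
                     gprime_threshold = config$thresholds$gprime_threshold,
                     use_delta_ci = config$thresholds$use_delta_ci,
                     replicates = config$replicates, level = config$level,
                     max_gap = config$regions$max_gap,
                     min_snps = config$regions$min_snps,
                     anchor = config$anchor, focus = config$focus,
                     fdr_threshold = config$fdr_threshold,
                     adjust = config$adjust),
                   funnel = funnel)
  jsonlite::write_json(manifest, outf("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_("done", "final gene set size=", length(final_genes))

  structure(list(config = config, variants = variants,
                 contrasts = contrasts, per_contrast = per_contrast,
                 regions = regions, effects = effects,
                 impact = imp, sea = sea_results,
                 comparison = comparison, pruned = pruned,
                 pruned_union = pruned_union,
                 focus_genes = focus_genes, final_genes = final_genes,
                 pathways = pathways, funnel = funnel,
                 manifest = manifest),
            class = "refine_run")
}

#' @export
print.refine_run <- function(x, ...) {
  cat("ontoqtl refinement run (seed", x$config$seed, ")\n")
  f <- x$funnel
  cat("  variants read:            ", f$variants_read, "\n")
  cat("  contrasts (with regions): ", f$contrasts, " (",
      f$contrasts_with_regions, ")\n", sep = "")
  cat("  QTL regions:              ", f$qtl_regions, "\n")
  cat("  genes in QTLs:            ", f$genes_in_qtls, "\n")
  cat("  ... with non-syn SNPs:    ", f$genes_nonsyn_in_qtls, "\n")
  cat("  enriched terms (union):   ", f$enriched_terms_union, "\n")
  cat("  terms under anchor:       ", f$pruned_terms, "\n")
  cat("  final gene set:           ", f$final_genes, "\n")
  if (!is.null(x$pathways) && nrow(x$pathways))
    cat("  top pathway:              ", x$pathways$set[1], " (fdr=",
        signif(x$pathways$fdr[1], 3), ")\n", sep = "")
  invisible(x)
}
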