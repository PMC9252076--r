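# Reading pooled-bulk variant calls and applying the genotype filters.
#
# Pool variants are kept in a plain data.frame (class "pool_variants") with
# one row per biallelic site and, for every pool label P, columns
# P_ref / P_alt (AD-based allele depths) and P_gq (genotype quality).

#' Filter configuration for pooled variants
#'
#' Thresholds applied by [apply_filters()], in the order listed. Defaults
#' reproduce the conventional pooled-genotyping filters for ~100x bulks:
#' per-pool depth at least 40x, combined depth of the contrasted pair
#' within \[100, 400\]x, GATK genotype quality at least 99 in each pool,
#' and combined reference-allele frequency at least 0.2.
#'
#' @param min_pool_depth Minimum AD-based depth (ref+alt) per pool.
#' @param min_combined_depth,max_combined_depth Bounds on the summed depth
#'   of the two contrasted pools. Sites above the maximum are typically
#'   collapsed repeats.
#' @param min_gq Minimum genotype quality per pool (phred-like).
#' @param min_ref_freq Minimum reference-allele read fraction; guards
#'   against paralog-collapsed or mis-called sites when one parent is a
#'   homozygous reference line.
#' @param ref_freq_mode `"combined"` computes the reference fraction on
#'   the summed depths of the two pools; `"per-pool"` requires each pool
#'   to pass individually.
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(min_pool_depth = 40,
                          min_combined_depth = 100,
                          max_combined_depth = 400,
                          min_gq = 99,
                          min_ref_freq = 0.2,
                          ref_freq_mode = c("combined", "per-pool")) {
  ref_freq_mode <- match.arg(ref_freq_mode)
  stopifnot(min_ref_freq >= 0, min_ref_freq < 1,
            min_combined_depth <= max_combined_depth,
            min_pool_depth >= 0)
  structure(list(min_pool_depth = min_pool_depth,
                 min_combined_depth = min_combined_depth,
                 max_combined_depth = max_combined_depth,
                 min_gq = min_gq,
                 min_ref_freq = min_ref_freq,
                 ref_freq_mode = ref_freq_mode),
            class = "filter_config")
}

#' Enumerate pool contrasts
#'
#' All unordered pairs of pool labels, in lexicographic order of the input
#' (so four trait-ordered pools yield the canonical six contrasts).
#'
#' @param pool_labels Character vector of at least two distinct labels.
#' @return A data.frame with columns `pool_a`, `pool_b` and a contrast
#'   `id` of the form `"A-B"`.
#' @export
#' @examples
#' enumerate_contrasts(c("EF", "IF", "LF", "NF"))
enumerate_contrasts <- function(pool_labels) {
  if (length(pool_labels) < 2L)
    stop("need at least two pool labels")
  if (anyDuplicated(pool_labels))
    stop("duplicate pool labels: ",
         paste(unique(pool_labels[duplicated(pool_labels)]), collapse = ", "))
  pairs <- combn(pool_labels, 2L)
  data.frame(pool_a = pairs[1L, ], pool_b = pairs[2L, ],
             id = paste(pairs[1L, ], pairs[2L, ], sep = "-"),
             stringsAsFactors = FALSE)
}

#' Read pooled variants from a VCF
#'
#' Loads a (possibly bgzipped) VCF and extracts per-pool AD allele depths
#' and GQ for the named samples. Records are returned sorted by
#' (chromosome, position). Sites are reduced to one alternate allele:
#' multi-allelic records are kept only when a single alternate carries at
#' least `multiallelic_frac` of the alternate depth summed over the
#' requested pools; others are dropped and counted. Indels and other
#' non-SNP records pass through tagged by `type` so the effect classifier
#' can use them; the BSA statistics work on SNPs only.
#'
#' @param vcf_path Path to the VCF.
#' @param pool_names Ordered character vector of sample names to extract.
#' @param multiallelic_frac Dominance fraction above which one alternate
#'   of a multi-allelic site is retained (default 0.95).
#' @return A `"pool_variants"` data.frame with columns `chrom`, `pos`,
#'   `ref`, `alt`, `type` and per-pool `<pool>_ref`, `<pool>_alt`,
#'   `<pool>_gq`. Attributes: `pools`, `n_multiallelic_dropped`.
#' @export
read_pool_variants <- function(vcf_path, pool_names,
                               multiallelic_frac = 0.95) {
  if (!file.exists(vcf_path)) stop("no such VCF: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1L]
  missing <- setdiff(pool_names, samples)
  if (length(missing))
    stop("sample(s) not in VCF: ", paste(missing, collapse = ", "))
  fmt <- vcf@gt[, 1L]
  if (!all(grepl("\\bAD\\b", fmt)))
    stop("VCF records lack the AD (allele depth) FORMAT field")

  fix <- vcf@fix
  ad <- vcfR::extract.gt(vcf, element = "AD")[, pool_names, drop = FALSE]
  gq <- vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)
  gq <- gq[, pool_names, drop = FALSE]
  gq[is.na(gq)] <- 0

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  n <- length(pos)
  npool <- length(pool_names)
  # AD strings -> depth matrix, one row per record, alleles ref,alt1,alt2,...
  ad_list <- strsplit(ifelse(is.na(ad), "0", ad), ",", fixed = TRUE)
  dim(ad_list) <- dim(ad)

  keep <- logical(n)
  out_alt <- character(n)
  ref_d <- matrix(0L, n, npool)
  alt_d <- matrix(0L, n, npool)
  n_multi_dropped <- 0L

  alts_split <- strsplit(alt, ",", fixed = TRUE)
  for (i in seq_len(n)) {
    alts <- alts_split[[i]]
    depths <- vapply(seq_len(npool), function(j) {
      d <- suppressWarnings(as.integer(ad_list[[i, j]]))
      d[is.na(d)] <- 0L
      length(d) <- length(alts) + 1L
      d[is.na(d)] <- 0L
      d
    }, integer(length(alts) + 1L))
    # depths: (1 + n_alt) x npool
    if (length(alts) == 1L) {
      keep[i] <- TRUE
      out_alt[i] <- alts
      ref_d[i, ] <- depths[1L, ]
      alt_d[i, ] <- depths[2L, ]
    } else {
      alt_tot <- rowSums(depths)[-1L]
      if (sum(alt_tot) > 0 && max(alt_tot) / sum(alt_tot) >= multiallelic_frac) {
        k <- which.max(alt_tot)
        keep[i] <- TRUE
        out_alt[i] <- alts[k]
        ref_d[i, ] <- depths[1L, ]
        alt_d[i, ] <- depths[k + 1L, ]
      } else {
        n_multi_dropped <- n_multi_dropped + 1L
      }
    }
  }

  df <- data.frame(chrom = chrom[keep], pos = pos[keep],
                   ref = ref[keep], alt = out_alt[keep],
                   stringsAsFactors = FALSE)
  df$type <- ifelse(nchar(df$ref) == 1L & nchar(df$alt) == 1L, "snp", "indel")
  for (j in seq_along(pool_names)) {
    p <- pool_names[j]
    df[[paste0(p, "_ref")]] <- ref_d[keep, j]
    df[[paste0(p, "_alt")]] <- alt_d[keep, j]
    df[[paste0(p, "_gq")]] <- gq[keep, j]
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, pools = pool_names,
            n_multiallelic_dropped = n_multi_dropped,
            class = c("pool_variants", "data.frame"))
}

#' Apply genotype filters to a pool contrast
#'
#' Evaluates the filter rules in a fixed order — per-pool depth, combined
#' depth (low then high), per-pool genotype quality, reference-allele
#' frequency — and attributes each removed record to the first rule it
#' fails, so the report counts partition the removals.
#'
#' @param variants A `"pool_variants"` data.frame (see
#'   [read_pool_variants()]).
#' @param contrast Character vector of two pool labels, or one row of
#'   [enumerate_contrasts()].
#' @param config A [filter_config()].
#' @return A list with `variants` (the survivors, same class) and
#'   `report`, a `"filter_report"` with per-rule removal counts.
#' @export
apply_filters <- function(variants, contrast, config = filter_config()) {
  if (is.data.frame(contrast)) contrast <- c(contrast$pool_a[1], contrast$pool_b[1])
  stopifnot(length(contrast) == 2L)
  pools <- attr(variants, "pools")
  if (!all(contrast %in% pools))
    stop("contrast pool(s) absent from variants: ",
         paste(setdiff(contrast, pools), collapse = ", "))
  a <- contrast[1]; b <- contrast[2]
  da <- variants[[paste0(a, "_ref")]] + variants[[paste0(a, "_alt")]]
  db <- variants[[paste0(b, "_ref")]] + variants[[paste0(b, "_alt")]]
  comb <- da + db
  ra <- variants[[paste0(a, "_ref")]]
  rb <- variants[[paste0(b, "_ref")]]

  fail_pool_depth <- da < config$min_pool_depth | db < config$min_pool_depth
  fail_low_comb <- comb < config$min_combined_depth
  fail_high_comb <- comb > config$max_combined_depth
  fail_gq <- variants[[paste0(a, "_gq")]] < config$min_gq |
    variants[[paste0(b, "_gq")]] < config$min_gq
  if (config$ref_freq_mode == "combined") {
    rf <- ifelse(comb > 0, (ra + rb) / comb, 0)
    fail_rf <- rf < config$min_ref_freq
  } else {
    rfa <- ifelse(da > 0, ra / da, 0)
    rfb <- ifelse(db > 0, rb / db, 0)
    fail_rf <- rfa < config$min_ref_freq | rfb < config$min_ref_freq
  }

  # first-failing-rule attribution
  rule <- rep(NA_character_, nrow(variants))
  rule[fail_rf] <- "low_ref_freq"
  rule[fail_gq] <- "low_gq"
  rule[fail_high_comb] <- "high_combined_depth"
  rule[fail_low_comb] <- "low_combined_depth"
  rule[fail_pool_depth] <- "low_pool_depth"

  keep <- is.na(rule)
  removed <- table(factor(rule, levels = c("low_pool_depth",
                                           "low_combined_depth",
                                           "high_combined_depth",
                                           "low_gq", "low_ref_freq")))
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pools") <- pools
  class(out) <- class(variants)
  report <- structure(list(contrast = paste(a, b, sep = "-"),
                           input = nrow(variants),
                           surviving = sum(keep),
                           removed = as.list(as.integer(removed))),
                      class = "filter_report")
  names(report$removed) <- names(removed)
  list(variants = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Pooled-variant filter report, contrast", x$contrast, "\n")
  cat("  input records:   ", x$input, "\n")
  cat("  surviving:       ", x$surviving, "\n")
  for (r in names(x$removed))
    cat(sprintf("  removed, %-20s %d\n", paste0(r, ":"), x$removed[[r]]))
  invisible(x)
}

#' Write pooled variants as a VCF
#'
#' Minimal VCFv4.2 writer carrying GT (always `0/1` placeholders for
#' pooled samples), AD and GQ, matching what [read_pool_variants()]
#' consumes. Used by the simulator and for exporting filtered sets.
#'
#' @param variants A `"pool_variants"` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(variants, path) {
  pools <- attr(variants, "pools")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ontoqtl",
           paste0("##contig=<ID=", unique(variants$chrom), ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", pools), collapse = "\t"))
  body <- character(nrow(variants))
  if (nrow(variants)) {
    gt_cols <- vapply(pools, function(p) {
      sprintf("0/1:%d,%d:%d",
              as.integer(variants[[paste0(p, "_ref")]]),
              as.integer(variants[[paste0(p, "_alt")]]),
              as.integer(round(variants[[paste0(p, "_gq")]])))
    }, character(nrow(variants)))
    gt_cols <- matrix(gt_cols, nrow = nrow(variants))
    body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                  variants$alt, ".", "PASS", ".", "GT:AD:GQ",
                  apply(gt_cols, 1L, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
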