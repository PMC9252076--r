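# Collapsing flagged SNPs into candidate QTL intervals and BED export.
# Internal coordinates are 1-based inclusive (VCF/GFF3 convention); the
# BED writer is the single site converting to 0-based half-open.

#' Region-calling configuration
#'
#' @param max_gap Maximum gap (bp) between consecutive flagged SNPs
#'   before a region breaks (default 1 Mb, the smoothing window).
#' @param min_snps Minimum flagged SNPs per region (default 10).
#' @return A `"region_config"` list.
#' @export
region_config <- function(max_gap = 1e6, min_snps = 10) {
  stopifnot(max_gap > 0, min_snps >= 1)
  structure(list(max_gap = max_gap, min_snps = min_snps),
            class = "region_config")
}

#' Call candidate QTL regions from flagged SNPs
#'
#' Regions are maximal runs of flagged SNPs within a chromosome whose
#' consecutive gaps do not exceed `max_gap`; runs with fewer than
#' `min_snps` members are discarded. Unflagged SNPs never break a run.
#' The region span is the position of the first and last member SNP.
#'
#' @param stats A `"contrast_stats"` data.frame with a `flagged` column
#'   (see [flag_candidates()]).
#' @param config A [region_config()].
#' @param contrast Contrast id recorded on each region (defaults to the
#'   stats attribute).
#' @return A data.frame of regions: `contrast`, `chrom`, `start`, `end`
#'   (1-based inclusive), `n_snps`, `max_gprime`, `mean_gprime`.
#' @export
call_regions <- function(stats, config = region_config(),
                         contrast = attr(stats, "contrast")) {
  fl <- stats[isTRUE_v(stats$flagged), , drop = FALSE]
  out <- list()
  for (cc in unique(fl$chrom)) {
    x <- fl[fl$chrom == cc, , drop = FALSE]
    x <- x[order(x$pos), , drop = FALSE]
    run <- cumsum(c(1L, as.integer(diff(x$pos) > config$max_gap)))
    for (r in split(seq_len(nrow(x)), run)) {
      if (length(r) < config$min_snps) next
      out[[length(out) + 1L]] <- data.frame(
        contrast = contrast %||% NA_character_,
        chrom = cc, start = min(x$pos[r]), end = max(x$pos[r]),
        n_snps = length(r),
        max_gprime = max(x$gprime[r]),
        mean_gprime = mean(x$gprime[r]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contrast = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_snps = integer(), max_gprime = numeric(),
                      mean_gprime = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

isTRUE_v <- function(x) !is.na(x) & x

#' Write QTL regions as BED
#'
#' BED6+3: chrom, 0-based start, half-open end, name = contrast id,
#' score = `min(1000, round(100 * max_gprime))`, strand ".", then the
#' extra columns `n_snps`, `max_gprime`, `mean_gprime` so the file
#' round-trips through [read_regions_bed()] losslessly.
#'
#' @param regions A [call_regions()] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ontoqtl QTL regions; BED6+3 (n_snps, max_gprime, mean_gprime)",
             con)
  if (nrow(regions)) {
    regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
    lines <- paste(regions$chrom,
                   regions$start - 1L,   # 1-based incl -> 0-based half-open
                   regions$end,
                   regions$contrast,
                   pmin(1000L, as.integer(round(100 * regions$max_gprime))),
                   ".",
                   regions$n_snps,
                   format(regions$max_gprime, digits = 15),
                   format(regions$mean_gprime, digits = 15),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read QTL regions from a BED6+3 file
#'
#' Inverse of [write_regions_bed()]; restores 1-based inclusive
#' coordinates.
#'
#' @param path BED path.
#' @return A regions data.frame as produced by [call_regions()].
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(contrast = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_snps = integer(), max_gprime = numeric(),
                      mean_gprime = numeric(), stringsAsFactors = FALSE))
  f <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  data.frame(contrast = as.character(f$V4), chrom = as.character(f$V1),
             start = f$V2 + 1L, end = f$V3,
             n_snps = f$V7, max_gprime = as.numeric(f$V8),
             mean_gprime = as.numeric(f$V9), stringsAsFactors = FALSE)
}
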