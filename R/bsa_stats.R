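# Per-SNP pool-contrast statistics: SNP-index, delta, G, tricube-smoothed
# G', log-normal null p-values, and simulation-based delta confidence
# intervals.

#' SNP-index: alternate-allele read fraction
#'
#' @param ref_depth,alt_depth Non-negative read counts (vectorized).
#' @return `alt_depth / (ref_depth + alt_depth)`, in \[0, 1\].
#' @export
#' @examples
#' snp_index(30, 10)  # 0.25
snp_index <- function(ref_depth, alt_depth) {
  tot <- ref_depth + alt_depth
  if (any(tot <= 0))
    stop("SNP-index undefined at zero total depth")
  alt_depth / tot
}

#' G statistic of a 2x2 allele-by-pool table
#'
#' The likelihood-ratio (G-test) statistic
#' \deqn{G = 2 \sum_i n_i \ln(n_i / \hat n_i)}
#' over the four cells ref/alt x pool A/pool B, with expected counts
#' \eqn{\hat n_i} under row/column independence and the convention
#' \eqn{0 \ln 0 = 0}. G is 0 exactly when the two pools have identical
#' allele proportions. Vectorized over sites.
#'
#' @param ref_a,alt_a,ref_b,alt_b Allele depths in pools A and B.
#' @return Non-negative G values.
#' @export
#' @examples
#' g_statistic(20, 20, 20, 20)  # 0
#' g_statistic(30, 10, 10, 30)  # ~20.93
g_statistic <- function(ref_a, alt_a, ref_b, alt_b) {
  na <- ref_a + alt_a
  nb <- ref_b + alt_b
  if (any(na <= 0) || any(nb <= 0))
    stop("each pool needs at least one read")
  n <- na + nb
  nref <- ref_a + ref_b
  nalt <- alt_a + alt_b
  term <- function(o, e) ifelse(o == 0, 0, o * log(o / e))
  g <- 2 * (term(ref_a, na * nref / n) + term(alt_a, na * nalt / n) +
              term(ref_b, nb * nref / n) + term(alt_b, nb * nalt / n))
  pmax(g, 0)  # clamp -0 / roundoff at equality
}

#' Tricube kernel weights
#'
#' `(1 - (d/h)^3)^3` for distances `d <= h`, zero beyond.
#'
#' @param d Non-negative distances (bp).
#' @param h Kernel half-width (bp).
#' @return Weights in \[0, 1\].
#' @export
tricube <- function(d, h) {
  ifelse(abs(d) <= h, (1 - (abs(d) / h)^3)^3, 0)
}

#' Smoothing configuration for G'
#'
#' The window is specified by its total width W (default 1 Mb); the
#' tricube half-width is `W/2` on each side of the focal SNP when
#' `width_is_total` (the default), or W itself when a half-width
#' convention is wanted.
#'
#' @param window_width Window width W in bp.
#' @param width_is_total If `TRUE` (default) `h = W/2`; if `FALSE`,
#'   `h = W`.
#' @return A `"smoothing_config"` list with the resolved half-width `h`.
#' @export
smoothing_config <- function(window_width = 1e6, width_is_total = TRUE) {
  stopifnot(window_width > 0)
  structure(list(window_width = window_width,
                 width_is_total = width_is_total,
                 h = if (width_is_total) window_width / 2 else window_width),
            class = "smoothing_config")
}

#' Tricube-smoothed G'
#'
#' For each SNP i, \eqn{G'_i = \sum_j k_j G_j / \sum_j k_j} with tricube
#' weights over physical distance; smoothing never crosses chromosome
#' boundaries.
#'
#' @param chrom Chromosome per SNP.
#' @param pos Position per SNP (bp); must be sorted within chromosome.
#' @param g Raw G values.
#' @param config A [smoothing_config()].
#' @return G' per SNP, same order as the input.
#' @export
smooth_gprime <- function(chrom, pos, g, config = smoothing_config()) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(g))
  h <- config$h
  out <- numeric(length(g))
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    p <- pos[idx]
    if (is.unsorted(p)) stop("positions not sorted within chromosome ", cc)
    gg <- g[idx]
    lo <- findInterval(p - h, p) + 1L          # first neighbor within h
    hi <- findInterval(p + h, p)               # last neighbor within h
    sm <- vapply(seq_along(p), function(i) {
      j <- lo[i]:hi[i]
      w <- tricube(p[j] - p[i], h)
      sum(w * gg[j]) / sum(w)
    }, numeric(1))
    out[idx] <- sm
  }
  out
}

#' Null p-values for G' from a robustly fitted log-normal
#'
#' Most of the genome is unlinked to the trait, so the bulk of the G'
#' distribution estimates its own null. A log-normal null is fitted by
#' robust location/scale (median and MAD of log G' after trimming points
#' beyond `trim_k` MADs), and right-tail p-values are read off it;
#' q-values are Benjamini-Hochberg.
#'
#' @param gprime G' values across all chromosomes (at least 50).
#' @param trim_k Trimming constant in MAD units (default 3).
#' @return A data.frame with `p_value` and `q_value`.
#' @export
null_pvalues <- function(gprime, trim_k = 3) {
  if (length(gprime) < 50L)
    stop("need at least 50 SNPs to fit the G' null")
  if (any(gprime <= 0)) gprime <- pmax(gprime, .Machine$double.eps)
  lg <- log(gprime)
  s0 <- mad(lg)
  if (s0 == 0 || length(unique(gprime)) == 1L)
    stop("degenerate (constant) G' distribution; use the fixed-threshold mode")
  keep <- abs(lg - median(lg)) <= trim_k * s0
  mu <- median(lg[keep])
  sigma <- mad(lg[keep])
  if (sigma == 0)
    stop("degenerate G' distribution after trimming; use the fixed-threshold mode")
  p <- plnorm(gprime, meanlog = mu, sdlog = sigma, lower.tail = FALSE)
  data.frame(p_value = p, q_value = p.adjust(p, method = "BH"))
}

#' Simulate null confidence bounds for delta SNP-index
#'
#' Monte-Carlo null for \eqn{\Delta}(SNP-index) under no linkage to the
#' trait. Each replicate draws a per-pool allele frequency from the
#' cross design's segregation, then per-pool alternate depths from
#' Binomial(depth, frequency); the empirical two-sided quantiles of
#' \eqn{\Delta = index_B - index_A} at each depth form the bounds.
#'
#' Designs: `"f1_het_dh"` (heterozygous parent x doubled haploid; each
#' pooled individual carries the segregating allele with probability 1/2,
#' dosage on the 0/1 haplotype scale) and `"f2"` (dosage
#' Binomial(2, 1/2)/2).
#'
#' @param pool_size_a,pool_size_b Individuals per pool.
#' @param depths Integer vector of read depths to tabulate.
#' @param design Population design tag.
#' @param replicates Monte-Carlo replicates (default 10000).
#' @param level Two-sided confidence level (default 0.95).
#' @param seed Integer seed; bounds are reproducible given the seed.
#' @return A `"ci_table"` data.frame with `depth`, `lower`, `upper`, and
#'   attributes recording the design and replicate count.
#' @export
simulate_delta_ci <- function(pool_size_a, pool_size_b, depths,
                              design = c("f1_het_dh", "f2"),
                              replicates = 10000, level = 0.95,
                              seed = 1L) {
  design <- tryCatch(match.arg(design), error = function(e)
    stop("unknown design tag; supported: f1_het_dh, f2"))
  stopifnot(pool_size_a >= 1, pool_size_b >= 1, length(depths) >= 1)
  depths <- sort(unique(as.integer(depths)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draw_freq <- function(n_ind, r) {
    switch(design,
           f1_het_dh = rbinom(r, n_ind, 0.5) / n_ind,
           f2 = rbinom(r, 2L * n_ind, 0.5) / (2L * n_ind))
  }
  fa <- draw_freq(pool_size_a, replicates)
  fb <- draw_freq(pool_size_b, replicates)
  alpha <- (1 - level) / 2
  res <- t(vapply(depths, function(d) {
    ia <- rbinom(replicates, d, fa) / d
    ib <- rbinom(replicates, d, fb) / d
    quantile(ib - ia, probs = c(alpha, 1 - alpha), names = FALSE, type = 7)
  }, numeric(2)))
  structure(data.frame(depth = depths, lower = res[, 1], upper = res[, 2]),
            design = design, replicates = replicates, level = level,
            pool_sizes = c(pool_size_a, pool_size_b), seed = seed,
            class = c("ci_table", "data.frame"))
}

# save/restore global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Look up delta CI bounds at arbitrary depths
#'
#' Linear interpolation between tabulated depths; constant extrapolation
#' beyond the table's range.
#'
#' @param ci A [simulate_delta_ci()] table.
#' @param depth Depths to look up.
#' @return A two-column matrix `lower`, `upper`.
#' @export
ci_bounds <- function(ci, depth) {
  if (nrow(ci) == 1L) {
    cbind(lower = rep(ci$lower, length(depth)),
          upper = rep(ci$upper, length(depth)))
  } else {
    cbind(lower = approx(ci$depth, ci$lower, xout = depth, rule = 2)$y,
          upper = approx(ci$depth, ci$upper, xout = depth, rule = 2)$y)
  }
}

#' Candidate-flagging thresholds
#'
#' @param gprime_threshold Retain SNPs with G' strictly above this value
#'   (default 2.5).
#' @param use_delta_ci Additionally require delta SNP-index outside its
#'   simulated null confidence interval.
#' @return A `"threshold_config"` list.
#' @export
threshold_config <- function(gprime_threshold = 2.5, use_delta_ci = FALSE) {
  stopifnot(gprime_threshold >= 0)
  structure(list(gprime_threshold = gprime_threshold,
                 use_delta_ci = use_delta_ci),
            class = "threshold_config")
}

#' Compute per-SNP statistics for one pool contrast
#'
#' Builds the full per-SNP statistics table for a contrast: SNP-indices,
#' \eqn{\Delta}(SNP-index) (pool B minus pool A, so with trait-ordered
#' pools a positive delta means the alternate allele is enriched in the
#' higher pool), G, tricube-smoothed G', and (when at least 50 SNPs are
#' available and G' is not degenerate) log-normal null p/q-values.
#' Only SNP-type records enter; indels are ignored here.
#'
#' @param variants A filtered `"pool_variants"` data.frame.
#' @param contrast Two pool labels (A, B) or a row of
#'   [enumerate_contrasts()].
#' @param smoothing A [smoothing_config()].
#' @param pvalues Compute null p-values when feasible (default TRUE).
#' @param delta_outlier_ci Optional [simulate_delta_ci()] table: when
#'   given, SNPs whose delta falls outside these bounds are removed
#'   *before* smoothing — an artifact-removal mode for designs where
#'   such deltas are unattainable biologically. Off (NULL) by default;
#'   the usual route keeps all SNPs and applies the delta CI at the
#'   candidate-flagging stage instead.
#' @return A `"contrast_stats"` data.frame with columns `chrom`, `pos`,
#'   `depth_a`, `depth_b`, `snp_index_a`, `snp_index_b`, `delta`, `g`,
#'   `gprime`, and optionally `p_value`, `q_value`.
#' @export
compute_contrast_stats <- function(variants, contrast,
                                   smoothing = smoothing_config(),
                                   pvalues = TRUE,
                                   delta_outlier_ci = NULL) {
  if (is.data.frame(contrast)) contrast <- c(contrast$pool_a[1], contrast$pool_b[1])
  a <- contrast[1]; b <- contrast[2]
  v <- variants[variants$type == "snp", , drop = FALSE]
  ra <- v[[paste0(a, "_ref")]]; aa <- v[[paste0(a, "_alt")]]
  rb <- v[[paste0(b, "_ref")]]; ab <- v[[paste0(b, "_alt")]]
  st <- data.frame(chrom = v$chrom, pos = v$pos,
                   depth_a = ra + aa, depth_b = rb + ab,
                   snp_index_a = snp_index(ra, aa),
                   snp_index_b = snp_index(rb, ab),
                   stringsAsFactors = FALSE)
  st$delta <- st$snp_index_b - st$snp_index_a
  st$g <- g_statistic(ra, aa, rb, ab)
  if (!is.null(delta_outlier_ci)) {
    b <- ci_bounds(delta_outlier_ci, round((st$depth_a + st$depth_b) / 2))
    st <- st[st$delta >= b[, "lower"] & st$delta <= b[, "upper"], ,
             drop = FALSE]
  }
  st <- st[order(st$chrom, st$pos), , drop = FALSE]
  rownames(st) <- NULL
  st$gprime <- smooth_gprime(st$chrom, st$pos, st$g, smoothing)
  if (pvalues && nrow(st) >= 50L && length(unique(st$gprime)) > 1L) {
    pq <- null_pvalues(st$gprime)
    st$p_value <- pq$p_value
    st$q_value <- pq$q_value
  }
  structure(st, contrast = paste(a, b, sep = "-"),
            class = c("contrast_stats", "data.frame"))
}

#' Flag candidate SNPs
#'
#' A SNP is flagged iff its G' strictly exceeds the threshold and, when
#' `use_delta_ci` is set, its delta SNP-index falls outside the simulated
#' null confidence interval for its depth (the CI is looked up at the
#' rounded mean of the two pool depths).
#'
#' @param stats A `"contrast_stats"` data.frame.
#' @param thresholds A [threshold_config()].
#' @param ci A [simulate_delta_ci()] table (required when `use_delta_ci`).
#' @return `stats` with a logical `flagged` column.
#' @export
flag_candidates <- function(stats, thresholds = threshold_config(),
                            ci = NULL) {
  flag <- stats$gprime > thresholds$gprime_threshold
  if (isTRUE(thresholds$use_delta_ci)) {
    if (is.null(ci)) stop("use_delta_ci requires a CI table")
    d <- round((stats$depth_a + stats$depth_b) / 2)
    b <- ci_bounds(ci, d)
    flag <- flag & (stats$delta < b[, "lower"] | stats$delta > b[, "upper"])
  }
  stats$flagged <- flag
  stats
}

#' @export
print.contrast_stats <- function(x, ...) {
  cat("Pool-contrast SNP statistics:", attr(x, "contrast") %||% "", "\n")
  cat(" ", nrow(x), "SNPs on", length(unique(x$chrom)), "chromosome(s);",
      "max G' =", signif(max(x$gprime), 4), "\n")
  NextMethod()
}

#' Plot G' along the genome
#'
#' Simple per-chromosome line plot of smoothed G' with the retention
#' threshold, in base graphics.
#'
#' @param x A `"contrast_stats"` data.frame.
#' @param threshold Horizontal reference line (default 2.5).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.contrast_stats <- function(x, threshold = 2.5, ...) {
  chroms <- unique(x$chrom)
  offs <- setNames(cumsum(c(0, head(tapply(x$pos, x$chrom, max)[chroms], -1))),
                   chroms)
  gx <- x$pos + offs[x$chrom]
  graphics::plot(gx, x$gprime, type = "p", pch = 16, cex = 0.4,
                 col = (match(x$chrom, chroms) %% 2) + 1,
                 xlab = "genome position (bp, chromosomes concatenated)",
                 ylab = "G'", ...)
  graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
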