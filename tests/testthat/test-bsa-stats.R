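test_that("SNP-index is the alt read fraction", {
  expect_equal(snp_index(10, 10), 0.5)
  expect_equal(snp_index(40, 0), 0)
  expect_equal(snp_index(30, 10), 0.25)
  expect_equal(snp_index(c(10, 0), c(10, 5)), c(0.5, 1))
  expect_error(snp_index(0, 0), "zero total depth")
})

test_that("G matches hand-derived values and the entropy-form oracle", {
  expect_equal(g_statistic(20, 20, 20, 20), 0)
  # all expected counts are 20; 2*(60 ln 1.5 + 20 ln 0.5)
  expect_equal(g_statistic(30, 10, 10, 30),
               2 * (60 * log(1.5) + 20 * log(0.5)), tolerance = 1e-12)
  expect_equal(g_statistic(30, 10, 10, 30), 20.9299, tolerance = 1e-4)
  # 0*ln 0 convention
  expect_equal(g_statistic(0, 40, 40, 0), 160 * log(2), tolerance = 1e-12)
  expect_error(g_statistic(0, 0, 10, 10), "at least one read")

  set.seed(11)
  dev <- vapply(1:50, function(i) {
    tb <- rpois(4, 30) + c(1, 0, 1, 0)
    abs(g_statistic(tb[1], tb[2], tb[3], tb[4]) -
          g_oracle(tb[1], tb[2], tb[3], tb[4]))
  }, numeric(1))
  expect_lt(max(dev), 1e-9)
})

test_that("swapping pool labels negates delta and leaves G and G' unchanged", {
  pools <- c("A", "B")
  set.seed(5)
  n <- 60
  v <- make_variants("c1", sort(sample.int(5e6, n)), pools = pools,
                     depths = list(A = list(ref = 1, alt = 1),
                                   B = list(ref = 1, alt = 1)))
  v$A_ref <- rpois(n, 50) + 1; v$A_alt <- rpois(n, 50) + 1
  v$B_ref <- rpois(n, 30) + 1; v$B_alt <- rpois(n, 70) + 1
  ab <- compute_contrast_stats(v, c("A", "B"), pvalues = FALSE)
  ba <- compute_contrast_stats(v, c("B", "A"), pvalues = FALSE)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$g, ba$g)
  expect_equal(ab$gprime, ba$gprime)
  expect_equal(ab$delta, ab$snp_index_b - ab$snp_index_a)
})

test_that("tricube smoothing: self-weight, constants, hand oracle, locality", {
  cfg <- smoothing_config(1e6)   # h = 500 kb
  expect_equal(cfg$h, 5e5)
  w <- tricube(c(0, 2e5, 5e5, 7e5), 5e5)
  expect_equal(w[1], 1)
  expect_equal(w[3], 0)
  expect_equal(w[4], 0)
  expect_true(all(w >= 0 & w <= 1))

  # single SNP -> its own G
  expect_equal(smooth_gprime("c1", 1000, 7.3, cfg), 7.3)
  # constant G stays constant
  pos <- c(1e5, 3e5, 4e5, 9e5, 2e6)
  expect_equal(smooth_gprime(rep("c1", 5), pos, rep(3, 5), cfg), rep(3, 5))

  # three SNPs at 0 / 200 kb / 900 kb with G = (1, 2, 10), h = 500 kb:
  # middle SNP sees weights ((1-0.4^3)^3, 1, 0)
  w0 <- (1 - (2e5 / 5e5)^3)^3
  got <- smooth_gprime(rep("c1", 3), c(0, 2e5, 9e5), c(1, 2, 10), cfg)
  expect_equal(got[2], (w0 * 1 + 1 * 2) / (w0 + 1), tolerance = 1e-12)

  # invariant to a SNP at distance > h, and to other chromosomes
  base <- smooth_gprime(rep("c1", 2), c(1e5, 2e5), c(4, 6), cfg)
  with_far <- smooth_gprime(rep("c1", 3), c(1e5, 2e5, 9e5), c(4, 6, 100), cfg)
  expect_equal(with_far[1:2], base)
  two_chr <- smooth_gprime(c("c1", "c1", "c2"), c(1e5, 2e5, 1.5e5),
                           c(4, 6, 100), cfg)
  expect_equal(two_chr[1:2], base)
  expect_equal(two_chr[3], 100)
})

test_that("log-normal null p-values are calibrated and monotone in G'", {
  set.seed(7)
  gp <- stats::rlnorm(10000, meanlog = 1, sdlog = 0.5)
  pq <- null_pvalues(gp)
  expect_true(all(pq$p_value >= 0 & pq$p_value <= 1))
  expect_true(all(pq$q_value >= pq$p_value - 1e-12))
  # draws from the fitted null: ~5% below p = 0.05
  expect_lt(abs(mean(pq$p_value < 0.05) - 0.05), 0.01)
  # monotone nonincreasing in G'
  o <- order(gp)
  expect_true(all(diff(pq$p_value[o]) <= 1e-12))
  expect_equal(which.min(pq$p_value), which.max(gp))
  expect_error(null_pvalues(rep(2, 100)), "threshold mode")
  expect_error(null_pvalues(rlnorm(10)), "at least 50")
})

test_that("delta CI simulation: defaults, reproducibility, depth monotonicity", {
  ci <- simulate_delta_ci(10, 10, depths = c(50, 100, 400), seed = 3)
  expect_equal(attr(ci, "replicates"), 10000)
  expect_equal(attr(ci, "level"), 0.95)
  expect_true(all(ci$lower <= 0 & ci$upper >= 0))
  # reproducible bit-for-bit under the same seed
  expect_identical(ci, simulate_delta_ci(10, 10, c(50, 100, 400), seed = 3))
  # read noise shrinks with depth: bounds no wider at 400x than at 50x
  expect_gte(ci$upper[ci$depth == 50], ci$upper[ci$depth == 400])
  expect_lte(ci$lower[ci$depth == 50], ci$lower[ci$depth == 400])
  # law of large numbers: huge pools and depth pin delta at 0
  big <- simulate_delta_ci(1e6, 1e6, depths = 1e6, replicates = 2000,
                           seed = 4)
  expect_equal(big$lower, 0, tolerance = 5e-3)
  expect_equal(big$upper, 0, tolerance = 5e-3)
  expect_error(simulate_delta_ci(10, 10, 100, design = "bc1"),
               "f1_het_dh")
  # interpolation covers unseen depths
  b <- ci_bounds(ci, c(75, 1000))
  expect_true(b[1, "upper"] <= ci$upper[1] && b[1, "upper"] >= ci$upper[2])
  expect_equal(unname(b[2, "upper"]), ci$upper[ci$depth == 400])
})

test_that("the pre-smoothing delta-outlier removal mode drops out-of-CI SNPs", {
  pools <- c("A", "B")
  v <- make_variants("c1", c(1e5, 2e5, 3e5), pools = pools,
                     depths = list(A = list(ref = 50, alt = 50),
                                   B = list(ref = 50, alt = 50)))
  v$B_alt <- c(50, 95, 55); v$B_ref <- 100 - v$B_alt   # deltas 0, .45, .05
  ci <- structure(data.frame(depth = 100, lower = -0.3, upper = 0.3),
                  class = c("ci_table", "data.frame"))
  st_all <- compute_contrast_stats(v, pools, pvalues = FALSE)
  st_flt <- compute_contrast_stats(v, pools, pvalues = FALSE,
                                   delta_outlier_ci = ci)
  expect_equal(nrow(st_all), 3L)
  expect_equal(st_flt$pos, c(1e5, 3e5))
  expect_true(all(abs(st_flt$delta) <= 0.3))
})

test_that("candidate flagging respects the strict G' cutoff and the delta gate", {
  st <- data.frame(chrom = "c1", pos = c(1, 2, 3) * 1e5,
                   depth_a = 100, depth_b = 100,
                   snp_index_a = 0.5, snp_index_b = 0.5,
                   delta = c(0, 0.5, 0.5), g = 1,
                   gprime = c(2.5, 2.6, 2.4))
  f <- flag_candidates(st, threshold_config(2.5, use_delta_ci = FALSE))
  expect_equal(f$flagged, c(FALSE, TRUE, FALSE))  # 2.5 itself not retained

  ci <- structure(data.frame(depth = 100, lower = -0.3, upper = 0.3),
                  class = c("ci_table", "data.frame"))
  st$delta <- c(0.5, 0, 0.5)
  f <- flag_candidates(st, threshold_config(2.5, use_delta_ci = TRUE), ci)
  expect_equal(f$flagged, c(FALSE, FALSE, FALSE))
  st$delta <- c(0.5, 0.31, 0.5)
  f <- flag_candidates(st, threshold_config(2.5, use_delta_ci = TRUE), ci)
  expect_equal(f$flagged, c(FALSE, TRUE, FALSE))
  expect_error(flag_candidates(st, threshold_config(use_delta_ci = TRUE)),
               "CI table")
})
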