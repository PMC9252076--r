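test_that("annotation propagation follows the true-path rule and is idempotent", {
  ids <- c("a", "b", "c")
  g <- make_ontology(ids, data.frame(child = c("c", "b"), parent = c("b", "a")))
  prop <- propagate_annotations(list(g1 = "c"), g)
  expect_setequal(prop$g1, c("a", "b", "c"))
  expect_equal(propagate_annotations(prop, g)$g1, prop$g1)

  expect_warning(propagate_annotations(list(g1 = c("c", "zzz")), g), "zzz")

  # random DAG: per-gene recursive-ancestor oracle
  d <- random_dag_edges(25, 13)
  dag <- make_ontology(d$ids, d$edges)
  set.seed(14)
  ann <- lapply(1:10, function(i) sample(d$ids, sample(1:3, 1)))
  names(ann) <- paste0("g", 1:10)
  prop <- propagate_annotations(ann, dag)
  anc_oracle <- function(t) {
    out <- character(0)
    stack <- t
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v %in% out) next
      out <- c(out, v)
      stack <- c(stack, d$edges$parent[d$edges$child == v])
    }
    out
  }
  for (g_ in names(ann))
    expect_setequal(prop[[g_]],
                    Reduce(union, lapply(ann[[g_]], anc_oracle)))
})

test_that("hypergeometric SEA matches exhaustive enumeration and its contracts", {
  ids <- c("root", "t1", "t2")
  g <- make_ontology(ids, data.frame(child = c("t1", "t2"),
                                     parent = c("root", "root")))
  universe <- paste0("g", 1:10)
  # term t1 annotates 4 universe genes; study of 3 hits all 3 annotated
  ann <- c(lapply(setNames(universe[1:4], universe[1:4]), function(x) "t1"),
           lapply(setNames(universe[5:10], universe[5:10]), function(x) "t2"))
  res <- sea(universe[1:3], universe, ann, graph = g)
  r1 <- res[res$term == "t1", ]
  expect_equal(r1$p_value, 1 / 30, tolerance = 1e-12)
  expect_equal(r1$p_value, hyper_tail_enum(10, 4, 3, 3), tolerance = 1e-12)
  # the root annotates every gene -> p = 1
  expect_equal(res$p_value[res$term == "root"], 1)
  # terms with k = 0 are not tested
  expect_false("t2" %in% res$term)
  # study outside the universe is fatal and names offenders
  expect_error(sea(c("g1", "gX"), universe, ann, graph = g), "gX")
  # duplicates are deduplicated with a warning, result unchanged
  expect_warning(res2 <- sea(c("g1", "g2", "g3", "g1"), universe, ann,
                             graph = g), "duplicate")
  expect_equal(res2$p_value, res$p_value)
  # shrinking the study can only shrink k
  res3 <- sea(universe[1:2], universe, ann, graph = g)
  expect_lte(res3$k[res3$term == "t1"], r1$k)
})

test_that("BY adjustment: hand-derived values and dominance over BH and raw p", {
  # c(3) = 11/6; all three adjusted to 3*(11/6)*0.01 = 0.055
  expect_equal(by_adjust(c(0.01, 0.02, 0.03)), rep(0.055, 3),
               tolerance = 1e-12)
  expect_equal(by_adjust(0.4), 0.4)          # c(1) = 1
  expect_equal(by_adjust(rep(1, 5)), rep(1, 5))
  expect_error(by_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(15)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    by <- by_adjust(p)
    bh <- p.adjust(p, "BH")
    expect_equal(by, by_oracle(p), tolerance = 1e-12)
    expect_true(all(by >= bh - 1e-12))
    expect_true(all(bh >= p - 1e-12))
    # ties in p receive identical adjusted values
    pt <- c(0.02, 0.02, 0.5)
    expect_equal(by_adjust(pt)[1], by_adjust(pt)[2])
  }
})

test_that("cross-comparison merges contrasts and counts overlap correctly", {
  mk_res <- function(terms, fdr) data.frame(term = terms, k = 1, n = 5,
                                            K = 2, N = 50, p_value = fdr,
                                            fdr = fdr,
                                            enriched = fdr < 0.05)
  # disjoint enrichments -> union rows, nothing shared
  cc <- cross_compare(list(a = mk_res(c("x", "y", "z"), 0.01),
                           b = mk_res(c("u", "v", "w"), 0.01)))
  expect_equal(nrow(cc$fdr), 6L)
  expect_equal(unname(cc$summary["shared_by_all"]), 0L)
  expect_equal(unname(cc$summary["unique"]), 6L)
  # identical lists -> all shared
  cc2 <- cross_compare(list(a = mk_res(c("x", "y"), 0.01),
                            b = mk_res(c("x", "y"), 0.01)))
  expect_equal(unname(cc2$summary["shared_by_all"]), 2L)
  expect_error(cross_compare(list(a = mk_res("x", 0.01))), "two contrasts")

  # constructed three-way overlap vs set algebra
  res <- list(a = mk_res(c("s", "t", "u"), 0.01),
              b = mk_res(c("s", "t"), 0.01),
              c = mk_res(c("s", "v"), 0.01))
  cc3 <- cross_compare(res)
  sets <- lapply(res, function(r) r$term[r$enriched])
  all_terms <- unique(unlist(sets))
  counts <- vapply(all_terms, function(t)
    sum(vapply(sets, function(s) t %in% s, logical(1))), integer(1))
  expect_equal(unname(cc3$summary["shared_by_all"]), sum(counts == 3))
  expect_equal(unname(cc3$summary["shared_by_majority"]), sum(counts > 1.5))
  expect_equal(unname(cc3$summary["unique"]), sum(counts == 1))
  expect_true(is.na(cc3$fdr["u", "b"]))   # untested stays NA
})

test_that("pathway over-representation: closed forms, planted signal, GMT round trip", {
  universe <- paste0("g", 1:100)
  sets <- list(pw1 = universe[1:5], pw2 = universe[6:20],
               pw3 = universe[90:99])
  # study = one complete 5-gene pathway: p = 1 / C(100, 5)
  res <- pathway_enrich(universe[1:5], sets, universe)
  expect_equal(res$p_value[res$set == "pw1"], 1 / choose(100, 5),
               tolerance = 1e-12)
  expect_false("pw3" %in% res$set)        # disjoint set untested
  expect_error(pathway_enrich("nope", sets, universe), "no overlap")

  # planted signal: pathway genes over-drawn into the study list
  set.seed(16)
  study <- c(universe[1:4], sample(universe[21:100], 6))
  res2 <- pathway_enrich(study, sets, universe)
  expect_equal(res2$set[1], "pw1")

  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(lapply(back, identity)[names(sets)],
               sets, ignore_attr = TRUE)
})
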