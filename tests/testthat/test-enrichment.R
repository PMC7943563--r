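test_that("GMT parsing dedups within sets and drops empty sets", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET1\tdesc\ta\tb\tc",
               "SET2\tdesc\tx\ty",
               "DUP\tdesc\ta\ta\tb",
               "EMPTY\tdesc"), path)
  warns <- capture_warnings(sets <- read_gmt(path))
  expect_match(warns, "empty set", all = FALSE)
  expect_match(warns, "duplicate", all = FALSE)
  expect_setequal(names(sets), c("SET1", "SET2", "DUP"))
  expect_length(sets$DUP, 2L)

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET1\tdesc\ta", "LONE"), bad)
  expect_error(read_gmt(bad), "line 2", class = "nescore_format_error")
})

test_that("correlation ranking is descending with deterministic ties and exclusions", {
  sc <- c(s1 = -1, s2 = 0, s3 = 1)
  v <- rbind(pos = c(-1, 0, 1), neg = c(1, 0, -1),
             flat = c(2, 2, 2), mid = c(0, 1, 0))
  colnames(v) <- names(sc)
  expect_message(rk <- rank_genes_by_correlation(expression_matrix(v), sc),
                 "constant")
  expect_equal(rk$gene[1], "pos")
  expect_equal(rk$metric[1], 1)
  expect_equal(rk$gene[nrow(rk)], "neg")
  expect_equal(rk$metric[nrow(rk)], -1)
  expect_false("flat" %in% rk$gene)
  expect_false(is.unsorted(rev(rk$metric)))
})

test_that("enrichment score matches direct running-sum arithmetic", {
  ranked <- stats::setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  # single top gene: sum jumps straight to 1
  expect_equal(enrichment_score(ranked, "g1")$es, 1)
  # single bottom gene: sum reaches -1 just before the final hit
  expect_equal(enrichment_score(ranked, "g5")$es, -1)
  # frozen oracle for two mid-ranked hits (positions 2 and 4, p = 1):
  # running sum (-1/3, 1/3, 0, 1/3, 0); tie in |extreme| favours +1/3
  mid <- enrichment_score(ranked, c("g2", "g4"))
  expect_equal(mid$es, 1 / 3)
  expect_equal(mid$running_sum, c(-1, 1, 0, 1, 0) / 3)
  expect_equal(mid$leading_edge, "g2")

  expect_error(enrichment_score(ranked, paste0("g", 1:5)),
               class = "nescore_validation_error")
  expect_error(enrichment_score(ranked, "absent"),
               class = "nescore_validation_error")
})

test_that("enrichment score agrees with the brute-force oracle and fast path on random instances", {
  withr::with_seed(20, {
    for (rep in 1:40) {
      n <- sample(4:12, 1)
      metric <- sort(round(rnorm(n, 0, 2), 3), decreasing = TRUE)
      ranked <- stats::setNames(metric, paste0("g", seq_len(n)))
      k <- sample(seq_len(n - 1), 1)
      hit_idx <- sort(sample(n, k))
      set <- names(ranked)[hit_idx]
      hit <- names(ranked) %in% set
      if (sum(abs(metric[hit])) == 0) next
      es <- enrichment_score(ranked, set)$es
      expect_equal(es, brute_force_es(metric, hit), tolerance = 1e-12)
      expect_equal(es, nescore:::es_from_positions(hit_idx, abs(metric), n),
                   tolerance = 1e-12)
    }
  })
})

test_that("single-gene-set ES flips sign under ranking reversal", {
  # even list length: no gene sits at the exact midpoint, so the positive
  # and negative extremes never tie and the flip is exact
  ranked <- stats::setNames(c(5, 4, 2, 1, 0.5, 0.25), paste0("g", 1:6))
  reversed <- stats::setNames(-rev(unname(ranked)), rev(names(ranked)))
  for (g in names(ranked)) {
    expect_equal(enrichment_score(ranked, g)$es,
                 -enrichment_score(reversed, g)$es)
  }
})

test_that("preranked GSEA recovers a planted top set, is deterministic, and floors p-values", {
  withr::with_seed(8, {
    n <- 300
    metric <- sort(rnorm(n, 0, 1), decreasing = TRUE)
    ranked <- stats::setNames(metric, sprintf("g%03d", seq_len(n)))
    sets <- list(TOP = names(ranked)[1:20],
                 RANDOM = sample(names(ranked), 20))
    res <- preranked_gsea(ranked, sets, n_perm = 500, seed = 5)
    res2 <- preranked_gsea(ranked, sets, n_perm = 500, seed = 5)
    expect_identical(res, res2)
    top <- res[res$set == "TOP", ]
    expect_gt(top$nes, 0)
    expect_lte(top$pvalue, 10 / 501)
    expect_true(all(res$pvalue >= 1 / 501))
    expect_equal(sign(res$nes[res$es != 0]), sign(res$es[res$es != 0]))
  })
})

test_that("planted bottom set yields a negative NES (antisymmetry, statistical)", {
  withr::with_seed(13, {
    n <- 300
    metric <- sort(rnorm(n), decreasing = TRUE)
    ranked <- stats::setNames(metric, sprintf("g%03d", seq_len(n)))
    res <- preranked_gsea(ranked, list(BOTTOM = names(ranked)[(n - 19):n]),
                          n_perm = 500, seed = 5)
    expect_lt(res$nes, 0)
    expect_lt(res$pvalue, 0.05)
  })
})

test_that("preranked GSEA broadly agrees with fgsea on the same ranking", {
  skip_if_not_installed("fgsea")
  withr::with_seed(30, {
    n <- 500
    metric <- sort(rnorm(n), decreasing = TRUE)
    metric[1:15] <- metric[1:15] + 2
    ranked <- stats::setNames(metric, sprintf("g%03d", seq_len(n)))
    sets <- list(TOP = names(ranked)[1:15],
                 NULL1 = sample(names(ranked), 30),
                 NULL2 = sample(names(ranked), 50))
    mine <- preranked_gsea(ranked, sets, n_perm = 1000, seed = 2)
    ref <- suppressWarnings(
      fgsea::fgsea(sets, ranked, nPermSimple = 1000, scoreType = "std")
    )
    for (nm in names(sets)) {
      expect_equal(mine$es[mine$set == nm],
                   ref$ES[ref$pathway == nm], tolerance = 1e-6)
    }
    # both calls agree on which set is significant
    expect_lt(mine$padj[mine$set == "TOP"], 0.05)
    expect_lt(ref$padj[ref$pathway == "TOP"], 0.05)
    expect_gt(min(mine$pvalue[mine$set != "TOP"]), 0.05)
  })
})

test_that("ssGSEA matches the brute-force weighted-ECDF sum on a 4-gene toy", {
  v <- toy_matrix(cbind(s1 = c(5, 3, 2, 1)), genes = paste0("g", 1:4))
  got <- ssgsea(expression_matrix(v), list(SET = c("g1", "g3")),
                alpha = 0.25, normalize = FALSE)
  # independent evaluation of the four running-sum terms: ranks-from-bottom
  # are (4, 3, 2, 1); in-set weights 4^0.25, 2^0.25
  w1 <- 4^0.25; w3 <- 2^0.25; S <- w1 + w3
  expected <- (w1 / S - 0) + (w1 / S - 1 / 2) + (1 - 1 / 2) + (1 - 1)
  expect_equal(unname(got[1, "SET"]), expected)
})

test_that("ssGSEA with alpha = 0 reduces to the unweighted ECDF difference", {
  v <- toy_matrix(cbind(s1 = c(9, 7, 4, 2, 1)), genes = paste0("g", 1:5))
  got <- ssgsea(expression_matrix(v), list(SET = c("g1", "g2")),
                alpha = 0, normalize = FALSE)
  # hits at positions 1-2: in-ECDF (1/2, 1, 1, 1, 1), out-ECDF (0, 0, 1/3, 2/3, 1)
  expect_equal(unname(got[1, "SET"]), 1 / 2 + 1 + 2 / 3 + 1 / 3 + 0)
})

test_that("ssGSEA is monotone in set placement and normalization spans one unit", {
  genes <- paste0("g", 1:20)
  up <- c(20:11, 10:1); down <- rev(up)
  v <- toy_matrix(cbind(A = up, B = down), genes = genes)
  sets <- list(TOPA = genes[1:5])
  raw <- ssgsea(expression_matrix(v), sets, normalize = FALSE)
  expect_gt(raw["A", "TOPA"], raw["B", "TOPA"])
  norm <- ssgsea(expression_matrix(v), sets, normalize = TRUE)
  expect_equal(max(norm) - min(norm), 1)
})

test_that("consensus leading edge intersects, orders by reference metric, unions merged sets", {
  ref <- c(a = -0.9, b = -0.8, c = -0.5, d = -0.95, e = -0.2)
  # single dataset: top-k by |metric|
  expect_equal(leading_edge_top_k(list(c("a", "b", "c")), ref, k = 2),
               c("a", "b"))
  # intersection smaller than k, reference order
  got <- leading_edge_top_k(list(d1 = c("a", "b", "c"), d2 = c("b", "a", "e")),
                            ref, k = 25)
  expect_equal(got, c("a", "b"))
  # merged libraries are unioned per dataset before intersecting
  merged <- leading_edge_top_k(
    list(d1 = list(c("a"), c("b")), d2 = c("a", "b")), ref, k = 25)
  expect_setequal(merged, c("a", "b"))
  expect_warning(out <- leading_edge_top_k(list(c("a"), c("b")), ref),
                 "share no genes")
  expect_length(out, 0L)
})

test_that("sample-permutation GSEA orients planted programs and is seeded", {
  # NOTE: this null is deliberately conservative on tightly co-expressed
  # planted modules (the module clusters in every permuted ranking, keeping
  # null |ES| high), so only sign, bounds and determinism are asserted here.
  bundle <- generate_dataset(synthetic_config(n_samples = 60,
                                              n_background_genes = 200,
                                              seed = 55L))
  sc <- score_matrix(bundle$expr, bundle$signature)
  res <- gsea_sample_permutation(bundle$expr,
                                 stats::setNames(sc$ne_score, sc$sample),
                                 bundle$sets, n_perm = 100, seed = 4)
  expect_lt(res$es[res$set == "IMMUNE_PROGRAM"], 0)
  expect_gt(res$es[res$set == "REST_TARGETS"], 0)
  expect_true(all(res$pvalue >= 1 / 101 & res$pvalue <= 1))
  res2 <- gsea_sample_permutation(bundle$expr,
                                  stats::setNames(sc$ne_score, sc$sample),
                                  bundle$sets, n_perm = 100, seed = 4)
  expect_identical(res, res2)
})
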