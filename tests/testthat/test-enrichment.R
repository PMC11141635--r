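# Preranked GSEA, ssGSEA, z-scores and overlap tests.

test_that("ranking is descending with deterministic lexicographic ties", {
  r <- rank_genes(c(A = 2, B = 3))
  expect_equal(r$genes, c("B", "A"))
  r <- rank_genes(c(B = 1, A = 1))
  expect_equal(r$genes, c("A", "B"))
  r <- rank_genes(c(A = 1, B = 2, C = NaN))
  expect_equal(length(r$genes), 2L)
  expect_equal(r$n_excluded, 1L)
  expect_error(rank_genes(c(1, 2)), "named")
})

test_that("toy enrichment scores match the printed extremes", {
  ranked <- toy_ranked(c(4, 2, 1, 1))
  gs <- gene_set_collection(list(top = "g1", bottom = "g4",
                                 pair = c("g1", "g3")))
  res <- gsea_preranked(ranked, gs, n_perm = 50, seed = 1, min_size = 1)
  expect_equal(res$ES[res$set == "top"], 1.0)
  expect_equal(res$ES[res$set == "bottom"], -1.0)
  expect_equal(res$ES[res$set == "pair"], 0.8)
})

test_that("ES equals the brute-force running-sum oracle on enumerated subsets", {
  for (n in c(4, 6, 9, 12)) {
    scores <- withr::with_seed(100 + n, sort(round(rnorm(n), 2),
                                             decreasing = TRUE))
    ranked <- toy_ranked(scores)
    for (k in seq_len(min(4, n - 1))) {
      subsets <- utils::combn(n, k)
      for (j in seq_len(ncol(subsets))) {
        pos <- subsets[, j]
        gs <- gene_set_collection(list(S = paste0("g", pos)))
        res <- gsea_preranked(ranked, gs, n_perm = 2, seed = 1, min_size = 1)
        expect_es_equal(res$ES, oracle_es(scores, pos),
                        label = sprintf("n=%d subset={%s}", n,
                                        paste(pos, collapse = ",")))
      }
    }
  }
})

test_that("ES agrees with the fgsea reference statistic", {
  skip_if_not_installed("fgsea")
  scores <- withr::with_seed(7, sort(rnorm(30), decreasing = TRUE))
  names(scores) <- paste0("g", 1:30)
  ranked <- toy_ranked(unname(scores), names(scores))
  for (pos in list(c(1, 5, 9), c(2, 28, 30), c(10, 11, 12, 13))) {
    gs <- gene_set_collection(list(S = names(scores)[pos]))
    res <- gsea_preranked(ranked, gs, n_perm = 2, seed = 1, min_size = 1)
    expect_equal(res$ES,
                 fgsea::calcGseaStat(scores, selectedStats = pos,
                                     gseaParam = 1),
                 tolerance = 1e-12)
  }
})

test_that("negating scores and reversing the list negates ES", {
  scores <- c(5, 3, 2, 0.5, -1, -4)
  ranked <- toy_ranked(scores)
  pos <- c(2, 5)
  gs <- gene_set_collection(list(S = paste0("g", pos)))
  es <- gsea_preranked(ranked, gs, n_perm = 2, seed = 1, min_size = 1)$ES
  rev_scores <- rev(-scores)
  rev_ranked <- toy_ranked(rev_scores, paste0("g", 6:1))
  es_rev <- gsea_preranked(rev_ranked, gs, n_perm = 2, seed = 1,
                           min_size = 1)$ES
  expect_equal(es_rev, -es, tolerance = 1e-12)
})

test_that("Monte-Carlo nominal p converges to the exhaustive enumeration", {
  scores <- c(3.2, 2.1, 1.4, 0.9, 0.5, 0.2)
  ranked <- toy_ranked(scores)
  for (pos in list(c(1, 2), c(3, 5), c(1, 6))) {
    gs <- gene_set_collection(list(S = paste0("g", pos)))
    res <- gsea_preranked(ranked, gs, n_perm = 10000, seed = 42,
                          min_size = 1)
    null_es <- oracle_all_subset_es(scores, length(pos))
    p_exact <- oracle_nominal_p(res$ES, null_es)
    se <- sqrt(p_exact * (1 - p_exact) / 10000)
    expect_lt(abs(res$p - p_exact), max(3 * se, 1e-3),
              label = sprintf("subset {%s}: mc=%.4f exact=%.4f",
                              paste(pos, collapse = ","), res$p, p_exact))
  }
})

test_that("NES sign matches ES sign and permutation seeding is reproducible", {
  scores <- withr::with_seed(9, sort(rnorm(40), decreasing = TRUE))
  ranked <- toy_ranked(scores)
  gs <- gene_set_collection(list(hi = paste0("g", 1:5),
                                 lo = paste0("g", 36:40)))
  r1 <- gsea_preranked(ranked, gs, n_perm = 200, seed = 5)
  r2 <- gsea_preranked(ranked, gs, n_perm = 200, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(sign(r1$NES) == sign(r1$ES)))
  expect_gt(r1$NES[r1$set == "hi"], 0)
  expect_lt(r1$NES[r1$set == "lo"], 0)
})

test_that("sets outside the size window are skipped with a reason", {
  ranked <- toy_ranked(c(4, 3, 2, 1))
  gs <- gene_set_collection(list(small = "g1", ok = c("g1", "g2")))
  res <- gsea_preranked(ranked, gs, n_perm = 10, seed = 1, min_size = 2)
  expect_equal(res$set, "ok")
  skipped <- attr(res, "skipped")
  expect_equal(skipped$set, "small")
  expect_equal(skipped$reason, "below_min_size")
  gs_all <- gene_set_collection(list(everything = paste0("g", 1:4)))
  expect_error(gsea_preranked(ranked, gs_all, n_perm = 10, seed = 1,
                              min_size = 1), "universe")
})

test_that("ssGSEA matches the direct-summation oracle", {
  v <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
  mat <- cbind(s1 = v)
  gs <- gene_set_collection(list(S = c("b", "d")))
  got <- ssgsea_score(mat, gs, alpha = 0.25, normalize = FALSE)
  expect_equal(got["S", "s1"], oracle_ssgsea(v, c("b", "d"), 0.25),
               tolerance = 1e-12)
  expect_equal(got["S", "s1"], 0.08642723, tolerance = 1e-6)
  # larger random instance, several sets
  m <- withr::with_seed(3, matrix(rnorm(60), 20,
        dimnames = list(paste0("g", 1:20), paste0("s", 1:3))))
  gs2 <- gene_set_collection(list(A = paste0("g", c(1, 4, 7)),
                                  B = paste0("g", 11:18)))
  got2 <- ssgsea_score(m, gs2, alpha = 0.25, normalize = FALSE)
  for (s in colnames(m)) {
    expect_equal(got2["A", s], oracle_ssgsea(m[, s], gs2$sets$A, 0.25),
                 tolerance = 1e-10)
    expect_equal(got2["B", s], oracle_ssgsea(m[, s], gs2$sets$B, 0.25),
                 tolerance = 1e-10)
  }
})

test_that("ssGSEA extremal and invariance properties hold", {
  v <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
  mat <- cbind(s1 = v)
  singles <- gene_set_collection(
    setNames(as.list(names(v)), paste0("set_", names(v))))
  sc <- ssgsea_score(mat, singles, alpha = 0, normalize = FALSE)
  expect_equal(rownames(sc)[which.max(sc[, 1])], "set_a")  # top gene wins
  # identical columns give identical scores
  m2 <- cbind(s1 = v, s2 = v)
  sc2 <- ssgsea_score(m2, gene_set_collection(list(S = c("a", "d"))),
                      normalize = FALSE)
  expect_equal(sc2[, "s1"], sc2[, "s2"])
  # empty intersection is skipped with a reason
  sc3 <- ssgsea_score(mat, gene_set_collection(list(S = "zz")),
                      normalize = FALSE)
  expect_true(is.na(sc3["S", "s1"]))
  expect_equal(attr(sc3, "skipped")$reason, rep("no_members_in_matrix", 1))
})

test_that("z-scores standardize each set across samples", {
  m <- rbind(S1 = c(1, 2, 3), S2 = c(4, 4, 4))
  colnames(m) <- paste0("c", 1:3)
  expect_warning(z <- zscore_across_samples(m), "constant")
  expect_equal(unname(z["S1", ]), c(-1, 0, 1))  # sample-sd convention
  expect_equal(unname(z["S2", ]), c(0, 0, 0))
  big <- withr::with_seed(2, matrix(rnorm(50), 5))
  zb <- zscore_across_samples(big)
  expect_equal(unname(rowMeans(zb)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(zb, 1, sd)), rep(1, 5), tolerance = 1e-12)
  expect_error(zscore_across_samples(matrix(1:3, ncol = 1)), "at least two")
})

test_that("hypergeometric overlap test covers the trivial poles", {
  u <- paste0("g", 1:100)
  res <- overlap_test(u[1:10], u[1:10], u)
  expect_equal(res$overlap, 10)
  res_all <- overlap_test(u, u, u)
  expect_equal(res_all$overlap, 100)
  expect_equal(res_all$p, 1)
  res_disj <- overlap_test(u[1:10], u[51:60], u)
  expect_equal(res_disj$overlap, 0)
  expect_equal(res_disj$p, 1)
  expect_error(overlap_test("a", "a", character()), "empty universe")
  # cross-check against direct enumeration
  k <- res$overlap
  p_manual <- sum(dhyper(10:10, 10, 90, 10))
  expect_equal(res$p, p_manual, tolerance = 1e-12)
})

test_that("two-tailed Fisher p matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), oracle_fisher_2x2(5, 0, 0, 5),
               tolerance = 1e-12)
  for (tab in list(c(8, 2, 3, 7), c(1, 9, 5, 5), c(0, 10, 10, 0))) {
    expect_equal(do.call(fisher_exact_2x2, as.list(tab)),
                 do.call(oracle_fisher_2x2, as.list(tab)),
                 tolerance = 1e-9,
                 label = paste(tab, collapse = ","))
  }
  expect_error(fisher_exact_2x2(-1, 0, 0, 5), "non-negative")
  expect_error(fisher_exact_2x2(1.5, 0, 0, 5), "integer")
})
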