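# Spike-in scale factors, peak curation, peak merging and
# differential-region classification.

test_that("scale factors follow the mean-over-count formula", {
  expect_equal(unname(spikein_scale_factors(c(100, 300))), c(2, 2 / 3))
  expect_equal(unname(spikein_scale_factors(c(50, 50, 50))), rep(1, 3))
  expect_equal(unname(spikein_scale_factors(777)), 1)
  expect_error(spikein_scale_factors(c(a = 100, b = 0)), "sample: b")
  expect_error(spikein_scale_factors(numeric()), "no samples")
})

test_that("scaling equalizes spike-in totals to the pre-scaling mean", {
  spike <- c(s1 = 120, s2 = 480, s3 = 333, s4 = 1)
  f <- spikein_scale_factors(spike)
  expect_equal(unname(spike * f), rep(mean(spike), 4))
})

test_that("AUC curation keeps the log2(AUC+1) >= 13 boundary exactly", {
  regions <- region_table(rep("chr1", 3), c(0, 2000, 4000),
                          c(1000, 3000, 5000), c("at", "below", "high"))
  signal <- list(regions = regions, auc = c(8191, 8190, 1e6))
  out <- curate_peaks(signal, auc_min_log2 = 13)
  expect_equal(out$regions$name, c("at", "high"))  # 8191 -> log2(8192)=13
  expect_equal(unname(attr(out, "removed")), c(1, 0))
})

test_that("any blacklist overlap, even 1 bp, removes a region", {
  regions <- region_table(rep("chr1", 3), c(0, 1000, 2000),
                          c(100, 1100, 2100), c("a", "b", "c"))
  signal <- list(regions = regions, auc = rep(1e6, 3),
                 counts = matrix(1:6, 3,
                                 dimnames = list(regions$name, c("s1", "s2"))))
  bl <- region_table("chr1", 1099, 1500)  # overlaps region b by 1 bp
  out <- curate_peaks(signal, bl)
  expect_equal(out$regions$name, c("a", "c"))
  expect_equal(rownames(out$counts), c("a", "c"))
  expect_equal(unname(attr(out, "removed")), c(0, 1))
  # abutting (half-open) is not an overlap
  bl2 <- region_table("chr1", 1100, 1500)
  out2 <- curate_peaks(signal, bl2)
  expect_equal(nrow(out2$regions), 3)
})

test_that("curation is idempotent and bookkeeping sums to input - output", {
  regions <- region_table(rep("chr1", 4), c(0, 2000, 4000, 6000),
                          c(1000, 3000, 5000, 7000))
  signal <- list(regions = regions, auc = c(10, 1e6, 1e6, 1e6))
  bl <- region_table("chr1", 4500, 4600)
  out <- curate_peaks(signal, bl)
  expect_equal(sum(attr(out, "removed")),
               nrow(signal$regions) - nrow(out$regions))
  again <- curate_peaks(out, bl)
  expect_equal(again$regions, out$regions)
  expect_equal(unname(attr(again, "removed")), c(0, 0))
})

test_that("peak merging unions overlapping and abutting intervals", {
  a <- region_table("chr1", 0, 100)
  b <- region_table("chr1", 50, 150)
  m <- merge_condition_peaks(a, b)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 0)
  expect_equal(m$end, 150)
  # abutting-by-0 merged
  m2 <- merge_condition_peaks(region_table("chr1", 0, 10),
                              region_table("chr1", 10, 20))
  expect_equal(nrow(m2), 1)
  expect_equal(c(m2$start, m2$end), c(0, 20))
  # disjoint unchanged; output sorted
  d <- region_table(c("chr1", "chr1"), c(20, 0), c(30, 10))
  m3 <- merge_condition_peaks(d)
  expect_equal(nrow(m3), 2)
  expect_equal(m3$start, c(0, 20))
  # idempotent
  expect_equal(merge_condition_peaks(m3, m3)[, 1:3], m3[, 1:3])
})

test_that("identical conditions classify as not significant with delta 0", {
  fx <- generate_region_fixture(8, 3, 5000, noise_sd = 0, spikein_cv = 0,
                                seed = 1L)
  res <- differential_regions(fx$counts, fx$groups, fx$auc,
                              treated = "treated")
  expect_equal(res$delta, rep(0, 8))
  expect_equal(res$class, rep("not_significant", 8))
})

test_that("a 4-fold effect region is classified as increase; NB p agrees with the relabeling oracle", {
  fx <- generate_region_fixture(10, 3, 5000, effect_regions = 4,
                                fold_change = 4, base_depth = 1000,
                                noise_sd = 0, spikein_cv = 0, seed = 2L)
  res_nb <- differential_regions(fx$counts, fx$groups, fx$auc,
                                 treated = "treated")
  expect_equal(res_nb$delta[4], log2(4001) - log2(1001), tolerance = 1e-12)
  expect_gt(res_nb$delta[4], 1.9)
  expect_equal(res_nb$class[4], "increase")
  expect_true(all(res_nb$class[-4] == "not_significant"))
  # exact permutation over the C(6,3) = 20 relabelings: the observed
  # split and its mirror are the two most extreme, p = 2/20 = 0.10
  res_perm <- differential_regions(fx$counts, fx$groups, fx$auc,
                                   treated = "treated",
                                   method = "permutation")
  expect_equal(res_perm$p[4], 0.1, tolerance = 1e-12)
  expect_equal(res_perm$class[4], "increase")
})

test_that("the delta gate binds even at tiny p", {
  # counts strongly separated, but AUC delta just under the 1.5 cutoff
  counts <- matrix(c(100, 110, 105, 1000, 990, 1010), 1)
  colnames(counts) <- paste0("s", 1:6)
  groups <- setNames(rep(c("control", "treated"), each = 3), colnames(counts))
  auc <- matrix(c(rep(100, 3), rep(100 * 2^1.49, 3)), 1,
                dimnames = list("r1", colnames(counts)))
  res <- differential_regions(counts, groups, auc, treated = "treated")
  expect_lt(res$p, 0.01)
  expect_lt(res$delta, 1.5)
  expect_equal(res$class, "not_significant")
})

test_that("all-zero regions get p = 1 and decreases are called symmetric", {
  counts <- rbind(zero = rep(0L, 6),
                  down = c(4000, 3900, 4100, 1000, 990, 1010))
  colnames(counts) <- paste0("s", 1:6)
  groups <- setNames(rep(c("control", "treated"), each = 3), colnames(counts))
  auc <- counts
  res <- differential_regions(counts, groups, auc, treated = "treated")
  expect_equal(res$p[1], 1)
  expect_equal(res$class[1], "not_significant")
  expect_lt(res$delta[2], -1.5)
  expect_equal(res$class[2], "decrease")
})

test_that("spike-in scale factors feed through the differential call", {
  # treated samples sequenced twice as deep; spike-in factors undo it
  counts <- rbind(r1 = c(1000, 1010, 990, 2000, 2020, 1980))
  colnames(counts) <- paste0("s", 1:6)
  groups <- setNames(rep(c("control", "treated"), each = 3), colnames(counts))
  auc <- counts
  sf <- spikein_scale_factors(c(1000, 1000, 1000, 2000, 2000, 2000))
  names(sf) <- colnames(counts)
  res <- differential_regions(counts, groups, auc, treated = "treated",
                              scale_factors = sf)
  expect_lt(abs(res$delta), 0.2)
  expect_equal(res$class, "not_significant")
})

test_that("null fixtures rarely cross the significance gate", {
  fx <- generate_region_fixture(200, 3, 5000, noise_sd = 0.1,
                                spikein_cv = 0, seed = 6L)
  res <- differential_regions(fx$counts, fx$groups, fx$auc,
                              treated = "treated")
  expect_lte(mean(res$p <= 0.10), 0.10 + 0.07)
  expect_true(all(res$class == "not_significant"))
})

test_that("group contracts are validated", {
  counts <- matrix(1:6, 1); colnames(counts) <- paste0("s", 1:6)
  expect_error(differential_regions(counts, rep("a", 6), counts),
               "exactly two conditions")
  expect_error(differential_regions(counts, c(rep("a", 3), rep("b", 3)),
                                    counts, treated = "c"),
               "unknown treated level")
})
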