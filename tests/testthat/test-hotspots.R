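test_that("coverage counts carriers per SNP with full-group denominator", {
  lay <- genome_layout("chr1", 1e5, list(chr1 = seq(1000, 99000, by = 1000)))
  samples <- data.frame(sample_id = c("a", "b", "c", "d"), group_id = "all")
  seg <- roh_segments(c("a", "b"), "chr1", c(10000, 10000), c(20000, 20000))
  cov <- coverage_track(seg, lay, samples)
  inside <- cov$snps$pos >= 10000 & cov$snps$pos < 20000
  expect_true(all(cov$snps$freq[inside] == 0.5))
  expect_true(all(cov$snps$freq[!inside] == 0))
  # one individual's self-overlapping segments count once
  seg2 <- roh_segments(c("a", "a"), "chr1", c(10000, 15000), c(20000, 25000))
  cov2 <- coverage_track(seg2, lay, samples)
  expect_equal(max(cov2$snps$count), 1L)
  # no segments -> all-zero track; empty group errors
  expect_true(all(coverage_track(roh_segments(), lay, samples)$snps$count == 0))
  expect_error(coverage_track(seg, lay, samples, group_id = "zz"),
               "0 individuals")
})

test_that("permutation null is deterministic and conserves the statistic range", {
  lay <- uniform_layout(2, 1e6, 200, "even")
  set.seed(1)
  ds <- simulate_null_segments(lay, 8, 4, median_kb = 50, log_sd = 0.4)
  n1 <- permute_null(ds$segments, lay, ds$samples, n_perm = 50, seed = 9)
  n2 <- permute_null(ds$segments, lay, ds$samples, n_perm = 50, seed = 9)
  expect_identical(n1$max_freq, n2$max_freq)
  n3 <- permute_null(ds$segments, lay, ds$samples, n_perm = 50, seed = 10)
  expect_false(identical(n1$max_freq, n3$max_freq))
  expect_true(all(n1$max_freq >= 0 & n1$max_freq <= 1))
  # an all-genome segment leaves no freedom: max always 1
  lay1 <- genome_layout("c", 1e5, list(c = seq(1, 1e5, by = 1000)))
  segall <- roh_segments("a", "c", 0, 1e5)
  sm <- data.frame(sample_id = "a", group_id = "all")
  nf <- permute_null(segall, lay1, sm, n_perm = 30, seed = 1)
  expect_true(all(nf$max_freq == 1))
  # zero segments -> all-zero null
  n0 <- permute_null(roh_segments(), lay1, sm, n_perm = 20, seed = 1)
  expect_true(all(n0$max_freq == 0))
  # segment longer than chromosome errors
  expect_error(permute_null(roh_segments("a", "c", 0, 2e5), lay1, sm,
                            n_perm = 5, seed = 1), "longer than")
})

test_that("null max distribution matches exhaustive placement enumeration", {
  # 2 individuals, one 10 bp segment each, 100 bp chromosome, SNP at every bp:
  # max = 1 iff the two placements share a covered SNP, else 0.5
  lay <- genome_layout("c", 100, list(c = 1:100))
  seg <- roh_segments(c("a", "b"), "c", c(0, 0), c(10, 10))
  sm <- data.frame(sample_id = c("a", "b"), group_id = "all")
  starts <- 0:90
  p_overlap <- mean(outer(starts, starts,
                          function(s1, s2) abs(s1 - s2) < 10))
  nul <- permute_null(seg, lay, sm, n_perm = 4000, seed = 5)
  expect_true(all(nul$max_freq %in% c(0.5, 1)))
  got <- mean(nul$max_freq == 1)
  se <- sqrt(p_overlap * (1 - p_overlap) / 4000)
  expect_lt(abs(got - p_overlap), 4 * se)
})

test_that("hotspot calling applies threshold, empirical P and merging rules", {
  # known null: maxima 0.01..1.00 -> 99th percentile threshold = 0.99
  nul <- fake_null((1:100) / 100)
  obs <- fake_track(c(0.995, 1, 0.5, 1), pos = c(100, 200, 5e6, 5000100))
  hr <- call_hotspots(obs, nul)
  expect_equal(hr$threshold_freq, 0.99)
  # 0.995 and 1 exceed; 0.5 does not; non-adjacent SNPs give 2 hotspots
  expect_equal(nrow(hr$hotspots), 2L)
  expect_equal(hr$hotspots$start, c(100, 5000100))
  expect_equal(hr$hotspots$end, c(201, 5000101))
  # empirical P: (1 + #{max >= f}) / (n_perm + 1)
  expect_equal(hr$snp_table$p_value[2], (1 + 1) / 101)   # f = 1
  expect_equal(hr$snp_table$p_value[3], (1 + 51) / 101)  # f = 0.5
  # gap bridging merges significant SNPs across the distance when allowed
  hr2 <- call_hotspots(obs, nul, merge_gap_bp = 1e7)
  expect_equal(nrow(hr2$hotspots), 1L)
  # index-adjacent significant SNPs merge regardless of bp distance
  obs3 <- fake_track(c(1, 1), pos = c(100, 5000))
  expect_equal(nrow(call_hotspots(obs3, nul)$hotspots), 1L)
  # an intervening insignificant SNP splits them unless bridged
  obs4 <- fake_track(c(1, 0.5, 1), pos = c(100, 2500, 5000))
  expect_equal(nrow(call_hotspots(obs4, nul)$hotspots), 2L)
  expect_equal(nrow(call_hotspots(obs4, nul, merge_gap_bp = 1e4)$hotspots), 1L)
  # degenerate no-freedom case: threshold 1, strict inequality, no calls
  hr4 <- call_hotspots(fake_track(1), fake_null(rep(1, 100)))
  expect_equal(hr4$threshold_freq, 1)
  expect_equal(nrow(hr4$hotspots), 0L)
  # threshold monotone in 1 - alpha
  t_strict <- call_hotspots(obs, nul, alpha = 0.01)$threshold_freq
  t_loose <- call_hotspots(obs, nul, alpha = 0.10)$threshold_freq
  expect_gte(t_strict, t_loose)
  expect_error(call_hotspots(obs, nul, alpha = 0), "alpha")
})

test_that("region overlap frequency respects half-open convention", {
  samples <- data.frame(sample_id = c("a", "b"), group_id = "all")
  seg <- roh_segments("a", "chr1", 1000, 2000)
  regions <- data.frame(chrom = "chr1",
                        start = c(1200, 2000, 500),
                        end = c(1300, 2500, 1000))
  tab <- region_overlap_frequency(seg, samples, regions)
  expect_equal(tab$freq, c(0.5, 0, 0))  # inside; touch at end; touch at start
  expect_equal(nrow(region_overlap_frequency(seg, samples,
                                             regions[0, , drop = FALSE])), 0L)
  expect_error(region_overlap_frequency(seg, samples,
                                        data.frame(chrom = "c", start = 10, end = 1)),
               "malformed")
})

test_that("hotspot threshold falls as group size grows", {
  lay <- uniform_layout(1, 2e7, 1000, "even")
  set.seed(17)
  thresholds <- vapply(c(5, 10, 25, 50), function(n) {
    ds <- simulate_null_segments(lay, n, 10, median_kb = 500, log_sd = 0.4)
    permute_null(ds$segments, lay, ds$samples, n_perm = 300,
                 seed = 100 + n) -> nul
    sort(nul$max_freq)[ceiling(0.99 * 300)]
  }, numeric(1))
  expect_lt(spearman_cor(c(5, 10, 25, 50), thresholds)$rho, 0)
  expect_true(all(diff(thresholds) <= 0))
})
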