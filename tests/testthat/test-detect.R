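make_gt <- function(calls, pos, chrom_len = max(pos) + 1, ids = NULL) {
  calls <- if (is.matrix(calls)) calls else matrix(calls, nrow = 1)
  lay <- genome_layout("chr1", chrom_len, list(chr1 = pos + 1))  # pos internal
  genotype_matrix(calls, lay,
                  ids %||% sprintf("s%02d", seq_len(nrow(calls))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a clean homozygous stretch yields one maximal segment", {
  pos <- seq(0, by = 10000, length.out = 60)
  gt <- make_gt(rep(2L, 60), pos)
  seg <- detect_roh(gt)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 60L)
  expect_equal(seg$length_bp, 590001)  # first to last SNP + 1
  expect_equal(seg$start, 0)
  expect_equal(seg$end, 590001)
})

test_that("a large gap splits runs and each side fails min_snps", {
  pos <- c(seq(0, by = 10000, length.out = 30),
           seq(0, by = 10000, length.out = 30) + 29 * 10000 + 1.2e6)
  gt <- make_gt(rep(0L, 60), pos)
  expect_equal(nrow(detect_roh(gt)), 0L)
  # relaxing min_snps recovers both sides
  seg <- detect_roh(gt, roh_params(min_snps = 20, min_length_bp = 250000))
  expect_equal(nrow(seg), 2L)
  expect_true(all(seg$n_snps == 30))
})

test_that("het and missing allowances bound every reported segment", {
  set.seed(31)
  for (rep in 1:20) {
    m <- sample(60:150, 1)
    pos <- sort(sample.int(m * 12000, m)) - 1
    calls <- sample(c(0L, 1L, 2L, NA), m, TRUE, prob = c(0.45, 0.07, 0.45, 0.03))
    p <- roh_params(min_snps = sample(5:20, 1),
                    min_length_bp = sample(c(5e4, 2e5), 1),
                    max_het = sample(0:3, 1), max_missing = sample(0:3, 1))
    seg <- detect_roh(make_gt(calls, pos), p)
    if (!nrow(seg)) next
    for (k in seq_len(nrow(seg))) {
      idx <- which(pos >= seg$start[k] & pos < seg$end[k])
      expect_gte(length(idx), p$min_snps)
      expect_lte(sum(calls[idx] == 1L, na.rm = TRUE), p$max_het)
      expect_lte(sum(is.na(calls[idx])), p$max_missing)
      expect_gte(seg$length_bp[k], p$min_length_bp)
      expect_true(all(diff(pos[idx]) < p$max_gap_bp))
      expect_lte((seg$length_bp[k] / 1000) / seg$n_snps[k],
                 p$max_density_kb_per_snp)
    }
    # disjoint within an individual
    if (nrow(seg) > 1) {
      s <- seg[order(seg$start), ]
      expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
    }
  }
})

test_that("exact mode equals brute-force enumeration on random instances", {
  set.seed(77)
  for (rep in 1:40) {
    m <- sample(20:120, 1)
    pos <- sort(sample.int(m * 15000, m)) - 1
    calls <- sample(c(0L, 1L, 2L, NA), m, TRUE,
                    prob = c(0.4, runif(1, 0.02, 0.15), 0.4, 0.05))
    p <- roh_params(min_snps = sample(3:15, 1),
                    min_length_bp = sample(c(2e4, 1e5, 3e5), 1),
                    max_gap_bp = sample(c(1e5, 1e6), 1),
                    max_het = sample(0:4, 1), max_missing = sample(0:4, 1),
                    max_density_kb_per_snp = sample(c(10, 50), 1))
    got <- detect_roh(make_gt(calls, pos), p)
    want <- brute_detect(calls, pos, p)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("relaxing one constraint never shrinks covered bp", {
  set.seed(19)
  m <- 200
  pos <- sort(sample.int(2.4e6, m)) - 1
  calls <- sample(c(0L, 1L, 2L, NA), m, TRUE, prob = c(0.44, 0.07, 0.44, 0.05))
  gt <- make_gt(calls, pos)
  covered <- function(p) sum(detect_roh(gt, p)$length_bp)
  base <- roh_params(min_snps = 10, min_length_bp = 1e5, max_het = 1,
                     max_missing = 1)
  expect_lte(covered(roh_params(min_snps = 10, min_length_bp = 2e5,
                                max_het = 1, max_missing = 1)), covered(base))
  expect_gte(covered(roh_params(min_snps = 10, min_length_bp = 1e5,
                                max_het = 3, max_missing = 1)), covered(base))
  expect_gte(covered(roh_params(min_snps = 10, min_length_bp = 1e5,
                                max_het = 1, max_missing = 4)), covered(base))
  expect_gte(covered(roh_params(min_snps = 5, min_length_bp = 1e5,
                                max_het = 1, max_missing = 1)), covered(base))
})

test_that("window mode recovers clean planted tracts like exact mode", {
  cfg <- sim_config(seed = 21, n_individuals = c(all = 4), n_chrom = 1,
                    chrom_length_bp = 1e7, mean_spacing_bp = 1000,
                    tracts = list(short = NULL, medium = NULL,
                                  long = list(mean_count = 2, median_kb = 2000,
                                              log_sd = 0.2)))
  sim <- simulate_panel(cfg)
  exact <- detect_roh(sim$genotypes, roh_params(mode = "exact"))
  win <- detect_roh(sim$genotypes, roh_params(mode = "window"))
  # same tracts found: every exact segment overlaps a window-mode segment
  for (k in seq_len(nrow(exact))) {
    hit <- win$sample_id == exact$sample_id[k] &
      win$start < exact$end[k] & win$end > exact$start[k]
    expect_true(any(hit))
  }
  expect_equal(nrow(win), nrow(exact))
})

test_that("sensitivity grid reports monotone counts and burden summaries add up", {
  cfg <- sim_config(seed = 5, n_individuals = c(all = 6), n_chrom = 1,
                    chrom_length_bp = 5e6, mean_spacing_bp = 1000)
  sim <- simulate_panel(cfg)
  grid <- sensitivity_grid(sim$genotypes, roh_params(),
                           "min_length_bp", c(1e5, 5e5, 1e6))
  expect_equal(nrow(grid), 3L)
  expect_true(all(diff(grid$n_segments) <= 0))
  grid2 <- sensitivity_grid(sim$genotypes, roh_params(), "max_het", c(0, 3, 5))
  expect_true(all(diff(grid2$n_segments) >= 0))
  expect_error(sensitivity_grid(sim$genotypes, roh_params(), "nope", 1),
               "unknown parameter")

  seg <- roh_segments(c("a", "a", "b"), "chr1",
                      c(0, 1e6, 0), c(6e5, 1.4e6, 2e6),
                      class = c("short", "medium", "long"))
  samples <- data.frame(sample_id = c("a", "b", "c"), group_id = c("g", "g", "h"))
  burden <- summarize_burden(seg, samples)
  expect_equal(burden$per_individual$n_roh, c(2L, 1L, 0L))
  expect_equal(burden$per_individual$total_bp, c(1e6, 2e6, 0))
  expect_equal(burden$per_individual$bp_short, c(6e5, 0, 0))
  expect_equal(burden$per_group$mean_total_bp, c(1.5e6, 0))
})
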