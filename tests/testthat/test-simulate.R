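test_that("no tracts and no error means zero autozygosity", {
  cfg <- sim_config(seed = 3, n_individuals = c(all = 4), n_chrom = 1,
                    chrom_length_bp = 1e6, mean_spacing_bp = 2000,
                    tracts = list(short = NULL, medium = NULL, long = NULL))
  sim <- simulate_panel(cfg)
  expect_true(all(sim$truth$fractions$fraction == 0))
  expect_equal(nrow(sim$truth$tracts), 0L)
})

test_that("realized fractions are tract-union over genome length", {
  # one tract covering a full 10 Mb chromosome of a 100 Mb genome -> 0.1
  cfg <- sim_config(seed = 8, n_individuals = c(all = 1), n_chrom = 10,
                    chrom_length_bp = 1e7, mean_spacing_bp = 10000,
                    tracts = list(short = NULL, medium = NULL, long = NULL))
  sim <- simulate_panel(cfg)
  tr <- data.frame(sample_id = sim$genotypes$samples$sample_id,
                   chrom = "chr1", start = 0, end = 1e7, class = "long",
                   stringsAsFactors = FALSE)
  frac <- rohscan:::union_length(tr) / genome_size(sim$genotypes$layout)
  expect_equal(frac, 0.1)
  # realized fractions in truth match an independent union computation
  cfg2 <- sim_config(seed = 9, n_individuals = c(all = 5), n_chrom = 2,
                     chrom_length_bp = 5e6, mean_spacing_bp = 5000)
  sim2 <- simulate_panel(cfg2)
  for (sid in sim2$genotypes$samples$sample_id) {
    own <- sim2$truth$tracts[sim2$truth$tracts$sample_id == sid, ]
    merged <- 0
    for (ch in unique(own$chrom)) {
      iv <- own[own$chrom == ch, c("start", "end")]
      iv <- iv[order(iv$start), ]
      cov <- 0; cur_s <- -1; cur_e <- -1
      for (k in seq_len(nrow(iv))) {
        if (iv$start[k] > cur_e) {
          cov <- cov + max(0, cur_e - cur_s); cur_s <- iv$start[k]; cur_e <- iv$end[k]
        } else cur_e <- max(cur_e, iv$end[k])
      }
      merged <- merged + cov + max(0, cur_e - cur_s)
    }
    expect_equal(sim2$truth$fractions$fraction[
      sim2$truth$fractions$sample_id == sid],
      merged / genome_size(sim2$genotypes$layout), tolerance = 1e-12)
  }
})

test_that("background genotypes follow HWE at the configured frequency", {
  cfg <- sim_config(seed = 12, n_individuals = c(all = 10), n_chrom = 1,
                    chrom_length_bp = 1e6, mean_spacing_bp = 1000,
                    freq_range = c(0.5, 0.5),
                    tracts = list(short = NULL, medium = NULL, long = NULL))
  sim <- simulate_panel(cfg)
  het_prop <- mean(sim$genotypes$calls == 1L)
  n_calls <- length(sim$genotypes$calls)
  expect_lt(abs(het_prop - 0.5), 4 * sqrt(0.25 / n_calls))
})

test_that("planted tracts are perfectly homozygous without het error", {
  cfg <- sim_config(seed = 19, n_individuals = c(all = 6), n_chrom = 2,
                    chrom_length_bp = 5e6, mean_spacing_bp = 1000,
                    het_error_rate = 0, missing_rate = 0.02)
  sim <- simulate_panel(cfg)
  lay <- sim$genotypes$layout
  tr <- sim$truth$tracts
  for (k in seq_len(nrow(tr))) {
    cols <- rohscan:::chrom_col_index(lay, tr$chrom[k])
    pos <- lay$positions[[tr$chrom[k]]]
    inside <- cols[pos >= tr$start[k] & pos < tr$end[k]]
    row <- match(tr$sample_id[k], sim$genotypes$samples$sample_id)
    vals <- sim$genotypes$calls[row, inside]
    expect_false(any(vals == 1L, na.rm = TRUE))
  }
  # het error rate plants isolated hets inside tracts
  cfg2 <- sim_config(seed = 19, n_individuals = c(all = 6), n_chrom = 2,
                     chrom_length_bp = 5e6, mean_spacing_bp = 1000,
                     het_error_rate = 0.05)
  sim2 <- simulate_panel(cfg2)
  tr2 <- sim2$truth$tracts
  n_het_inside <- 0
  for (k in seq_len(nrow(tr2))) {
    cols <- rohscan:::chrom_col_index(lay, tr2$chrom[k])
    pos <- sim2$genotypes$layout$positions[[tr2$chrom[k]]]
    inside <- cols[pos >= tr2$start[k] & pos < tr2$end[k]]
    row <- match(tr2$sample_id[k], sim2$genotypes$samples$sample_id)
    n_het_inside <- n_het_inside +
      sum(sim2$genotypes$calls[row, inside] == 1L, na.rm = TRUE)
  }
  expect_gt(n_het_inside, 0)
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  cfg <- sim_config(seed = 33, n_individuals = c(a = 3), n_chrom = 1,
                    chrom_length_bp = 1e6, mean_spacing_bp = 2000)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  expect_identical(s1$truth$tracts, s2$truth$tracts)
  cfg2 <- cfg; cfg2$seed <- 34L
  s3 <- simulate_panel(cfg2)
  expect_false(identical(s1$genotypes$calls, s3$genotypes$calls))
})

test_that("tract length law medians match configuration within 5%", {
  lay <- uniform_layout(1, 5e7, 100, "even")
  set.seed(2)
  ds <- simulate_null_segments(lay, 250, 20, median_kb = 800, log_sd = 0.5)
  expect_equal(nrow(ds$segments), 5000L)
  expect_lt(abs(median(ds$segments$length_bp) / 1000 - 800) / 800, 0.05)
})

test_that("hotspot carriers always cover the island interval", {
  hs <- data.frame(chrom = "chr1", start = 2e6, end = 2.5e6,
                   carrier_fraction = 0.8)
  cfg <- sim_config(seed = 44, n_individuals = c(all = 10), n_chrom = 2,
                    chrom_length_bp = 5e6, mean_spacing_bp = 2000,
                    hotspots = hs)
  sim <- simulate_panel(cfg)
  expect_equal(sim$truth$hotspots$n_carriers, 8L)
  carriers <- attr(sim$truth$hotspots, "carriers")[[1]]
  expect_length(carriers, 8L)
  for (sid in carriers) {
    own <- sim$truth$tracts[sim$truth$tracts$sample_id == sid, ]
    expect_true(any(own$chrom == "chr1" & own$start <= 2e6 & own$end >= 2.5e6))
  }
  expect_error(simulate_panel(sim_config(
    seed = 1, n_individuals = c(all = 2), n_chrom = 1, chrom_length_bp = 1e6,
    mean_spacing_bp = 2000,
    hotspots = data.frame(chrom = "chr1", start = 0, end = 2e6,
                          carrier_fraction = 1))), "longer than")
})

test_that("covariate-linked frequencies follow the logistic link", {
  covariates <- list(
    table = data.frame(group_id = c("a", "b", "c"), bio1 = c(-10, 10, 25)),
    linked_snps = data.frame(chrom = "chr1", snp_index = 5, covariate = "bio1",
                             a = 0, b = 0.15))
  cfg <- sim_config(seed = 50, n_individuals = c(a = 40, b = 40, c = 40),
                    n_chrom = 1, chrom_length_bp = 1e6, mean_spacing_bp = 2000,
                    tracts = list(short = NULL, medium = NULL, long = NULL),
                    covariates = covariates)
  sim <- simulate_panel(cfg)
  lf <- sim$truth$linked_freq
  expect_equal(lf$p, plogis(0.15 * c(-10, 10, 25)))
  # empirical frequencies track the planted ones
  col <- 5
  for (g in c("a", "b", "c")) {
    rows <- sim$genotypes$samples$group_id == g
    p_hat <- mean(sim$genotypes$calls[rows, col]) / 2
    expect_lt(abs(p_hat - lf$p[lf$group_id == g]), 0.2)
  }
})

test_that("inbreeding gradient reaches its targets", {
  targets <- seq(0, 0.4, length.out = 8)
  cfg <- sim_config(seed = 60, n_individuals = c(all = 8), n_chrom = 2,
                    chrom_length_bp = 1e7, mean_spacing_bp = 5000,
                    tracts = list(short = NULL, medium = NULL, long = NULL),
                    target_fraction = targets)
  sim <- simulate_panel(cfg)
  got <- sim$truth$fractions$fraction
  expect_true(all(got >= targets))
  expect_gt(spearman_cor(targets, got)$rho, 0.9)
})

test_that("truth tables round-trip through TSV", {
  cfg <- sim_config(seed = 70, n_individuals = c(all = 3), n_chrom = 1,
                    chrom_length_bp = 2e6, mean_spacing_bp = 2000)
  sim <- simulate_panel(cfg)
  dir <- withr::local_tempdir()
  paths <- truth_report(sim$truth, dir)
  back <- read.table(paths[["tracts"]], header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  expect_equal(back$start, sim$truth$tracts$start)
  expect_equal(back$end, sim$truth$tracts$end)
  # empty truth still writes headered files
  empty <- structure(list(
    tracts = sim$truth$tracts[0, ], hotspots = NULL,
    fractions = sim$truth$fractions[0, ], linked_freq = NULL),
    class = "sim_truth")
  dir2 <- withr::local_tempdir()
  paths2 <- truth_report(empty, dir2)
  for (p in paths2) {
    lines <- readLines(p)
    expect_length(lines, 1L)  # header only
  }
})
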