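# Independent reference implementations used as oracles. These deliberately
# re-derive results by direct enumeration / direct formula evaluation and
# share no code with the package internals they check.

# Brute-force ROH detection: enumerate every SNP-index interval, keep those
# satisfying all constraints, keep the ones not extensible in either
# direction, then resolve overlaps greedily (earliest start, then longest).
# calls: vector of 0/1/2/NA; pos: internal 0-based positions; p: roh_params.
brute_detect <- function(calls, pos, p) {
  m <- length(calls)
  # Q[i, j]: does interval [i..j] satisfy every constraint? Built by direct
  # enumeration over all m^2 intervals via per-start cumulative sums.
  Q <- matrix(FALSE, m, m)
  het <- cumsum(c(0, calls == 1L & !is.na(calls)))
  mis <- cumsum(c(0, is.na(calls)))
  gaps <- c(diff(pos), Inf)
  for (i in seq_len(m)) {
    j <- i:m
    n <- j - i + 1
    len <- pos[j] - pos[i] + 1
    hc <- het[j + 1] - het[i]
    mc <- mis[j + 1] - mis[i]
    gap_ok <- c(TRUE, cummax(gaps[i:(m - 1)])[seq_len(m - i)] < p$max_gap_bp)
    if (i == m) gap_ok <- TRUE
    Q[i, j] <- n >= p$min_snps & len >= p$min_length_bp &
      hc <= p$max_het & mc <= p$max_missing & gap_ok &
      (len / 1000) / n <= p$max_density_kb_per_snp
  }
  qual <- which(Q, arr.ind = TRUE)
  qual <- qual[qual[, 1] <= qual[, 2], , drop = FALSE]
  keep_max <- vapply(seq_len(nrow(qual)), function(k) {
    i <- qual[k, 1]; j <- qual[k, 2]
    left_ok <- i > 1 && Q[i - 1, j]
    right_ok <- j < m && Q[i, j + 1]
    !left_ok && !right_ok
  }, logical(1))
  q <- qual[keep_max, , drop = FALSE]
  if (!nrow(q)) return(data.frame(start = numeric(0), end = numeric(0)))
  q <- q[order(q[, 1], -(q[, 2] - q[, 1])), , drop = FALSE]
  keep <- list()
  cur_end <- 0
  for (k in seq_len(nrow(q))) {
    if (q[k, 1] > cur_end) {
      keep[[length(keep) + 1]] <- q[k, ]
      cur_end <- q[k, 2]
    }
  }
  q <- do.call(rbind, keep)
  data.frame(start = pos[q[, 1]], end = pos[q[, 2]] + 1)
}

# Nucleotide diversity by explicit pairwise allele comparison: at every
# site, count mismatching pairs among the 2n non-missing alleles.
pi_pairwise_oracle <- function(calls_matrix) {
  vapply(seq_len(ncol(calls_matrix)), function(j) {
    g <- calls_matrix[, j]
    g <- g[!is.na(g)]
    alleles <- unlist(lapply(g, function(x) switch(as.character(x),
                                                   `0` = c(0, 0),
                                                   `1` = c(0, 1),
                                                   `2` = c(1, 1))))
    n <- length(alleles)
    if (n < 2) return(0)
    diffs <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n)
      diffs <- diffs + (alleles[a] != alleles[b])
    diffs / (n * (n - 1) / 2)
  }, numeric(1))
}

# Direct re-evaluation of the homozygosity-excess estimator for one
# individual, looping over sites.
f_hom_oracle <- function(calls_matrix, row) {
  num <- 0; e_hom <- 0; m <- 0
  for (j in seq_len(ncol(calls_matrix))) {
    col <- calls_matrix[, j]
    n_al <- 2 * sum(!is.na(col))
    if (n_al < 2) next
    x <- calls_matrix[row, j]
    if (is.na(x)) next
    p <- sum(col, na.rm = TRUE) / n_al
    e_hom <- e_hom + (1 - 2 * p * (1 - p) * n_al / (n_al - 1))
    num <- num + (x != 1)
    m <- m + 1
  }
  (num - e_hom) / (m - e_hom)
}

# Direct re-evaluation of the GRM-diagonal and uniting-gametes estimators.
f_grm_uni_oracle <- function(calls_matrix, row) {
  grm <- c(); uni <- c()
  for (j in seq_len(ncol(calls_matrix))) {
    col <- calls_matrix[, j]
    n_al <- 2 * sum(!is.na(col))
    if (n_al < 2) next
    p <- sum(col, na.rm = TRUE) / n_al
    if (p <= 0 || p >= 1) next
    x <- calls_matrix[row, j]
    if (is.na(x)) next
    h <- 2 * p * (1 - p)
    grm <- c(grm, (x - 2 * p)^2 / h - 1)
    uni <- c(uni, (x^2 - (1 + 2 * p) * x + 2 * p^2) / h)
  }
  c(f_grm = mean(grm), f_uni = mean(uni))
}

# Small random genotype panel on a fresh layout (single chromosome).
random_panel <- function(n_ind, n_snp, chrom_len = n_snp * 1000,
                         miss_rate = 0.05, groups = "all") {
  pos <- sort(sample.int(chrom_len, n_snp))
  lay <- genome_layout("chr1", chrom_len, list(chr1 = pos))
  p <- runif(n_snp, 0.1, 0.9)
  calls <- vapply(p, function(pp)
    sample(0:2, n_ind, TRUE, c((1 - pp)^2, 2 * pp * (1 - pp), pp^2)),
    integer(n_ind))
  calls <- matrix(as.integer(calls), n_ind, n_snp)
  calls[matrix(runif(n_ind * n_snp) < miss_rate, n_ind, n_snp)] <- NA_integer_
  genotype_matrix(calls, lay, sprintf("s%02d", seq_len(n_ind)),
                  rep_len(groups, n_ind))
}

# Hand-built coverage_track / null objects for unit-testing the caller.
fake_track <- function(freq, pos = seq_along(freq) * 100, chrom = "chr1", n = 10) {
  structure(list(group_id = "all", n = n,
                 snps = data.frame(chrom = chrom, pos = pos,
                                   count = round(freq * n), freq = freq,
                                   stringsAsFactors = FALSE)),
            class = "coverage_track")
}
fake_null <- function(max_freq, seed = 1) {
  structure(list(group_id = "all", n_perm = length(max_freq),
                 max_freq = max_freq, seed = seed),
            class = "null_max_distribution")
}
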