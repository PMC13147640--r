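#' ROH-based inbreeding coefficient F_ROH
#'
#' `F_ROH` is the total length of an individual's ROH divided by the total
#' autosome length of the layout. With `per_class = TRUE` the numerator is
#' additionally restricted to each length class.
#'
#' @param segments segment data.frame; an individual's segments must be
#'   disjoint (as produced by [detect_roh()]).
#' @param layout a [genome_layout()] supplying the denominator.
#' @param samples optional data.frame (`sample_id`, ...) listing the full
#'   panel so ROH-free individuals appear with `F_ROH = 0`; defaults to the
#'   individuals present in `segments`.
#' @param per_class also return `f_roh_short`/`f_roh_medium`/`f_roh_long`
#'   (requires classified segments).
#' @return data.frame with `sample_id`, `f_roh` (+ per-class columns).
#' @export
f_roh <- function(segments, layout, samples = NULL, per_class = FALSE) {
  total <- genome_size(layout)
  ids <- if (!is.null(samples)) samples$sample_id else unique(segments$sample_id)
  # disjointness check per individual/chromosome
  if (nrow(segments)) {
    key <- paste(segments$sample_id, segments$chrom)
    for (k in unique(key)) {
      s <- segments[key == k, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
        stop("overlapping segments for one individual on ", k)
    }
  }
  f <- factor(segments$sample_id, levels = ids)
  sum0 <- function(x, fac) {
    out <- tapply(x, fac, sum)
    out[is.na(out)] <- 0
    as.numeric(out)
  }
  res <- data.frame(sample_id = ids,
                    f_roh = sum0(segments$length_bp, f) / total,
                    stringsAsFactors = FALSE)
  if (per_class) {
    for (cl in c("short", "medium", "long")) {
      sel <- !is.na(segments$class) & segments$class == cl
      fc <- factor(segments$sample_id[sel], levels = ids)
      res[[paste0("f_roh_", cl)]] <-
        sum0(segments$length_bp[sel], fc) / total
    }
  }
  res
}

#' Excess-homozygosity inbreeding coefficient F_HOM
#'
#' Method-of-moments estimator over each individual's non-missing sites:
#' `F_HOM = (O_hom - E_hom) / (m - E_hom)`, where `m` is the site count and
#' `E_hom = sum_i (1 - 2 p_i (1 - p_i) n_i / (n_i - 1))` uses the
#' sample-size-corrected expected heterozygosity with `n_i` the non-missing
#' allele count at site i. Allele frequencies come from the panel itself;
#' sites with fewer than 2 non-missing alleles are excluded.
#'
#' @param genotypes a [genotype_matrix()].
#' @return data.frame with `sample_id`, `f_hom` (`NA` with a warning for
#'   individuals where the denominator vanishes), `n_sites`.
#' @export
f_hom <- function(genotypes) {
  af <- allele_freq(genotypes)
  use <- af$n_alleles >= 2
  p <- af$p[use]
  corr <- af$n_alleles[use] / (af$n_alleles[use] - 1)
  ehet_site <- 2 * p * (1 - p) * corr
  g <- genotypes$calls[, use, drop = FALSE]
  obs <- !is.na(g)
  m <- rowSums(obs)
  o_hom <- rowSums(g != 1L, na.rm = TRUE)
  e_hom <- as.numeric(obs %*% (1 - ehet_site))
  denom <- m - e_hom
  fh <- ifelse(abs(denom) < 1e-12, NA_real_, (o_hom - e_hom) / denom)
  if (anyNA(fh)) warning("F_HOM undefined for ", sum(is.na(fh)), " individual(s)")
  data.frame(sample_id = genotypes$samples$sample_id, f_hom = fh,
             n_sites = m, stringsAsFactors = FALSE)
}

#' GRM-diagonal and uniting-gametes inbreeding coefficients
#'
#' With genotype `x` in `{0, 1, 2}` and panel allele frequency `p_i`,
#' `F_GRM = mean_i[ (x - 2 p_i)^2 / (2 p_i (1 - p_i)) - 1 ]` (the
#' variance-standardized genomic-relationship diagonal minus one) and
#' `F_UNI = mean_i[ (x^2 - (1 + 2 p_i) x + 2 p_i^2) / (2 p_i (1 - p_i)) ]`
#' (the correlation of uniting gametes). Means are over each individual's
#' non-missing sites; sites monomorphic in the panel are excluded.
#'
#' @param genotypes a [genotype_matrix()].
#' @return data.frame with `sample_id`, `f_grm`, `f_uni`, `n_sites`.
#' @export
f_grm_uni <- function(genotypes) {
  af <- allele_freq(genotypes)
  use <- af$n_alleles >= 2 & af$p > 0 & af$p < 1
  if (!any(use)) {
    warning("no polymorphic sites; F_GRM/F_UNI undefined")
    return(data.frame(sample_id = genotypes$samples$sample_id,
                      f_grm = NA_real_, f_uni = NA_real_, n_sites = 0L))
  }
  p <- af$p[use]
  het <- 2 * p * (1 - p)
  g <- genotypes$calls[, use, drop = FALSE]
  obs <- !is.na(g)
  m <- rowSums(obs)
  x <- g; x[!obs] <- 0L
  # F_GRM: (x - 2p)^2 / het - 1, summed over observed sites
  t_grm <- sweep(x, 2, 2 * p)^2
  t_grm <- sweep(t_grm, 2, het, "/")
  t_grm[!obs] <- 0
  f_grm <- (rowSums(t_grm) - m) / m
  # F_UNI: (x^2 - (1 + 2p) x + 2 p^2) / het
  t_uni <- x^2 - sweep(x, 2, 1 + 2 * p, "*")
  t_uni <- sweep(t_uni, 2, 2 * p^2, "+")
  t_uni <- sweep(t_uni, 2, het, "/")
  t_uni[!obs] <- 0
  f_uni <- rowSums(t_uni) / m
  bad <- m == 0
  if (any(bad)) {
    warning("no included sites for ", sum(bad), " individual(s)")
    f_grm[bad] <- NA_real_; f_uni[bad] <- NA_real_
  }
  data.frame(sample_id = genotypes$samples$sample_id, f_grm = f_grm,
             f_uni = f_uni, n_sites = m, stringsAsFactors = FALSE)
}

#' Observed and expected heterozygosity
#'
#' `Ho` is each individual's heterozygous-call proportion over its
#' non-missing sites. `He` per group is the mean over SNPs of
#' `2 p (1 - p)` with `p` estimated from that group's non-missing alleles
#' (monomorphic sites contribute 0).
#'
#' @param genotypes a [genotype_matrix()].
#' @return list with `per_individual` (`sample_id`, `group_id`, `ho`,
#'   `n_nonmissing`) and `per_group` (`group_id`, `he`, `mean_ho`).
#' @export
heterozygosity <- function(genotypes) {
  g <- genotypes$calls
  nm <- rowSums(!is.na(g))
  ho <- rowSums(g == 1L, na.rm = TRUE) / pmax(nm, 1)
  ho[nm == 0] <- NA_real_
  per <- data.frame(sample_id = genotypes$samples$sample_id,
                    group_id = genotypes$samples$group_id,
                    ho = ho, n_nonmissing = nm, stringsAsFactors = FALSE)
  groups <- unique(genotypes$samples$group_id)
  he <- vapply(groups, function(grp) {
    af <- allele_freq(genotypes, rows = genotypes$samples$group_id == grp)
    p <- af$p[af$n_alleles > 0]
    if (!length(p)) return(NA_real_)
    mean(2 * p * (1 - p))
  }, numeric(1))
  grp <- data.frame(group_id = groups, he = he,
                    mean_ho = as.numeric(tapply(per$ho, factor(per$group_id,
                                                levels = groups), mean,
                                                na.rm = TRUE)),
                    stringsAsFactors = FALSE)
  list(per_individual = per, per_group = grp)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rho is the Pearson correlation of average ranks (ties averaged) over
#' pairwise-complete observations; the two-sided p-value uses the
#' t-approximation with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @param labels optional length-2 character vector naming the pair.
#' @return data.frame with `var_x`, `var_y`, `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y, labels = c(deparse(substitute(x)),
                                          deparse(substitute(y)))) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero variance in ranks; rho undefined")
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  data.frame(var_x = labels[1], var_y = labels[2], rho = rho, p_value = p,
             n = n, stringsAsFactors = FALSE)
}

#' Pairwise Spearman correlation matrix of inbreeding metrics
#'
#' @param df data.frame of per-individual metrics (e.g. joined outputs of
#'   [f_roh()], [f_hom()], [f_grm_uni()], [heterozygosity()]).
#' @param vars columns to correlate.
#' @return long-format data.frame of all pairs (see [spearman_cor()]).
#' @export
correlation_table <- function(df, vars) {
  stopifnot(all(vars %in% names(df)))
  pairs <- utils::combn(vars, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    spearman_cor(df[[pairs[1, k]]], df[[pairs[2, k]]],
                 labels = pairs[, k])
  }))
}
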