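#' Sliding windows over a genome layout
#'
#' Per chromosome, windows `[k*step, k*step + size)` for k = 0, 1, ... while
#' the start lies inside the chromosome; the final window is truncated at
#' the chromosome end.
#'
#' @param layout a [genome_layout()].
#' @param size_bp window size (default 50 kb).
#' @param step_bp step (default 20 kb); must not exceed `size_bp`.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open).
#' @export
make_windows <- function(layout, size_bp = 50000, step_bp = 20000) {
  if (size_bp <= 0 || step_bp <= 0) stop("size and step must be positive")
  if (step_bp > size_bp) stop("step must be <= size")
  out <- lapply(seq_len(nrow(layout$chromosomes)), function(k) {
    L <- layout$chromosomes$length_bp[k]
    starts <- seq(0, L - 1, by = step_bp)
    data.frame(chrom = layout$chromosomes$chrom[k], start = starts,
               end = pmin(starts + size_bp, L), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize a per-site selection statistic in windows
#'
#' Sites are assigned to every window containing them. Aggregation by
#' statistic: `prop_ihs` = fraction of sites with `|value| >=
#' ihs_abs_threshold` (windows with fewer than `min_snps` sites are
#' dropped, as in the usual |iHS| workflow); `max_clr` = window maximum;
#' `xpehh_mean`/`fst_mean`/`custom` = window mean.
#'
#' @param per_site data.frame `chrom`, `pos` (1-based bp), `value`, sorted
#'   by chrom then pos.
#' @param windows window table from [make_windows()].
#' @param statistic one of `"prop_ihs"`, `"max_clr"`, `"xpehh_mean"`,
#'   `"fst_mean"`, `"custom"`.
#' @param min_snps minimum sites per window (`prop_ihs` only).
#' @param ihs_abs_threshold |iHS| cut-off defining a swept site.
#' @return data.frame `chrom`, `start`, `end`, `statistic`, `value`,
#'   `n_snps`.
#' @export
window_summarize <- function(per_site, windows, statistic,
                             min_snps = 10L, ihs_abs_threshold = 2) {
  stats_known <- c("prop_ihs", "max_clr", "xpehh_mean", "fst_mean", "custom")
  if (!statistic %in% stats_known) stop("unknown statistic: ", statistic)
  if (!all(c("chrom", "pos", "value") %in% names(per_site)))
    stop("per_site must have chrom/pos/value")
  o <- order(match(per_site$chrom, unique(per_site$chrom)), per_site$pos)
  if (any(o != seq_len(nrow(per_site)))) stop("per-site table not sorted")
  rows <- lapply(seq_len(nrow(windows)), function(k) {
    sel <- per_site$chrom == windows$chrom[k] &
      per_site$pos - 1 >= windows$start[k] & per_site$pos - 1 < windows$end[k]
    v <- per_site$value[sel]
    n <- length(v)
    if (statistic == "prop_ihs" && n < min_snps) return(NULL)
    val <- switch(statistic,
                  prop_ihs = if (n) mean(abs(v) >= ihs_abs_threshold) else NA_real_,
                  max_clr = if (n) max(v) else NA_real_,
                  if (n) mean(v) else NA_real_)
    data.frame(chrom = windows$chrom[k], start = windows$start[k],
               end = windows$end[k], statistic = statistic, value = val,
               n_snps = n, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), statistic = character(0),
                      value = numeric(0), n_snps = integer(0)))
  do.call(rbind, rows)
}

#' Windowed nucleotide diversity from genotypes
#'
#' Per site, `pi_site = n/(n-1) * 2 p (1-p)` with `n` the group's
#' non-missing allele count and `p` its alternate-allele frequency (the
#' unbiased per-site mean pairwise difference). The window value is the sum
#' of `pi_site` over sites in the window divided by the window's bp length
#' (truncated windows use the truncated length).
#'
#' @param genotypes a [genotype_matrix()].
#' @param windows window table from [make_windows()].
#' @param group_id group to use (`NULL` = all samples; needs >= 2
#'   individuals).
#' @return data.frame `chrom`, `start`, `end`, `statistic` (= `"pi"`),
#'   `value`, `n_snps`.
#' @export
pi_windows <- function(genotypes, windows, group_id = NULL) {
  rows <- if (is.null(group_id)) rep(TRUE, nrow(genotypes$calls))
  else genotypes$samples$group_id == group_id
  if (sum(rows) < 2) stop("group must have >= 2 individuals")
  af <- allele_freq(genotypes, rows = rows)
  layout <- genotypes$layout
  site <- do.call(rbind, lapply(layout$chromosomes$chrom, function(ch) {
    cols <- chrom_col_index(layout, ch)
    data.frame(chrom = ch, pos0 = layout$positions[[ch]],
               p = af$p[cols], n = af$n_alleles[cols],
               stringsAsFactors = FALSE)
  }))
  usable <- site$n >= 2
  site$pi <- 0
  site$pi[usable] <- site$n[usable] / (site$n[usable] - 1) *
    2 * site$p[usable] * (1 - site$p[usable])
  out <- windows
  out$statistic <- "pi"
  vals <- vapply(seq_len(nrow(windows)), function(k) {
    sel <- site$chrom == windows$chrom[k] & site$pos0 >= windows$start[k] &
      site$pos0 < windows$end[k]
    sum(site$pi[sel]) / (windows$end[k] - windows$start[k])
  }, numeric(1))
  out$value <- vals
  out$n_snps <- vapply(seq_len(nrow(windows)), function(k)
    sum(site$chrom == windows$chrom[k] & site$pos0 >= windows$start[k] &
          site$pos0 < windows$end[k]), integer(1))
  out
}

#' Retain outlier windows by z-standardization
#'
#' Values of one statistic are z-standardized across all its windows;
#' nominal one-sided normal p-values are taken in the configured tail
#' (lower for diversity-like statistics where sweeps deplete the value,
#' upper for `prop_ihs`/`max_clr`/XP-EHH/F_ST) and windows with `p < alpha`
#' are retained and merged into maximal half-open intervals.
#'
#' @param stats window table (`chrom`, `start`, `end`, `value`) from
#'   [window_summarize()] or [pi_windows()]; >= 10 windows.
#' @param alpha retention threshold on the nominal p.
#' @param tail `"upper"` or `"lower"`.
#' @return list: `windows` (input plus `z`, `nominal_p`, `retained`),
#'   `intervals` (merged retained regions: `chrom`, `start`, `end`).
#' @export
retain_windows <- function(stats, alpha = 0.01, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (nrow(stats) < 10) stop("need >= 10 windows for a stable z-scale")
  s <- stats::sd(stats$value)
  if (!is.finite(s) || s == 0) stop("zero standard deviation across windows")
  z <- (stats$value - mean(stats$value)) / s
  p <- if (tail == "upper") stats::pnorm(z, lower.tail = FALSE)
  else stats::pnorm(z, lower.tail = TRUE)
  stats$z <- z
  stats$nominal_p <- p
  stats$retained <- p < alpha
  list(windows = stats,
       intervals = merge_intervals(stats[stats$retained, , drop = FALSE]))
}

# internal: union of half-open intervals, per chromosome
merge_intervals <- function(df) {
  if (!nrow(df))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  out <- list()
  for (ch in unique(df$chrom)) {
    s <- df[df$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    cur_s <- s$start[1]; cur_e <- s$end[1]
    for (k in seq_len(nrow(s))[-1]) {
      if (s$start[k] <= cur_e) cur_e <- max(cur_e, s$end[k])
      else {
        out[[length(out) + 1]] <- data.frame(chrom = ch, start = cur_s, end = cur_e)
        cur_s <- s$start[k]; cur_e <- s$end[k]
      }
    }
    out[[length(out) + 1]] <- data.frame(chrom = ch, start = cur_s, end = cur_e)
  }
  do.call(rbind, out)
}

#' Hotspot-by-selection overlap accounting
#'
#' Counts, for every hotspot, how many selection methods have a retained
#' interval intersecting it (half-open intersection; touching is not
#' overlap), and summarizes the percentage of hotspot SNPs lying inside the
#' retained intervals of at least one and at least two methods.
#'
#' @param hotspots a [call_hotspots()] result.
#' @param retained_sets named list of retained-interval tables (`chrom`,
#'   `start`, `end`), one per selection method (e.g. from
#'   [retain_windows()]`$intervals`).
#' @param layout a [genome_layout()] (SNP positions for the percentage
#'   accounting).
#' @return list: `per_hotspot` (hotspot rows plus `n_methods` and a logical
#'   column per method), `pct_snps_ge1`, `pct_snps_ge2` (percent of hotspot
#'   SNPs supported by >= 1 / >= 2 methods).
#' @export
overlap_report <- function(hotspots, retained_sets, layout) {
  stopifnot(inherits(hotspots, "hotspot_result"))
  hs <- hotspots$hotspots
  methods <- names(retained_sets)
  if (is.null(methods) || any(!nzchar(methods)))
    stop("retained_sets must be a named list")
  bad <- unlist(lapply(retained_sets, function(r)
    setdiff(unique(r$chrom), layout$chromosomes$chrom)))
  if (length(bad)) stop("mismatched chromosomes: ", paste(unique(bad), collapse = ", "))
  overlaps_any <- function(ch, s, e, set)
    any(set$chrom == ch & set$start < e & set$end > s)
  for (mth in methods)
    hs[[mth]] <- vapply(seq_len(nrow(hs)), function(k)
      overlaps_any(hs$chrom[k], hs$start[k], hs$end[k], retained_sets[[mth]]),
      logical(1))
  hs$n_methods <- if (nrow(hs))
    rowSums(as.matrix(hs[, methods, drop = FALSE])) else integer(0)
  # per-SNP support over significant hotspot SNPs
  sig <- hotspots$snp_table[hotspots$snp_table$significant, , drop = FALSE]
  if (nrow(sig)) {
    support <- vapply(methods, function(mth) {
      set <- retained_sets[[mth]]
      vapply(seq_len(nrow(sig)), function(k)
        any(set$chrom == sig$chrom[k] & set$start <= sig$pos[k] &
              set$end > sig$pos[k]), logical(1))
    }, logical(nrow(sig)))
    support <- matrix(support, nrow = nrow(sig))
    nsup <- rowSums(support)
    pct1 <- 100 * mean(nsup >= 1)
    pct2 <- 100 * mean(nsup >= 2)
  } else {
    pct1 <- NA_real_; pct2 <- NA_real_
  }
  list(per_hotspot = hs, pct_snps_ge1 = pct1, pct_snps_ge2 = pct2)
}
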