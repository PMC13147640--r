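#' ROH detection parameters
#'
#' Defaults follow the common WGS parameterization: a run must contain at
#' least 50 consecutive SNPs, span at least 500 kb, contain no inter-SNP gap
#' of 1 Mb or more, and tolerate at most 3 heterozygous and 5 missing calls;
#' SNP density must not exceed 50 kb per SNP.
#'
#' @param min_snps minimum SNP sites per run (>= 2).
#' @param min_length_bp minimum run length in bp.
#' @param max_gap_bp runs are split where the distance between consecutive
#'   SNPs is `>= max_gap_bp`.
#' @param max_het maximum heterozygous calls tolerated.
#' @param max_missing maximum missing calls tolerated.
#' @param max_density_kb_per_snp maximum kb per SNP, `(length_bp/1000)/n_snps`.
#' @param mode `"exact"` (segment-level constraints, oracle-verifiable;
#'   default) or `"window"` (PLINK-style scanning windows with per-window
#'   het/missing allowances).
#' @param window_snps window size in SNPs (window mode).
#' @param window_hit_threshold minimum fraction of acceptable windows
#'   overlapping a SNP for it to enter a candidate run (window mode).
#' @return list of class `roh_params`.
#' @export
roh_params <- function(min_snps = 50L, min_length_bp = 500000,
                       max_gap_bp = 1e6, max_het = 3L, max_missing = 5L,
                       max_density_kb_per_snp = 50, mode = c("exact", "window"),
                       window_snps = 50L, window_hit_threshold = 0.05) {
  mode <- match.arg(mode)
  p <- list(min_snps = as.integer(min_snps), min_length_bp = min_length_bp,
            max_gap_bp = max_gap_bp, max_het = as.integer(max_het),
            max_missing = as.integer(max_missing),
            max_density_kb_per_snp = max_density_kb_per_snp, mode = mode,
            window_snps = as.integer(window_snps),
            window_hit_threshold = window_hit_threshold)
  if (p$min_snps < 2) stop("min_snps must be >= 2")
  if (p$min_length_bp <= 0 || p$max_gap_bp <= 0 ||
      p$max_density_kb_per_snp <= 0 || p$window_snps < 1)
    stop("thresholds must be positive")
  if (p$max_het < 0 || p$max_missing < 0) stop("counts must be >= 0")
  class(p) <- "roh_params"
  p
}

#' Detect runs of homozygosity
#'
#' In exact mode, per individual and chromosome, every maximal SNP-index
#' interval is reported whose heterozygous count, missing count, inter-SNP
#' gaps, SNP count, bp length and kb-per-SNP density all satisfy the
#' parameters; "maximal" means extending one SNP in either direction
#' violates a constraint or runs off the chromosome. Overlapping maximal
#' intervals are resolved greedily (earliest start, then longest) so an
#' individual's reported segments are disjoint. In window mode a
#' PLINK-style scan is used: windows of `window_snps` are acceptable if
#' their het/missing counts are within the allowances, each SNP scores the
#' fraction of overlapping windows that are acceptable, SNPs at or above
#' `window_hit_threshold` form candidate runs (split at gaps), and the
#' segment-level size/length/density filters are applied last.
#'
#' Segment intervals are 0-based half-open with `start` at the first SNP of
#' the run and `end` at the last SNP plus one.
#'
#' @param genotypes a [genotype_matrix()].
#' @param params a [roh_params()].
#' @return segment data.frame (see [roh_segments()]).
#' @export
detect_roh <- function(genotypes, params = roh_params()) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(params, "roh_params"))
  layout <- genotypes$layout
  if (any(lengths(layout$positions) == 0))
    stop("layout contains a chromosome with no SNPs")
  out <- vector("list", 0)
  for (chrom in layout$chromosomes$chrom) {
    cols <- chrom_col_index(layout, chrom)
    pos <- layout$positions[[chrom]]
    for (r in seq_len(nrow(genotypes$calls))) {
      calls <- genotypes$calls[r, cols]
      seg <- if (params$mode == "exact")
        detect_exact_one(calls, pos, params)
      else
        detect_window_one(calls, pos, params)
      if (nrow(seg)) {
        seg$sample_id <- genotypes$samples$sample_id[r]
        seg$chrom <- chrom
        out[[length(out) + 1]] <- seg
      }
    }
  }
  if (!length(out)) return(roh_segments())
  res <- do.call(rbind, out)
  roh_segments(res$sample_id, res$chrom, res$start, res$end,
               n_snps = res$n_snps, n_het = res$n_het,
               n_missing = res$n_missing)
}

# internal: exact mode on one individual x chromosome; returns start/end/
# counts. Candidates come from the compiled scan; overlaps resolved greedily
# by earliest start then longest.
detect_exact_one <- function(calls, pos, params) {
  cand <- cpp_detect_exact(as.integer(calls), as.numeric(pos),
                           params$max_het, params$max_missing,
                           params$max_gap_bp, params$min_snps,
                           params$min_length_bp, params$max_density_kb_per_snp)
  resolve_candidates(cand, calls, pos)
}

# internal: greedy disjoint resolution shared by exact mode and the tests'
# brute-force oracle (candidates are 0-based [i, j] SNP index pairs)
resolve_candidates <- function(cand, calls, pos) {
  if (nrow(cand) == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_snps = integer(0), n_het = integer(0),
                      n_missing = integer(0)))
  i <- cand[, 1] + 1L; j <- cand[, 2] + 1L
  ord <- order(i, -(j - i))
  i <- i[ord]; j <- j[ord]
  keep_i <- integer(0); keep_j <- integer(0); cur_end <- 0L
  for (k in seq_along(i)) {
    if (i[k] > cur_end) {
      keep_i <- c(keep_i, i[k]); keep_j <- c(keep_j, j[k])
      cur_end <- j[k]
    }
  }
  data.frame(
    start = pos[keep_i], end = pos[keep_j] + 1,
    n_snps = keep_j - keep_i + 1L,
    n_het = vapply(seq_along(keep_i), function(k)
      sum(calls[keep_i[k]:keep_j[k]] == 1L, na.rm = TRUE), integer(1)),
    n_missing = vapply(seq_along(keep_i), function(k)
      sum(is.na(calls[keep_i[k]:keep_j[k]])), integer(1))
  )
}

# internal: PLINK-style scanning-window mode on one individual x chromosome
detect_window_one <- function(calls, pos, params) {
  m <- length(calls)
  W <- params$window_snps
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_snps = integer(0), n_het = integer(0),
                      n_missing = integer(0))
  if (m < W) return(empty)
  het <- cumsum(c(0L, calls == 1L & !is.na(calls)))
  mis <- cumsum(c(0L, is.na(calls)))
  nw <- m - W + 1L
  w <- seq_len(nw)
  acceptable <- (het[w + W] - het[w]) <= params$max_het &
    (mis[w + W] - mis[w]) <= params$max_missing
  acc_cum <- cumsum(c(0L, acceptable))
  k <- seq_len(m)
  wlo <- pmax(1L, k - W + 1L)
  whi <- pmin(k, nw)
  n_win <- whi - wlo + 1L
  n_acc <- acc_cum[whi + 1L] - acc_cum[wlo]
  frac <- ifelse(n_win > 0, n_acc / n_win, 0)
  hit <- frac >= params$window_hit_threshold
  # candidate runs of consecutive hit SNPs, split at large gaps
  run_break <- c(TRUE, !hit[-m] | !hit[-1] | diff(pos) >= params$max_gap_bp)
  out <- empty
  idx <- which(hit)
  if (!length(idx)) return(empty)
  grp <- cumsum(run_break)[idx]
  for (g in unique(grp)) {
    ii <- idx[grp == g]
    i <- ii[1]; j <- ii[length(ii)]
    n <- j - i + 1L
    len <- pos[j] - pos[i] + 1
    if (n < params$min_snps || len < params$min_length_bp) next
    if ((len / 1000) / n > params$max_density_kb_per_snp) next
    out <- rbind(out, data.frame(
      start = pos[i], end = pos[j] + 1, n_snps = n,
      n_het = sum(calls[i:j] == 1L, na.rm = TRUE),
      n_missing = sum(is.na(calls[i:j]))))
  }
  out
}

#' One-factor-at-a-time sensitivity analysis of ROH detection
#'
#' Re-runs [detect_roh()] varying a single parameter and reports, per value:
#' total ROH count, mean segment length (kb), mean ROH per individual, mean
#' total F_ROH and (when class boundaries are supplied or fit) mean F_ROH
#' per length class.
#'
#' @param genotypes a [genotype_matrix()].
#' @param base baseline [roh_params()].
#' @param vary name of the parameter to vary (a field of `roh_params`).
#' @param values vector of values for that parameter.
#' @param boundaries_kb optional length-2 class boundaries (kb). If `NULL`
#'   and the baseline run yields at least 30 segments, boundaries are fit
#'   once on the baseline segment lengths with [fit_length_mixture()] and
#'   reused across the grid; otherwise per-class columns are `NA`.
#' @param seed seed for the one-off mixture fit.
#' @return data.frame with one row per value.
#' @export
sensitivity_grid <- function(genotypes, base = roh_params(), vary, values,
                             boundaries_kb = NULL, seed = 1L) {
  if (!vary %in% setdiff(names(unclass(base)), "mode"))
    stop("unknown parameter: ", vary)
  n_ind <- nrow(genotypes$calls)
  total_bp <- genome_size(genotypes$layout)
  if (is.null(boundaries_kb)) {
    base_seg <- detect_roh(genotypes, base)
    if (nrow(base_seg) >= 30 &&
        length(unique(base_seg$length_bp)) > 1)
      boundaries_kb <- fit_length_mixture(base_seg$length_bp / 1000,
                                          seed = seed)$boundaries_kb
  }
  rows <- lapply(values, function(v) {
    p <- unclass(base); p[[vary]] <- v
    p <- do.call(roh_params, p)
    seg <- detect_roh(genotypes, p)
    froh_cls <- c(short = NA_real_, medium = NA_real_, long = NA_real_)
    if (!is.null(boundaries_kb) && nrow(seg)) {
      seg <- classify_segments(seg, boundaries_kb)
      fr <- f_roh(seg, genotypes$layout, samples = genotypes$samples,
                  per_class = TRUE)
      froh_cls <- c(short = mean(fr$f_roh_short), medium = mean(fr$f_roh_medium),
                    long = mean(fr$f_roh_long))
    }
    fr_tot <- f_roh(seg, genotypes$layout, samples = genotypes$samples)
    data.frame(value = v, n_segments = nrow(seg),
               mean_kb = if (nrow(seg)) mean(seg$length_bp) / 1000 else 0,
               mean_per_individual = nrow(seg) / n_ind,
               mean_f_roh = mean(fr_tot$f_roh),
               mean_f_roh_short = froh_cls[["short"]],
               mean_f_roh_medium = froh_cls[["medium"]],
               mean_f_roh_long = froh_cls[["long"]])
  })
  do.call(rbind, rows)
}

#' Per-individual and per-group ROH burden summaries
#'
#' @param segments segment data.frame (classified or not).
#' @param samples data.frame with `sample_id` and `group_id` covering every
#'   individual of the panel (individuals without segments get zeros).
#' @return list with `per_individual` (count and cumulative bp, overall and
#'   per class) and `per_group` (means of the same quantities).
#' @export
summarize_burden <- function(segments, samples) {
  stopifnot(all(c("sample_id", "group_id") %in% names(samples)))
  ids <- samples$sample_id
  classes <- c("short", "medium", "long")
  per <- data.frame(sample_id = ids, group_id = samples$group_id,
                    stringsAsFactors = FALSE)
  f <- factor(segments$sample_id, levels = ids)
  per$n_roh <- as.integer(tabulate(f, nbins = length(ids)))
  sum_by <- function(x, fac) {
    out <- tapply(x, fac, sum)
    out[is.na(out)] <- 0
    as.numeric(out)
  }
  per$total_bp <- if (nrow(segments)) sum_by(segments$length_bp, f) else 0
  for (cl in classes) {
    sel <- !is.na(segments$class) & segments$class == cl
    fc <- factor(segments$sample_id[sel], levels = ids)
    per[[paste0("n_", cl)]] <- as.integer(tabulate(fc, nbins = length(ids)))
    per[[paste0("bp_", cl)]] <-
      if (any(sel)) sum_by(segments$length_bp[sel], fc) else 0
  }
  gf <- factor(per$group_id, levels = unique(per$group_id))
  num_cols <- setdiff(names(per), c("sample_id", "group_id"))
  grp <- data.frame(group_id = levels(gf), stringsAsFactors = FALSE)
  for (cc in num_cols)
    grp[[paste0("mean_", cc)]] <- as.numeric(tapply(per[[cc]], gf, mean))
  list(per_individual = per, per_group = grp)
}
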