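#' Per-SNP ROH coverage track for a group
#'
#' For every SNP position, the number of group individuals having an ROH
#' whose half-open interval contains the SNP (an individual counts at most
#' once per SNP), and the corresponding frequency. The denominator is the
#' full group size, including ROH-free individuals.
#'
#' @param segments segment data.frame (any individuals; rows outside the
#'   group are ignored).
#' @param layout a [genome_layout()].
#' @param samples data.frame with `sample_id`, `group_id` defining the panel.
#' @param group_id group to profile; `NULL` uses all samples as one group.
#' @return list of class `coverage_track`: `group_id`, `n` (group size),
#'   `snps` (data.frame `chrom`, `pos` internal 0-based, `count`, `freq`).
#' @export
coverage_track <- function(segments, layout, samples, group_id = NULL) {
  members <- if (is.null(group_id)) samples$sample_id
  else samples$sample_id[samples$group_id == group_id]
  if (!length(members)) stop("group has 0 individuals")
  seg <- segments[segments$sample_id %in% members, , drop = FALSE]
  chroms <- layout$chromosomes$chrom
  counts <- cpp_coverage_counts(
    as.integer(match(seg$sample_id, members) - 1L),
    as.integer(match(seg$chrom, chroms) - 1L),
    as.numeric(seg$start), as.numeric(seg$end),
    unname(layout$positions), length(members))
  snps <- do.call(rbind, lapply(seq_along(chroms), function(c) {
    data.frame(chrom = chroms[c], pos = layout$positions[[c]],
               count = as.integer(counts[[c]]), stringsAsFactors = FALSE)
  }))
  snps$freq <- snps$count / length(members)
  structure(list(group_id = if (is.null(group_id)) "all" else group_id,
                 n = length(members), snps = snps),
            class = "coverage_track")
}

#' Permutation null distribution of the maximum SNP-wise ROH frequency
#'
#' Under the null, each segment is independently redistributed to a uniform
#' start on `[0, chrom_len - length]` on its own chromosome for its own
#' individual, preserving all segment lengths and per-individual,
#' per-chromosome counts. For each permutation the per-SNP coverage
#' frequency is recomputed (individuals deduplicated, so displaced segments
#' of one individual may overlap) and the genome-wide maximum recorded.
#'
#' @param segments group segments (rows outside the group are ignored).
#' @param layout a [genome_layout()].
#' @param samples data.frame with `sample_id`, `group_id`.
#' @param group_id group to permute; `NULL` = all samples.
#' @param n_perm number of permutations.
#' @param seed integer seed (set via `set.seed`; same seed, same result).
#' @return list of class `null_max_distribution`: `group_id`, `n_perm`,
#'   `max_freq` (length `n_perm`), `seed`.
#' @export
permute_null <- function(segments, layout, samples, group_id = NULL,
                         n_perm = 10000L, seed = 1L) {
  members <- if (is.null(group_id)) samples$sample_id
  else samples$sample_id[samples$group_id == group_id]
  if (!length(members)) stop("group has 0 individuals")
  seg <- segments[segments$sample_id %in% members, , drop = FALSE]
  chroms <- layout$chromosomes$chrom
  ci <- match(seg$chrom, chroms)
  if (anyNA(ci)) stop("unknown chromosome in segments")
  too_long <- seg$length_bp > layout$chromosomes$length_bp[ci]
  if (any(too_long)) stop("segment longer than its chromosome")
  set.seed(seed)
  mx <- if (nrow(seg) == 0) rep(0, n_perm) else
    cpp_permute_null(as.integer(match(seg$sample_id, members) - 1L),
                     as.integer(ci - 1L), as.numeric(seg$length_bp),
                     as.numeric(layout$chromosomes$length_bp),
                     unname(layout$positions), length(members),
                     as.integer(n_perm))
  structure(list(group_id = if (is.null(group_id)) "all" else group_id,
                 n_perm = as.integer(n_perm), max_freq = mx, seed = seed),
            class = "null_max_distribution")
}

#' Call ROH hotspots against a max-statistic permutation null
#'
#' The genome-wide significance threshold is the empirical `1 - alpha`
#' quantile of the permutation maxima (order statistic at
#' `ceiling((1 - alpha) * n_perm)`); a SNP is significant iff its observed
#' frequency strictly exceeds the threshold, which keeps the family-wise
#' error rate at or below `alpha` and is conservative under ties. Each SNP
#' also gets a FWER-adjusted empirical P,
#' `(1 + #permutation maxima >= freq) / (n_perm + 1)`. Runs of consecutive
#' significant SNPs on a chromosome are merged into hotspots, optionally
#' bridging inter-SNP gaps below `merge_gap_bp`.
#'
#' @param observed a [coverage_track()].
#' @param null a [permute_null()] result for the same group/layout.
#' @param alpha nominal FWER level, in (0, 1).
#' @param merge_gap_bp if set, significant SNPs on the same chromosome whose
#'   bp distance is below this value are merged even when non-significant
#'   SNPs lie between them; default merges strictly consecutive SNPs only.
#' @return list of class `hotspot_result`: `group_id`, `threshold_freq`,
#'   `alpha`, `hotspots` (data.frame `chrom`, `start`, `end`, `peak_freq`,
#'   `min_p`, `n_snps`), `snp_table` (per-SNP `freq`, `p_value`,
#'   `significant`).
#' @export
call_hotspots <- function(observed, null, alpha = 0.01, merge_gap_bp = NULL) {
  stopifnot(inherits(observed, "coverage_track"),
            inherits(null, "null_max_distribution"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!length(null$max_freq)) stop("empty null distribution")
  sorted <- sort(null$max_freq)
  threshold <- sorted[ceiling((1 - alpha) * length(sorted))]
  snps <- observed$snps
  # empirical P: fraction of permutation maxima at or above the observed
  # frequency, with the +1 correction
  ecdf_ge <- function(f) {
    idx <- findInterval(f - 1e-12, sorted)
    (1 + length(sorted) - idx) / (length(sorted) + 1)
  }
  snps$p_value <- ecdf_ge(snps$freq)
  snps$significant <- snps$freq > threshold
  hot <- list()
  for (ch in unique(snps$chrom)) {
    s <- snps[snps$chrom == ch, ]
    sig <- which(s$significant)
    if (!length(sig)) next
    new_run <- c(TRUE, if (length(sig) > 1) {
      adjacent <- diff(sig) == 1
      bridged <- if (!is.null(merge_gap_bp))
        diff(s$pos[sig]) < merge_gap_bp else FALSE
      !(adjacent | bridged)
    })
    grp <- cumsum(new_run)
    for (g in unique(grp)) {
      ii <- sig[grp == g]
      hot[[length(hot) + 1]] <- data.frame(
        chrom = ch, start = s$pos[ii[1]], end = s$pos[ii[length(ii)]] + 1,
        peak_freq = max(s$freq[ii]), min_p = min(s$p_value[ii]),
        n_snps = length(ii), stringsAsFactors = FALSE)
    }
  }
  hotspots <- if (length(hot)) do.call(rbind, hot) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               peak_freq = numeric(0), min_p = numeric(0), n_snps = integer(0))
  structure(list(group_id = observed$group_id, threshold_freq = threshold,
                 alpha = alpha, hotspots = hotspots, snp_table = snps),
            class = "hotspot_result")
}

#' Frequency of individuals with an ROH overlapping each region
#'
#' For every supplied interval and every group, the fraction of group
#' members having at least one ROH whose half-open interval intersects the
#' region (touching at an endpoint is not overlap).
#'
#' @param segments segment data.frame.
#' @param samples data.frame with `sample_id`, `group_id`.
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open, e.g. from [read_segments()] with `dialect = "bed"`).
#' @return data.frame: `chrom`, `start`, `end`, `group_id`, `n_carriers`,
#'   `n`, `freq`.
#' @export
region_overlap_frequency <- function(segments, samples, regions) {
  if (!all(c("chrom", "start", "end") %in% names(regions)))
    stop("regions must have chrom/start/end")
  if (nrow(regions) && any(regions$end < regions$start))
    stop("malformed interval: end < start")
  groups <- unique(samples$group_id)
  out <- list()
  for (k in seq_len(nrow(regions))) {
    ov <- segments$chrom == regions$chrom[k] &
      segments$start < regions$end[k] & segments$end > regions$start[k]
    carriers <- unique(segments$sample_id[ov])
    for (grp in groups) {
      members <- samples$sample_id[samples$group_id == grp]
      out[[length(out) + 1]] <- data.frame(
        chrom = regions$chrom[k], start = regions$start[k],
        end = regions$end[k], group_id = grp,
        n_carriers = sum(members %in% carriers), n = length(members),
        freq = sum(members %in% carriers) / length(members),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), group_id = character(0),
                      n_carriers = integer(0), n = integer(0),
                      freq = numeric(0)))
  do.call(rbind, out)
}
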