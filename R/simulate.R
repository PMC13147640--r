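#' Simulation configuration for synthetic genotype panels
#'
#' Describes a multi-group diploid SNP panel with Hardy-Weinberg background
#' genotypes and planted autozygous tracts: per-class tract count/length
#' laws reproducing a three-modal length mixture, optional group-shared
#' hotspot islands, genotyping error inside tracts, genome-wide missingness,
#' an optional per-individual inbreeding gradient, and optional
#' covariate-linked SNPs whose per-group allele frequency follows
#' `plogis(a + b * covariate)`.
#'
#' @param seed integer seed; the whole simulation is deterministic under it.
#' @param n_individuals named integer vector, one entry per group.
#' @param n_chrom,chrom_length_bp,mean_spacing_bp genome layout: equal-length
#'   chromosomes with `chrom_length_bp / mean_spacing_bp` SNP positions drawn
#'   uniformly at random per chromosome.
#' @param freq_range allele-frequency law: uniform on `[f_min, f_max]`.
#' @param tracts per-class tract model: named list (`short`, `medium`,
#'   `long`) of `list(mean_count, median_kb, log_sd)` - tract counts are
#'   Poisson per individual, lengths log-normal. Class medians must be
#'   ordered short < medium < long. `NULL` entries plant no tracts.
#' @param het_error_rate probability a site inside a planted tract is flipped
#'   to heterozygous.
#' @param missing_rate genome-wide probability a call is missing.
#' @param hotspots optional data.frame `chrom`, `start`, `end` (0-based
#'   half-open), `carrier_fraction`, optional `group_id` (default: all
#'   groups); carriers receive a medium-class tract fully covering the
#'   interval, extended by `hotspot_flank_bp` split across both sides.
#' @param hotspot_flank_bp extra tract length around a hotspot interval.
#' @param target_fraction optional per-individual target autozygous fraction
#'   (length = total individuals); tracts from the gradient length law are
#'   added until each individual's tract union reaches its target.
#' @param gradient_tract list(median_kb, log_sd) for gradient tracts.
#' @param covariates optional list with `table` (data.frame `group_id`,
#'   covariate columns) and `linked_snps` (data.frame `chrom`, `snp_index`,
#'   `covariate`, `a`, `b`).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_individuals = c(all = 20L),
                       n_chrom = 2L, chrom_length_bp = 10e6,
                       mean_spacing_bp = 2000, freq_range = c(0.05, 0.5),
                       tracts = list(
                         short = list(mean_count = 2, median_kb = 600, log_sd = 0.2),
                         medium = list(mean_count = 1, median_kb = 1200, log_sd = 0.25),
                         long = list(mean_count = 0.4, median_kb = 3000, log_sd = 0.35)),
                       het_error_rate = 0, missing_rate = 0,
                       hotspots = NULL, hotspot_flank_bp = 200000,
                       target_fraction = NULL,
                       gradient_tract = list(median_kb = 2000, log_sd = 0.3),
                       covariates = NULL) {
  if (is.null(names(n_individuals)))
    names(n_individuals) <- paste0("g", seq_along(n_individuals))
  stopifnot(all(n_individuals >= 1), n_chrom >= 1, chrom_length_bp > 0,
            mean_spacing_bp > 0, length(freq_range) == 2,
            freq_range[1] > 0, freq_range[2] <= 0.5,
            het_error_rate >= 0, het_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  med <- vapply(c("short", "medium", "long"), function(cl)
    if (is.null(tracts[[cl]])) NA_real_ else tracts[[cl]]$median_kb, numeric(1))
  got <- med[!is.na(med)]
  if (length(got) > 1 && any(diff(got) <= 0))
    stop("tract length medians must be ordered short < medium < long")
  if (!is.null(hotspots)) {
    stopifnot(all(c("chrom", "start", "end", "carrier_fraction") %in% names(hotspots)),
              all(hotspots$carrier_fraction >= 0),
              all(hotspots$carrier_fraction <= 1))
  }
  if (!is.null(target_fraction) &&
      length(target_fraction) != sum(n_individuals))
    stop("target_fraction must have one entry per individual")
  structure(list(seed = as.integer(seed), n_individuals = n_individuals,
                 n_chrom = as.integer(n_chrom),
                 chrom_length_bp = chrom_length_bp,
                 mean_spacing_bp = mean_spacing_bp, freq_range = freq_range,
                 tracts = tracts, het_error_rate = het_error_rate,
                 missing_rate = missing_rate, hotspots = hotspots,
                 hotspot_flank_bp = hotspot_flank_bp,
                 target_fraction = target_fraction,
                 gradient_tract = gradient_tract, covariates = covariates),
            class = "sim_config")
}

#' Simulate a genotype panel with planted autozygosity
#'
#' Background genotypes are drawn per site from Hardy-Weinberg proportions
#' at the site's allele frequency. Inside every planted tract, genotypes
#' are forced homozygous (allele chosen by the site frequency) and then
#' flipped to heterozygous with probability `het_error_rate` per site;
#' missingness is applied uniformly at random afterwards. Tract placement
#' is uniform on `[0, chrom_len - tract_len]`, chromosomes chosen
#' proportionally to length; an individual's own tracts may overlap (the
#' union is used for autozygous fractions). Hotspot carriers (a seeded
#' sample of `round(carrier_fraction * n)` group members) receive a tract
#' fully covering the hotspot interval.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth` (class
#'   `sim_truth`): `tracts` (sample_id, chrom, start, end, class),
#'   `hotspots` (with realized carrier counts and carrier ids),
#'   `fractions` (per-individual realized autozygous fraction),
#'   `linked_freq` (per-group planted frequency at covariate-linked SNPs,
#'   or `NULL`).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_snp_chrom <- max(2L, round(config$chrom_length_bp / config$mean_spacing_bp))
  layout <- uniform_layout(config$n_chrom, config$chrom_length_bp,
                           n_snp_chrom, spacing = "uniform")
  total_bp <- genome_size(layout)
  chroms <- layout$chromosomes$chrom
  chrom_len <- layout$chromosomes$length_bp
  m <- n_snps(layout)
  groups <- names(config$n_individuals)
  sample_id <- unlist(lapply(groups, function(g)
    sprintf("%s_%03d", g, seq_len(config$n_individuals[[g]]))))
  group_id <- rep(groups, times = config$n_individuals)
  n <- length(sample_id)

  # site frequencies (shared across groups except covariate-linked SNPs)
  p_site <- stats::runif(m, config$freq_range[1], config$freq_range[2])
  p_group <- matrix(p_site, nrow = length(groups), ncol = m, byrow = TRUE,
                    dimnames = list(groups, NULL))
  linked_freq <- NULL
  if (!is.null(config$covariates)) {
    cov_tab <- config$covariates$table
    link <- config$covariates$linked_snps
    rows <- list()
    for (k in seq_len(nrow(link))) {
      col <- chrom_col_index(layout, link$chrom[k])[link$snp_index[k]]
      covv <- cov_tab[[link$covariate[k]]][match(groups, cov_tab$group_id)]
      pg <- stats::plogis(link$a[k] + link$b[k] * covv)
      p_group[, col] <- pg
      rows[[k]] <- data.frame(group_id = groups, chrom = link$chrom[k],
                              snp_index = link$snp_index[k],
                              covariate = link$covariate[k], p = pg,
                              stringsAsFactors = FALSE)
    }
    linked_freq <- do.call(rbind, rows)
  }

  # tract placement ---------------------------------------------------
  draw_len <- function(median_kb, log_sd) {
    len <- stats::rlnorm(1, meanlog = log(median_kb * 1000), sdlog = log_sd)
    tries <- 0
    while (len > max(chrom_len) && tries < 100) {
      len <- stats::rlnorm(1, meanlog = log(median_kb * 1000), sdlog = log_sd)
      tries <- tries + 1
    }
    round(min(len, max(chrom_len)))
  }
  place <- function(len) {
    ok <- chrom_len >= len
    ci <- sample.int(length(chroms), 1, prob = chrom_len * ok)
    start <- floor(stats::runif(1) * (chrom_len[ci] - len + 1))
    c(ci, start, start + len)
  }
  tr <- list()
  add_tract <- function(sid, ci, start, end, cls)
    tr[[length(tr) + 1]] <<- data.frame(sample_id = sid, chrom = chroms[ci],
                                        start = start, end = end, class = cls,
                                        stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    for (cl in c("short", "medium", "long")) {
      law <- config$tracts[[cl]]
      if (is.null(law) || law$mean_count <= 0) next
      cnt <- stats::rpois(1, law$mean_count)
      for (t in seq_len(cnt)) {
        len <- draw_len(law$median_kb, law$log_sd)
        pl <- place(len)
        add_tract(sample_id[i], pl[1], pl[2], pl[3], cl)
      }
    }
  }
  # inbreeding gradient: top up to the per-individual target fraction
  if (!is.null(config$target_fraction)) {
    for (i in seq_len(n)) {
      target_bp <- config$target_fraction[i] * total_bp
      repeat {
        own <- which(vapply(tr, function(d) d$sample_id == sample_id[i],
                            logical(1)))
        cur <- if (length(own)) union_length(do.call(rbind, tr[own])) else 0
        if (cur >= target_bp) break
        len <- draw_len(config$gradient_tract$median_kb,
                        config$gradient_tract$log_sd)
        pl <- place(len)
        add_tract(sample_id[i], pl[1], pl[2], pl[3], "gradient")
      }
    }
  }
  # hotspot carriers
  hs_truth <- NULL
  if (!is.null(config$hotspots)) {
    hs <- config$hotspots
    hs$n_carriers <- NA_integer_
    carriers_all <- character(0)
    carrier_list <- vector("list", nrow(hs))
    for (k in seq_len(nrow(hs))) {
      members <- if ("group_id" %in% names(hs) && !is.na(hs$group_id[k]))
        sample_id[group_id == hs$group_id[k]] else sample_id
      n_c <- round(hs$carrier_fraction[k] * length(members))
      if (abs(n_c - hs$carrier_fraction[k] * length(members)) > 1e-9)
        message("hotspot ", k, ": carrier count rounded to ", n_c)
      carriers <- sample(members, n_c)
      ci <- match(hs$chrom[k], chroms)
      if (is.na(ci)) stop("unknown hotspot chromosome: ", hs$chrom[k])
      span <- hs$end[k] - hs$start[k]
      if (span > chrom_len[ci]) stop("tract longer than chromosome")
      for (sid in carriers) {
        fl <- config$hotspot_flank_bp
        s0 <- max(0, hs$start[k] - floor(fl / 2))
        e0 <- min(chrom_len[ci], hs$end[k] + ceiling(fl / 2))
        add_tract(sid, ci, s0, e0, "medium")
      }
      hs$n_carriers[k] <- n_c
      carrier_list[[k]] <- carriers
    }
    hs_truth <- hs
    attr(hs_truth, "carriers") <- carrier_list
  }
  tracts <- if (length(tr)) do.call(rbind, tr) else
    data.frame(sample_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), class = character(0))

  # genotypes ----------------------------------------------------------
  pg <- p_group[match(group_id, groups), , drop = FALSE]
  u <- matrix(stats::runif(n * m), n, m)
  hom_ref <- (1 - pg)^2
  calls <- matrix(1L, n, m)
  calls[u < hom_ref] <- 0L
  calls[u >= hom_ref + 2 * pg * (1 - pg)] <- 2L
  # overlay planted tracts: force homozygous, then per-site het error
  if (nrow(tracts)) {
    ri <- match(tracts$sample_id, sample_id)
    for (k in seq_len(nrow(tracts))) {
      cols <- chrom_col_index(layout, tracts$chrom[k])
      pos <- layout$positions[[tracts$chrom[k]]]
      inside <- cols[pos >= tracts$start[k] & pos < tracts$end[k]]
      if (!length(inside)) next
      hom <- ifelse(stats::runif(length(inside)) < pg[ri[k], inside], 2L, 0L)
      if (config$het_error_rate > 0) {
        flip <- stats::runif(length(inside)) < config$het_error_rate
        hom[flip] <- 1L
      }
      calls[ri[k], inside] <- hom
    }
  }
  if (config$missing_rate > 0)
    calls[matrix(stats::runif(n * m), n, m) < config$missing_rate] <- NA_integer_

  genotypes <- genotype_matrix(calls, layout, sample_id, group_id)
  fractions <- data.frame(
    sample_id = sample_id, group_id = group_id,
    target = if (is.null(config$target_fraction)) NA_real_
    else config$target_fraction,
    fraction = vapply(sample_id, function(sid)
      union_length(tracts[tracts$sample_id == sid, , drop = FALSE]) / total_bp,
      numeric(1)),
    stringsAsFactors = FALSE)
  truth <- structure(list(tracts = tracts, hotspots = hs_truth,
                          fractions = fractions, linked_freq = linked_freq),
                     class = "sim_truth")
  list(genotypes = genotypes, truth = truth)
}

# internal: total length of the union of (chrom, start, end) intervals
union_length <- function(df) {
  if (!nrow(df)) return(0)
  merged <- merge_intervals(df[, c("chrom", "start", "end")])
  sum(merged$end - merged$start)
}

#' Simulate a bare null segment panel
#'
#' Places a fixed number of ROH segments per individual uniformly at random
#' on the genome (chromosome chosen proportionally to length, start uniform
#' on `[0, chrom_len - length]`), with log-normal lengths. This is the null
#' model of the hotspot permutation test and is used for its calibration.
#'
#' @param layout a [genome_layout()].
#' @param n_individuals number of individuals (`ind_001`, ...).
#' @param segments_per_individual segment count per individual.
#' @param median_kb,log_sd log-normal length law.
#' @return list with `segments` and `samples` (single group `"all"`). Uses
#'   the current RNG state; wrap in `set.seed()` for reproducibility.
#' @export
simulate_null_segments <- function(layout, n_individuals = 25L,
                                   segments_per_individual = 20L,
                                   median_kb = 800, log_sd = 0.5) {
  chrom_len <- layout$chromosomes$length_bp
  chroms <- layout$chromosomes$chrom
  n_seg <- n_individuals * segments_per_individual
  ci <- sample.int(length(chroms), n_seg, replace = TRUE, prob = chrom_len)
  len <- round(pmin(stats::rlnorm(n_seg, log(median_kb * 1000), log_sd),
                    chrom_len[ci]))
  start <- floor(stats::runif(n_seg) * (chrom_len[ci] - len + 1))
  sample_id <- rep(sprintf("ind_%03d", seq_len(n_individuals)),
                   each = segments_per_individual)
  list(segments = roh_segments(sample_id, chroms[ci], start, start + len),
       samples = data.frame(sample_id = sprintf("ind_%03d",
                                                seq_len(n_individuals)),
                            group_id = "all", stringsAsFactors = FALSE))
}

#' Write ground-truth tables of a simulation
#'
#' Writes `tracts.tsv`, `hotspots.tsv` and `fractions.tsv` (plus
#' `linked_freq.tsv` when covariate-linked SNPs were planted) under
#' `out_dir`, keyed by `sample_id`/`chrom` for joining with pipeline
#' outputs. Empty truth still produces headered files.
#'
#' @param truth the `truth` element of [simulate_panel()].
#' @param out_dir output directory (created if absent).
#' @return named character vector of file paths, invisibly.
#' @export
truth_report <- function(truth, out_dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  hs <- truth$hotspots
  if (is.null(hs))
    hs <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), carrier_fraction = numeric(0),
                     n_carriers = integer(0))
  paths <- c(tracts = w(truth$tracts, "tracts.tsv"),
             hotspots = w(hs, "hotspots.tsv"),
             fractions = w(truth$fractions, "fractions.tsv"))
  if (!is.null(truth$linked_freq))
    paths <- c(paths, linked_freq = w(truth$linked_freq, "linked_freq.tsv"))
  invisible(paths)
}
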