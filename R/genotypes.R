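#' Genotype matrix container
#'
#' Wraps an individuals-by-sites integer matrix of diploid genotype codes
#' (0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' `NA` = missing) together with the [genome_layout()] describing the site
#' coordinates and a sample table with group assignments. Columns are ordered
#' chromosome-by-chromosome following the layout.
#'
#' @param calls integer matrix, individuals in rows, sites in columns; values
#'   in `{0, 1, 2, NA}`.
#' @param layout a [genome_layout()]; total SNP count must equal `ncol(calls)`.
#' @param sample_id character vector of unique sample names (rows of `calls`).
#' @param group_id character vector of group labels, recycled if length 1;
#'   defaults to a single group `"all"`.
#' @return An object of class `genotype_matrix`: list with `calls`, `layout`,
#'   `samples` (data.frame `sample_id`, `group_id`).
#' @export
genotype_matrix <- function(calls, layout, sample_id, group_id = "all") {
  stopifnot(inherits(layout, "genome_layout"))
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != n_snps(layout))
    stop("calls has ", ncol(calls), " columns but layout has ",
         n_snps(layout), " SNPs")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  sample_id <- as.character(sample_id)
  if (length(sample_id) != nrow(calls) || anyDuplicated(sample_id))
    stop("sample_id must be unique and match nrow(calls)")
  group_id <- rep_len(as.character(group_id), nrow(calls))
  rownames(calls) <- sample_id
  structure(
    list(calls = calls, layout = layout,
         samples = data.frame(sample_id = sample_id, group_id = group_id,
                              stringsAsFactors = FALSE)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "individuals x", ncol(x$calls),
      "SNPs,", length(unique(x$samples$group_id)), "group(s)\n")
  invisible(x)
}

# internal: column index range (1-based) of a chromosome within the calls
# matrix, following layout order
chrom_col_index <- function(layout, chrom) {
  sizes <- lengths(layout$positions)
  chroms <- layout$chromosomes$chrom
  k <- match(chrom, chroms)
  if (is.na(k)) stop("unknown chromosome: ", chrom)
  start <- if (k == 1) 1L else sum(sizes[seq_len(k - 1)]) + 1L
  if (sizes[k] == 0L) return(integer(0))
  seq.int(start, start + sizes[k] - 1L)
}

#' Per-site alternate-allele frequencies from a panel
#'
#' Frequencies are computed from non-missing calls only: at site i with
#' `n_i` non-missing individuals, `p_i = (het + 2 hom_alt) / (2 n_i)`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param rows optional integer/logical row subset (e.g. one group).
#' @return data.frame with `p` (alt-allele frequency, `NaN` where no calls)
#'   and `n_alleles` (non-missing allele count, `2 n_i`) per site.
#' @export
allele_freq <- function(genotypes, rows = NULL) {
  g <- genotypes$calls
  if (!is.null(rows)) g <- g[rows, , drop = FALSE]
  n_gt <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  data.frame(p = alt / (2 * n_gt), n_alleles = 2L * n_gt)
}
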