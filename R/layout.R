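#' Genome layout: chromosomes and SNP map
#'
#' A `genome_layout` holds the coordinate system every other function works
#' in: an ordered set of named chromosomes with lengths, and per chromosome a
#' strictly increasing vector of SNP positions. Positions are stored
#' internally in 0-based half-open convention (a SNP at external 1-based
#' position p occupies the internal base `[p-1, p)`); all readers and writers
#' convert at the boundary.
#'
#' @param chromosomes character vector of unique chromosome names.
#' @param lengths_bp positive integer vector of chromosome lengths (bp),
#'   parallel to `chromosomes`.
#' @param snp_positions named list (one element per chromosome) of strictly
#'   increasing 1-based SNP positions; each position must lie in
#'   `[1, length_bp]`. Converted to internal 0-based on construction.
#'
#' @return An object of class `genome_layout` with elements `chromosomes`
#'   (data.frame: `chrom`, `length_bp`) and `positions` (named list of
#'   internal 0-based positions).
#' @export
#' @examples
#' genome_layout("chr1", 1e6, list(chr1 = c(100, 5000, 999999)))
genome_layout <- function(chromosomes, lengths_bp, snp_positions) {
  chromosomes <- as.character(chromosomes)
  if (anyDuplicated(chromosomes))
    stop("chromosome names must be unique")
  lengths_bp <- as.numeric(lengths_bp)
  if (length(lengths_bp) != length(chromosomes) || any(lengths_bp < 1))
    stop("lengths_bp must be positive and parallel to chromosomes")
  if (!all(chromosomes %in% names(snp_positions)))
    stop("snp_positions must have an element for every chromosome")
  positions <- vector("list", length(chromosomes))
  names(positions) <- chromosomes
  for (k in seq_along(chromosomes)) {
    chrom <- chromosomes[k]
    p <- as.numeric(snp_positions[[chrom]])
    if (length(p) && (any(p < 1) || any(p > lengths_bp[k])))
      stop("SNP positions on ", chrom, " outside [1, chromosome length]")
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("SNP positions on ", chrom, " not strictly increasing")
    positions[[chrom]] <- p - 1  # internal 0-based
  }
  structure(
    list(
      chromosomes = data.frame(chrom = chromosomes, length_bp = lengths_bp,
                               stringsAsFactors = FALSE),
      positions = positions
    ),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$chromosomes), "chromosome(s),",
      n_snps(x), "SNPs,", format(genome_size(x), big.mark = ","),
      "bp total\n")
  invisible(x)
}

#' Total genome size of a layout
#' @param layout a [genome_layout()].
#' @return Total chromosome length in bp.
#' @export
genome_size <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(layout$chromosomes$length_bp)
}

#' Total SNP count of a layout
#' @param layout a [genome_layout()].
#' @return Number of SNP sites across all chromosomes.
#' @export
n_snps <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(lengths(layout$positions))
}

#' Build a layout with uniformly spread SNPs
#'
#' Convenience constructor used by the simulator and in examples: `n_chrom`
#' chromosomes of equal length, with SNP positions either evenly spaced or
#' drawn uniformly at random (sorted, deduplicated).
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp length of every chromosome in bp.
#' @param n_snps_per_chrom number of SNP sites per chromosome.
#' @param spacing `"even"` for a regular grid, `"uniform"` for positions
#'   drawn uniformly at random (uses the current RNG state).
#' @return A [genome_layout()]. Chromosomes are named `chr1`, `chr2`, ...
#' @export
uniform_layout <- function(n_chrom, chrom_length_bp, n_snps_per_chrom,
                           spacing = c("even", "uniform")) {
  spacing <- match.arg(spacing)
  chroms <- paste0("chr", seq_len(n_chrom))
  pos <- lapply(chroms, function(ch) {
    if (spacing == "even") {
      step <- chrom_length_bp / n_snps_per_chrom
      round(step * (seq_len(n_snps_per_chrom) - 0.5)) + 1
    } else {
      sort(unique(ceiling(stats::runif(n_snps_per_chrom) * chrom_length_bp)))
    }
  })
  names(pos) <- chroms
  genome_layout(chroms, rep(chrom_length_bp, n_chrom), pos)
}

# internal: external (1-based) positions for a chromosome
external_positions <- function(layout, chrom) layout$positions[[chrom]] + 1
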