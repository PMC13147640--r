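#' Read a VCF of biallelic SNPs into a genotype matrix
#'
#' Reads diploid genotypes from a VCF (via the vcfR parser) and recodes them
#' as 0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing. Multi-allelic or
#' non-SNP (indel) records are skipped in lenient mode or rejected in strict
#' mode. Duplicate positions on a chromosome keep the first record (a message
#' notes the drop). Chromosome lengths are taken from `##contig` header lines
#' when present, else from the last SNP position per chromosome.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param sample_to_group optional named character vector mapping sample name
#'   to group id; every name must exist in the VCF. Samples not in the
#'   mapping keep group `"all"`.
#' @param strict if `TRUE`, any multi-allelic/non-SNP record is an error;
#'   if `FALSE` (default) such records are skipped.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, sample_to_group = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("cannot read ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", alt, fixed = TRUE)
  if (strict && any(!is_snp))
    stop(sum(!is_snp), " non-biallelic-SNP record(s) in strict mode")
  if (!any(is_snp)) stop("no biallelic SNP records in ", path)

  chrom <- fix[is_snp, "CHROM"]
  pos <- as.numeric(fix[is_snp, "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(gt))
  gt <- gt[is_snp, , drop = FALSE]

  # first record wins at duplicated positions
  keep <- !duplicated(paste(chrom, pos))
  if (any(!keep))
    message("read_vcf: dropped ", sum(!keep), " duplicate position record(s)")
  chrom <- chrom[keep]; pos <- pos[keep]; gt <- gt[keep, , drop = FALSE]

  ord <- order(match(chrom, unique(chrom)), pos)
  chrom <- chrom[ord]; pos <- pos[ord]; gt <- gt[ord, , drop = FALSE]

  # genotype strings -> codes; any ploidy-2 combination of 0/1 alleles
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  a <- sub("[/|].*$", "", gt)
  b <- sub("^[^/|]*[/|]", "", gt)
  ok <- a %in% c("0", "1") & b %in% c("0", "1")
  code[ok] <- as.integer(a[ok]) + as.integer(b[ok])
  code <- t(code)  # individuals x sites

  chroms <- unique(chrom)
  contig_len <- vcf_contig_lengths(v)
  lens <- vapply(chroms, function(ch) {
    if (ch %in% names(contig_len)) contig_len[[ch]] else max(pos[chrom == ch])
  }, numeric(1))
  positions <- split(pos, factor(chrom, levels = chroms))
  layout <- genome_layout(chroms, lens, positions)

  samples <- colnames(v@gt)[-1]
  groups <- rep("all", length(samples))
  if (!is.null(sample_to_group)) {
    missing_s <- setdiff(names(sample_to_group), samples)
    if (length(missing_s))
      stop("samples in mapping absent from VCF: ", paste(missing_s, collapse = ", "))
    hit <- match(samples, names(sample_to_group))
    groups[!is.na(hit)] <- unname(sample_to_group[hit[!is.na(hit)]])
  }
  genotype_matrix(code, layout, samples, groups)
}

# internal: parse ##contig=<ID=...,length=...> header lines
vcf_contig_lengths <- function(v) {
  meta <- v@meta
  hits <- grep("^##contig=", meta, value = TRUE)
  ids <- sub('.*ID=([^,>"]+).*', "\\1", hits)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", hits)))
  stats::setNames(lens, ids)[!is.na(lens)]
}

#' Write a genotype matrix as an uncompressed VCF
#'
#' Minimal VCFv4.2 writer used by the simulator so that panels round-trip
#' through [read_vcf()]. REF/ALT are written as A/G placeholders; genotypes
#' are unphased (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  layout <- genotypes$layout
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (k in seq_len(nrow(layout$chromosomes)))
    writeLines(sprintf("##contig=<ID=%s,length=%s>",
                       layout$chromosomes$chrom[k],
                       format_bp(layout$chromosomes$length_bp[k])), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", genotypes$samples$sample_id),
                   collapse = "\t"), con)
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  calls <- genotypes$calls
  col0 <- 0L
  for (chrom in layout$chromosomes$chrom) {
    pos <- external_positions(layout, chrom)
    if (!length(pos)) next
    block <- calls[, col0 + seq_along(pos), drop = FALSE]
    col0 <- col0 + length(pos)
    gts <- matrix("./.", nrow(block), ncol(block))
    idx <- !is.na(block)
    gts[idx] <- gt_str[as.character(block[idx])]
    lines <- paste(chrom, format_bp(pos), ".", "A", "G", ".", "PASS", ".", "GT",
                   apply(gts, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
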