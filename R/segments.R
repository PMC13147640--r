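#' ROH segment tables
#'
#' Throughout the package an ROH segment set is a plain data.frame with one
#' row per homozygous run and columns:
#' \describe{
#'   \item{sample_id}{individual carrying the run}
#'   \item{chrom}{chromosome name}
#'   \item{start, end}{internal 0-based half-open bp interval; `start` is the
#'     internal position of the first SNP of the run and `end` the internal
#'     position of the last SNP plus one}
#'   \item{n_snps}{SNP sites spanned}
#'   \item{n_het, n_missing}{heterozygous / missing calls tolerated inside}
#'   \item{length_bp}{`end - start`}
#'   \item{class}{optional length class `"short"`, `"medium"`, `"long"` (`NA`
#'     until classified)}
#' }
#'
#' @param sample_id,chrom,start,end,n_snps,n_het,n_missing column vectors;
#'   `n_het`/`n_missing` default to 0, `n_snps` to `NA`.
#' @param class optional class labels.
#' @return validated segment data.frame (class `roh_segments` prepended).
#' @export
roh_segments <- function(sample_id = character(), chrom = character(),
                         start = numeric(), end = numeric(),
                         n_snps = NA_integer_, n_het = 0L, n_missing = 0L,
                         class = NA_character_) {
  n <- max(length(sample_id), length(chrom), length(start), length(end))
  if (!length(start)) n <- 0L
  df <- data.frame(
    sample_id = rep_len(as.character(sample_id), n),
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n), end = rep_len(as.numeric(end), n),
    n_snps = rep_len(as.integer(n_snps), n),
    n_het = rep_len(as.integer(n_het), n),
    n_missing = rep_len(as.integer(n_missing), n),
    stringsAsFactors = FALSE
  )
  df$length_bp <- df$end - df$start
  df$class <- rep_len(as.character(class), n)
  if (any(df$end < df$start)) stop("segment end < start")
  class(df) <- c("roh_segments", "data.frame")
  df
}

# internal: coerce/validate an external data.frame into segment form
as_roh_segments <- function(df) {
  needed <- c("sample_id", "chrom", "start", "end")
  if (!all(needed %in% names(df)))
    stop("segment table must have columns: ", paste(needed, collapse = ", "))
  roh_segments(df$sample_id, df$chrom, df$start, df$end,
               n_snps = if ("n_snps" %in% names(df)) df$n_snps else NA_integer_,
               n_het = if ("n_het" %in% names(df)) df$n_het else 0L,
               n_missing = if ("n_missing" %in% names(df)) df$n_missing else 0L,
               class = if ("class" %in% names(df)) df$class else NA_character_)
}

# internal: count SNPs of `layout` inside [start, end) on `chrom`
count_snps_in <- function(layout, chrom, start, end) {
  pos <- layout$positions[[chrom]]
  if (is.null(pos)) stop("unknown chromosome: ", chrom)
  sum(pos >= start & pos < end)
}

#' Read ROH segments from a PLINK-style .hom table or a BED file
#'
#' The `.hom` dialect is whitespace-delimited with a header and (at minimum)
#' columns `IID`, `CHR`, `POS1`, `POS2` (1-based inclusive bp), optionally
#' `NSNP`, `NHET`, `NMISS`, `CLASS`. BED input is tab-delimited, 0-based
#' half-open, with columns chrom/start/end/name where `name` carries the
#' sample id; BED rows have no SNP counts, so a `layout` is required to
#' recompute them (otherwise `n_snps` is `NA`).
#'
#' @param path file path.
#' @param dialect `"hom"` or `"bed"`.
#' @param layout optional [genome_layout()] used to validate chromosome names
#'   and recompute missing SNP counts.
#' @return segment data.frame (see [roh_segments()]), 0-based half-open.
#' @export
read_segments <- function(path, dialect = c("hom", "bed"), layout = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read ", path)
  if (dialect == "hom") {
    tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                             check.names = FALSE, comment.char = "#")
    iid <- tab[[if ("IID" %in% names(tab)) "IID" else "FID"]]
    seg <- roh_segments(
      sample_id = iid, chrom = as.character(tab$CHR),
      start = tab$POS1 - 1, end = tab$POS2,  # 1-based inclusive -> half-open
      n_snps = if ("NSNP" %in% names(tab)) tab$NSNP else NA_integer_,
      n_het = if ("NHET" %in% names(tab)) tab$NHET else 0L,
      n_missing = if ("NMISS" %in% names(tab)) tab$NMISS else 0L,
      class = if ("CLASS" %in% names(tab)) tab$CLASS else NA_character_
    )
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
    if (!length(lines)) return(roh_segments())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ncols <- lengths(parts)
    if (any(ncols < 3)) stop("malformed BED line")
    seg <- roh_segments(
      sample_id = vapply(parts, function(x) if (length(x) >= 4) x[4] else NA_character_,
                         character(1)),
      chrom = vapply(parts, `[`, character(1), 1),
      start = as.numeric(vapply(parts, `[`, character(1), 2)),
      end = as.numeric(vapply(parts, `[`, character(1), 3))
    )
  }
  if (any(seg$end < seg$start)) stop("segment end < start")
  if (!is.null(layout)) {
    unknown <- setdiff(unique(seg$chrom), layout$chromosomes$chrom)
    if (length(unknown)) stop("unknown chromosome: ", paste(unknown, collapse = ", "))
    fix <- is.na(seg$n_snps)
    if (any(fix))
      seg$n_snps[fix] <- mapply(function(ch, s, e) count_snps_in(layout, ch, s, e),
                                seg$chrom[fix], seg$start[fix], seg$end[fix])
  }
  seg
}

#' Write ROH segments as a .hom-style table or BED
#'
#' `.hom` output is 1-based inclusive (`POS1 = start + 1`, `POS2 = end`) with
#' a `KB` column (`length_bp/1000`, 3 decimals); BED output is 0-based
#' half-open with the sample id in the name column.
#'
#' @param segments segment data.frame.
#' @param path output path.
#' @param dialect `"hom"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, dialect = c("hom", "bed")) {
  dialect <- match.arg(dialect)
  segments <- as_roh_segments(segments)
  if (dialect == "hom") {
    out <- data.frame(
      FID = segments$sample_id, IID = segments$sample_id,
      CHR = segments$chrom, POS1 = format_bp(segments$start + 1),
      POS2 = format_bp(segments$end),
      KB = sprintf("%.3f", segments$length_bp / 1000),
      NSNP = segments$n_snps, NHET = segments$n_het,
      NMISS = segments$n_missing, CLASS = segments$class,
      stringsAsFactors = FALSE
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#chrom\tstart\tend\tname", con)
    if (nrow(segments))
      writeLines(paste(segments$chrom, format_bp(segments$start),
                       format_bp(segments$end), segments$sample_id,
                       sep = "\t"), con)
  }
  invisible(path)
}

# internal: integer bp rendered without scientific notation
format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)
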