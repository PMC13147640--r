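#' Binary ROH presence/absence matrix
#'
#' Recodes ROH segments as an individuals-by-regions 0/1 matrix. Regions are
#' the atomic partition of the union of all in-scope segments at every
#' distinct segment start/end breakpoint, so each individual's segment
#' either fully covers a region or misses it entirely; an entry is 1 iff an
#' in-scope segment of that individual covers the whole region.
#'
#' @param segments segment data.frame; must carry class labels when
#'   `class_scope != "total"`.
#' @param samples data.frame with `sample_id` listing the panel (rows of the
#'   matrix; individuals without segments get all-zero rows).
#' @param class_scope `"total"`, `"short"`, `"medium"` or `"long"`.
#' @return list of class `binary_roh_matrix`: `matrix` (0/1, rownames =
#'   sample ids), `regions` (data.frame `chrom`, `start`, `end`),
#'   `class_scope`, `constant_cols` (indices of columns equal across all
#'   individuals, flagged but retained).
#' @export
build_binary_matrix <- function(segments, samples,
                                class_scope = c("total", "short", "medium", "long")) {
  class_scope <- match.arg(class_scope)
  seg <- segments
  if (class_scope != "total") {
    if (all(is.na(seg$class)))
      stop("segments carry no class labels; classify first")
    seg <- seg[!is.na(seg$class) & seg$class == class_scope, , drop = FALSE]
  }
  ids <- samples$sample_id
  if (!nrow(seg)) {
    warning("no in-scope segments; empty matrix")
    return(structure(list(matrix = matrix(0L, length(ids), 0,
                                          dimnames = list(ids, NULL)),
                          regions = data.frame(chrom = character(0),
                                               start = numeric(0),
                                               end = numeric(0)),
                          class_scope = class_scope,
                          constant_cols = integer(0)),
                     class = "binary_roh_matrix"))
  }
  regions <- do.call(rbind, lapply(unique(seg$chrom), function(ch) {
    s <- seg[seg$chrom == ch, ]
    bp <- sort(unique(c(s$start, s$end)))
    cand <- data.frame(chrom = ch, start = bp[-length(bp)], end = bp[-1],
                       stringsAsFactors = FALSE)
    # keep only pieces inside the union of segments
    covered <- vapply(seq_len(nrow(cand)), function(k)
      any(s$start <= cand$start[k] & s$end >= cand$end[k]), logical(1))
    cand[covered, , drop = FALSE]
  }))
  ord <- order(match(regions$chrom, unique(seg$chrom)), regions$start)
  regions <- regions[ord, , drop = FALSE]
  rownames(regions) <- NULL
  mat <- matrix(0L, length(ids), nrow(regions), dimnames = list(ids, NULL))
  ri <- match(seg$sample_id, ids)
  for (k in seq_len(nrow(seg))) {
    hit <- regions$chrom == seg$chrom[k] & regions$start >= seg$start[k] &
      regions$end <= seg$end[k]
    mat[ri[k], hit] <- 1L
  }
  const <- which(apply(mat, 2, function(col) length(unique(col)) == 1))
  structure(list(matrix = mat, regions = regions, class_scope = class_scope,
                 constant_cols = const),
            class = "binary_roh_matrix")
}

#' PCA of a binary ROH matrix
#'
#' Columns are mean-centered (no variance scaling, since entries are segment
#' indicators rather than allele counts) and the top-k singular directions
#' are extracted. For reproducibility each component's sign is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param bmat a [build_binary_matrix()] result (or a plain numeric matrix).
#' @param k number of components (truncated with a warning if it exceeds
#'   `min(n - 1, n_regions)`).
#' @param scale. also divide columns by their standard deviation.
#' @return list of class `roh_pca`: `scores` (n x k), `loadings`,
#'   `explained` (variance fractions, descending), `k`.
#' @export
pca_binary <- function(bmat, k = 2L, scale. = FALSE) {
  m <- if (inherits(bmat, "binary_roh_matrix")) bmat$matrix else as.matrix(bmat)
  n <- nrow(m)
  if (n < 2 || ncol(m) < 1) stop("need >= 2 individuals and >= 1 region")
  kmax <- min(n - 1L, ncol(m))
  if (k > kmax) {
    warning("k truncated from ", k, " to ", kmax)
    k <- kmax
  }
  x <- scale(m, center = TRUE, scale = scale.)
  x[is.nan(x)] <- 0  # zero-variance columns under scaling
  sv <- svd(x, nu = k, nv = k)
  total_var <- sum(x^2)
  explained <- if (total_var > 0) sv$d^2 / total_var else rep(0, length(sv$d))
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(m)
  structure(list(scores = scores, loadings = loadings,
                 explained = explained[seq_len(k)], k = k),
            class = "roh_pca")
}

#' Export a binary ROH matrix for external structure tools
#'
#' Writes a transposed pseudo-genotype coding (one marker row per region,
#' one column per sample, entries 0/1) plus a region map and a sample list,
#' so external PCA/ancestry tools can consume the recoded data. Format:
#' `<prefix>.geno.tsv` (marker x sample table with `region_id` key),
#' `<prefix>.regions.tsv` (`region_id`, `chrom`, `start`, `end`),
#' `<prefix>.samples.tsv`.
#'
#' @param bmat a [build_binary_matrix()] result (non-empty).
#' @param prefix output path prefix.
#' @return character vector of the three file paths, invisibly.
#' @export
export_structure_inputs <- function(bmat, prefix) {
  stopifnot(inherits(bmat, "binary_roh_matrix"))
  if (ncol(bmat$matrix) == 0) stop("empty matrix; nothing to export")
  region_id <- sprintf("R%06d", seq_len(nrow(bmat$regions)))
  geno <- data.frame(region_id, t(bmat$matrix), check.names = FALSE)
  paths <- paste0(prefix, c(".geno.tsv", ".regions.tsv", ".samples.tsv"))
  utils::write.table(geno, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(region_id, bmat$regions), paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(bmat$matrix)), paths[3],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read back matrices written by [export_structure_inputs()]
#'
#' @param prefix path prefix used at export time.
#' @return a `binary_roh_matrix` equivalent to the exported one (constant
#'   columns re-flagged).
#' @export
read_structure_inputs <- function(prefix) {
  geno <- utils::read.table(paste0(prefix, ".geno.tsv"), header = TRUE,
                            sep = "\t", check.names = FALSE)
  regions <- utils::read.table(paste0(prefix, ".regions.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
  mat <- t(as.matrix(geno[, -1, drop = FALSE]))
  storage.mode(mat) <- "integer"
  const <- which(apply(mat, 2, function(col) length(unique(col)) == 1))
  structure(list(matrix = mat,
                 regions = regions[, c("chrom", "start", "end")],
                 class_scope = "total", constant_cols = const),
            class = "binary_roh_matrix")
}
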