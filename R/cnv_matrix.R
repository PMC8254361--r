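#' Construct a single-cell copy-number matrix
#'
#' The central data container: a cells-by-bins matrix of copy-number values
#' together with the genomic bin coordinates, unique cell identifiers and a
#' per-cell sample label. All downstream operations (filtering, distances,
#' SHscore, partition scan) take a `cnv_matrix`.
#'
#' Bin coordinates are stored 0-based half-open (`[start, end)`); the readers
#' convert from the 1-based inclusive convention used by caller output such as
#' Ginkgo's SegCopy (see [read_cnv()]). Bins must be non-overlapping within a
#' chromosome; they are sorted into genomic order on construction. Copy
#' numbers may be fractional (some callers emit non-integer states) but must
#' be non-negative and complete: missing values are refused, not imputed.
#'
#' @param values numeric matrix, cells in rows, bins in columns.
#' @param bins data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), one row per column of `values`.
#' @param cells character vector of unique cell identifiers; defaults to the
#'   rownames of `values`.
#' @param sample sample label(s): either one label applied to every cell or a
#'   vector with one label per cell.
#' @return An object of class `cnv_matrix`: a list with elements `values`
#'   (matrix with cells as rownames), `bins` (data.frame) and `sample`
#'   (character vector per cell).
#' @examples
#' m <- cnv_matrix(rbind(c1 = c(2, 2, 2), c2 = c(2, 4, 2)),
#'                 bins = data.frame(chrom = "chr1",
#'                                   start = c(0, 1e6, 2e6),
#'                                   end   = c(1e6, 2e6, 3e6)))
#' m
#' @export
cnv_matrix <- function(values, bins, cells = rownames(values), sample = "S") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cells))
    cells <- paste0("cell", seq_len(nrow(values)), recycle0 = TRUE)
  cells <- as.character(cells)
  if (length(cells) != nrow(values))
    stop("'cells' must have one entry per row of 'values'")
  if (anyDuplicated(cells))
    stop("duplicate cell identifiers: ",
         paste(unique(cells[duplicated(cells)]), collapse = ", "))
  if (anyNA(values))
    stop("missing copy-number values are not allowed (refusing to impute)")
  if (any(values < 0))
    stop("negative copy-number values are not allowed")
  bins <- validate_bins(bins, n = ncol(values))
  ord <- genomic_order(bins)
  bins <- bins[ord, , drop = FALSE]
  rownames(bins) <- NULL
  values <- values[, ord, drop = FALSE]
  rownames(values) <- cells
  colnames(values) <- bin_ids(bins)
  if (length(sample) == 1L) sample <- rep(sample, length(cells))
  if (length(sample) != length(cells))
    stop("'sample' must be a single label or one label per cell")
  structure(list(values = values, bins = bins,
                 sample = as.character(sample)),
            class = "cnv_matrix")
}

validate_bins <- function(bins, n) {
  bins <- as.data.frame(bins)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(bins)))
    stop("'bins' needs columns chrom, start, end")
  bins <- bins[need]
  bins$chrom <- as.character(bins$chrom)
  bins$start <- as.numeric(bins$start)
  bins$end <- as.numeric(bins$end)
  if (nrow(bins) != n)
    stop("number of bins (", nrow(bins), ") does not match value columns (",
         n, ")")
  if (any(is.na(bins$start)) || any(is.na(bins$end)))
    stop("bin coordinates must be numeric")
  if (any(bins$start >= bins$end))
    stop("bins must satisfy start < end")
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1L && any(b$start[-1L] < b$end[-nrow(b)]))
      stop("overlapping bins on ", ch)
  }
  bins
}

# Natural chromosome order: chr1 < chr2 < ... < chr10 < chrX; non-numeric
# names sort after numeric ones, alphabetically.
chrom_rank <- function(chrom) {
  key <- sub("^chr", "", chrom, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(key))
  rank <- ifelse(is.na(num), Inf, num)
  order(rank, key)  # not used directly; see genomic_order
  list(rank = rank, key = key)
}

genomic_order <- function(bins) {
  r <- chrom_rank(bins$chrom)
  order(r$rank, r$key, bins$start)
}

bin_ids <- function(bins) {
  paste0(bins$chrom, ":", format(bins$start + 1, scientific = FALSE,
                                 trim = TRUE),
         "-", format(bins$end, scientific = FALSE, trim = TRUE))
}

#' @export
print.cnv_matrix <- function(x, ...) {
  cat("cnv_matrix: ", nrow(x$values), " cells x ", ncol(x$values),
      " bins\n", sep = "")
  tab <- table(x$sample)
  cat("samples: ",
      paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "),
      "\n", sep = "")
  cat("chromosomes: ", paste(unique(x$bins$chrom), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.cnv_matrix <- function(object, ...) {
  v <- object$values
  cat("cnv_matrix with", nrow(v), "cells,", ncol(v), "bins,",
      length(unique(object$sample)), "sample(s)\n")
  cat("copy-number range: [", min(v), ", ", max(v), "]\n", sep = "")
  cat("per-cell ploidy (bin-length weighted):\n")
  print(summary(cell_ploidy(object)))
  invisible(object)
}

#' @export
dim.cnv_matrix <- function(x) dim(x$values)

#' Subset a copy-number matrix by cells and/or bins
#'
#' @param x a [cnv_matrix()].
#' @param cells,bins index vectors (logical, integer or cell names).
#' @return a `cnv_matrix` restricted to the requested cells/bins.
#' @export
cnv_subset <- function(x, cells = NULL, bins = NULL) {
  stopifnot(inherits(x, "cnv_matrix"))
  v <- x$values
  s <- x$sample
  b <- x$bins
  if (!is.null(cells)) {
    if (is.character(cells)) cells <- match(cells, rownames(v))
    v <- v[cells, , drop = FALSE]
    s <- s[cells]
  }
  if (!is.null(bins)) {
    v <- v[, bins, drop = FALSE]
    b <- b[bins, , drop = FALSE]
  }
  cnv_matrix(v, b, cells = rownames(v), sample = s)
}

#' Aggregate copy-number matrices from multiple samples
#'
#' Row-concatenates per-sample matrices sharing an identical bin set into one
#' multi-sample `cnv_matrix`; each cell carries the label of the matrix it
#' came from, so every downstream operation sees one matrix plus one grouping.
#'
#' @param matrices list of [cnv_matrix()] objects over identical bins.
#' @param labels unique sample label per matrix; defaults to the (single)
#'   existing label of each input.
#' @return a `cnv_matrix` with `sum(n_cells)` rows.
#' @examples
#' b <- data.frame(chrom = "chr1", start = 0, end = 1e6)
#' a <- cnv_matrix(rbind(a1 = 2, a2 = 2), b)
#' d <- cnv_matrix(rbind(d1 = 4, d2 = 4), b)
#' cnv_aggregate(list(a, d), labels = c("A", "D"))
#' @export
cnv_aggregate <- function(matrices, labels = NULL) {
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, inherits, TRUE, "cnv_matrix")))
  if (is.null(labels))
    labels <- vapply(matrices, function(m) unique(m$sample)[1L], "")
  if (length(labels) != length(matrices) || anyDuplicated(labels))
    stop("'labels' must be unique, one per matrix")
  ref <- matrices[[1L]]$bins
  for (i in seq_along(matrices)[-1L]) {
    b <- matrices[[i]]$bins
    if (nrow(b) != nrow(ref))
      stop("bin-set mismatch: matrix ", i, " has ", nrow(b),
           " bins, expected ", nrow(ref))
    diff <- which(b$chrom != ref$chrom | b$start != ref$start |
                    b$end != ref$end)
    if (length(diff))
      stop("bin-set mismatch: matrix ", i, " first differs at bin ",
           diff[1L], " (", bin_ids(b)[diff[1L]], " vs ",
           bin_ids(ref)[diff[1L]], ")")
  }
  values <- do.call(rbind, lapply(matrices, `[[`, "values"))
  sample <- rep(labels, vapply(matrices, function(m) nrow(m$values), 1L))
  if (anyDuplicated(rownames(values)))  # disambiguate colliding cell ids
    rownames(values) <- paste(sample, rownames(values), sep = ".")
  cnv_matrix(values, ref, cells = rownames(values), sample = sample)
}
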