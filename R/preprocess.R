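#' Per-cell ploidy from a copy-number profile
#'
#' Ploidy is the bin-length-weighted mean copy number of a cell, i.e. the
#' average genome copy number (about 2 for a diploid cell). When the caller
#' supplies its own ploidy estimate, pass it to [filter_cells()] directly; this
#' is the fallback computed from the matrix itself.
#'
#' @param x a [cnv_matrix()] or a numeric profile vector.
#' @param bin_lengths base pairs per bin; taken from the bins of a
#'   `cnv_matrix`, required (or assumed equal) for a bare vector.
#' @return numeric vector of ploidies, one per cell.
#' @examples
#' cell_ploidy(c(2, 4), bin_lengths = c(3e6, 1e6))  # 2.5
#' @export
cell_ploidy <- function(x, bin_lengths = NULL) {
  if (inherits(x, "cnv_matrix")) {
    if (is.null(bin_lengths)) bin_lengths <- x$bins$end - x$bins$start
    x <- x$values
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!ncol(x)) stop("empty profile")
  if (is.null(bin_lengths)) bin_lengths <- rep(1, ncol(x))
  if (all(bin_lengths == 0)) stop("all bin lengths are zero")
  drop(x %*% bin_lengths) / sum(bin_lengths)
}

#' Per-cell median absolute deviation of the copy-number profile
#'
#' The raw (unscaled) MAD, `median(|x - median(x)|)`, used as a noisiness
#' proxy: cells in S phase or with amplification artifacts show erratic
#' profiles and hence a high MAD.
#'
#' @param x a [cnv_matrix()] or a numeric profile vector.
#' @return numeric vector of MADs, one per cell.
#' @examples
#' cell_mad(c(1, 2, 3, 4, 5))  # 1
#' cell_mad(c(2, 2, 2, 10))    # 0
#' @export
cell_mad <- function(x) {
  if (inherits(x, "cnv_matrix")) x <- x$values
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!ncol(x)) stop("empty profile")
  apply(x, 1, stats::mad, constant = 1)
}

#' Filter cells by ploidy and profile noise
#'
#' Two-step filter used before heterogeneity scoring of tumor samples:
#' first remove diploid or pseudo-diploid cells, whose ploidy falls inside
#' `ploidy_interval` (closed at both ends) — such cells are uninformative
#' about tumor CNA structure; then remove cells whose profile MAD strictly
#' exceeds the `mad_percentile`-th percentile (linear interpolation between
#' order statistics) of the MADs of the cells surviving the ploidy step —
#' those profiles are considered noisy. A cell sitting exactly at the
#' percentile is kept. Set `mad_on_all = TRUE` to compute the percentile on
#' all input cells instead of the ploidy survivors.
#'
#' Note the filter is not exactly idempotent: re-filtering recomputes the MAD
#' percentile on the already-filtered population, which can trim further cells.
#'
#' @param x a [cnv_matrix()].
#' @param ploidy optional caller-supplied per-cell ploidies (take precedence
#'   over [cell_ploidy()]).
#' @param mad optional caller-supplied per-cell MADs.
#' @param ploidy_interval closed interval of ploidies to *remove*
#'   (default `c(1.6, 2.9)`).
#' @param mad_percentile percentile above which cells are removed
#'   (default 95; 100 disables the MAD step).
#' @param mad_on_all compute the MAD percentile on all cells rather than the
#'   ploidy-surviving ones.
#' @return list with `matrix` (the filtered [cnv_matrix()]) and `report`
#'   (class `filter_report`: counts per step and the thresholds used).
#' @export
filter_cells <- function(x, ploidy = NULL, mad = NULL,
                         ploidy_interval = c(1.6, 2.9),
                         mad_percentile = 95, mad_on_all = FALSE) {
  stopifnot(inherits(x, "cnv_matrix"))
  if (ploidy_interval[1] > ploidy_interval[2])
    stop("ploidy interval has low > high")
  n <- nrow(x$values)
  if (is.null(ploidy)) ploidy <- cell_ploidy(x)
  if (is.null(mad)) mad <- cell_mad(x)
  stopifnot(length(ploidy) == n, length(mad) == n)
  rm_ploidy <- ploidy >= ploidy_interval[1] & ploidy <= ploidy_interval[2]
  pool <- if (mad_on_all) mad else mad[!rm_ploidy]
  cutoff <- if (length(pool)) quantile(pool, mad_percentile / 100,
                                       names = FALSE, type = 7) else Inf
  rm_mad <- !rm_ploidy & mad > cutoff
  keep <- !rm_ploidy & !rm_mad
  report <- structure(list(n_input = n,
                           n_removed_ploidy = sum(rm_ploidy),
                           n_removed_mad = sum(rm_mad),
                           n_kept = sum(keep),
                           ploidy_interval = ploidy_interval,
                           mad_percentile = mad_percentile,
                           mad_cutoff = cutoff),
                      class = "filter_report")
  list(matrix = cnv_subset(x, cells = which(keep)), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("cell filter: ", x$n_input, " cells in, ", x$n_kept, " kept\n",
      "  removed as (pseudo-)diploid (ploidy in [",
      x$ploidy_interval[1], ", ", x$ploidy_interval[2], "]): ",
      x$n_removed_ploidy, "\n",
      "  removed as noisy (MAD > ", x$mad_percentile, "th pct = ",
      signif(x$mad_cutoff, 4), "): ", x$n_removed_mad, "\n", sep = "")
  invisible(x)
}

#' Keep the most variable genomic bins
#'
#' Retains the `n_top` bins with the highest across-cell variance, preserving
#' genomic order; ties are broken in favour of earlier genomic position.
#'
#' @param x a [cnv_matrix()].
#' @param n_top number of bins to keep (between 1 and the bin count).
#' @return a [cnv_matrix()] with `n_top` bins.
#' @export
select_variable_features <- function(x, n_top) {
  stopifnot(inherits(x, "cnv_matrix"))
  nb <- ncol(x$values)
  if (n_top < 1 || n_top > nb)
    stop("'n_top' must be between 1 and the number of bins (", nb, ")")
  v <- apply(x$values, 2, var)
  keep <- sort(order(-v, seq_len(nb))[seq_len(n_top)])
  cnv_subset(x, bins = keep)
}

#' Embed cells in a low-dimensional space
#'
#' Thin wrapper over PCA ([stats::prcomp()]) and UMAP (`uwot::umap`) for
#' visualisation and clustering. Deterministic given `seed`; rows follow the
#' cell order of the input.
#'
#' @param x a [cnv_matrix()] or numeric matrix (cells in rows).
#' @param method `"pca"` or `"umap"`.
#' @param n_components embedding dimensionality (>= 1, less than both the
#'   number of cells and of bins).
#' @param seed integer seed (used for UMAP; PCA is deterministic).
#' @return numeric matrix, cells x `n_components`, with cell rownames.
#' @export
reduce_dims <- function(x, method = c("pca", "umap"), n_components = 2,
                        seed = 1L) {
  method <- match.arg(method)
  v <- if (inherits(x, "cnv_matrix")) x$values else as.matrix(x)
  if (n_components < 1) stop("'n_components' must be >= 1")
  if (n_components >= min(dim(v)))
    stop("'n_components' must be smaller than both matrix dimensions")
  if (nrow(v) < 3) stop("too few cells to embed")
  emb <- switch(method,
    pca = prcomp(v, center = TRUE, scale. = FALSE,
                 rank. = n_components)$x[, seq_len(n_components),
                                         drop = FALSE],
    umap = {
      if (!requireNamespace("uwot", quietly = TRUE))
        stop("the 'uwot' package is required for UMAP embeddings")
      set.seed(seed)
      uwot::umap(v, n_components = n_components,
                 n_neighbors = min(15, nrow(v) - 1),
                 n_threads = 1, n_sgd_threads = 0)
    })
  emb <- as.matrix(emb)
  rownames(emb) <- rownames(v)
  colnames(emb) <- paste0(toupper(method), seq_len(n_components))
  emb
}
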