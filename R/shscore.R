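#' Spatial Heterogeneity score for a sample partition
#'
#' For every cell p with block S_p under the partition, let
#' a(p) be the mean L1 distance from p to the other cells of its own block,
#' and b(p) the minimum, over the other blocks S_k, of the mean distance from
#' p to the cells of S_k. The per-cell score is
#' sh(p) = (b(p) - a(p)) / max(a(p), b(p)), in \[-1, 1\], and the SHscore is
#' the plain mean of sh(p) over all cells of the dataset (unbalanced samples
#' therefore weight the score by their cell counts). These are exactly the
#' quantities of the silhouette index, with sample-blocks as clusters and L1
#' distances; a score near 1 flags internally homogeneous, mutually
#' segregated samples, a score near 0 well-mixed ones, and 0.2 is the
#' conventional annotation threshold between the two readings.
#'
#' Conventions: a cell alone in its block gets sh(p) = 0 (standard silhouette
#' convention), as does a cell with a(p) = b(p) = 0 (exact duplicates across
#' blocks). Scores are computed on the full bin set as given; apply
#' [select_variable_features()] upstream if feature selection is wanted.
#'
#' @param x a [cnv_matrix()] holding the aggregated samples.
#' @param partition a [sample_partition()], or a list of character vectors of
#'   sample labels. Defaults to one block per sample.
#' @param D optional precomputed distance matrix from [cnv_dist()] (reused
#'   across partitions by [sh_scan()]).
#' @return object of class `sh_result`: list with `score`, `per_cell_sh`
#'   (named per cell), `partition`, `n_cells`.
#' @examples
#' b <- data.frame(chrom = "chr1", start = 0, end = 1e6)
#' m <- cnv_matrix(rbind(a1 = 2, a2 = 2, b1 = 4, b2 = 4), b,
#'                 sample = c("A", "A", "B", "B"))
#' shscore(m)  # perfectly separated duplicates: score 1
#' @export
shscore <- function(x, partition = NULL, D = NULL) {
  stopifnot(inherits(x, "cnv_matrix"))
  if (is.null(partition))
    partition <- sample_partition(as.list(unique(x$sample)))
  if (!inherits(partition, "sample_partition"))
    partition <- sample_partition(partition)
  blk <- partition_blocks_of(partition, x$sample)
  if (is.null(D)) D <- cnv_dist(x)
  sh <- silhouette_values(D, blk)
  names(sh) <- rownames(x$values)
  structure(list(score = mean(sh), per_cell_sh = sh, partition = partition,
                 n_cells = length(sh)),
            class = "sh_result")
}

# Silhouette widths from a dense distance matrix and integer block labels.
# Vectorised: D %*% indicator gives the per-block distance sums per cell.
silhouette_values <- function(D, blk) {
  n <- nrow(D)
  k <- max(blk)
  G <- matrix(0, n, k)
  G[cbind(seq_len(n), blk)] <- 1
  sums <- D %*% G                      # n x k: sum of d(p, q) for q in block
  sizes <- colSums(G)
  own <- sums[cbind(seq_len(n), blk)]
  a <- own / (sizes[blk] - 1)          # NaN/Inf for singleton blocks
  means <- sweep(sums, 2, sizes, "/")
  means[cbind(seq_len(n), blk)] <- Inf
  b <- do.call(pmin, as.data.frame(means))
  sh <- (b - a) / pmax(a, b)
  sh[sizes[blk] == 1L] <- 0            # singleton-block convention
  sh[is.nan(sh)] <- 0                  # a = b = 0: duplicates across blocks
  sh
}

#' @export
print.sh_result <- function(x, ...) {
  cat("SHscore: ", format(x$score, digits = 4), "  (", x$n_cells,
      " cells; partition: ", x$partition$name, ")\n", sep = "")
  cat(if (x$score >= 0.2)
    "  >= 0.2: samples separated by non-negligible evolutionary distance\n"
    else
      "  < 0.2: subclones well-mixed or spatial differences negligible\n")
  invisible(x)
}

#' @export
summary.sh_result <- function(object, ...) {
  print(object)
  cat("per-cell sh(p):\n")
  print(summary(object$per_cell_sh))
  invisible(object)
}
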