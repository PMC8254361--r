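#' Pairwise Manhattan distances between cells
#'
#' Computes the full cell-by-cell distance matrix d(p, q) = sum over bins of
#' |CN_p - CN_q|. The L1 norm is used deliberately: in high dimension it
#' discriminates near from far neighbours better than Euclidean distance, and
#' copy-number profiles routinely span thousands of bins. The computation is
#' exact (no approximate neighbours) and the dense matrix is materialised
#' once, then reused across all partitions of a scan.
#'
#' @param x a [cnv_matrix()] or numeric matrix (cells in rows).
#' @param metric distance metric; only `"l1"` (Manhattan) is supported.
#' @return symmetric numeric matrix with zero diagonal and cell ids as
#'   dimnames, with attribute `metric`.
#' @examples
#' m <- rbind(a = c(2, 3), b = c(4, 1))
#' cnv_dist(m)  # d(a, b) = 4
#' @export
cnv_dist <- function(x, metric = "l1") {
  if (!identical(metric, "l1"))
    stop("unsupported metric '", metric, "': only \"l1\" is available")
  v <- if (inherits(x, "cnv_matrix")) x$values else as.matrix(x)
  if (nrow(v) < 2) stop("need at least 2 cells to compute distances")
  storage.mode(v) <- "double"
  D <- .l1_dist_cpp(v)
  dimnames(D) <- list(rownames(v), rownames(v))
  attr(D, "metric") <- "l1"
  D
}
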