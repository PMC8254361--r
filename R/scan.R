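#' Scan all sample partitions for the most divergent grouping
#'
#' Enumerates every partition of the samples of an aggregated dataset into
#' >= 2 blocks (see [enumerate_partitions()]), computes the SHscore of each on
#' a single shared distance matrix, and reports them sorted by decreasing
#' score; ties are broken by fewer blocks, then canonical name. The
#' best-scoring partition identifies which samples behave as one population
#' and which stand apart: a high score for "S2+S3 vs S1" with a low
#' all-separate score means S2 and S3 are alike and S1 divergent.
#'
#' @param x a [cnv_matrix()] with >= 2 samples.
#' @param max_samples,allow_large enumeration cap, as in
#'   [enumerate_partitions()].
#' @return object of class `sh_scan`: list with `table` (data.frame:
#'   `partition`, `n_blocks`, `score`, sorted), `best` (the [shscore()]
#'   result of the top partition), `partitions` (the enumerated list) and
#'   `n_cells`.
#' @export
sh_scan <- function(x, max_samples = 6, allow_large = FALSE) {
  stopifnot(inherits(x, "cnv_matrix"))
  samples <- unique(x$sample)
  if (length(samples) < 2) stop("need >= 2 samples to scan partitions")
  parts <- enumerate_partitions(samples, max_samples = max_samples,
                                allow_large = allow_large)
  D <- cnv_dist(x)
  scores <- vapply(parts, function(p) shscore(x, p, D = D)$score, 0)
  nblk <- vapply(parts, function(p) length(p$blocks), 1L)
  nm <- vapply(parts, `[[`, "", "name")
  ord <- order(-scores, nblk, nm)
  tab <- data.frame(partition = nm[ord], n_blocks = nblk[ord],
                    score = scores[ord], stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 best = shscore(x, parts[[ord[1L]]], D = D),
                 partitions = parts[ord],
                 n_cells = nrow(x$values)),
            class = "sh_scan")
}

#' @export
print.sh_scan <- function(x, n = 10, ...) {
  cat("partition scan over", x$n_cells, "cells,",
      nrow(x$table), "partitions\n")
  print(head(transform(x$table, score = round(score, 4)), n))
  if (nrow(x$table) > n) cat("... (", nrow(x$table) - n, " more)\n", sep = "")
  cat("best:", x$table$partition[1L], "\n")
  invisible(x)
}

#' @export
summary.sh_scan <- function(object, ...) {
  print(object, n = nrow(object$table))
  invisible(object)
}

#' @describeIn sh_scan barplot of partition scores with the 0.2 annotation
#'   threshold.
#' @param n show only the top `n` partitions.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.sh_scan <- function(x, n = 15, ...) {
  tab <- head(x$table, n)
  op <- par(mar = c(4, 14, 2, 1))
  on.exit(par(op))
  barplot(rev(tab$score), names.arg = rev(tab$partition), horiz = TRUE,
          las = 1, cex.names = 0.7, xlab = "SHscore",
          main = "sample partition scan", ...)
  abline(v = 0.2, lty = 2, col = "grey40")
  invisible(x)
}

#' Aggregated copy-number heatmap with sample-labelled dendrogram
#'
#' Hierarchically clusters the cells of an aggregated dataset on the same L1
#' distance matrix used by the SHscore and draws a heatmap whose rows (cells)
#' carry a colour bar encoding the sample of origin, so one can see whether
#' cells from different samples segregate into different branches or mix.
#' Uses `pheatmap` when installed, otherwise a base-graphics fallback.
#'
#' @param x a [cnv_matrix()].
#' @param linkage `"ward"` (mapped to `hclust`'s `"ward.D2"`), `"average"`
#'   or `"complete"`.
#' @param file optional path; when given, the figure is written as PNG.
#' @param D optional precomputed [cnv_dist()] matrix.
#' @return invisibly, a list with the `hclust` object and the dendrogram
#'   leaf `order` (cell indices).
#' @export
cnv_heatmap <- function(x, linkage = c("ward", "average", "complete"),
                        file = NULL, D = NULL) {
  stopifnot(inherits(x, "cnv_matrix"))
  linkage <- match.arg(linkage)
  if (is.null(D)) D <- cnv_dist(x)
  hc <- hclust(as.dist(D),
               method = c(ward = "ward.D2", average = "average",
                          complete = "complete")[[linkage]])
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    ann <- data.frame(sample = x$sample, row.names = rownames(x$values))
    pheatmap::pheatmap(x$values, cluster_rows = hc, cluster_cols = FALSE,
                       annotation_row = ann, show_rownames = FALSE,
                       show_colnames = FALSE,
                       color = hcl.colors(50, "Blue-Red 2"),
                       main = "aggregated copy-number heatmap")
  } else {
    image(t(x$values[hc$order, , drop = FALSE]),
          col = hcl.colors(50, "Blue-Red 2"), axes = FALSE,
          xlab = "genomic bins", ylab = "cells (clustered)")
  }
  invisible(list(hclust = hc, order = hc$order))
}
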