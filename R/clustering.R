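#' Cluster cells with a standard algorithm
#'
#' Uniform wrapper over established clustering implementations, returning a
#' provenance-carrying result object. Supported methods: `"kmeans"`
#' ([stats::kmeans()]), `"hierarchical"` ([stats::hclust()] on L1 distances,
#' cut at `k`), `"spectral"` (`kernlab::specc`) and `"gmm"`
#' (`mclust::Mclust` Gaussian mixtures). Stochastic methods are made
#' deterministic by `seed`.
#'
#' @param x a [cnv_matrix()], embedding or numeric matrix (cells in rows).
#' @param method clustering algorithm name.
#' @param k number of clusters (required by all supported methods).
#' @param seed integer seed for stochastic methods.
#' @param linkage linkage for `"hierarchical"` (as in [cnv_heatmap()]).
#' @param ... further arguments passed to the backend.
#' @return object of class `cluster_result`: list with `labels` (integer per
#'   cell), `method`, `params`, `seed`.
#' @export
cluster_cells <- function(x, method = c("kmeans", "hierarchical",
                                        "spectral", "gmm"),
                          k = 2, seed = 1L, linkage = "ward", ...) {
  method <- tryCatch(match.arg(method),
                     error = function(e)
                       stop("unknown clustering method '", method[1L],
                            "'; supported: kmeans, hierarchical, spectral, ",
                            "gmm", call. = FALSE))
  v <- if (inherits(x, "cnv_matrix")) x$values else as.matrix(x)
  if (k < 1 || k > nrow(v)) stop("'k' out of range")
  set.seed(seed)
  labels <- switch(method,
    kmeans = kmeans(v, centers = k, nstart = 10, ...)$cluster,
    hierarchical = {
      hc <- hclust(as.dist(cnv_dist(v)),
                   method = c(ward = "ward.D2", average = "average",
                              complete = "complete")[[linkage]])
      cutree(hc, k = k)
    },
    spectral = {
      # specc's automatic kernel-width search occasionally lands on an
      # empty k-means cluster; retry with a fixed median-heuristic width
      res <- tryCatch(kernlab::specc(v, centers = k, ...),
                      error = function(e) NULL)
      if (is.null(res)) {
        sigma <- 1 / (2 * stats::median(dist(v))^2)
        set.seed(seed)
        res <- kernlab::specc(v, centers = k, kpar = list(sigma = sigma),
                              ...)
      }
      as.integer(res)
    },
    gmm = {
      mclustBIC <- mclust::mclustBIC  # Mclust() resolves this by name
      mclust::Mclust(v, G = k, verbose = FALSE, ...)$classification
    })
  structure(list(labels = as.integer(unname(labels)), method = method,
                 params = c(list(k = k, ...),
                            if (method == "hierarchical")
                              list(linkage = linkage)),
                 seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("clustering by ", x$method, " (k = ", x$params$k, ", seed = ",
      x$seed, "): ", length(unique(x$labels)), " clusters over ",
      length(x$labels), " cells\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Evaluate a clustering
#'
#' Internal metrics (need the data): `"silhouette"` (mean silhouette width on
#' L1 distances, via `cluster::silhouette`), `"davies_bouldin"` (lower is
#' better), `"calinski_harabasz"` (higher is better). External metrics (need
#' the true labels): `"ari"` (adjusted Rand index, via
#' `mclust::adjustedRandIndex`), `"v_measure"`, `"fowlkes_mallows"`,
#' `"mutual_information"` (in nats). All external metrics are invariant to
#' relabelling of cluster ids.
#'
#' @param labels integer/factor cluster assignment (or a `cluster_result`).
#' @param truth reference labels, for external metrics.
#' @param data the clustered data (matrix or [cnv_matrix()]), for internal
#'   metrics.
#' @param metric metric name (see above).
#' @return a single numeric score.
#' @export
evaluate_clustering <- function(labels, truth = NULL, data = NULL,
                                metric = c("silhouette", "davies_bouldin",
                                           "calinski_harabasz", "ari",
                                           "v_measure", "fowlkes_mallows",
                                           "mutual_information")) {
  metric <- match.arg(metric)
  if (inherits(labels, "cluster_result")) labels <- labels$labels
  labels <- as.integer(factor(labels))
  internal <- metric %in% c("silhouette", "davies_bouldin",
                            "calinski_harabasz")
  if (internal) {
    if (is.null(data)) stop("metric '", metric, "' requires 'data'")
    v <- if (inherits(data, "cnv_matrix")) data$values else as.matrix(data)
    if (length(unique(labels)) < 2)
      stop("internal metrics are undefined for a single cluster")
    switch(metric,
      silhouette = mean(cluster::silhouette(labels,
                                            dist(v, method = "manhattan"))[, 3]),
      davies_bouldin = davies_bouldin(v, labels),
      calinski_harabasz = calinski_harabasz(v, labels))
  } else {
    if (is.null(truth)) stop("metric '", metric, "' requires 'truth'")
    truth <- as.integer(factor(truth))
    if (length(truth) != length(labels))
      stop("'labels' and 'truth' differ in length")
    switch(metric,
      ari = mclust::adjustedRandIndex(labels, truth),
      v_measure = v_measure(labels, truth),
      fowlkes_mallows = fowlkes_mallows(labels, truth),
      mutual_information = mutual_information(labels, truth))
  }
}

# Davies-Bouldin index with centroid (Euclidean) dispersion, the textbook
# definition.
davies_bouldin <- function(v, labels) {
  ks <- sort(unique(labels))
  cent <- t(vapply(ks, function(k) colMeans(v[labels == k, , drop = FALSE]),
                   numeric(ncol(v))))
  s <- vapply(seq_along(ks), function(i) {
    rows <- v[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(rows, 2, cent[i, ])^2)))
  }, 0)
  m <- as.matrix(dist(cent))
  r <- vapply(seq_along(ks), function(i) {
    max(vapply(seq_along(ks)[-i], function(j) (s[i] + s[j]) / m[i, j], 0))
  }, 0)
  mean(r)
}

calinski_harabasz <- function(v, labels) {
  n <- nrow(v)
  ks <- sort(unique(labels))
  k <- length(ks)
  gmean <- colMeans(v)
  ssb <- 0
  ssw <- 0
  for (g in ks) {
    rows <- v[labels == g, , drop = FALSE]
    cm <- colMeans(rows)
    ssb <- ssb + nrow(rows) * sum((cm - gmean)^2)
    ssw <- ssw + sum(sweep(rows, 2, cm)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

mutual_information <- function(labels, truth) {
  tab <- table(labels, truth) / length(labels)
  hx <- entropy_nats(rowSums(tab))
  hy <- entropy_nats(colSums(tab))
  hxy <- entropy_nats(as.vector(tab))
  hx + hy - hxy
}

v_measure <- function(labels, truth) {
  tab <- table(labels, truth) / length(labels)
  hc <- entropy_nats(colSums(tab))   # entropy of classes (truth)
  hk <- entropy_nats(rowSums(tab))   # entropy of clusters
  mi <- hc + hk - entropy_nats(as.vector(tab))
  homogeneity <- if (hc == 0) 1 else mi / hc
  completeness <- if (hk == 0) 1 else mi / hk
  if (homogeneity + completeness == 0) 0 else
    2 * homogeneity * completeness / (homogeneity + completeness)
}

fowlkes_mallows <- function(labels, truth) {
  tab <- table(labels, truth)
  tk <- sum(tab^2) - length(labels)          # 2 * pairs together in both
  pk <- sum(rowSums(tab)^2) - length(labels) # 2 * pairs together in labels
  qk <- sum(colSums(tab)^2) - length(labels) # 2 * pairs together in truth
  if (pk == 0 || qk == 0) return(0)
  tk / sqrt(pk * qk)
}
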