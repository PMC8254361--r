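# Fixtures are built in code: small copy-number matrices with known
# structure, used across the unit tests.

toy_bins <- function(n = 3, chrom = "chr1", width = 1e6) {
  data.frame(chrom = chrom, start = (seq_len(n) - 1) * width,
             end = seq_len(n) * width)
}

# The 3-bin x 2-cell table used for round-trip and identity checks.
toy_matrix <- function() {
  cnv_matrix(rbind(cellA = c(2, 2, 2), cellB = c(2, 4, 2)), toy_bins(3),
             sample = "T")
}

# Two internally-duplicated clones at L1 distance `gap` per bin.
separated_clones <- function(n_per = 5, n_bins = 10, gap = 2,
                             labels = c("A", "B")) {
  a <- matrix(2, n_per, n_bins)
  b <- matrix(2 + gap, n_per, n_bins)
  rownames(a) <- paste0("a", seq_len(n_per))
  rownames(b) <- paste0("b", seq_len(n_per))
  cnv_matrix(rbind(a, b), toy_bins(n_bins),
             sample = rep(labels, each = n_per))
}

# Random integer copy-number matrix (uniform states 0..6).
random_cnv <- function(n_cells, n_bins, seed, samples = "S") {
  set.seed(seed)
  v <- matrix(sample(0:6, n_cells * n_bins, replace = TRUE), n_cells)
  rownames(v) <- paste0("c", seq_len(n_cells))
  cnv_matrix(v, toy_bins(n_bins),
             sample = rep_len(samples, n_cells))
}

# Brute-force silhouette with L1 distances: the independent oracle for the
# SHscore (explicit double loops, no shared code with the implementation).
oracle_shscore <- function(values, sample_labels) {
  n <- nrow(values)
  d <- function(i, j) sum(abs(values[i, ] - values[j, ]))
  sh <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(sample_labels == sample_labels[i]), i)
    if (!length(own)) { sh[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), 0))
    b <- Inf
    for (g in setdiff(unique(sample_labels), sample_labels[i])) {
      mem <- which(sample_labels == g)
      b <- min(b, mean(vapply(mem, function(j) d(i, j), 0)))
    }
    sh[i] <- if (a == 0 && b == 0) 0 else (b - a) / max(a, b)
  }
  list(score = mean(sh), per_cell_sh = sh)
}
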