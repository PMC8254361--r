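# Seeded, scripted drivers for the simulation experiments that validate the
# SHscore. Each returns an `experiment_report`: the per-replicate scores, a
# summary (min / max / median / IQR per scenario), the relevant test
# statistics, and the exact configuration + seeds, so every report is
# reproducible bitwise from (config, seed).

experiment_report <- function(scenario, data, tests, config, seed) {
  by <- if ("scenario" %in% names(data)) data$scenario else
    rep(scenario, nrow(data))
  summ <- do.call(rbind, lapply(split(data$score, by), function(s) {
    data.frame(n = length(s), min = min(s), max = max(s),
               median = median(s), IQR = stats::IQR(s))
  }))
  summ <- cbind(scenario = rownames(summ), summ)
  rownames(summ) <- NULL
  structure(list(scenario = scenario, data = data, summary = summ,
                 tests = tests, config = config, seed = seed),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment:", x$scenario, "(seed", x$seed, ")\n")
  print(transform(x$summary, min = round(min, 4), max = round(max, 4),
                  median = round(median, 4), IQR = round(IQR, 4)))
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    cat(nm, ": ", paste(names(t), signif(unlist(t), 4), sep = " = ",
                        collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Mean silhouette of an integer grouping on a precomputed distance matrix.
score_grouping <- function(D, labels) {
  mean(silhouette_values(D, as.integer(factor(labels))))
}

derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Two-sided Mann-Whitney U (a.k.a. unpaired Wilcoxon rank-sum): exact for
# groups of <= 20, normal approximation above.
mann_whitney <- function(x, y) {
  wilcox.test(x, y, exact = max(length(x), length(y)) <= 20,
              correct = TRUE)$p.value
}

#' Regional-subsampling experiment (segregated vs intermixed subclones)
#'
#' For each replicate, grows a tree, scores the founder-progeny (hom,
#' spatially segregated) and the random-shuffle (het, spatially intermixed)
#' five-way groupings of the same leaves on one shared distance matrix, and
#' compares the two score distributions with a two-sided Mann-Whitney U test.
#' Segregation should yield clearly positive scores; intermixing scores
#' tightly around zero.
#'
#' @param replicates number of simulated trees.
#' @param n_leaves leaves per tree.
#' @param k number of samples/founders.
#' @param seed integer seed.
#' @param genome,bin_size as in [sim_config()].
#' @return an `experiment_report`; `data` has one row per (replicate,
#'   scenario in hom/het).
#' @export
run_regional <- function(replicates = 20, n_leaves = 1000, k = 5, seed = 1L,
                         genome = "reduced", bin_size = NULL) {
  seeds <- derive_seeds(seed, 2L * replicates)
  rows <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    cfg <- sim_config(n_leaves, genome = genome, bin_size = bin_size,
                      seed = seeds[i])
    tree <- simulate_tree(cfg)
    D <- cnv_dist(node_states(tree))
    hom <- score_grouping(D, scenario_hom(tree, k))
    het <- score_grouping(D, scenario_het(tree, k,
                                          seed = seeds[replicates + i]))
    rows[[i]] <- data.frame(replicate = i,
                            scenario = c("hom", "het"),
                            score = c(hom, het))
  }
  data <- do.call(rbind, rows)
  hom <- data$score[data$scenario == "hom"]
  het <- data$score[data$scenario == "het"]
  experiment_report("regional", data,
                    tests = list(mann_whitney = list(
                      p_value = mann_whitney(hom, het))),
                    config = list(replicates = replicates,
                                  n_leaves = n_leaves, k = k,
                                  genome = genome),
                    seed = seed)
}

#' Metastasis-seeding experiment (early vs late spreading)
#'
#' Simulates primary/metastasis pairs seeded early (1/4 of final cell count)
#' and late (3/4), scores each pair as a two-sample dataset and compares the
#' early and late score distributions. A later seed leaves the metastasis
#' less time to diverge on its own but a more private primary history, which
#' shifts scores upward.
#'
#' @param replicates pairs per scenario.
#' @param n_leaves_each leaves per tree (default 500).
#' @param seed integer seed.
#' @param genome,bin_size as in [sim_config()].
#' @return an `experiment_report` with scenarios `"early"` and `"late"`.
#' @export
run_metastasis <- function(replicates = 20, n_leaves_each = 500, seed = 1L,
                           genome = "reduced", bin_size = NULL) {
  seeds <- derive_seeds(seed, 2L * replicates)
  rows <- vector("list", 2L * replicates)
  for (i in seq_len(replicates)) {
    for (sc in c("early", "late")) {
      cfg <- sim_config(n_leaves_each, genome = genome, bin_size = bin_size,
                        seed = seeds[if (sc == "early") i else
                          replicates + i])
      res <- scenario_metastasis(cfg,
                                 seed_point = if (sc == "early") 0.25
                                 else 0.75,
                                 n_leaves_each = n_leaves_each)
      rows[[(i - 1L) * 2L + (sc == "late") + 1L]] <-
        data.frame(replicate = i, scenario = sc,
                   score = shscore(res$pooled)$score)
    }
  }
  data <- do.call(rbind, rows)
  early <- data$score[data$scenario == "early"]
  late <- data$score[data$scenario == "late"]
  experiment_report("metastasis", data,
                    tests = list(mann_whitney = list(
                      p_value = mann_whitney(early, late))),
                    config = list(replicates = replicates,
                                  n_leaves_each = n_leaves_each,
                                  genome = genome),
                    seed = seed)
}

#' Parameter-independence experiment
#'
#' Replicates draw the expected event size theta ~ U\[500, 5e6\] bp and the
#' copy-gain parameter ~ U\[0.1, 0.9\], simulate a root-split sample pair
#' ([scenario_var()]) and record its SHscore; Pearson correlation tests
#' check that the score does not track either parameter.
#'
#' @param replicates number of simulated pairs.
#' @param seed integer seed.
#' @param n_leaves leaves per tree.
#' @param genome,bin_size as in [sim_config()].
#' @return an `experiment_report`; `data` has columns `theta`, `gain_p`,
#'   `score`; `tests` the two Pearson results.
#' @export
run_var <- function(replicates = 50, seed = 1L, n_leaves = 1000,
                    genome = "reduced", bin_size = NULL) {
  seeds <- derive_seeds(seed, replicates)
  rows <- lapply(seq_len(replicates), function(i) {
    v <- scenario_var(seeds[i], n_leaves = n_leaves, genome = genome,
                      bin_size = bin_size)
    data.frame(replicate = i, theta = v$theta, gain_p = v$gain_p,
               score = shscore(v$pooled)$score)
  })
  data <- do.call(rbind, rows)
  ct_t <- cor.test(data$theta, data$score)
  ct_p <- cor.test(data$gain_p, data$score)
  experiment_report("var", data,
                    tests = list(
                      pearson_theta = list(r = unname(ct_t$estimate),
                                           p_value = ct_t$p.value),
                      pearson_gain_p = list(r = unname(ct_p$estimate),
                                            p_value = ct_p$p.value)),
                    config = list(replicates = replicates,
                                  n_leaves = n_leaves, genome = genome),
                    seed = seed)
}

#' Evolutionary-distance experiment on one deep tree
#'
#' Grows a single deep tree, tracks the subtrees of the first `first_k`
#' generated cells as fully segregated samples (IQR-filtered to balance
#' cardinalities), scores sample pairs and computes the Pearson correlation
#' between each pair's SHscore and the edge distance between its founder
#' cells (the samples' MRCAs). The score should rise with MRCA distance.
#'
#' @param total_leaves leaves of the deep tree.
#' @param first_k founders tracked.
#' @param n_pairs_scored number of pairs to score (`NULL` = all).
#' @param seed integer seed.
#' @param genome,bin_size as in [sim_config()].
#' @return an `experiment_report`; `data` has one row per scored pair with
#'   `founder_a`, `founder_b`, `mrca_distance`, `score`.
#' @export
run_deep <- function(total_leaves = 10000, first_k = 20,
                     n_pairs_scored = NULL, seed = 1L, genome = "reduced",
                     bin_size = NULL) {
  seeds <- derive_seeds(seed, 2L)
  cfg <- sim_config(total_leaves, genome = genome, bin_size = bin_size,
                    seed = seeds[1L])
  tree <- simulate_tree(cfg)
  samples <- subtree_samples(tree, first_k, iqr_filter = TRUE)
  if (length(samples) < 2) stop("fewer than 2 samples retained")
  pairs <- combn(length(samples), 2)
  if (!is.null(n_pairs_scored) && n_pairs_scored < ncol(pairs)) {
    set.seed(seeds[2L])
    pairs <- pairs[, sample.int(ncol(pairs), n_pairs_scored), drop = FALSE]
  }
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- samples[[pairs[1, j]]]
    b <- samples[[pairs[2, j]]]
    pooled <- cnv_aggregate(list(a$matrix, b$matrix))
    data.frame(founder_a = a$founder, founder_b = b$founder,
               mrca_distance = mrca_distance(tree, a$founder, b$founder),
               score = shscore(pooled)$score)
  })
  data <- do.call(rbind, rows)
  ct <- cor.test(data$mrca_distance, data$score)
  experiment_report("deep", data,
                    tests = list(pearson_mrca = list(
                      r = unname(ct$estimate), p_value = ct$p.value)),
                    config = list(total_leaves = total_leaves,
                                  first_k = first_k,
                                  n_samples = length(samples),
                                  genome = genome),
                    seed = seed)
}

#' Downsampling-robustness experiment
#'
#' Scores a fixed two-sample comparison while randomly downsampling the
#' first sample to each requested fraction of its cells, several draws per
#' fraction. A robust score should move little across fractions and draws.
#'
#' @param sample_a,sample_b single-sample [cnv_matrix()] objects over the
#'   same bins.
#' @param fractions fractions of `sample_a` cells to keep.
#' @param draws random draws per fraction.
#' @param seed integer seed.
#' @return an `experiment_report`; `data` has one row per (fraction, draw);
#'   the summary is per fraction.
#' @export
run_downsampling <- function(sample_a, sample_b,
                             fractions = c(0.25, 0.5, 0.75, 1),
                             draws = 10, seed = 1L) {
  stopifnot(inherits(sample_a, "cnv_matrix"), inherits(sample_b, "cnv_matrix"))
  seeds <- derive_seeds(seed, length(fractions) * draws)
  n_a <- nrow(sample_a$values)
  rows <- list()
  idx <- 0L
  for (f in fractions) {
    for (d in seq_len(draws)) {
      idx <- idx + 1L
      set.seed(seeds[idx])
      keep <- sort(sample.int(n_a, max(2L, round(f * n_a))))
      pooled <- cnv_aggregate(list(cnv_subset(sample_a, cells = keep),
                                   sample_b),
                              labels = c("A", "B"))
      rows[[idx]] <- data.frame(scenario = paste0("fraction_", f),
                                fraction = f, draw = d,
                                score = shscore(pooled)$score)
    }
  }
  data <- do.call(rbind, rows)
  experiment_report("downsampling", data, tests = list(),
                    config = list(fractions = fractions, draws = draws),
                    seed = seed)
}
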