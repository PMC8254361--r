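test_that("configuration is validated", {
  expect_s3_class(sim_config(10), "sim_config")
  expect_error(sim_config(1), "n_leaves")
  expect_error(sim_config(10, gain_p = 0), "gain_p")
  expect_error(sim_config(10, gain_p = 1.5), "gain_p")
  expect_error(sim_config(10, theta = 1e12), "infeasible")
  expect_error(sim_config(10, split_shape = -1), "positive")
})

test_that("trees have the forced node counts and are seed-reproducible", {
  cfg <- sim_config(2, seed = 1)
  tr <- simulate_tree(cfg)
  expect_identical(tr$leaves, c(2L, 3L))       # root with two leaf children
  expect_identical(tr$parent[2:3], c(1L, 1L))

  cfg50 <- sim_config(50, seed = 2)
  t1 <- simulate_tree(cfg50)
  expect_length(t1$leaves, 50)
  expect_length(t1$parent, 99)                 # 49 internal + 50 leaves
  t2 <- simulate_tree(cfg50)
  expect_identical(leaves_to_matrix(t1)$values, leaves_to_matrix(t2)$values)
  expect_identical(t1$divided_at, t2$divided_at)
  # beta-split propensities also reproducible
  cfgb <- sim_config(30, seed = 3, split_shape = 0.5)
  expect_identical(simulate_tree(cfgb)$divided_at,
                   simulate_tree(cfgb)$divided_at)
})

test_that("event sizes and copy changes follow their stated distributions", {
  # theta far below the chromosome length so truncation is negligible
  cfg <- sim_config(10, theta = 1e5, gain_p = 0.4, seed = 4)
  ev <- draw_cna_events(cfg, 1e5)
  expect_lt(abs(mean(ev$end - ev$start) - cfg$theta) / cfg$theta, 0.05)
  expect_lt(abs(mean(abs(ev$delta)) - 1 / cfg$gain_p) * cfg$gain_p, 0.05)
  expect_true(all(ev$end - ev$start >= 1))
  expect_true(all(ev$end <= cfg$genome[ev$chrom]))
  # loss fraction
  expect_lt(abs(mean(ev$delta < 0) - cfg$loss_fraction), 0.01)
})

test_that("events change exactly the overlapped bins with a CN floor", {
  bins <- toy_bins(5, width = 1e6)
  state <- c(2, 2, 2, 2, 2)
  up <- apply_event(state, bins,
                    list(chrom = "chr1", start = 1.5e6, end = 3.2e6,
                         delta = 2))
  expect_equal(up, c(2, 4, 4, 4, 2))
  down <- apply_event(state, bins,
                      list(chrom = "chr1", start = 0, end = 2e6, delta = -3))
  expect_equal(down, c(0, 0, 2, 2, 2))       # floored at 0, not -1
  dead <- apply_event(c(0, 0, 2, 2, 2), bins,
                      list(chrom = "chr1", start = 0, end = 2e6, delta = 2))
  expect_equal(dead, c(0, 0, 2, 2, 2))       # deleted DNA cannot re-amplify
  expect_error(apply_event(state, bins,
                           list(chrom = "chr9", start = 0, end = 1,
                                delta = 1)), "unknown chromosome")
  expect_error(apply_event(state, bins,
                           list(chrom = "chr1", start = 0, end = 9e6,
                                delta = 1)), "outside")
})

test_that("every leaf state equals the root state plus its path events", {
  cfg <- sim_config(40, theta = 5e6, seed = 6)
  tr <- simulate_tree(cfg)
  m <- leaves_to_matrix(tr)
  kids <- spathet:::tree_children(tr)
  for (leaf in sample(tr$leaves, 5)) {
    # replay the root-to-leaf path with the public single-event API
    path <- leaf
    v <- leaf
    while (v != 1L) { v <- tr$parent[v]; path <- c(v, path) }
    state <- tr$root_state
    for (node in path[-1]) {
      ev <- tr$events[[node]]
      if (!is.null(ev)) for (r in seq_len(nrow(ev)))
        state <- apply_event(state, tr$bins,
                             list(chrom = names(cfg$genome)[ev[r, 1]],
                                  start = ev[r, 2], end = ev[r, 3],
                                  delta = ev[r, 4]))
      }
    expect_equal(unname(m$values[paste0("cell", leaf), ]), state)
  }
})

test_that("an event-free tree exports an all-diploid matrix with full bins", {
  cfg <- sim_config(8, events_per_division = 0, theta = 2e5, seed = 7,
                    genome = c(chrA = 1.05e6, chrB = 5e5), bin_size = 2e5)
  m <- leaves_to_matrix(simulate_tree(cfg))
  expect_true(all(m$values == 2))
  expect_equal(ncol(m$values), ceiling(1.05e6 / 2e5) + ceiling(5e5 / 2e5))
  expect_equal(nrow(m$values), 8)
})

test_that("founder-progeny groupings partition the leaves", {
  cfg <- sim_config(200, seed = 8)
  tr <- simulate_tree(cfg)
  hom <- scenario_hom(tr, 5)
  expect_length(hom, 200)
  expect_setequal(unique(hom), paste0("S", 1:5))
  expect_equal(sum(table(hom)), 200)
  # k = 2 splits at the root: founders are the root's two children
  hom2 <- scenario_hom(tr, 2)
  f2 <- tree_founders(tr, 2)
  expect_identical(f2, c(2L, 3L))
  fo <- spathet:::founder_assignment(tr, f2)
  expect_identical(hom2, paste0("S", match(fo[tr$leaves], f2)))
  # founders are an antichain whose progenies cover every leaf
  expect_false(anyNA(match(fo[tr$leaves], f2)))
})

test_that("random (het) groupings are seeded and roughly balanced", {
  cfg <- sim_config(500, seed = 9)
  tr <- simulate_tree(cfg)
  h1 <- scenario_het(tr, 5, seed = 42)
  h2 <- scenario_het(tr, 5, seed = 42)
  expect_identical(h1, h2)
  expect_true(all(table(h1) > 500 / 5 - 4 * sqrt(100)))
  expect_true(all(table(h1) < 500 / 5 + 4 * sqrt(100)))
})

test_that("metastasis seeding copies a primary cell state into a new root", {
  cfg <- sim_config(60, seed = 10)
  res <- scenario_metastasis(cfg, seed_point = 0.25, n_leaves_each = 60)
  expect_equal(nrow(res$primary$values), 60)
  expect_equal(nrow(res$metastasis$values), 60)
  expect_identical(unique(res$pooled$sample), c("P", "M"))
  seed_state <- drop(spathet:::node_states(res$trees$primary,
                                           nodes = res$seed_node))
  expect_equal(res$trees$metastasis$root_state, unname(seed_state))
  # the seed cell was extant when 1/4 of the cells existed: id bound forced
  s <- max(2, ceiling(0.25 * 60))
  expect_lte(res$seed_node, 2 * (s - 1) + 1)
  # same config seed: fully reproducible
  res2 <- scenario_metastasis(cfg, seed_point = 0.25, n_leaves_each = 60)
  expect_identical(res$pooled$values, res2$pooled$values)
})

test_that("var-scenario draws parameters in range and splits at the root", {
  v <- scenario_var(77, n_leaves = 120)
  expect_gte(v$theta, 500); expect_lte(v$theta, 5e6)
  expect_gte(v$gain_p, 0.1); expect_lte(v$gain_p, 0.9)
  expect_equal(nrow(v$pooled$values), 120)
  expect_setequal(unique(v$pooled$sample), c("S1", "S2"))
  v2 <- scenario_var(77, n_leaves = 120)
  expect_identical(v$pooled$values, v2$pooled$values)
  expect_identical(v$theta, v2$theta)
})

test_that("subtree samples respect the founder count and IQR filter", {
  cfg <- sim_config(800, seed = 12)
  tr <- simulate_tree(cfg)
  all20 <- subtree_samples(tr, 20, iqr_filter = FALSE)
  expect_length(all20, 20)
  sizes <- vapply(all20, `[[`, 0, "n_cells")
  expect_equal(sum(sizes), 800)
  filt <- subtree_samples(tr, 20, iqr_filter = TRUE)
  q <- quantile(sizes, c(0.25, 0.75))
  kept <- vapply(filt, `[[`, 0, "n_cells")
  expect_true(all(kept >= q[1] & kept <= q[2]))
  expect_lt(length(filt), 20)
})

test_that("MRCA edge distances match a graph shortest-path oracle", {
  cfg <- sim_config(50, seed = 13)
  tr <- simulate_tree(cfg)
  expect_equal(mrca_distance(tr, 4, 4), 0)
  # siblings created by the same division are two edges apart
  expect_equal(mrca_distance(tr, 2, 3), 2)
  edges <- cbind(tr$parent[-1], seq_along(tr$parent)[-1])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  set.seed(14)
  for (i in 1:20) {
    ab <- sample(seq_along(tr$parent), 2)
    expect_equal(mrca_distance(tr, ab[1], ab[2]),
                 as.numeric(igraph::distances(g, ab[1], ab[2])))
  }
  expect_error(mrca_distance(tr, 1, 1000), "unknown node")
})

test_that("segregated founder groupings outscore shuffled ones on average", {
  homs <- hets <- numeric(10)
  for (s in 1:10) {
    cfg <- sim_config(300, seed = 9000 + s)
    tr <- simulate_tree(cfg)
    D <- cnv_dist(leaves_to_matrix(tr)$values)
    homs[s] <- mean(spathet:::silhouette_values(
      D, as.integer(factor(scenario_hom(tr, 5)))))
    hets[s] <- mean(spathet:::silhouette_values(
      D, as.integer(factor(scenario_het(tr, 5, seed = 9100 + s)))))
  }
  expect_gt(median(homs), median(hets))
  expect_lt(median(hets), 0)  # shuffled labels sit slightly below zero
})
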