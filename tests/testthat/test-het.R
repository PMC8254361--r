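test_that("L1 distances match hand sums and a brute-force oracle", {
  m <- rbind(a = c(2, 3), b = c(4, 1))
  D <- cnv_dist(m)
  expect_equal(D["a", "b"], 4)
  expect_equal(diag(D), c(a = 0, b = 0))

  m2 <- rbind(a = c(2, 2), b = c(2, 2))
  expect_equal(max(cnv_dist(m2)), 0)

  set.seed(11)
  v <- matrix(sample(0:6, 3 * 5, replace = TRUE), 3)
  D3 <- cnv_dist(v)
  for (i in 1:3) for (j in 1:3)
    expect_equal(D3[i, j], sum(abs(v[i, ] - v[j, ])))
  expect_equal(unname(D3), unname(as.matrix(dist(v, method = "manhattan"))),
               ignore_attr = TRUE)
  expect_true(isSymmetric(D3))

  expect_error(cnv_dist(m, metric = "euclidean"), "unsupported metric")
  expect_error(cnv_dist(m[1, , drop = FALSE]), "at least 2 cells")
})

test_that("worked per-cell examples: a, b and sh come out exactly", {
  # one bin; block A = {2, 3, 5}, block B = {10}
  # cell [2]: a = (1 + 3)/2 = 2, b = 8, sh = 6/8
  # cell [3]: a = (1 + 2)/2 = 1.5, b = 7, sh = 5.5/7
  # cell [5]: a = (3 + 2)/2 = 2.5, b = 5, sh = 2.5/5
  # cell [10]: singleton block, sh = 0
  m <- cnv_matrix(rbind(p1 = 2, p2 = 3, p3 = 5, q1 = 10), toy_bins(1),
                  sample = c("A", "A", "A", "B"))
  r <- shscore(m)
  expect_equal(unname(r$per_cell_sh),
               c(6 / 8, 5.5 / 7, 2.5 / 5, 0))
  expect_equal(r$score, mean(c(6 / 8, 5.5 / 7, 2.5 / 5, 0)))

  # two other blocks with mean distances 5 and 3: b is the minimum
  m2 <- cnv_matrix(rbind(p1 = 0, p2 = 0, q1 = 3, q2 = 3, r1 = 5, r2 = 5),
                   toy_bins(1), sample = c("A", "A", "B", "B", "C", "C"))
  r2 <- shscore(m2)
  expect_equal(unname(r2$per_cell_sh[1]), (3 - 0) / 3)
})

test_that("perfect separation scores exactly 1, mirrored pairs -0.5", {
  expect_equal(shscore(separated_clones(2, 1))$score, 1)
  m <- cnv_matrix(rbind(a1 = 2, a2 = 4, b1 = 2, b2 = 4), toy_bins(1),
                  sample = c("S1", "S1", "S2", "S2"))
  r <- shscore(m)
  expect_equal(r$score, -0.5)            # every cell: a = 2, b = 1
  expect_equal(unname(r$per_cell_sh), rep(-0.5, 4))
})

test_that("shscore equals the brute-force silhouette oracle (<= 50 cells)", {
  set.seed(19)
  for (rep in 1:12) {
    n <- sample(6:50, 1)
    k <- sample(2:4, 1)
    labels <- paste0("S", sample(k, n, replace = TRUE))
    if (length(unique(labels)) < 2) next
    m <- random_cnv(n, sample(4:20, 1), seed = 100 + rep)
    m$sample <- labels
    r <- shscore(m)
    o <- oracle_shscore(m$values, labels)
    expect_equal(r$score, o$score, tolerance = 1e-12)
    expect_equal(unname(r$per_cell_sh), o$per_cell_sh, tolerance = 1e-12)
    # and against the established silhouette implementation
    sil <- cluster::silhouette(as.integer(factor(labels)),
                               dist(m$values, method = "manhattan"))
    expect_equal(r$score, mean(sil[, "sil_width"]), tolerance = 1e-12)
  }
})

test_that("sh(p) respects bounds, scale invariance and the 0-conventions", {
  set.seed(23)
  for (rep in 1:10) {
    m <- random_cnv(30, 10, seed = 200 + rep,
                    samples = c("A", "B", "C"))
    r <- shscore(m)
    expect_true(all(r$per_cell_sh >= -1 & r$per_cell_sh <= 1))
    expect_gte(r$score, -1)
    expect_lte(r$score, 1)
    # multiplying all CN values by a positive constant changes nothing
    m2 <- m
    m2$values <- m$values * 3.7
    expect_equal(shscore(m2)$per_cell_sh, r$per_cell_sh)
  }
  # duplicates across blocks: a = b = 0 gives 0, not NaN
  dup <- cnv_matrix(rbind(a1 = 2, a2 = 2, b1 = 2, b2 = 2), toy_bins(1),
                    sample = c("A", "A", "B", "B"))
  expect_equal(shscore(dup)$score, 0)
})

test_that("labels absent from the partition or empty blocks are refused", {
  m <- separated_clones(2, 2)
  expect_error(shscore(m, list("A", "C")), "not covered")
  expect_error(shscore(m, list(c("A", "B"), "C")), "no cells")
  expect_error(sample_partition(list(c("A", "B"))), "at least 2")
  expect_error(sample_partition(list("A", character(0))), "empty")
  expect_error(sample_partition(list(c("A", "B"), "B")), "not disjoint")
})

test_that("partition enumeration matches Bell-number counts and names", {
  p3 <- enumerate_partitions(c("S1", "S2", "S3"))
  expect_length(p3, 4)
  expect_setequal(vapply(p3, `[[`, "", "name"),
                  c("S1 vs S2 vs S3", "S1+S2 vs S3", "S1+S3 vs S2",
                    "S1 vs S2+S3"))
  expect_length(enumerate_partitions(c("A", "B")), 1)
  expect_length(enumerate_partitions(LETTERS[1:4]), 14)
  expect_length(enumerate_partitions(LETTERS[1:5]), 51)
  expect_error(enumerate_partitions(LETTERS[1:7]), "cap")
  expect_length(enumerate_partitions(LETTERS[1:7], allow_large = TRUE), 876)
  expect_identical(sample_partition(list(c("S_D", "S_C", "S_E"),
                                         "S_B"))$name,
                   "S_B vs S_C+S_D+S_E")
})

test_that("the scan finds the constructed best partition", {
  # clone X split into samples A and B; clone Y is sample C:
  # the top partition must merge the i.i.d. samples A and B
  set.seed(31)
  x <- matrix(2 + rbinom(40 * 12, 1, 0.1), 40, 12)
  y <- matrix(5 + rbinom(20 * 12, 1, 0.1), 20, 12)
  v <- rbind(x, y)
  rownames(v) <- paste0("c", 1:60)
  m <- cnv_matrix(v, toy_bins(12),
                  sample = c(rep(c("A", "B"), 20), rep("C", 20)))
  sc <- sh_scan(m)
  expect_identical(sc$table$partition[1], "A+B vs C")
  expect_false(is.unsorted(rev(sc$table$score)))
  expect_identical(sc$best$partition$name, "A+B vs C")
  expect_gt(sc$best$score, 0.8)
  # two perfectly separated clones as two samples score ~1 on the split
  m2 <- separated_clones(5, 8, gap = 4)
  sc2 <- sh_scan(m2)
  expect_equal(sc2$table$score[1], 1)
})

test_that("random labels on one homogeneous population score near zero", {
  set.seed(37)
  meds <- replicate(20, {
    m <- random_cnv(60, 15, seed = sample.int(1e6, 1),
                    samples = paste0("S", 1:5))
    m$sample <- sample(m$sample)
    shscore(m)$score
  })
  expect_lt(abs(median(meds)), 0.05)
})

test_that("the aggregated heatmap clusters clones apart and writes a file", {
  m <- separated_clones(6, 10, gap = 4)
  f <- withr::local_tempfile(fileext = ".png")
  res <- cnv_heatmap(m, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  # top split of the dendrogram is sample-pure
  top <- cutree(res$hclust, k = 2)
  expect_equal(length(unique(paste(top, m$sample))), 2)
})
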