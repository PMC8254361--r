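#' Configuration for the tumor-evolution simulator
#'
#' Parameters of the generative model used to validate the SHscore: a binary
#' cell-division tree grown one division at a time from a single diploid
#' cell, with copy-number events accruing on every edge. Leaves are the
#' sampled cells; internal nodes are intermediate copy-number states that no
#' longer exist.
#'
#' The event model: each daughter edge receives Poisson(`events_per_division`)
#' CNA events. An event picks a chromosome with probability proportional to
#' its length, a uniform start position, a length drawn from an Exponential
#' with mean `theta` base pairs (truncated at the chromosome end, so the mean
#' is honoured when `theta` is small relative to chromosome length), and a
#' signed copy change: a deletion with probability `loss_fraction`, otherwise
#' a gain, with magnitude Geometric with mean `1/gain_p` copies in either
#' direction. Copy number is floored at 0 and bins at 0 are immune to gains
#' (deleted DNA cannot re-amplify).
#'
#' Division order: by default every extant cell is equally likely to divide
#' next (a Yule process). Setting `split_shape` to a positive number gives
#' each division a Beta(`split_shape`, `split_shape`) split of the parent's
#' division propensity between the daughters, and cells divide with
#' probability proportional to propensity — a sequential analogue of
#' beta-splitting tree shapes (small values give imbalanced trees, large
#' values balanced ones).
#'
#' @param n_leaves number of cells to sample (>= 2).
#' @param theta expected CNA event size in base pairs.
#' @param gain_p reciprocal of the expected number of copies gained (or
#'   lost), in (0, 1].
#' @param events_per_division expected CNA events per daughter edge.
#' @param loss_fraction probability that an event is a deletion.
#' @param genome `"reduced"` (one 100 Mbp chromosome), `"hg"` (22
#'   autosome-like chromosomes, ~2.9 Gbp), or a named numeric vector of
#'   chromosome lengths in bp.
#' @param bin_size genomic bin width in bp (defaults: 100 kb reduced,
#'   500 kb hg).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param split_shape optional Beta shape for division propensities (see
#'   above); `NULL` for the uniform (Yule) default.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_leaves, theta = 2.5e6, gain_p = 0.5,
                       events_per_division = 1, loss_fraction = 0.5,
                       genome = "reduced", bin_size = NULL, seed = NULL,
                       split_shape = NULL) {
  if (is.character(genome)) {
    genome <- match.arg(genome, c("reduced", "hg"))
    if (genome == "reduced") {
      if (is.null(bin_size)) bin_size <- 1e5
      genome <- c(chr1 = 1e8)
    } else {
      if (is.null(bin_size)) bin_size <- 5e5
      mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
              115, 107, 103, 90, 81, 78, 59, 63, 48, 51)
      genome <- setNames(mb * 1e6, paste0("chr", seq_along(mb)))
    }
  }
  genome <- unlist(genome)
  if (is.null(names(genome)))
    names(genome) <- paste0("chr", seq_along(genome))
  if (is.null(bin_size)) bin_size <- 1e5
  stopifnot(n_leaves >= 2, theta > 0, gain_p > 0, gain_p <= 1,
            events_per_division >= 0, loss_fraction >= 0, loss_fraction <= 1,
            bin_size > 0, all(genome > 0))
  if (theta > sum(genome))
    stop("'theta' exceeds the genome size: infeasible event sizes")
  if (!is.null(split_shape) && split_shape <= 0)
    stop("'split_shape' must be positive")
  structure(list(n_leaves = as.integer(n_leaves), theta = theta,
                 gain_p = gain_p, events_per_division = events_per_division,
                 loss_fraction = loss_fraction, genome = genome,
                 bin_size = bin_size, seed = seed, split_shape = split_shape),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("simulation config: ", x$n_leaves, " leaves; theta = ",
      format(x$theta, scientific = FALSE), " bp; gain_p = ", x$gain_p,
      "; ", x$events_per_division, " event(s)/division; loss fraction ",
      x$loss_fraction, "\n  genome: ", length(x$genome),
      " chromosome(s), ", format(sum(x$genome), big.mark = ","),
      " bp in ", sum(ceiling(x$genome / x$bin_size)), " bins of ",
      format(x$bin_size, scientific = FALSE), " bp\n", sep = "")
  invisible(x)
}

# Bin table (0-based half-open) for a genome/bin_size pair.
genome_bins <- function(genome, bin_size) {
  pieces <- lapply(names(genome), function(ch) {
    len <- genome[[ch]]
    start <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = start, end = pmin(start + bin_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Draw copy-number events from the simulator's event model
#'
#' Samples `n` events exactly as the tree simulator does on each edge; mainly
#' useful to inspect or check the event-size and copy-change distributions.
#'
#' @param config a [sim_config()].
#' @param n number of events to draw.
#' @return data.frame with columns `chrom`, `start`, `end` (bp, truncated at
#'   the chromosome end) and `delta` (signed copies).
#' @export
draw_cna_events <- function(config, n) {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  g <- config$genome
  ci <- sample.int(length(g), n, replace = TRUE, prob = g)
  start <- floor(runif(n, 0, g[ci]))
  len <- pmax(1, rexp(n, rate = 1 / config$theta))
  end <- pmin(start + len, g[ci])
  mag <- rgeom(n, config$gain_p) + 1
  sign <- ifelse(runif(n) < config$loss_fraction, -1L, 1L)
  data.frame(chrom = names(g)[ci], start = start, end = end,
             delta = sign * mag, stringsAsFactors = FALSE)
}

# One edge's worth of events as a compact matrix (chrom index, start, end,
# delta); NULL when no event fires. Keeps per-edge allocation minimal.
draw_edge_events <- function(g, theta, gain_p, rate, loss_fraction) {
  k <- rpois(1L, rate)
  if (k == 0L) return(NULL)
  ci <- sample.int(length(g), k, replace = TRUE, prob = g)
  start <- floor(runif(k, 0, g[ci]))
  end <- pmin(start + pmax(1, rexp(k, rate = 1 / theta)), g[ci])
  mag <- rgeom(k, gain_p) + 1
  sign <- ifelse(runif(k) < loss_fraction, -1, 1)
  cbind(ci, start, end, sign * mag, deparse.level = 0)
}

#' Simulate a cell-division tree with copy-number events
#'
#' Grows a binary tree from one diploid founder cell to `n_leaves` extant
#' cells under the model described in [sim_config()]. Nodes are numbered in
#' birth order (root = 1; division j creates nodes 2j and 2j + 1), which is
#' the order used to define the "first k generated cells" of the sampling
#' scenarios. Events are logged per edge, so any node's genome can be
#' replayed exactly from the root state.
#'
#' @param config a [sim_config()].
#' @param root_state optional per-bin copy-number vector for the founder
#'   (default: diploid, 2 everywhere); used to seed metastasis trees.
#' @return object of class `cna_tree`: list with `parent` (per node),
#'   `events` (per-edge event matrices), `divided_at` (node divided at each
#'   division, in order), `leaves` (ids, birth order), `bins`, `root_state`,
#'   `config`.
#' @export
simulate_tree <- function(config, root_state = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_leaves
  g <- config$genome
  bins <- genome_bins(g, config$bin_size)
  if (is.null(root_state)) root_state <- rep(2, nrow(bins))
  stopifnot(length(root_state) == nrow(bins))
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  events <- vector("list", n_nodes)
  divided_at <- integer(n - 1L)
  extant <- integer(n)
  extant[1L] <- 1L
  count <- 1L
  weighted <- !is.null(config$split_shape)
  if (weighted) {
    w <- numeric(n)
    w[1L] <- 1
  }
  for (j in seq_len(n - 1L)) {
    idx <- if (weighted)
      sample.int(count, 1L, prob = w[seq_len(count)])
    else sample.int(count, 1L)
    node <- extant[idx]
    divided_at[j] <- node
    c1 <- 2L * j
    c2 <- 2L * j + 1L
    parent[c1] <- node
    parent[c2] <- node
    # single-bracket list assignment: NULL (no events) must not shrink
    events[c1] <- list(draw_edge_events(g, config$theta, config$gain_p,
                                        config$events_per_division,
                                        config$loss_fraction))
    events[c2] <- list(draw_edge_events(g, config$theta, config$gain_p,
                                        config$events_per_division,
                                        config$loss_fraction))
    extant[idx] <- c1
    count <- count + 1L
    extant[count] <- c2
    if (weighted) {
      v <- rbeta(1, config$split_shape, config$split_shape)
      w[count] <- w[idx] * (1 - v)
      w[idx] <- w[idx] * v
    }
  }
  structure(list(parent = parent, events = events, divided_at = divided_at,
                 leaves = sort(extant), bins = bins,
                 root_state = root_state, config = config),
            class = "cna_tree")
}

#' @export
print.cna_tree <- function(x, ...) {
  nev <- sum(vapply(x$events, function(e) if (is.null(e)) 0L else nrow(e),
                    0L))
  cat("cell-division tree: ", length(x$leaves), " leaves, ",
      length(x$parent), " nodes, ", nev, " copy-number events\n", sep = "")
  invisible(x)
}

#' Apply a copy-number event to a binned genome state
#'
#' All bins overlapped by `[start, end)` on the event's chromosome change by
#' `delta` copies; copy number is floored at 0 and bins already at 0 are
#' unaffected by gains (deleted DNA cannot re-amplify).
#'
#' @param state per-bin copy-number vector.
#' @param bins bin table (`chrom`, `start`, `end`, 0-based half-open).
#' @param event list or one-row data.frame with `chrom`, `start`, `end`,
#'   `delta`.
#' @return the updated state vector.
#' @export
apply_event <- function(state, bins, event) {
  if (!event$chrom %in% bins$chrom) stop("unknown chromosome: ", event$chrom)
  if (event$start < 0 || event$end > max(bins$end[bins$chrom == event$chrom]))
    stop("event outside chromosome bounds")
  idx <- which(bins$chrom == event$chrom & bins$start < event$end &
                 bins$end > event$start)
  seg <- state[idx]
  if (event$delta > 0) {
    hit <- seg > 0
    seg[hit] <- seg[hit] + event$delta
  } else {
    seg <- pmax(0, seg + event$delta)
  }
  state[idx] <- seg
  state
}

# Fast in-replay version: bins are uniform per chromosome, so the overlapped
# bin range is arithmetic. ev is the compact matrix from draw_edge_events.
apply_edge_events <- function(state, ev, offsets, bin_size, nbins_chrom) {
  for (r in seq_len(nrow(ev))) {
    ci <- ev[r, 1L]
    i1 <- offsets[ci] + floor(ev[r, 2L] / bin_size) + 1
    i2 <- offsets[ci] + min(ceiling(ev[r, 3L] / bin_size), nbins_chrom[ci])
    delta <- ev[r, 4L]
    seg <- state[i1:i2]
    if (delta > 0) {
      hit <- seg > 0
      seg[hit] <- seg[hit] + delta
    } else {
      seg <- pmax(0, seg + delta)
    }
    state[i1:i2] <- seg
  }
  state
}

# Children lookup: division j created nodes 2j, 2j+1 from divided_at[j].
tree_children <- function(tree) {
  n_nodes <- length(tree$parent)
  child1 <- integer(n_nodes)
  child2 <- integer(n_nodes)
  j <- seq_along(tree$divided_at)
  child1[tree$divided_at] <- 2L * j
  child2[tree$divided_at] <- 2L * j + 1L
  list(child1 = child1, child2 = child2)
}

# Replay the event log to recover CN states. Returns a matrix with one row
# per requested node (default: the leaves, in birth order).
node_states <- function(tree, nodes = tree$leaves) {
  cfg <- tree$config
  g <- cfg$genome
  nbins_chrom <- ceiling(g / cfg$bin_size)
  offsets <- cumsum(c(0, nbins_chrom[-length(nbins_chrom)]))
  kids <- tree_children(tree)
  want <- logical(length(tree$parent))
  want[nodes] <- TRUE
  out <- matrix(NA_real_, length(nodes), nrow(tree$bins))
  pos <- match(seq_along(tree$parent), nodes)
  # depth-first with an explicit (node, state) stack
  stack <- list(list(1L, tree$root_state))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top[[1L]]
    state <- top[[2L]]
    ev <- tree$events[[node]]
    if (!is.null(ev))
      state <- apply_edge_events(state, ev, offsets, cfg$bin_size,
                                 nbins_chrom)
    if (want[node]) out[pos[node], ] <- state
    c1 <- kids$child1[node]
    if (c1 > 0L) {
      stack[[length(stack) + 1L]] <- list(c1, state)
      stack[[length(stack) + 1L]] <- list(kids$child2[node], state)
    }
  }
  rownames(out) <- paste0("node", nodes)
  out
}

#' Export the leaves of a simulated tree as a copy-number matrix
#'
#' @param tree a [simulate_tree()] result.
#' @param grouping optional sample label per leaf (birth order), e.g. from
#'   [scenario_hom()] or [scenario_het()]; default: a single label.
#' @param sample label used when `grouping` is absent.
#' @return a [cnv_matrix()] with one row per leaf, leaves in birth order and
#'   cell ids `cell<node id>`.
#' @export
leaves_to_matrix <- function(tree, grouping = NULL, sample = "sim") {
  stopifnot(inherits(tree, "cna_tree"))
  states <- node_states(tree)
  rownames(states) <- paste0("cell", tree$leaves)
  if (is.null(grouping)) grouping <- rep(sample, length(tree$leaves))
  stopifnot(length(grouping) == length(tree$leaves))
  cnv_matrix(states, tree$bins, sample = as.character(grouping))
}

#' First k generated cells of a tree
#'
#' The extant cells at the moment the tree first contained `k` cells, i.e.
#' after k - 1 divisions (root counted as cell 1). Their progenies partition
#' the leaves; they are the founders of the segregation scenarios.
#'
#' @param tree a [cna_tree].
#' @param k founder count (2 <= k <= n_leaves).
#' @return integer node ids, in birth order.
#' @export
tree_founders <- function(tree, k) {
  stopifnot(inherits(tree, "cna_tree"), k >= 2,
            k <= length(tree$leaves))
  sort(setdiff(seq_len(2L * (k - 1L) + 1L),
               tree$divided_at[seq_len(k - 1L)]))
}

# Founder (among the given antichain) that each node descends from.
founder_assignment <- function(tree, founders) {
  n_nodes <- length(tree$parent)
  fo <- integer(n_nodes)
  fo[founders] <- founders
  for (v in seq_len(n_nodes)[-1L]) {
    if (fo[v] == 0L) fo[v] <- fo[tree$parent[v]]
  }
  fo
}

#' Spatial segregation (hom) grouping
#'
#' Labels each leaf by the founder — among the first `k` generated cells —
#' whose progeny it belongs to, emulating subclones that segregated into
#' isolated niches very early in tumor growth.
#'
#' @param tree a [cna_tree].
#' @param k number of founders (default 5).
#' @return character sample label per leaf (`"S1"` ... `"Sk"`, by founder
#'   birth order), in leaf birth order.
#' @export
scenario_hom <- function(tree, k = 5) {
  f <- tree_founders(tree, k)
  fo <- founder_assignment(tree, f)
  lab <- match(fo[tree$leaves], f)
  if (anyNA(lab)) stop("degenerate tree: founder without leaves")
  paste0("S", lab)
}

#' Spatial intermixing (het) grouping
#'
#' Assigns leaves uniformly at random to `k` samples, emulating subclones so
#' well mixed in space that regional sampling draws indistinguishable
#' populations.
#'
#' @param tree a [cna_tree].
#' @param k number of samples (default 5).
#' @param seed integer seed.
#' @return character sample label per leaf.
#' @export
scenario_het <- function(tree, k = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0("S", sample.int(k, length(tree$leaves), replace = TRUE))
}

#' Simulate a primary tumor and a seeded metastasis
#'
#' Grows a primary tree; when it has generated `seed_point` of its final cell
#' count, one extant cell is picked at random and its copy-number state
#' founds a second, independently growing tree (the metastasis). Both trees
#' are grown to `n_leaves_each` leaves under the same event model. An early
#' seed (default 1/4) leaves the metastasis a long independent history; a
#' late seed (3/4) a short one.
#'
#' @param config a [sim_config()] (its `n_leaves` is overridden by
#'   `n_leaves_each`; its `seed` drives the whole scenario).
#' @param seed_point fraction of the final cell count at which the metastasis
#'   seeds (0.25 = early, 0.75 = late).
#' @param n_leaves_each leaves per tree (default 500).
#' @return list with `primary` and `metastasis` ([cnv_matrix()], sample
#'   labels `"P"` / `"M"`), `pooled` (their aggregate), `seed_node` (primary
#'   node id that seeded the metastasis) and the two `trees`.
#' @export
scenario_metastasis <- function(config, seed_point = 0.25,
                                n_leaves_each = 500) {
  stopifnot(inherits(config, "sim_config"), seed_point > 0, seed_point < 1)
  cfg <- config
  cfg$n_leaves <- as.integer(n_leaves_each)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  cfg$seed <- seeds[1L]
  primary <- simulate_tree(cfg)
  s <- max(2L, ceiling(seed_point * n_leaves_each))
  extant_then <- tree_founders(primary, s)
  set.seed(seeds[2L])
  seed_node <- extant_then[sample.int(length(extant_then), 1L)]
  seed_state <- drop(node_states(primary, nodes = seed_node))
  cfg_m <- cfg
  cfg_m$seed <- seeds[3L]
  met <- simulate_tree(cfg_m, root_state = seed_state)
  pm <- leaves_to_matrix(primary, sample = "P")
  mm <- leaves_to_matrix(met, sample = "M")
  list(primary = pm, metastasis = mm,
       pooled = cnv_aggregate(list(pm, mm), labels = c("P", "M")),
       seed_node = seed_node, seed_point = seed_point,
       trees = list(primary = primary, metastasis = met))
}

#' Simulate a sample pair with random event-model parameters
#'
#' Draws the expected CNA size theta from U\[500, 5e6\] bp and the
#' copy-gain parameter from U\[0.1, 0.9\], grows one tree and splits it at
#' the root into two subtree samples — the design used to check that the
#' SHscore does not depend on the event-size and copy-gain parameters.
#'
#' @param seed integer seed.
#' @param n_leaves total leaves of the tree (default 1000).
#' @param genome,bin_size as in [sim_config()].
#' @return list with `pooled` (a two-sample [cnv_matrix()], labels `"S1"`,
#'   `"S2"` for the root's two subtrees), `theta`, `gain_p`, `tree`.
#' @export
scenario_var <- function(seed, n_leaves = 1000, genome = "reduced",
                         bin_size = NULL) {
  set.seed(seed)
  theta <- runif(1, 500, 5e6)
  gain_p <- runif(1, 0.1, 0.9)
  cfg <- sim_config(n_leaves, theta = theta, gain_p = gain_p,
                    genome = genome, bin_size = bin_size,
                    seed = sample.int(.Machine$integer.max - 1L, 1L))
  tree <- simulate_tree(cfg)
  grouping <- scenario_hom(tree, k = 2)
  list(pooled = leaves_to_matrix(tree, grouping = grouping),
       theta = theta, gain_p = gain_p, tree = tree)
}

#' Extract founder-subtree samples from a deep tree
#'
#' Tracks the subtrees rooted in the first `first_k` generated cells —
#' emulating complete spatial segregation of the subclones they founded —
#' and exports each as a sample. With `iqr_filter`, only samples whose leaf
#' count lies within \[Q1, Q3\] of the founder leaf counts are retained,
#' balancing sample cardinalities.
#'
#' @param tree a [cna_tree].
#' @param first_k number of founders to track.
#' @param iqr_filter keep only samples with leaf counts inside the
#'   interquartile range (default TRUE).
#' @return list with one element per retained founder: `matrix` (a
#'   single-sample [cnv_matrix()], label `"S<founder id>"`), `founder`
#'   (node id), `n_cells`.
#' @export
subtree_samples <- function(tree, first_k, iqr_filter = TRUE) {
  f <- tree_founders(tree, first_k)
  fo <- founder_assignment(tree, f)
  leaf_f <- fo[tree$leaves]
  counts <- table(factor(leaf_f, levels = f))
  keep <- f
  if (iqr_filter) {
    q <- quantile(as.numeric(counts), c(0.25, 0.75), names = FALSE)
    keep <- f[counts >= q[1] & counts <= q[2]]
  }
  states <- node_states(tree)   # leaves, birth order
  rownames(states) <- paste0("cell", tree$leaves)
  lapply(keep, function(fd) {
    rows <- which(leaf_f == fd)
    list(matrix = cnv_matrix(states[rows, , drop = FALSE], tree$bins,
                             sample = paste0("S", fd)),
         founder = fd, n_cells = length(rows))
  })
}

#' Edge distance between two nodes of a tree
#'
#' Number of edges on the unique path between two nodes — used as the
#' evolutionary (MRCA) distance between the founder cells of two samples.
#'
#' @param tree a [cna_tree].
#' @param a,b node ids.
#' @return integer edge count (0 when `a == b`).
#' @export
mrca_distance <- function(tree, a, b) {
  n_nodes <- length(tree$parent)
  if (a < 1 || a > n_nodes || b < 1 || b > n_nodes)
    stop("unknown node id")
  if (a == b) return(0L)
  path_up <- function(v) {
    p <- v
    while (v != 1L) {
      v <- tree$parent[v]
      p <- c(p, v)
    }
    p
  }
  pa <- path_up(a)
  pb <- path_up(b)
  common <- intersect(pa, pb)[1L]  # both paths end at root; first shared
  (match(common, pa) - 1L) + (match(common, pb) - 1L)
}
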