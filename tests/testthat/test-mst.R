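test_that("to_weights is 1 - PLI off-diagonal and keeps symmetry", {
  m <- matrix(c(0, 0.9, 0, 0.9, 0, 0.4, 0, 0.4, 0), 3, 3)
  w <- to_weights(m)
  expect_equal(w$values[1, 2], 0.1)
  expect_equal(w$values[1, 3], 1)
  expect_identical(w$values, t(w$values))
  expect_equal(diag(w$values), rep(0, 3))
})

test_that("Kruskal picks the cheapest acyclic edges", {
  w <- matrix(1, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.2
  w[1, 3] <- w[3, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.4
  t <- kruskal_mst(w)
  expect_equal(t$edges[, c("i", "j")], data.frame(i = c(1L, 2L), j = c(2L, 3L)))
  expect_equal(sum(t$edges$weight), 0.6)
})

test_that("any full 62-channel matrix yields a valid 61-edge tree", {
  set.seed(31)
  pli <- matrix(0, 62, 62)
  pli[upper.tri(pli)] <- runif(61 * 31)
  pli <- pli + t(pli)
  t <- kruskal_mst(to_weights(pli))
  expect_equal(nrow(t$edges), 61L)
  # connected + acyclic follows from 61 edges and full reachability
  adj <- eegmst:::tree_adjacency(t)
  expect_true(all(!is.na(eegmst:::tree_bfs_depths(adj, 1L, 62L))))

  bad <- matrix(NA_real_, 3, 3)
  expect_error(kruskal_mst(bad), "non-finite")
})

test_that("Kruskal matches an independent MST implementation on random instances", {
  skip_if_not_installed("igraph")
  set.seed(17)
  for (r in 1:20) {
    n <- 12
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- runif(n * (n - 1) / 2)
    w <- w + t(w)
    ours <- sum(kruskal_mst(w)$edges$weight)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    theirs <- sum(igraph::E(igraph::mst(g))$weight)
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("the selected edge set is invariant under monotone weight transforms", {
  set.seed(13)
  for (r in 1:10) {
    w <- matrix(0, 10, 10)
    w[upper.tri(w)] <- runif(45, 0.01, 1)
    w <- w + t(w)
    e1 <- kruskal_mst(w)$edges[, c("i", "j")]
    e2 <- kruskal_mst(w^3)$edges[, c("i", "j")]     # strictly increasing on (0,1)
    e3 <- kruskal_mst(5 * w + 2)$edges[, c("i", "j")]
    expect_identical(e1, e2)
    expect_identical(e1, e3)
  }
})

test_that("equal-weight ties resolve deterministically by channel index", {
  w <- matrix(0.5, 6, 6); diag(w) <- 0
  t1 <- kruskal_mst(w)
  t2 <- kruskal_mst(w)
  expect_identical(t1$edges, t2$edges)
  # lexicographic rule admits every (1, j) edge first: a star at node 1
  expect_identical(t1$edges$i, rep(1L, 5))
})

test_that("node metrics match closed forms on the star and the chain", {
  star <- kruskal_mst(star_weights(62))
  nm <- node_metrics(star)
  centre <- which(nm$degree == 61)
  expect_length(centre, 1L)
  expect_equal(nm$betweenness[centre], 1)
  expect_true(all(nm$betweenness[-centre] == 0))
  expect_equal(sum(nm$degree), 2 * 61)

  chain <- kruskal_mst(chain_weights(62))
  nc <- node_metrics(chain)
  ends <- which(nc$degree == 1)
  expect_equal(nc$eccentricity[ends], c(1, 1))
  expect_equal(mean(nc$eccentricity), 46 / 61)
  expect_equal(sum(nc$degree), 2 * 61)

  two <- structure(list(n_nodes = 2L,
                        edges = data.frame(i = 1L, j = 2L, weight = 1),
                        node_labels = c("a", "b")), class = "spanning_tree")
  expect_error(node_metrics(two), "fewer than 3")
})

test_that("tree metrics match closed forms on the chain and star (N = 62)", {
  tmc <- tree_metrics(kruskal_mst(chain_weights(62)))
  expect_equal(tmc$diameter, 1)
  expect_equal(tmc$leaf_fraction, 2 / 61)
  expect_equal(tmc$kappa, 242 / 122)
  expect_equal(tmc$ecc_mean, 46 / 61)
  expect_equal(tmc$degree_max, 2)

  tms <- tree_metrics(kruskal_mst(star_weights(62)))
  expect_equal(tms$leaf_fraction, 1)
  expect_equal(tms$diameter, 2 / 61)
  expect_equal(tms$tree_hierarchy, 0.5)
  expect_equal(tms$bc_max, 1)
  expect_equal(tms$kappa, 31)
  expect_equal(tms$degree_max, 61)
})

test_that("metric extremes over all trees on small n are the star and the chain", {
  n <- 6
  idx <- all_trees_edge_index(n)
  lf <- numeric(ncol(idx)); dia <- numeric(ncol(idx))
  for (k in seq_len(ncol(idx))) {
    lin <- idx[, k]
    i <- (lin - 1L) %% n + 1L
    j <- (lin - 1L) %/% n + 1L
    t <- structure(list(n_nodes = n,
                        edges = data.frame(i = i, j = j, weight = 1),
                        node_labels = as.character(1:n)),
                   class = "spanning_tree")
    nm <- node_metrics(t)
    lf[k] <- sum(nm$degree == 1) / (n - 1)
    dia[k] <- max(nm$eccentricity)
  }
  expect_equal(max(lf), 1)                 # star
  expect_equal(min(lf), 2 / (n - 1))       # chain
  expect_equal(max(dia), 1)                # chain
})

test_that("tree hierarchy approaches its star/chain limits as N grows", {
  th_star <- vapply(c(10, 30, 62), function(n)
    tree_metrics(kruskal_mst(star_weights(n)))$tree_hierarchy, 0)
  expect_equal(th_star, rep(0.5, 3))
  th_chain <- vapply(c(10, 30, 62), function(n)
    tree_metrics(kruskal_mst(chain_weights(n)))$tree_hierarchy, 0)
  expect_true(all(diff(th_chain) < 0))
  expect_lt(th_chain[3], 0.05)
})

test_that("metrics_for_subject composes deterministically and respects ranges", {
  # two tight cliques bridged weakly: exactly one inter-block MST edge
  set.seed(5)
  pli <- matrix(0.05, 8, 8)
  pli[1:4, 1:4] <- 0.9
  pli[5:8, 5:8] <- 0.9
  pli[2, 6] <- pli[6, 2] <- 0.4
  diag(pli) <- 0
  pli <- pli + matrix(runif(64, 0, 0.01), 8)   # break ties irregularly
  pli[lower.tri(pli)] <- t(pli)[lower.tri(pli)]
  diag(pli) <- 0
  t <- kruskal_mst(to_weights(pli))
  cross <- sum((t$edges$i <= 4) != (t$edges$j <= 4))
  expect_equal(cross, 1L)
  # brute force confirms optimality on this 8-node instance
  expect_equal(sum(t$edges$weight), enumerate_mst_weight(1 - pli))

  cm <- structure(list(values = pli, channel_labels = paste0("c", 1:8),
                       band = "beta", n_epochs = 1L, subject_id = "x"),
                  class = "pli_matrix")
  tm1 <- metrics_for_subject(cm)
  tm2 <- metrics_for_subject(cm)
  expect_identical(tm1, tm2)
  expect_true(tm1$leaf_fraction > 0 && tm1$leaf_fraction <= 1)
  expect_true(tm1$diameter > 0 && tm1$diameter <= 1)
  expect_gte(tm1$kappa, 2 * 7 / 8)
})

test_that("trees serialize to labelled edge lists", {
  t <- kruskal_mst(star_weights(5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tree(t, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 4L)
  expect_true(all(c("node_i", "node_j", "weight") %in% names(df)))
})
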