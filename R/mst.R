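# Minimum spanning tree construction (Kruskal, on 1-PLI dissimilarities)
# and the standard tree metric suite.

#' Convert a PLI matrix to MST edge weights
#'
#' The weight of an edge is `1 - PLI`, so that lower weight means stronger
#' phase coupling and the minimum spanning tree keeps the strongest
#' connections.
#'
#' @param cm a `pli_matrix` (or plain symmetric matrix in \[0, 1\]).
#' @return object of class `weight_matrix`: `values` (symmetric, diagonal
#'   ignored) and `channel_labels`.
#' @export
to_weights <- function(cm) {
  v <- if (inherits(cm, "pli_matrix")) cm$values else as.matrix(cm)
  labels <- rownames(v) %||% paste0("ch", seq_len(nrow(v)))
  w <- 1 - v
  diag(w) <- 0
  structure(list(values = w, channel_labels = labels),
            class = "weight_matrix")
}

#' Minimum spanning tree by Kruskal's algorithm
#'
#' Sorts all edges by ascending weight and adds each edge unless it would
#' close a cycle (union–find), until all `N` nodes are connected by
#' `M = N - 1` edges. Ties are broken lexicographically by channel index
#' pair, which makes the tree deterministic on degenerate (equal-weight)
#' inputs.
#'
#' @param wm a `weight_matrix` from [to_weights()] (or a plain symmetric
#'   matrix of finite dissimilarities).
#' @return object of class `spanning_tree`: `n_nodes`, `edges`
#'   (data.frame `i`, `j`, `weight` with `i < j`), `node_labels`.
#' @export
kruskal_mst <- function(wm) {
  v <- if (inherits(wm, "weight_matrix")) wm$values else as.matrix(wm)
  labels <- if (inherits(wm, "weight_matrix")) wm$channel_labels
            else rownames(v) %||% paste0("ch", seq_len(nrow(v)))
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 nodes")
  ut <- which(upper.tri(v))
  w <- v[ut]
  if (any(!is.finite(w))) stop("non-finite edge weight")
  ei <- row(v)[ut]; ej <- col(v)[ut]
  ord <- order(w, ei, ej)                      # lexicographic tie rule

  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  sel <- integer(n - 1L); k <- 0L
  for (e in ord) {
    ra <- find(ei[e]); rb <- find(ej[e])
    if (ra != rb) {
      parent[ra] <- rb
      k <- k + 1L
      sel[k] <- e
      if (k == n - 1L) break
    }
  }
  if (k < n - 1L) stop("input graph is not connected")
  edges <- data.frame(i = ei[sel], j = ej[sel], weight = w[sel])
  structure(list(n_nodes = n, edges = edges, node_labels = labels),
            class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("<spanning_tree> %d nodes, %d edges, total weight %.4f\n",
              x$n_nodes, nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

# adjacency list of the tree
tree_adjacency <- function(t) {
  adj <- vector("list", t$n_nodes)
  for (k in seq_len(nrow(t$edges))) {
    i <- t$edges$i[k]; j <- t$edges$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# hop-count distances from one node by BFS
tree_bfs_depths <- function(adj, root, n) {
  depth <- rep(NA_integer_, n)
  depth[root] <- 0L
  frontier <- root
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in adj[[u]]) if (is.na(depth[v])) {
        depth[v] <- depth[u] + 1L
        nxt <- c(nxt, v)
      }
    }
    frontier <- nxt
  }
  depth
}

#' Node-level MST metrics
#'
#' Degree (edge count per node), betweenness centrality and eccentricity.
#' Betweenness counts, for each node `i`, the ordered pairs of other nodes
#' whose unique tree path passes through `i`, normalized by
#' `(N-1)(N-2)` — so the centre of a star scores exactly 1 and every leaf 0.
#' On a tree this equals `((N-1)(N-2) - sum_c s_c (s_c - 1)) / ((N-1)(N-2))`
#' where `s_c` are the component sizes of the forest left after deleting
#' node `i`. Eccentricity is the longest hop-count shortest path from the
#' node, normalized by `M = N - 1`.
#'
#' @param t a `spanning_tree`.
#' @return data.frame with columns `node`, `label`, `degree`, `betweenness`,
#'   `eccentricity`.
#' @export
node_metrics <- function(t) {
  stopifnot(inherits(t, "spanning_tree"))
  n <- t$n_nodes
  if (n < 3L) stop("betweenness centrality is undefined for fewer than 3 nodes")
  m <- n - 1L
  adj <- tree_adjacency(t)
  degree <- lengths(adj)

  bc <- numeric(n)
  norm <- (n - 1) * (n - 2)
  for (i in seq_len(n)) {
    if (degree[i] == 1L) next                 # leaves lie on no other path
    # component sizes after deleting i: BFS from each neighbour avoiding i
    seen <- rep(FALSE, n); seen[i] <- TRUE
    s <- integer(0)
    for (nb in adj[[i]]) {
      if (seen[nb]) next
      size <- 0L
      frontier <- nb; seen[nb] <- TRUE
      while (length(frontier)) {
        size <- size + length(frontier)
        nxt <- integer(0)
        for (u in frontier) for (v in adj[[u]]) if (!seen[v]) {
          seen[v] <- TRUE; nxt <- c(nxt, v)
        }
        frontier <- nxt
      }
      s <- c(s, size)
    }
    bc[i] <- (norm - sum(s * (s - 1))) / norm
  }

  ecc <- vapply(seq_len(n), function(i)
    max(tree_bfs_depths(adj, i, n)) / m, 0)

  data.frame(node = seq_len(n), label = t$node_labels,
             degree = degree, betweenness = bc, eccentricity = ecc,
             stringsAsFactors = FALSE)
}

#' Tree-level MST metrics
#'
#' The seven-summary suite: maximum degree, maximum betweenness, diameter
#' (longest hop path / M), mean eccentricity, leaf fraction `L/M`, tree
#' hierarchy `L / (2 M BC_max)`, and kappa, the degree divergence
#' `<k^2>/<k>` measuring the breadth of the degree distribution. The band's
#' mean PLI is carried alongside as the eighth group-comparison variable.
#'
#' @param t a `spanning_tree`.
#' @param nm node metrics from [node_metrics()] (computed if missing).
#' @param mean_pli scalar mean PLI to carry along (optional).
#' @return named list of class `tree_metrics` with elements `degree_max`,
#'   `bc_max`, `diameter`, `ecc_mean`, `leaf_fraction`, `tree_hierarchy`,
#'   `kappa`, `mean_pli`.
#' @export
tree_metrics <- function(t, nm = node_metrics(t), mean_pli = NA_real_) {
  stopifnot(inherits(t, "spanning_tree"))
  n <- t$n_nodes
  m <- n - 1L
  bc_max <- max(nm$betweenness)
  if (bc_max <= 0) stop("tree hierarchy undefined: BC_max is 0")
  leaves <- sum(nm$degree == 1L)
  k <- nm$degree
  structure(list(
    degree_max = max(k),
    bc_max = bc_max,
    diameter = max(nm$eccentricity),          # already normalized by M
    ecc_mean = mean(nm$eccentricity),
    leaf_fraction = leaves / m,
    tree_hierarchy = leaves / (2 * m * bc_max),
    kappa = mean(k^2) / mean(k),
    mean_pli = mean_pli),
    class = "tree_metrics")
}

#' @export
print.tree_metrics <- function(x, ...) {
  cat("<tree_metrics>\n")
  for (nm in names(x))
    cat(sprintf("  %-14s %.4f\n", nm, x[[nm]]))
  invisible(x)
}

#' Full MST metric pipeline for one connectivity matrix
#'
#' Composition of [to_weights()], [kruskal_mst()], [node_metrics()] and
#' [tree_metrics()], carrying the matrix's mean PLI.
#'
#' @param cm a `pli_matrix`.
#' @return a `tree_metrics` list (see [tree_metrics()]).
#' @export
metrics_for_subject <- function(cm) {
  t <- kruskal_mst(to_weights(cm))
  tree_metrics(t, mean_pli = mean_pli(cm))
}

#' Metric names used in group comparisons
#' @return character vector of the 8 per-band variables.
#' @export
metric_names <- function() {
  c("mean_pli", "bc_max", "diameter", "ecc_mean", "degree_max",
    "leaf_fraction", "tree_hierarchy", "kappa")
}

#' Serialize a spanning tree as an edge-list CSV
#' @param t a `spanning_tree`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(t, path) {
  stopifnot(inherits(t, "spanning_tree"))
  df <- data.frame(node_i = t$node_labels[t$edges$i],
                   node_j = t$node_labels[t$edges$j],
                   weight = t$edges$weight)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot an MST on a 2-D sensor layout
#'
#' Convenience plot: nodes at their sensor positions (or on a circle when no
#' layout is available) with the tree's edges drawn between them.
#'
#' @param t a `spanning_tree`.
#' @param positions optional nodes x 2 coordinate matrix.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the coordinates used.
#' @export
plot_mst_sensors <- function(t, positions = NULL, ...) {
  n <- t$n_nodes
  if (is.null(positions)) {
    a <- 2 * pi * (seq_len(n) - 1L) / n
    positions <- cbind(cos(a), sin(a))
  }
  graphics::plot(positions, asp = 1, pch = 19, cex = 0.8,
                 xlab = "", ylab = "", axes = FALSE, ...)
  graphics::segments(positions[t$edges$i, 1], positions[t$edges$i, 2],
                     positions[t$edges$j, 1], positions[t$edges$j, 2],
                     col = "grey40")
  graphics::text(positions, labels = t$node_labels, pos = 3, cex = 0.6)
  invisible(positions)
}
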