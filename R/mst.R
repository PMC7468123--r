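#' Maximum-weight spanning tree of a connectivity matrix
#'
#' Functional-connectivity convention: the "minimum spanning tree" of a
#' coherence network is the spanning tree retaining the strongest edges,
#' i.e. the maximum-weight spanning tree (equivalently the minimum spanning
#' tree of reciprocal or negated weights).  Construction is Kruskal's
#' algorithm with a deterministic tie-break: edges sorted by weight
#' descending, then by lexicographic node-index pair, so the tree is unique
#' even with tied weights.
#'
#' @param x A \code{connectivity_matrix} or a symmetric numeric matrix with
#'   positive off-diagonal weights.
#' @return An object of class \code{spanning_tree}: \code{node_ids},
#'   \code{edges} (data frame \code{from}, \code{to}, \code{weight} with
#'   \eqn{N-1} rows, node indices), and \code{n_nodes}.
#' @export
maximum_spanning_tree <- function(x) {
  if (inherits(x, "connectivity_matrix")) {
    W <- x$weights
    ids <- x$node_ids
  } else {
    W <- as.matrix(x)
    ids <- rownames(W)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(W)))
  }
  n <- nrow(W)
  if (n < 2L) stop("need at least 2 nodes")
  if (ncol(W) != n || max(abs(W - t(W))) > 1e-9) stop("matrix must be symmetric")
  ut <- upper.tri(W)
  if (any(W[ut] <= 0)) stop("all off-diagonal weights must be positive (fully connected graph)")

  idx <- which(ut, arr.ind = TRUE)
  w <- W[ut]
  ord <- order(-w, idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  w <- w[ord]

  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  from <- to <- integer(n - 1L)
  wt <- numeric(n - 1L)
  k <- 0L
  for (e in seq_along(w)) {
    ra <- find(idx[e, 1L]); rb <- find(idx[e, 2L])
    if (ra != rb) {
      parent[ra] <- rb
      k <- k + 1L
      from[k] <- idx[e, 1L]; to[k] <- idx[e, 2L]; wt[k] <- w[e]
      if (k == n - 1L) break
    }
  }
  if (k < n - 1L) stop("graph is disconnected")
  structure(list(node_ids = ids, n_nodes = n,
                 edges = data.frame(from = from, to = to, weight = wt)),
            class = "spanning_tree")
}

#' Build a spanning tree from an explicit edge list
#'
#' Mostly used for fixtures (paths, stars) and for reading exported trees.
#'
#' @param n_nodes Number of nodes.
#' @param from,to Integer node indices of each edge (length \eqn{N-1}).
#' @param weight Edge weights (recycled).
#' @param node_ids Optional node identifiers.
#' @return A \code{spanning_tree}.
#' @export
spanning_tree <- function(n_nodes, from, to, weight = 1, node_ids = NULL) {
  n <- as.integer(n_nodes)
  if (length(from) != n - 1L || length(to) != n - 1L) stop("a tree on N nodes has N-1 edges")
  edges <- data.frame(from = as.integer(from), to = as.integer(to),
                      weight = rep_len(as.numeric(weight), n - 1L))
  tr <- structure(list(node_ids = node_ids %||% as.character(seq_len(n)),
                       n_nodes = n, edges = edges),
                  class = "spanning_tree")
  adj <- .tree_adjacency(tr)   # validates connectivity/acyclicity via reach
  seen <- .bfs_order(adj, 1L)
  if (length(seen) != n) stop("edge list does not form a spanning tree")
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Adjacency list of a tree (list of integer neighbour vectors).
.tree_adjacency <- function(tree) {
  adj <- vector("list", tree$n_nodes)
  for (e in seq_len(nrow(tree$edges))) {
    a <- tree$edges$from[e]; b <- tree$edges$to[e]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

.bfs_order <- function(adj, root) {
  n <- length(adj)
  seen <- logical(n)
  queue <- integer(n); queue[1L] <- root; seen[root] <- TRUE
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (u in adj[[v]]) if (!seen[u]) { tail <- tail + 1L; queue[tail] <- u; seen[u] <- TRUE }
  }
  queue[seq_len(tail)]
}

# BFS distances (in edges) from a root.
.bfs_depths <- function(adj, root) {
  n <- length(adj)
  depth <- rep(NA_integer_, n)
  depth[root] <- 0L
  queue <- integer(n); queue[1L] <- root
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (u in adj[[v]]) if (is.na(depth[u])) {
      depth[u] <- depth[v] + 1L
      tail <- tail + 1L; queue[tail] <- u
    }
  }
  depth
}

#' Mean MST edge weight (connectivity strength)
#'
#' @param tree A \code{spanning_tree}.
#' @return Arithmetic mean of the \eqn{N-1} edge weights.
#' @export
mean_edge_weight <- function(tree) mean(tree$edges$weight)

#' Tree diameter
#'
#' Longest path between any two nodes, counted in edges (all edges length 1),
#' found with the standard double-BFS sweep.  Also returned normalised by the
#' edge count \eqn{N-1}.
#'
#' @param tree A \code{spanning_tree}.
#' @return List with \code{diameter_edges} and \code{diameter_norm}.
#' @export
tree_diameter <- function(tree) {
  adj <- .tree_adjacency(tree)
  d1 <- .bfs_depths(adj, 1L)
  far <- which.max(d1)
  d2 <- .bfs_depths(adj, far)
  de <- max(d2)
  list(diameter_edges = as.integer(de),
       diameter_norm = de / (tree$n_nodes - 1L))
}

#' Per-node degree
#'
#' @param tree A \code{spanning_tree}.
#' @return Integer vector of edge counts per node (sums to \eqn{2(N-1)}).
#' @export
degree_vector <- function(tree) {
  tabulate(c(tree$edges$from, tree$edges$to), nbins = tree$n_nodes)
}

#' Degree divergence (kappa)
#'
#' \eqn{\kappa = \langle k^2 \rangle / \langle k \rangle} over all nodes; a
#' broad degree distribution (dominant hubs) gives large kappa.  For trees,
#' a star attains \eqn{N/2} and a path \eqn{(4N-6)/(2N-2)}.
#'
#' @param tree A \code{spanning_tree}.
#' @return Kappa.
#' @export
tree_kappa <- function(tree) {
  k <- degree_vector(tree)
  mean(k^2) / mean(k)
}

#' Leaf fraction
#'
#' Fraction of nodes with exactly one edge, a measure of how star-like
#' (integrated) the backbone is.
#'
#' @param tree A \code{spanning_tree}.
#' @return Leaves / N.
#' @export
leaf_fraction <- function(tree) mean(degree_vector(tree) == 1L)

#' Normalised betweenness centrality on a tree
#'
#' For node \eqn{x}, the fraction of unordered pairs \eqn{\{y, z\}} (both
#' \eqn{\ne x}) whose unique tree path passes through \eqn{x}, normalised by
#' \eqn{(N-1)(N-2)/2} so a star hub attains exactly 1 and every leaf 0.
#' In a tree each pair has exactly one path, so this is exact combinatorics
#' on subtree sizes, not path sampling: removing \eqn{x} splits the tree into
#' components of sizes \eqn{s_1, \dots, s_k}, and the passing pairs number
#' \eqn{((N-1)^2 - \sum s_i^2)/2}.
#'
#' @param tree A \code{spanning_tree}.
#' @return Numeric vector of betweenness values in \eqn{[0, 1]}.
#' @export
betweenness_vector <- function(tree) {
  n <- tree$n_nodes
  adj <- .tree_adjacency(tree)
  order <- .bfs_order(adj, 1L)
  parent <- integer(n)
  parent[1L] <- 0L
  for (v in order) for (u in adj[[v]]) if (u != parent[v]) parent[u] <- v
  size <- rep(1L, n)
  for (v in rev(order)) if (parent[v] > 0L) size[parent[v]] <- size[parent[v]] + size[v]
  btw <- numeric(n)
  for (x in seq_len(n)) {
    comp <- size[adj[[x]][adj[[x]] != parent[x]]]        # child components
    if (parent[x] > 0L) comp <- c(comp, n - size[x])     # parent side
    btw[x] <- ((n - 1)^2 - sum(comp^2)) / 2
  }
  if (n > 2L) btw / ((n - 1) * (n - 2) / 2) else rep(0, n)
}

#' Edge overlap of two spanning trees
#'
#' Fraction of undirected edges shared by two spanning trees on the same node
#' set: 1 for identical trees, 0 for edge-disjoint ones.
#'
#' @param tree_a,tree_b \code{spanning_tree} objects on identical node sets.
#' @return Overlap in \eqn{[0, 1]}.
#' @export
tree_overlap <- function(tree_a, tree_b) {
  if (tree_a$n_nodes != tree_b$n_nodes ||
      !identical(tree_a$node_ids, tree_b$node_ids)) {
    stop("trees must share an identical node set")
  }
  key <- function(tr) {
    a <- pmin(tr$edges$from, tr$edges$to)
    b <- pmax(tr$edges$from, tr$edges$to)
    paste(a, b)
  }
  length(intersect(key(tree_a), key(tree_b))) / (tree_a$n_nodes - 1L)
}

#' Global MST metrics of one tree
#'
#' @param tree A \code{spanning_tree}.
#' @return One-row data frame: \code{strength}, \code{diameter_edges},
#'   \code{diameter_norm}, \code{kappa}, \code{leaf_fraction}.
#' @export
mst_global_metrics <- function(tree) {
  di <- tree_diameter(tree)
  data.frame(strength = mean_edge_weight(tree),
             diameter_edges = di$diameter_edges,
             diameter_norm = di$diameter_norm,
             kappa = tree_kappa(tree),
             leaf_fraction = leaf_fraction(tree))
}

#' Nodal MST metrics of one tree
#'
#' @param tree A \code{spanning_tree}.
#' @return Data frame: \code{node_id}, \code{degree}, \code{betweenness}.
#' @export
mst_nodal_metrics <- function(tree) {
  data.frame(node_id = tree$node_ids,
             degree = degree_vector(tree),
             betweenness = betweenness_vector(tree))
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("spanning_tree: %d nodes, %d edges, strength %.4f\n",
              x$n_nodes, nrow(x$edges), mean_edge_weight(x)))
  invisible(x)
}
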