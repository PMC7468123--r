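test_that("the strongest-edge backbone is selected on a worked 3-node example", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.9  # ab
  W[1, 3] <- W[3, 1] <- 0.5  # ac
  W[2, 3] <- W[3, 2] <- 0.8  # bc
  tr <- maximum_spanning_tree(W)
  expect_equal(sum(tr$edges$weight), 1.7)
  key <- paste(pmin(tr$edges$from, tr$edges$to), pmax(tr$edges$from, tr$edges$to))
  expect_setequal(key, c("1 2", "2 3"))
})

test_that("two nodes yield the single connecting edge", {
  W <- matrix(c(0, 0.4, 0.4, 0), 2)
  tr <- maximum_spanning_tree(W)
  expect_equal(nrow(tr$edges), 1L)
  expect_equal(tr$edges$weight, 0.4)
  d <- tree_diameter(tr)
  expect_equal(d$diameter_edges, 1L)
  expect_equal(d$diameter_norm, 1)
  expect_equal(leaf_fraction(tr), 1)
})

test_that("tree weight matches exhaustive spanning-tree enumeration on small graphs", {
  for (i in 1:40) {
    n <- 3 + (i %% 4)  # sizes 3..6 here; the full n<=7 sweep runs in acceptance
    W <- rand_sym_matrix(n, seed = 900 + i)
    tr <- maximum_spanning_tree(W)
    expect_equal(sum(tr$edges$weight), brute_force_max_tree_weight(W),
                 tolerance = 1e-12)
  }
})

test_that("backbone agrees with an independent graph-library implementation", {
  skip_if_not_installed("igraph")
  for (i in 1:10) {
    W <- rand_sym_matrix(25, seed = 40 + i)
    tr <- maximum_spanning_tree(W)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    ig <- igraph::mst(g, weights = -igraph::E(g)$weight)
    expect_equal(sum(tr$edges$weight), sum(igraph::E(ig)$weight),
                 tolerance = 1e-12)
  }
})

test_that("global metrics match hand values for stars and paths", {
  s5 <- star_tree(5); p5 <- path_tree(5)
  expect_equal(tree_diameter(p5)$diameter_edges, 4L)
  expect_equal(tree_diameter(p5)$diameter_norm, 1)
  expect_equal(tree_diameter(s5)$diameter_edges, 2L)
  expect_equal(tree_diameter(s5)$diameter_norm, 0.5)
  expect_equal(tree_kappa(s5), 2.5)    # degrees (4,1,1,1,1)
  expect_equal(tree_kappa(p5), 1.75)   # degrees (1,2,2,2,1)
  expect_equal(leaf_fraction(s5), 0.8)
  expect_equal(leaf_fraction(p5), 0.4)
  expect_equal(degree_vector(s5), c(4L, 1L, 1L, 1L, 1L))
})

test_that("kappa and leaf fraction follow their closed forms for N = 3..12", {
  for (N in 3:12) {
    expect_equal(tree_kappa(star_tree(N)), N / 2)
    expect_equal(tree_kappa(path_tree(N)), (4 * N - 6) / (2 * N - 2))
    expect_equal(leaf_fraction(star_tree(N)), (N - 1) / N)
    expect_equal(sum(degree_vector(path_tree(N))), 2L * (N - 1L))
  }
})

test_that("strength is the mean edge weight and scales linearly", {
  tr <- spanning_tree(3, from = c(1, 2), to = c(2, 3), weight = c(0.9, 0.8))
  expect_equal(mean_edge_weight(tr), 0.85)
  tr$edges$weight <- tr$edges$weight * 3
  expect_equal(mean_edge_weight(tr), 0.85 * 3)
})

test_that("tree betweenness is exact pair combinatorics", {
  s10 <- star_tree(10)
  b <- betweenness_vector(s10)
  expect_equal(b[1], 1)                   # hub of a star
  expect_equal(b[2:10], rep(0, 9))        # leaves
  p5 <- path_tree(5)
  expect_equal(betweenness_vector(p5)[3], 4 / 6)  # middle node
  skip_if_not_installed("igraph")
  set.seed(77)
  W <- rand_sym_matrix(20, seed = 123)
  tr <- maximum_spanning_tree(W)
  g <- igraph::graph_from_edgelist(cbind(tr$edges$from, tr$edges$to),
                                   directed = FALSE)
  ref <- igraph::betweenness(g, weights = rep(1, 19)) / (19 * 18 / 2)
  expect_equal(betweenness_vector(tr), unname(ref), tolerance = 1e-12)
})

test_that("edge overlap spans identical, partial and disjoint trees", {
  a <- spanning_tree(4, from = c(1, 2, 3), to = c(2, 3, 4))
  b <- spanning_tree(4, from = c(1, 1, 2), to = c(3, 4, 4))
  expect_equal(tree_overlap(a, a), 1)
  expect_equal(tree_overlap(a, b), 0)
  c_ <- spanning_tree(4, from = c(1, 1, 3), to = c(2, 3, 4))  # shares 1-2, 3-4 with a
  expect_equal(tree_overlap(a, c_), 2 / 3)
  d_ <- spanning_tree(4, from = c(1, 2, 2), to = c(2, 3, 4))  # shares 1-2, 2-3
  expect_equal(tree_overlap(a, d_), 2 / 3)
  e_ <- spanning_tree(4, from = c(2, 1, 1), to = c(1, 3, 4))  # shares only 1-2
  expect_equal(tree_overlap(a, e_), 1 / 3)
  expect_error(tree_overlap(a, star_tree(5)), "identical node set")
})

test_that("rescaling weights leaves topology metrics bit-identical and scales strength", {
  for (i in 1:5) {
    W <- rand_sym_matrix(15, seed = 200 + i)
    tr <- maximum_spanning_tree(W)
    for (c_scale in c(0.5, 2, 3.7)) {
      tr2 <- maximum_spanning_tree(W * c_scale)
      expect_identical(tr2$edges$from, tr$edges$from)
      expect_identical(tr2$edges$to, tr$edges$to)
      expect_identical(tree_diameter(tr2), tree_diameter(tr))
      expect_identical(tree_kappa(tr2), tree_kappa(tr))
      expect_identical(leaf_fraction(tr2), leaf_fraction(tr))
      expect_identical(degree_vector(tr2), degree_vector(tr))
      expect_identical(betweenness_vector(tr2), betweenness_vector(tr))
      expect_equal(mean_edge_weight(tr2), mean_edge_weight(tr) * c_scale)
    }
  }
})

test_that("invalid matrices are rejected", {
  W <- rand_sym_matrix(5, seed = 1)
  W[1, 2] <- W[1, 2] + 0.1   # asymmetric
  expect_error(maximum_spanning_tree(W), "symmetric")
  W2 <- rand_sym_matrix(5, seed = 2)
  W2[1, 3] <- W2[3, 1] <- 0  # not fully connected
  expect_error(maximum_spanning_tree(W2), "positive")
})

test_that("hub-heavier simulator templates produce hubbier backbones on average", {
  res <- sapply(c(0.1, 0.4), function(boost) {
    rowMeans(sapply(1:8, function(i) {
      tpl <- make_template(30, 4, 0.25, boost, jitter_sd = 0.02, seed = i)
      cm <- build_connectivity_matrix(simulate_panel(tpl, seed = 100 + i))
      tr <- maximum_spanning_tree(cm)
      c(kappa = tree_kappa(tr), leaf = leaf_fraction(tr))
    }))
  })
  expect_gt(res["kappa", 2], res["kappa", 1])
  expect_gt(res["leaf", 2], res["leaf", 1])
})
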