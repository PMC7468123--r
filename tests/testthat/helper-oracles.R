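# Fixtures and independent oracles shared across the suite.

# Star on n nodes: node 1 is the hub.
star_tree <- function(n, weight = 1) {
  spanning_tree(n, from = rep(1L, n - 1L), to = 2:n, weight = weight)
}

# Path 1-2-...-n.
path_tree <- function(n, weight = 1) {
  spanning_tree(n, from = 1:(n - 1L), to = 2:n, weight = weight)
}

# Random symmetric positive-weight matrix with (almost surely) distinct
# weights.
rand_sym_matrix <- function(n, seed) {
  set.seed(seed)
  W <- matrix(stats::runif(n * n, 0.05, 1), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

# Prufer-sequence decoding: a sequence over 1..n of length n-2 maps to a
# labelled tree; enumerating all sequences enumerates all n^(n-2) spanning
# trees of the complete graph.
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (v in seq) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (i in seq_along(seq)) {
    leaf <- which(degree == 1L)[1L]   # smallest remaining leaf
    v <- seq[i]
    edges[i, ] <- c(leaf, v)
    degree[leaf] <- 0L                # consumed
    degree[v] <- degree[v] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

# Brute-force maximum spanning-tree weight by exhaustive Prufer enumeration.
brute_force_max_tree_weight <- function(W) {
  n <- nrow(W)
  if (n == 2L) return(W[1L, 2L])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- -Inf
  for (r in seq_len(nrow(seqs))) {
    ed <- prufer_decode(as.integer(seqs[r, ]), n)
    tw <- sum(W[ed])
    if (tw > best) best <- tw
  }
  best
}

# Brute-force BH step-up: scan all cutoffs.
brute_force_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kstar <- 0L
  for (k in seq_len(m)) if (ps[k] <= k * q / m) kstar <- k
  flags <- rep(FALSE, m)
  if (kstar > 0L) flags[ord[seq_len(kstar)]] <- TRUE
  flags
}

# Small metrics table for inference tests: n subjects per group, optional
# planted group shifts and covariate effect.
simulate_metric_table <- function(n_per_group, groups = c("A", "B"),
                                  shifts = NULL, age_effect = 0, sd = 1,
                                  seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_along(groups), function(gi) {
    g <- groups[gi]
    age <- rnorm(n_per_group, 40, 10)
    sex <- sample(c("male", "female"), n_per_group, replace = TRUE)
    edu <- rnorm(n_per_group, 14, 2)
    shift <- if (is.null(shifts)) 0 else shifts[gi]
    y <- shift + age_effect * age + rnorm(n_per_group, sd = sd)
    data.frame(subject_id = paste0(g, seq_len(n_per_group)), group = g,
               age = age, sex = sex, education = edu, y = y,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
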