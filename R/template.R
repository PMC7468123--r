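#' Core-periphery coherence target
#'
#' Ground-truth template for the simulator: a symmetric zero-diagonal matrix
#' of target band coherences in which every edge incident to a hub node is
#' set to \code{base_level + hub_boost} and all remaining edges to
#' \code{base_level}, plus optional small seeded jitter.
#'
#' @param n_nodes Number of regions.
#' @param hub_count Number of hub nodes (the first \code{hub_count} indices).
#' @param base_level Peripheral target coherence in \eqn{[0, 1)}.
#' @param hub_boost Additional coherence on hub-incident edges;
#'   \code{base_level + hub_boost} must stay \eqn{\le 0.95}.
#' @param jitter_sd Standard deviation of symmetric edge-wise jitter
#'   (0 disables it).
#' @param seed Seed for the jitter.
#' @return An object of class \code{template_network}: \code{node_count},
#'   \code{target_coherence}, \code{hub_nodes}.
#' @export
make_template <- function(n_nodes, hub_count, base_level = 0.30,
                          hub_boost = 0.35, jitter_sd = 0, seed = 1L) {
  n <- as.integer(n_nodes)
  if (n <= 0L) stop("n_nodes must be positive")
  if (hub_count < 0L || hub_count >= n) stop("hub_count must be in [0, n_nodes)")
  if (base_level < 0 || hub_boost < 0 || base_level + hub_boost > 0.95) {
    stop("levels must satisfy 0 <= base_level and base_level + hub_boost <= 0.95")
  }
  C <- matrix(base_level, n, n)
  hubs <- seq_len(hub_count)
  if (hub_count > 0L) {
    C[hubs, ] <- base_level + hub_boost
    C[, hubs] <- base_level + hub_boost
  }
  if (jitter_sd > 0) {
    set.seed(seed)
    J <- matrix(stats::rnorm(n * n, sd = jitter_sd), n, n)
    C <- C + (J + t(J)) / 2
    C <- pmin(pmax(C, 0), 0.95)
  }
  diag(C) <- 0
  structure(list(node_count = n, target_coherence = C,
                 hub_nodes = as.integer(hubs)),
            class = "template_network")
}

.check_template <- function(template) {
  C <- template$target_coherence
  stopifnot(is.matrix(C), nrow(C) == ncol(C),
            max(abs(C - t(C))) < 1e-9, all(diag(C) == 0),
            all(C >= 0), all(C <= 1))
  invisible(template)
}

#' Apply a diagnostic-group effect to a coherence target
#'
#' Encodes the two planted group signatures the pipeline is designed to
#' dissociate: a global connectivity-strength deficit with unchanged topology
#' (schizophrenia-spectrum-like: \code{SCZ}, \code{SCP}) and a
#' topology-flattening with exactly preserved mean coherence
#' (bipolar-like: \code{BD}).  \code{HC} leaves the target untouched.
#'
#' For \code{SCZ}/\code{SCP} every off-diagonal entry is multiplied by
#' \eqn{1 - d}.  For \code{BD}, hub-incident edges are shrunk toward and
#' peripheral edges raised toward the global off-diagonal mean by the
#' flattening fraction, then the matrix is rescaled so its off-diagonal mean
#' equals the template's mean exactly.
#'
#' @param template A \code{template_network}.
#' @param group One of \code{"HC"}, \code{"SCP"}, \code{"SCZ"}, \code{"BD"}.
#' @param strength_deficit Fraction in \eqn{[0, 1)}.
#' @param topology_flattening Fraction in \eqn{[0, 1)}.
#' @return The modified \code{template_network}.
#' @export
apply_group_effect <- function(template, group, strength_deficit = 0,
                               topology_flattening = 0) {
  .check_template(template)
  if (!group %in% c("HC", "SCP", "SCZ", "BD")) {
    stop("unknown group label: ", group)
  }
  if (strength_deficit < 0 || strength_deficit >= 1 ||
      topology_flattening < 0 || topology_flattening >= 1) {
    stop("effect fractions must lie in [0, 1)")
  }
  C <- template$target_coherence
  if (group %in% c("SCZ", "SCP")) {
    C <- C * (1 - strength_deficit)
  } else if (group == "BD" && topology_flattening > 0) {
    C <- flatten_topology(C, topology_flattening)
  }
  template$target_coherence <- C
  template
}

#' Flatten the hub structure of a coherence matrix
#'
#' Moves every off-diagonal entry toward the global off-diagonal mean by
#' fraction \code{f}, then rescales multiplicatively so the off-diagonal mean
#' is preserved exactly (to machine precision).  With a two-level
#' hub/periphery target this shrinks hub-incident edges and raises peripheral
#' ones, reducing degree diversity of the downstream backbone while leaving
#' average coherence untouched.
#'
#' @param C Symmetric zero-diagonal coherence matrix.
#' @param f Flattening fraction in \eqn{[0, 1)}.
#' @return Flattened matrix.
#' @export
flatten_topology <- function(C, f) {
  off <- upper.tri(C)
  m <- mean(C[off])
  C2 <- C + f * (m - C)
  C2 <- C2 * (m / mean(C2[off]))
  diag(C2) <- 0
  C2
}

#' Nearest-correlation projection by eigenvalue clipping
#'
#' Arbitrary coherence targets need not be valid correlation matrices; the
#' simulator therefore clips negative eigenvalues at a small floor and
#' renormalises to unit diagonal.  For infeasible core-periphery targets the
#' projection yields the closest realisable structure (hub coherences are
#' bounded by feasibility, roughly \eqn{C_{hub} \le \sqrt{C_{periphery}}}).
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param eig_floor Eigenvalue floor.
#' @return Positive-definite correlation matrix.
#' @export
nearest_correlation <- function(R, eig_floor = 1e-6) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eig_floor)
  M <- e$vectors %*% (vals * t(e$vectors))
  stats::cov2cor(M)
}

#' @export
print.template_network <- function(x, ...) {
  off <- x$target_coherence[upper.tri(x$target_coherence)]
  cat(sprintf("template_network: %d nodes, %d hubs, mean target %.3f (range %.3f-%.3f)\n",
              x$node_count, length(x$hub_nodes), mean(off), min(off), max(off)))
  invisible(x)
}
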