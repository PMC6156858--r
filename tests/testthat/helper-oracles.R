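# Independent oracles and small fixture builders used across the suite.
# Each oracle is implemented from first principles, on a different code path
# than the functions it checks.

# Hypergeometric upper tail P(X >= k) by direct enumeration with choose().
hyper_tail_oracle <- function(k, K, N, n) {
  j <- seq(from = k, to = min(K, n))
  if (length(j) == 0L || k > min(K, n)) return(if (k <= 0) 1 else 0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Exhaustive minimum of the spin-glass Hamiltonian over all set partitions,
# enumerated as restricted growth strings; H computed directly from the
# adjacency matrix (not via hamiltonian()).
brute_force_min_hamiltonian <- function(g, gamma = 1) {
  gu <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  A <- igraph::as_adjacency_matrix(gu, sparse = FALSE)
  n <- nrow(A)
  k <- rowSums(A)
  m <- sum(k) / 2
  H_of <- function(lab) {
    H <- 0
    for (c in unique(lab)) {
      idx <- which(lab == c)
      if (length(idx) < 2L) next
      e_in <- sum(A[idx, idx]) / 2
      Kc <- sum(k[idx])
      H <- H - (e_in - gamma * (Kc^2 - sum(k[idx]^2)) / 2 / (2 * m))
    }
    H
  }
  best <- Inf
  lab <- integer(n); lab[1] <- 1L
  recurse <- function(i, mx) {
    if (i > n) {
      best <<- min(best, H_of(lab))
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) {
      lab[i] <<- v
      recurse(i + 1L, max(mx, v))
    }
  }
  if (n == 1L) return(0)
  recurse(2L, 1L)
  best
}

# Dominant eigenvector of A^T A (nonnegative, unit L2) via dense eigen().
# Returns NULL when the dominant eigenvalue is not well separated, in which
# case the eigenvector is not uniquely defined and no comparison is made.
hits_eigen_oracle <- function(A, min_gap_ratio = 0.9) {
  e <- eigen(crossprod(A), symmetric = TRUE)
  if (length(e$values) > 1 && e$values[2] > min_gap_ratio * e$values[1]) {
    return(NULL)
  }
  v <- abs(e$vectors[, 1])
  v / sqrt(sum(v^2))
}

# Two 4-cliques joined by a single bridge edge; the canonical case where the
# minimum-H partition is exactly the two cliques.
two_clique_bridge <- function() {
  el <- rbind(t(utils::combn(1:4, 2)), t(utils::combn(5:8, 2)), c(4, 5))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$name <- letters[1:8]
  g
}

# Hand-built 6-term ontology: root r; mid m1, m2; leaves l1, l2 under m1 and
# l3 under m2. Edges child -> parent.
toy_ontology <- function() {
  ontology(data.frame(
    child  = c("m1", "m2", "l1", "l2", "l3"),
    parent = c("r",  "r",  "m1", "m1", "m2")))
}

# Minimal two-plate set with noiseless, hand-computable signals.
toy_plates <- function() {
  data.frame(
    plate_id = rep(c("p1", "p2"), each = 5),
    well = rep(c("A1", "A2", "A3", "A4", "A5"), 2),
    role = rep(c("compound", "neg", "neg", "pos", "pos"), 2),
    compound_id = rep(c("cmpdX", NA, NA, NA, NA), 2),
    intensity = c(60, 100, 100, 20, 20,
                  60, 200, 200, 40, 40))
}
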