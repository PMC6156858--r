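# Ontology-graph summarization: induced subgraph of significant terms plus
# ancestors, spin-glass Potts-model community detection, HITS authority
# scores, representative selection and graph collapse.

#' Induced ontology subgraph of significant terms and their ancestors
#'
#' Node set is the significant terms plus every ancestor; edges are the
#' ontology's induced child -> parent edges. Significant terms carry a
#' logical `significant` vertex attribute.
#'
#' @param significant_terms non-empty character vector of term ids.
#' @param onto an [ontology()] object.
#' @return A directed [igraph::graph] with vertex attributes `significant`
#'   and `term_name`.
#' @export
build_subgraph <- function(significant_terms, onto) {
  stopifnot(inherits(onto, "ontology"))
  significant_terms <- unique(significant_terms)
  if (length(significant_terms) == 0L) stop("no significant terms supplied")
  unknown <- setdiff(significant_terms, onto$terms)
  if (length(unknown)) {
    stop("unknown term id(s): ", paste(unknown, collapse = ", "))
  }
  anc <- unique(unlist(lapply(significant_terms, ancestors, onto = onto),
                       use.names = FALSE))
  nodes <- unique(c(significant_terms, anc))
  g <- igraph::induced_subgraph(onto$graph, nodes)
  igraph::V(g)$significant <- igraph::V(g)$name %in% significant_terms
  igraph::V(g)$term_name <- unname(onto$names[igraph::V(g)$name])
  g
}

#' Spin-glass Potts-model Hamiltonian of a partition
#'
#' Evaluates H(sigma) = -sum over pairs i < j of
#' `(A_ij - gamma * k_i * k_j / (2m)) * delta(sigma_i, sigma_j)` on the
#' undirected simple view of the graph (Reichardt-Bornholdt configuration
#' null model; at `gamma = 1`, minimizing H is equivalent to maximizing
#' Newman modularity). An edgeless graph has H = 0 for every partition.
#'
#' @param graph an igraph object (any directions/multi-edges are collapsed).
#' @param partition named integer vector of community labels covering every
#'   vertex name.
#' @param gamma resolution parameter (default 1).
#' @return H as a single double.
#' @export
hamiltonian <- function(graph, partition, gamma = 1) {
  nodes <- igraph::V(graph)$name
  if (!all(nodes %in% names(partition))) {
    stop("partition does not label node(s): ",
         paste(setdiff(nodes, names(partition)), collapse = ", "))
  }
  gu <- igraph::simplify(igraph::as_undirected(graph, mode = "collapse"))
  m <- igraph::ecount(gu)
  if (m == 0L) return(0)
  A <- igraph::as_adjacency_matrix(gu, sparse = FALSE)
  k <- igraph::degree(gu)
  lab <- partition[nodes]
  H <- 0
  for (c in unique(lab)) {
    idx <- which(lab == c)
    if (length(idx) < 2L) next
    e_within <- sum(A[idx, idx]) / 2
    Kc <- sum(k[idx])
    null_pairs <- (Kc^2 - sum(k[idx]^2)) / 2
    H <- H - (e_within - gamma * null_pairs / (2 * m))
  }
  H
}

# Simulated annealing + greedy polish on one connected component.
# A: dense symmetric 0/1 adjacency; returns integer labels 1..q'.
anneal_component <- function(A, gamma, max_spins, schedule, greedy_only) {
  n <- nrow(A)
  if (n == 1L) return(1L)
  k <- rowSums(A)
  m <- sum(k) / 2
  fac <- gamma / (2 * m)
  q <- min(n, max_spins)
  neigh <- lapply(seq_len(n), function(i) which(A[i, ] > 0))

  lab <- if (greedy_only) seq_len(n) %% q + 1L else
    sample.int(q, n, replace = TRUE)
  Kc <- vapply(seq_len(q), function(c) sum(k[lab == c]), numeric(1))

  # attraction of node i to label c (excluding i itself):
  #   S(c; i) = e_ic - gamma * k_i * (K_c - [sigma_i == c] k_i) / (2m)
  delta_move <- function(i, b) {
    a <- lab[i]
    nl <- lab[neigh[[i]]]
    e_ib <- sum(nl == b)
    e_ia <- sum(nl == a)
    S_b <- e_ib - fac * k[i] * Kc[b]
    S_a <- e_ia - fac * k[i] * (Kc[a] - k[i])
    S_a - S_b          # H_new - H_old
  }
  apply_move <- function(i, b) {
    Kc[lab[i]] <<- Kc[lab[i]] - k[i]
    Kc[b] <<- Kc[b] + k[i]
    lab[i] <<- b
  }

  if (!greedy_only) {
    t <- schedule$t_start
    while (t > schedule$t_stop) {
      for (rep_i in seq_len(n)) {
        i <- sample.int(n, 1L)
        b <- sample.int(q, 1L)
        if (b == lab[i]) next
        dH <- delta_move(i, b)
        if (dH < 0 || stats::runif(1) < exp(-dH / t)) apply_move(i, b)
      }
      t <- t * schedule$cooling
    }
  }

  # zero-temperature polish: best single-node move until local minimum.
  # Candidates: neighbour labels and (if available) one empty label; any
  # other occupied label is dominated by the empty one.
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      cand <- unique(lab[neigh[[i]]])
      empty <- which(Kc == 0)
      if (length(empty)) cand <- c(cand, empty[1])
      cand <- setdiff(cand, lab[i])
      if (!length(cand)) next
      dH <- vapply(cand, function(b) delta_move(i, b), numeric(1))
      j <- which.min(dH)
      if (dH[j] < -1e-12) {
        apply_move(i, cand[j])
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  match(lab, unique(lab))
}

#' Spin-glass community detection
#'
#' Minimizes the Potts-model [hamiltonian()] on the undirected simple view
#' of the graph by simulated annealing over single-node label moves with at
#' most `max_spins` labels, followed by a greedy best-move polish, keeping
#' the best of `n_restarts` annealed restarts plus one deterministic greedy
#' run. Disconnected graphs are partitioned per weakly-connected component
#' with globally distinct labels. Deterministic under a fixed seed.
#'
#' @param graph an igraph object over term nodes.
#' @param gamma resolution parameter of the null model (default 1).
#' @param max_spins maximum number of spin states per component (default
#'   200, the cap used in the original analysis).
#' @param seed integer seed.
#' @param schedule list with `t_start`, `t_stop`, `cooling` (geometric
#'   factor per sweep) and `sweeps` (proposals per temperature, in units of
#'   node count).
#' @param n_restarts annealed restarts (default 5).
#' @return Named integer vector of community labels (1..q, contiguous) over
#'   the vertex names, with attribute `hamiltonian` (sum over components of
#'   the minimized H).
#' @export
spinglass_partition <- function(graph, gamma = 1, max_spins = 200L,
                                seed = 1L,
                                schedule = list(t_start = 1, t_stop = 0.01,
                                                cooling = 0.99, sweeps = 1),
                                n_restarts = 5L) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph")
  stop_if_not_count(max_spins, "max_spins")
  nodes <- igraph::V(graph)$name %||% as.character(seq_len(n))
  gu <- igraph::simplify(igraph::as_undirected(graph, mode = "collapse"))
  if (igraph::ecount(gu) == 0L) {
    warning("graph has no edges: every node is its own community")
    part <- stats::setNames(seq_len(n), nodes)
    attr(part, "hamiltonian") <- 0
    return(part)
  }
  comps <- igraph::components(gu, mode = "weak")
  part <- stats::setNames(integer(n), nodes)
  offset <- 0L
  total_H <- 0
  for (ci in seq_len(comps$no)) {
    members <- nodes[comps$membership == ci]
    sub <- igraph::induced_subgraph(gu, members)
    A <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
    sub_nodes <- igraph::V(sub)$name
    best <- NULL
    for (r in 0:n_restarts) {
      lab <- with_seed(derive_seed(seed, "spinglass", ci, r), {
        anneal_component(A, gamma, max_spins, schedule,
                         greedy_only = (r == 0L))
      })
      H <- hamiltonian(sub, stats::setNames(lab, sub_nodes), gamma)
      if (is.null(best) || H < best$H - 1e-12) best <- list(lab = lab, H = H)
    }
    part[sub_nodes] <- best$lab + offset
    offset <- offset + max(best$lab)
    total_H <- total_H + best$H
  }
  # relabel contiguously in order of first appearance over the node order
  part[] <- match(part, unique(part))
  attr(part, "hamiltonian") <- total_H
  part
}

#' HITS authority scores
#'
#' Power iteration of the hub/authority recurrence (h <- A a, a <- A^T h
#' with L2 normalization) until the L1 change of the authority vector falls
#' below `tol`; the fixed point is the dominant eigenvector of A^T A. With
#' ontology edges directed child -> parent, authority accumulates at
#' general (ancestral) terms — the "highest in-degree" node of each
#' community.
#'
#' @param graph a directed igraph object.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter iteration cap (default 1000).
#' @return Named numeric vector of nonnegative authority scores with unit L2
#'   norm; an edgeless graph returns all zeros with attribute
#'   `degenerate = TRUE`.
#' @export
authority_scores <- function(graph, tol = 1e-10, max_iter = 1000L) {
  n <- igraph::vcount(graph)
  nodes <- igraph::V(graph)$name %||% as.character(seq_len(n))
  if (igraph::ecount(graph) == 0L) {
    s <- stats::setNames(rep(0, n), nodes)
    attr(s, "degenerate") <- TRUE
    return(s)
  }
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  a <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    h <- A %*% a
    a_new <- crossprod(A, h)
    nrm <- sqrt(sum(a_new^2))
    if (nrm == 0) {
      s <- stats::setNames(rep(0, n), nodes)
      attr(s, "degenerate") <- TRUE
      return(s)
    }
    a_new <- as.vector(a_new) / nrm
    if (sum(abs(a_new - a)) < tol) {
      return(stats::setNames(a_new, nodes))
    }
    a <- a_new
  }
  stop(sprintf("HITS failed to converge in %d iterations (residual %.3g)",
               max_iter, sum(abs(a_new - a))))
}

#' Select a representative term per community by maximal authority
#'
#' Within each community the member with the highest authority score
#' represents it; when several members tie exactly for the maximum, one is
#' drawn uniformly at random. The tie-break RNG stream is derived from
#' (seed, community label), so adding a community never perturbs another's
#' choice.
#'
#' @param partition named community labels from [spinglass_partition()].
#' @param scores named authority scores from [authority_scores()] covering
#'   every node of `partition`.
#' @param seed integer seed for tie-breaking.
#' @param tie_tol relative tolerance for score ties (default 1e-12 of the
#'   community maximum; floating-point scores from identical arithmetic
#'   symmetric positions tie exactly).
#' @return Named character vector: community label -> representative term.
#' @export
select_representatives <- function(partition, scores, seed = 1L,
                                   tie_tol = 1e-12) {
  if (!all(names(partition) %in% names(scores))) {
    stop("scores do not cover node(s): ",
         paste(setdiff(names(partition), names(scores)), collapse = ", "))
  }
  labs <- sort(unique(as.integer(partition)))
  reps <- character(length(labs))
  names(reps) <- as.character(labs)
  for (i in seq_along(labs)) {
    members <- names(partition)[partition == labs[i]]
    s <- scores[members]
    mx <- max(s)
    tied <- members[s >= mx - tie_tol * max(1, abs(mx))]
    reps[i] <- if (length(tied) == 1L) tied else
      with_seed(derive_seed(seed, "rep", labs[i]),
                tied[sample.int(length(tied), 1L)])
  }
  reps
}

#' Collapse a term graph onto per-community representative nodes
#'
#' Stage 1 contracts every community into its representative: one community
#' node per community (carrying the representative term id and the member
#' count) and directed inter-community edges inherited from member edges,
#' deduplicated, with self-loops removed. Stage 2 re-attaches every
#' significant term as a leaf node with a single membership edge to its
#' community node. With `edge_mode = "rep-ancestry"` the inter-community
#' edges are instead drawn from representative A to representative B exactly
#' when B is an ancestor of A in the ontology (requires `onto`).
#'
#' @param graph the term graph the partition was computed on.
#' @param partition named community labels covering the graph.
#' @param reps community -> representative term map from
#'   [select_representatives()].
#' @param significant_terms character vector of significant term ids (each
#'   must be a node of `graph`).
#' @param edge_mode `"contracted"` (default) or `"rep-ancestry"`.
#' @param onto [ontology()] object, required for `"rep-ancestry"`.
#' @return A directed igraph with vertex attributes `kind`
#'   (community/term), `represents`, `member_count`, `color_index` and edge
#'   attribute `kind` (inter_community/membership).
#' @export
collapse <- function(graph, partition, reps, significant_terms,
                     edge_mode = c("contracted", "rep-ancestry"),
                     onto = NULL) {
  edge_mode <- match.arg(edge_mode)
  nodes <- igraph::V(graph)$name
  if (!all(nodes %in% names(partition))) stop("partition does not cover graph")
  labs <- sort(unique(as.integer(partition[nodes])))
  if (!all(as.character(labs) %in% names(reps))) {
    stop("missing representative for community(ies): ",
         paste(setdiff(as.character(labs), names(reps)), collapse = ", "))
  }
  for (l in as.character(labs)) {
    if (partition[[reps[[l]]]] != as.integer(l)) {
      stop(sprintf("representative '%s' is not a member of community %s",
                   reps[[l]], l))
    }
  }
  bad <- setdiff(significant_terms, nodes)
  if (length(bad)) {
    stop("significant term(s) not in graph: ", paste(bad, collapse = ", "))
  }

  cnode <- function(l) paste0("community_", l)
  member_count <- as.integer(table(factor(partition[nodes], levels = labs)))
  vdf <- data.frame(
    name = c(vapply(labs, cnode, character(1)), significant_terms),
    kind = c(rep("community", length(labs)),
             rep("term", length(significant_terms))),
    represents = c(unname(reps[as.character(labs)]), significant_terms),
    member_count = c(member_count, rep(1L, length(significant_terms))),
    color_index = c(labs, unname(partition[significant_terms])),
    stringsAsFactors = FALSE)

  if (edge_mode == "contracted") {
    el <- igraph::as_edgelist(graph)
    cu <- partition[el[, 1]]; cv <- partition[el[, 2]]
    keep <- cu != cv
    inter <- unique(data.frame(from = vapply(cu[keep], cnode, character(1)),
                               to = vapply(cv[keep], cnode, character(1)),
                               stringsAsFactors = FALSE))
  } else {
    if (is.null(onto)) stop("`onto` is required for edge_mode 'rep-ancestry'")
    pairs <- expand.grid(a = labs, b = labs)
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    keep <- mapply(function(a, b) {
      reps[[as.character(b)]] %in% ancestors(reps[[as.character(a)]], onto)
    }, pairs$a, pairs$b)
    inter <- data.frame(from = vapply(pairs$a[keep], cnode, character(1)),
                        to = vapply(pairs$b[keep], cnode, character(1)),
                        stringsAsFactors = FALSE)
  }
  membership <- data.frame(
    from = significant_terms,
    to = vapply(unname(partition[significant_terms]), cnode, character(1)),
    stringsAsFactors = FALSE)
  edf <- rbind(inter, membership)
  edf$kind <- c(rep("inter_community", nrow(inter)),
                rep("membership", nrow(membership)))
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

#' Export a collapsed graph as GraphML and DOT
#'
#' @param g a collapsed graph from [collapse()].
#' @param path output path for GraphML; the DOT copy is written next to it
#'   with a `.dot` extension (or to `dot_path`).
#' @param dot_path optional explicit DOT path.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, dot_path = NULL) {
  igraph::write_graph(g, path, format = "graphml")
  if (is.null(dot_path)) dot_path <- sub("\\.[A-Za-z]+$", ".dot", path)
  igraph::write_graph(g, dot_path, format = "dot")
  invisible(path)
}
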