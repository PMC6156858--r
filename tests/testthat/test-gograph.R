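test_that("ancestor sets follow child -> parent closure with set semantics", {
  o <- toy_ontology()
  expect_length(ancestors("r", o), 0)
  expect_setequal(ancestors("l1", o), c("m1", "r"))
  # diamond: two parents sharing a grandparent -> grandparent appears once
  dia <- ontology(data.frame(child = c("x", "x", "p1", "p2"),
                             parent = c("p1", "p2", "g", "g")))
  expect_setequal(ancestors("x", dia), c("p1", "p2", "g"))
  # depth-3 chain
  ch <- ontology(data.frame(child = c("a", "b", "c"),
                            parent = c("b", "c", "root")))
  expect_setequal(ancestors("a", ch), c("b", "c", "root"))
  expect_error(ancestors("nope", o), "unknown")
})

test_that("the induced subgraph is significant terms plus ancestors", {
  o <- toy_ontology()
  # one significant leaf in a chain -> the path to the root
  g1 <- build_subgraph("l3", o)
  expect_setequal(igraph::V(g1)$name, c("l3", "m2", "r"))
  expect_equal(igraph::ecount(g1), 2)
  # two significant siblings: union of ancestor paths, deduplicated
  g2 <- build_subgraph(c("l1", "l2"), o)
  expect_setequal(igraph::V(g2)$name, c("l1", "l2", "m1", "r"))
  expect_setequal(igraph::V(g2)$name[igraph::V(g2)$significant],
                  c("l1", "l2"))
  # all terms significant -> the whole ontology
  g3 <- build_subgraph(o$terms, o)
  expect_equal(igraph::vcount(g3), length(o$terms))
  expect_equal(igraph::ecount(g3), nrow(o$edges))
  expect_error(build_subgraph(character(), o), "no significant terms")
})

test_that("the Hamiltonian matches hand arithmetic and density bounds", {
  tri <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c"), c("a", "c")), directed = FALSE)
  expect_equal(hamiltonian(tri, c(a = 1, b = 1, c = 1)), -1)
  expect_equal(hamiltonian(tri, c(a = 1, b = 2, c = 3)), 0)  # all singletons
  # complete graph: the all-same partition minimizes H over every partition
  K5 <- igraph::make_full_graph(5)
  igraph::V(K5)$name <- letters[1:5]
  all_same <- setNames(rep(1, 5), letters[1:5])
  expect_equal(hamiltonian(K5, all_same),
               brute_force_min_hamiltonian(K5))
  expect_error(hamiltonian(tri, c(a = 1, b = 2)), "label")
})

test_that("spin-glass partitioning splits the two-clique bridge correctly", {
  g <- two_clique_bridge()
  p <- spinglass_partition(g, seed = 3)
  expect_equal(length(unique(p[letters[1:4]])), 1)
  expect_equal(length(unique(p[letters[5:8]])), 1)
  expect_false(p[["a"]] == p[["h"]])
  expect_equal(attr(p, "hamiltonian"), brute_force_min_hamiltonian(g),
               tolerance = 1e-12)
})

test_that("spin-glass partitioning handles cliques, caps and degenerate input", {
  K6 <- igraph::make_full_graph(6)
  igraph::V(K6)$name <- letters[1:6]
  p <- spinglass_partition(K6, seed = 1)
  expect_equal(length(unique(p)), 1)       # one clique, one community
  expect_lte(length(unique(p)), 200)

  noedge <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(noedge)$name <- letters[1:4]
  expect_warning(p0 <- spinglass_partition(noedge, seed = 1), "no edges")
  expect_equal(length(unique(p0)), 4)

  expect_identical(spinglass_partition(two_clique_bridge(), seed = 9),
                   spinglass_partition(two_clique_bridge(), seed = 9))
})

test_that("disconnected graphs get per-component communities with distinct labels", {
  el <- rbind(igraph::as_edgelist(two_clique_bridge()),
              t(utils::combn(paste0("z", 1:3), 2)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  p <- spinglass_partition(g, seed = 4)
  labs1 <- unique(p[letters[1:8]])
  labs2 <- unique(p[paste0("z", 1:3)])
  expect_length(intersect(labs1, labs2), 0)
  expect_equal(length(labs2), 1)
})

test_that("authority scores match closed forms and are well normalized", {
  # star with all edges pointing at the center
  star <- igraph::graph_from_edgelist(
    cbind(paste0("leaf", 1:5), "center"), directed = TRUE)
  a <- authority_scores(star)
  expect_equal(unname(a["center"]), 1)
  expect_equal(unname(a[paste0("leaf", 1:5)]), rep(0, 5))

  noedge <- igraph::make_empty_graph(3)
  igraph::V(noedge)$name <- letters[1:3]
  a0 <- authority_scores(noedge)
  expect_true(all(a0 == 0))
  expect_true(attr(a0, "degenerate"))
})

test_that("authority scores equal the dominant eigenvector of AtA", {
  set.seed(7)
  checked <- 0
  for (i in 1:30) {
    n <- sample(5:10, 1)
    g <- igraph::sample_gnp(n, 0.4, directed = TRUE)
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- paste0("v", seq_len(n))
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    oracle <- hits_eigen_oracle(A)
    if (is.null(oracle)) next                  # dominant pair not separated
    a <- authority_scores(g, tol = 1e-12)
    expect_lt(max(abs(unname(a[paste0("v", 1:n)]) - oracle)), 1e-8)
    expect_equal(sum(a^2), 1, tolerance = 1e-10)
    expect_true(all(a >= -1e-12))
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})

test_that("representative selection takes the authority maximum, seeded on ties", {
  part <- c(a = 1, b = 1, c = 1, d = 2, e = 2)
  scores <- c(a = 0.9, b = 0.5, c = 0.1, d = 0.3, e = 0.3)
  for (s in 1:5) {
    r <- select_representatives(part, scores, seed = s)
    expect_equal(unname(r["1"]), "a")          # unique max: seed-independent
  }
  expect_identical(select_representatives(part, scores, seed = 42),
                   select_representatives(part, scores, seed = 42))
  picks <- vapply(1:400, function(s)
    select_representatives(part, scores, seed = s)[["2"]], character(1))
  f <- mean(picks == "d")
  expect_gt(f, 0.4); expect_lt(f, 0.6)         # binomial slack around 1/2
  expect_error(select_representatives(part, scores[1:3], seed = 1), "cover")
})

test_that("collapse contracts communities and re-attaches significant terms", {
  g <- igraph::graph_from_edgelist(rbind(
    c("a", "b"), c("b", "c"), c("d", "e"), c("e", "f"),
    c("c", "d"), c("c", "e")), directed = TRUE)   # two parallel cross edges
  part <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  reps <- c(`1` = "b", `2` = "e")
  sig <- c("a", "d")
  cg <- collapse(g, part, reps, sig)
  kind <- igraph::V(cg)$kind
  expect_equal(sum(kind == "community"), 2)
  expect_equal(sum(kind == "term"), 2)
  el <- igraph::as_data_frame(cg, "edges")
  inter <- el[el$kind == "inter_community", ]
  expect_equal(nrow(inter), 1)                  # parallel edges deduplicated
  expect_equal(inter$from, "community_1")
  expect_equal(inter$to, "community_2")
  memb <- el[el$kind == "membership", ]
  expect_equal(nrow(memb), 2)                   # one membership edge per term
  expect_equal(sort(memb$from), c("a", "d"))
  # member counts conserve the input node count
  mc <- igraph::V(cg)$member_count[kind == "community"]
  expect_equal(sum(mc), igraph::vcount(g))
  expect_false(any(igraph::which_loop(cg)))
  expect_error(collapse(g, part, c(`1` = "d", `2` = "e"), sig),
               "not a member")
})

test_that("single-community collapse yields one hub with term leaves only", {
  g <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c")),
                                   directed = TRUE)
  part <- c(a = 1, b = 1, c = 1)
  cg <- collapse(g, part, c(`1` = "c"), significant_terms = c("a", "b"))
  el <- igraph::as_data_frame(cg, "edges")
  expect_equal(sum(el$kind == "inter_community"), 0)
  expect_equal(sum(el$kind == "membership"), 2)
})

test_that("rep-ancestry edge mode draws edges from ontology ancestry of reps", {
  o <- toy_ontology()
  g <- build_subgraph(c("l1", "l3"), o)
  part <- c(l1 = 1, m1 = 1, l3 = 2, m2 = 2, r = 2)
  reps <- c(`1` = "m1", `2` = "r")
  cg <- collapse(g, part, reps, c("l1", "l3"), edge_mode = "rep-ancestry",
                 onto = o)
  el <- igraph::as_data_frame(cg, "edges")
  inter <- el[el$kind == "inter_community", ]
  expect_equal(nrow(inter), 1)                  # r is an ancestor of m1
  expect_equal(inter$from, "community_1")
  expect_equal(inter$to, "community_2")
  expect_error(collapse(g, part, reps, "l1", edge_mode = "rep-ancestry"),
               "onto")
})

test_that("GraphML export round-trips nodes, edges and attributes", {
  dir <- withr::local_tempdir()
  g <- igraph::graph_from_edgelist(rbind(
    c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e")), directed = TRUE)
  part <- c(a = 1, b = 1, c = 1, d = 2, e = 2)
  cg <- collapse(g, part, c(`1` = "b", `2` = "d"), c("a", "e"))
  path <- file.path(dir, "collapsed.graphml")
  export_graph(cg, path)
  expect_true(file.exists(path))
  expect_true(file.exists(file.path(dir, "collapsed.dot")))
  rt <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(rt), igraph::vcount(cg))
  expect_equal(igraph::ecount(rt), igraph::ecount(cg))
  expect_setequal(igraph::V(rt)$kind, igraph::V(cg)$kind)
  expect_equal(sum(igraph::V(rt)$kind == "community"), 2)
})
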