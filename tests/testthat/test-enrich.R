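test_that("the CPM universe filter applies its boundary as stated", {
  mk_counts <- function(rows) {
    m <- do.call(rbind, rows)
    filler <- 1e6 - colSums(m)          # fixes every library at 1e6
    m <- rbind(m, filler)
    rownames(m) <- c(names(rows), "filler")
    colnames(m) <- paste0("s", seq_len(ncol(m)))
    m
  }
  counts <- mk_counts(list(
    zero = rep(0, 6),
    borderline = c(1.5, 1.5, 1.5, 0.5, 0.5, 0.5),  # CPM 1.5 in exactly 3
    under = c(1.5, 1.5, 0.5, 0.5, 0.5, 0.5),       # only 2 samples above
    high = rep(50, 6)))
  u <- define_universe(counts, cpm_min = 1, min_samples = 3)
  expect_true("borderline" %in% u)
  expect_true("high" %in% u)
  expect_false("zero" %in% u)
  expect_false("under" %in% u)

  uniform <- matrix(100, 5, 4, dimnames = list(paste0("g", 1:5),
                                               paste0("s", 1:4)))
  expect_setequal(define_universe(uniform, min_samples = 3), paste0("g", 1:5))
  bad <- uniform; bad[, 2] <- 0
  expect_error(define_universe(bad), "s2")
  expect_error(define_universe(uniform[, 1:2, drop = FALSE]), "fewer samples")
})

test_that("DE filtering is strict at both cutoffs", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(3, 1.0, -1.2, 0.2),
                   pvalue = c(1e-5, 1e-3, 1e-3, 0.5),
                   padj = c(1e-4, 0.01, 0.05, 0.9))
  f <- filter_de(de, alpha = 0.05, fc_threshold = 2)
  expect_setequal(f$significant, c("a", "b"))   # padj = 0.05 exactly: out
  expect_setequal(f$high_fc, "a")               # |log2fc| = 1 exactly: out
  expect_error(filter_de(de[, c("gene_id", "log2fc")]), "columns")
  de$padj[1] <- NA
  expect_error(filter_de(de), "missing")
})

test_that("planted DE genes are exactly the significant set", {
  o <- gen_ontology(30, seed = 3)
  ad <- gen_annotations_and_de(o, 800, frac_de = 0.1, seed = 13)
  f <- filter_de(ad$de)
  expect_setequal(f$significant, ad$de_genes)
})

test_that("annotation propagation closes over ancestors and is idempotent", {
  o <- toy_ontology()
  raw <- list(gRoot = "r", gDeep = "l1", gBoth = c("l1", "l3"))
  prop <- propagate_annotations(raw, o)
  expect_equal(prop$gRoot, "r")
  expect_setequal(prop$gDeep, c("l1", "m1", "r"))
  expect_setequal(prop$gBoth, c("l1", "m1", "l3", "m2", "r"))
  expect_identical(propagate_annotations(prop, o), prop)
  expect_error(propagate_annotations(list(g = "unknown_term"), o),
               "unknown_term")
})

test_that("the Fisher p equals the hypergeometric tail, exactly on the 5-of-20 case", {
  genes <- sprintf("u%02d", 1:20)
  in_term <- genes[1:5]
  ann <- setNames(lapply(genes, function(g)
    if (g %in% in_term) "t" else character(0)), genes)
  p <- fisher_term_test("t", study = in_term, universe = genes,
                        annotations = ann)
  expect_equal(p, 1 / choose(20, 5), tolerance = 1e-12)
  # study = universe -> p = 1 for any term
  expect_equal(as.numeric(fisher_term_test("t", genes, genes, ann)), 1)
  # unannotated term -> 1, flagged
  p0 <- fisher_term_test("absent", in_term, genes, ann)
  expect_equal(as.numeric(p0), 1)
  expect_true(attr(p0, "degenerate"))
  expect_error(fisher_term_test("t", c(in_term, "new"), genes, ann),
               "subset")
})

test_that("the Fisher p matches enumeration and an R oracle on random instances", {
  set.seed(42)
  for (i in 1:60) {
    N <- sample(10:50, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    genes <- sprintf("g%03d", 1:N)
    in_term <- sample(genes, K)
    study <- sample(genes, n)
    ann <- setNames(lapply(genes, function(g)
      if (g %in% in_term) "t" else character(0)), genes)
    p <- as.numeric(fisher_term_test("t", study, genes, ann))
    k <- sum(study %in% in_term)
    expect_equal(p, hyper_tail_oracle(k, K, N, n), tolerance = 1e-12)
    ft <- stats::fisher.test(
      matrix(c(k, n - k, K - k, N - K - (n - k)), 2),
      alternative = "greater")$p.value
    expect_equal(p, ft, tolerance = 1e-9)
  }
})

test_that("the Fisher p is monotone decreasing in the overlap at fixed margins", {
  N <- 40; K <- 12; n <- 10
  p <- vapply(0:min(K, n), function(k)
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE), numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("enrichment excludes sparse terms and ranks contiguously", {
  o <- toy_ontology()
  genes <- sprintf("g%02d", 1:40)
  # l1 gets 12 genes, l3 gets 4 (below the minimum after propagation? l3's
  # ancestors m2/r inherit them); direct counts: l1 12, l3 4
  raw <- setNames(lapply(seq_along(genes), function(i) {
    if (i <= 12) "l1" else if (i <= 16) "l3" else "l2"
  }), genes)
  ann <- propagate_annotations(raw, o)
  res <- run_enrichment(study = genes[1:10], universe = genes,
                        annotations = ann, onto = o, min_annotated = 5)
  expect_false("l3" %in% res$term_id)       # 4 annotated genes: excluded
  expect_true("l1" %in% res$term_id)
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_false(is.unsorted(res$p_fisher))
  expect_lt(res$p_fisher[res$term_id == "l1"], 0.05)
  expect_error(run_enrichment(character(), genes, ann), "empty study")
  # top_n truncation
  res2 <- run_enrichment(genes[1:10], genes, ann, onto = o,
                         min_annotated = 1, top_n = 2)
  expect_equal(nrow(res2), 2)
  expect_equal(res2$rank, 1:2)
})

test_that("enrichment output is bit-reproducible across runs", {
  o <- gen_ontology(40, seed = 5)
  ad <- gen_annotations_and_de(o, 400, frac_de = 0.1,
                               planted_terms = setdiff(o$terms, o$root)[1:2],
                               enrichment_odds = 10, seed = 6)
  ann <- propagate_annotations(ad$annotations, o)
  r1 <- run_enrichment(ad$de_genes, ad$de$gene_id, ann, onto = o)
  r2 <- run_enrichment(ad$de_genes, ad$de$gene_id, ann, onto = o)
  expect_identical(r1, r2)
})

test_that("planted terms are detected in nearly all seeded replicates", {
  o <- gen_ontology(50, seed = 21)
  planted <- setdiff(o$terms, o$root)[c(5, 15)]
  hit <- matrix(NA, 40, length(planted))
  for (i in seq_len(40)) {
    ad <- gen_annotations_and_de(o, 400, frac_de = 0.1,
                                 planted_terms = planted,
                                 enrichment_odds = 20, seed = 100 + i)
    ann <- propagate_annotations(ad$annotations, o)
    res <- run_enrichment(ad$de_genes, ad$de$gene_id, ann, onto = o)
    hit[i, ] <- planted %in% res$term_id[res$significant]
  }
  expect_gte(mean(hit), 0.95)
})

test_that("type-I error over null replicates stays within Monte-Carlo slack", {
  o <- gen_ontology(40, seed = 31)
  frac <- numeric(60)
  for (i in seq_len(60)) {
    ad <- gen_annotations_and_de(o, 300, frac_de = 0.1,
                                 enrichment_odds = 1, seed = 200 + i)
    ann <- propagate_annotations(ad$annotations, o)
    res <- run_enrichment(ad$de_genes, ad$de$gene_id, ann, onto = o)
    frac[i] <- mean(res$significant)
  }
  expect_lte(mean(frac), 0.08)
})
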