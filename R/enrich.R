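# Classic-Fisher GO over-representation: universe definition by CPM filter,
# DE-table filtering, true-path annotation propagation and per-term
# one-sided Fisher (hypergeometric upper-tail) testing.

#' Define the gene universe by a counts-per-million filter
#'
#' A gene is quantified — and belongs to the enrichment universe — when its
#' CPM exceeds `cpm_min` in at least `min_samples` samples
#' (CPM(g, s) = 1e6 * count(g, s) / library_size(s)).
#'
#' @param counts count matrix, genes x samples.
#' @param cpm_min CPM cutoff (strict `>`; default 1).
#' @param min_samples minimum number of samples above the cutoff (default 3).
#' @return Character vector of retained gene ids.
#' @export
define_universe <- function(counts, cpm_min = 1, min_samples = 3L) {
  stop_if_not_count(min_samples, "min_samples")
  if (ncol(counts) < min_samples) {
    stop("fewer samples than `min_samples`")
  }
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[libsize == 0], collapse = ", "))
  }
  cpm <- t(t(counts) / libsize) * 1e6
  keep <- rowSums(cpm > cpm_min) >= min_samples
  rownames(counts)[keep]
}

#' Filter a differential-expression table
#'
#' Splits a DE table into the significant genes (`padj < alpha`, strict) and
#' the high-fold-change subset (significant and `|log2fc| > log2(fc)`,
#' strict). Both cutoffs follow the study's conventions (alpha 0.05, fold
#' change 2, two-sided on the log scale).
#'
#' @param de data.frame with columns `gene_id`, `log2fc`, `padj` (and
#'   typically `pvalue`).
#' @param alpha adjusted-p significance level in (0, 1).
#' @param fc_threshold linear fold-change cutoff (> 1).
#' @return list with `significant` and `high_fc` character vectors of gene
#'   ids.
#' @export
filter_de <- function(de, alpha = 0.05, fc_threshold = 2) {
  need <- c("gene_id", "log2fc", "padj")
  if (!all(need %in% names(de))) {
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  }
  stop_if_not_fraction(alpha, "alpha", open_lo = TRUE, open_hi = TRUE)
  if (fc_threshold <= 1) stop("`fc_threshold` must exceed 1")
  if (anyNA(de$padj)) stop("missing `padj` values")
  sig <- de$gene_id[de$padj < alpha]
  high <- de$gene_id[de$padj < alpha & abs(de$log2fc) > log2(fc_threshold)]
  list(significant = sig, high_fc = high)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term; this closure makes term gene counts monotone along the
#' hierarchy and is assumed by the Fisher testing step. Idempotent.
#'
#' @param raw named list, gene -> character vector of directly annotated
#'   term ids.
#' @param onto an [ontology()] object covering every annotated term.
#' @return Named list, gene -> term ids including all ancestors (sorted,
#'   unique).
#' @export
propagate_annotations <- function(raw, onto) {
  stopifnot(inherits(onto, "ontology"))
  used <- unique(unlist(raw, use.names = FALSE))
  unknown <- setdiff(used, onto$terms)
  if (length(unknown)) {
    stop("unknown term id(s) in annotations: ",
         paste(unknown, collapse = ", "))
  }
  closure <- stats::setNames(
    lapply(used, function(t) c(t, ancestors(t, onto))), used)
  lapply(raw, function(ts) {
    sort(unique(unlist(closure[unique(ts)], use.names = FALSE)))
  })
}

#' One-sided Fisher over-representation test for a single term
#'
#' Classic per-term Fisher exact test of the 2x2 table (in study and
#' annotated, in study not annotated; out of study annotated, out of study
#' not annotated), one-sided for over-representation — identical to the
#' hypergeometric upper tail P(X >= k) with k study genes annotated, K
#' universe genes annotated, study size n and universe size N.
#'
#' @param term term id to test.
#' @param study character vector of study gene ids (must be a subset of
#'   `universe`).
#' @param universe character vector of universe gene ids.
#' @param annotations gene -> terms map after [propagate_annotations()].
#' @return p-value in [0, 1]. A term with no annotated genes in the universe
#'   returns 1 with attribute `degenerate = TRUE`.
#' @export
fisher_term_test <- function(term, study, universe, annotations) {
  if (!all(study %in% universe)) stop("`study` must be a subset of `universe`")
  in_term <- names(annotations)[vapply(annotations, function(ts)
    term %in% ts, logical(1))]
  K <- sum(universe %in% in_term)
  if (K == 0L) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  N <- length(unique(universe))
  n <- length(unique(study))
  k <- sum(unique(study) %in% in_term)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Classic-Fisher term over-representation analysis
#'
#' Tests every ontology term for over-representation of the study set in the
#' universe, after excluding terms with fewer than `min_annotated` annotated
#' universe genes, and returns the `top_n` terms by ascending p-value —
#' mirroring the study's procedure (minimum 5 annotated genes, top 1000
#' terms, significance at raw p < alpha with no multiple-testing
#' correction).
#'
#' @param study,universe gene id vectors, `study` a non-empty subset of
#'   `universe`.
#' @param annotations gene -> terms map after [propagate_annotations()].
#' @param onto optional [ontology()]; when supplied, term names are carried
#'   into the output and only its terms are tested.
#' @param min_annotated minimum universe annotation count (default 5).
#' @param alpha term significance level on the raw Fisher p (default 0.05).
#' @param top_n number of lowest-p terms retained (default 1000).
#' @return data.frame sorted ascending by p: `term_id`, `term_name`,
#'   `n_universe`, `n_study`, `p_fisher`, `rank`, `significant`.
#' @export
run_enrichment <- function(study, universe, annotations, onto = NULL,
                           min_annotated = 5L, alpha = 0.05,
                           top_n = 1000L) {
  if (length(study) == 0L) stop("empty study set")
  if (!all(study %in% universe)) stop("`study` must be a subset of `universe`")
  stop_if_not_count(min_annotated, "min_annotated", min = 0L)
  stop_if_not_count(top_n, "top_n")
  study <- unique(study); universe <- unique(universe)
  ann <- annotations[names(annotations) %in% universe]
  term_genes <- invert_annotations(ann)
  if (!is.null(onto)) {
    term_genes <- term_genes[names(term_genes) %in% onto$terms]
  }
  K <- lengths(term_genes)
  term_genes <- term_genes[K >= min_annotated]
  if (length(term_genes) == 0L) {
    return(data.frame(term_id = character(), term_name = character(),
                      n_universe = integer(), n_study = integer(),
                      p_fisher = numeric(), rank = integer(),
                      significant = logical()))
  }
  N <- length(universe)
  n <- length(study)
  k <- vapply(term_genes, function(g) sum(study %in% g), integer(1))
  K <- lengths(term_genes)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(term_id = names(term_genes),
                    term_name = if (!is.null(onto))
                      unname(onto$names[names(term_genes)])
                    else names(term_genes),
                    n_universe = unname(K), n_study = unname(k),
                    p_fisher = unname(p))
  res <- res[order(res$p_fisher, res$term_id), , drop = FALSE]
  res <- utils::head(res, top_n)
  res$rank <- seq_len(nrow(res))
  res$significant <- res$p_fisher < alpha
  rownames(res) <- NULL
  res
}

#' Write / read a DE table as TSV
#'
#' Columns: `gene_id`, `log2fc`, `pvalue`, `padj`.
#'
#' @param de data.frame.
#' @param path file path.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  utils::read.delim(path)
}
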