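# Expression summaries: log-CPM variance-stabilizing transform, per-gene
# scaling, top-variance PCA and per-community expression profiles.

#' Log-CPM variance-stabilizing transform
#'
#' `log2(CPM + pseudocount)` per entry, where
#' CPM(g, s) = 1e6 * count(g, s) / library_size(s). Monotone in counts and
#' invariant to per-sample library-size rescaling.
#'
#' @param counts nonnegative count matrix, genes x samples.
#' @param pseudocount added before the log (default 1, so zero counts map
#'   to 0).
#' @return Real matrix of the same shape; the `condition` attribute of the
#'   input, if any, is carried over.
#' @export
vst <- function(counts, pseudocount = 1) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[libsize == 0], collapse = ", "))
  }
  out <- log2(t(t(counts) / libsize) * 1e6 + pseudocount)
  attr(out, "condition") <- attr(counts, "condition")
  out
}

#' Scale matrix rows to the unit interval or to z-scores
#'
#' `unit_interval` maps each row to [0, 1] by (x - min)/(max - min);
#' `zscore` centers to mean 0 and scales to sd 1. Constant rows become all
#' zeros and are flagged.
#'
#' @param m real matrix, genes x samples.
#' @param mode `"unit_interval"` or `"zscore"`.
#' @return Matrix of the same shape with attributes `mode` and
#'   `degenerate_rows` (character vector of constant-row names).
#' @export
scale_rows <- function(m, mode = c("unit_interval", "zscore")) {
  mode <- match.arg(mode)
  if (any(!is.finite(m))) stop("matrix entries must be finite")
  rng <- apply(m, 1, range)
  constant <- rng[1, ] == rng[2, ]
  out <- m
  if (mode == "unit_interval") {
    span <- rng[2, ] - rng[1, ]
    span[constant] <- 1
    out <- (m - rng[1, ]) / span
  } else {
    mu <- rowMeans(m)
    sd_ <- apply(m, 1, stats::sd)
    sd_[constant] <- 1
    out <- (m - mu) / sd_
  }
  out[constant, ] <- 0
  attr(out, "mode") <- mode
  attr(out, "degenerate_rows") <- rownames(m)[constant]
  attr(out, "condition") <- attr(m, "condition")
  out
}

#' PCA of samples on the top-variance genes
#'
#' Restricts to the `n_top` highest-variance genes (the transcriptome
#' overview used the top 500), centers and scales each gene row to mean 0 /
#' sd 1, and computes principal components of the samples by singular value
#' decomposition. Component signs are fixed so the largest-magnitude gene
#' loading of each PC is positive, making the output reproducible and
#' invariant to gene order.
#'
#' @param m real matrix genes x samples (e.g. [vst()] output), >= 3 samples.
#' @param n_top number of top-variance genes (default 500; capped at the
#'   gene count with a warning).
#' @return list with `coords` (data.frame: `sample`, `PC1`, `PC2`, plus the
#'   `condition` attribute of `m` as a column when present) and
#'   `var_explained` (named percent of variance on PC1/PC2).
#' @export
pca_top_variance <- function(m, n_top = 500L) {
  if (ncol(m) < 3L) stop("PCA needs at least 3 samples")
  stop_if_not_count(n_top, "n_top")
  if (n_top > nrow(m)) {
    warning("`n_top` exceeds gene count; using all genes")
    n_top <- nrow(m)
  }
  v <- apply(m, 1, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(n_top)]
  keep <- keep[v[keep] > 0]
  sub <- scale_rows(m[keep, , drop = FALSE], "zscore")
  p <- stats::prcomp(t(sub), center = FALSE, scale. = FALSE)
  flip <- apply(p$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, `*`)
  ve <- 100 * p$sdev^2 / sum(p$sdev^2)
  coords <- data.frame(sample = colnames(m),
                       PC1 = scores[, 1],
                       PC2 = if (ncol(scores) >= 2) scores[, 2] else 0,
                       row.names = NULL)
  cond <- attr(m, "condition")
  if (!is.null(cond)) coords$condition <- as.character(cond)
  list(coords = coords,
       var_explained = c(PC1 = ve[1], PC2 = if (length(ve) >= 2) ve[2] else 0))
}

#' Per-community expression profiles and heatmap ordering
#'
#' A community's member genes are the genes annotated to any of its member
#' terms. Heatmap rows are grouped by community (ascending label) and
#' ordered within each community by hierarchical clustering of the scaled
#' rows (Euclidean distance, average linkage). A gene annotated to terms in
#' several communities appears once per community. Communities without any
#' annotated gene present in the matrix are dropped with a warning.
#'
#' @param scaled scaled expression matrix from [scale_rows()].
#' @param annotations gene -> term map (after ancestor propagation, so that
#'   membership in ancestral terms counts).
#' @param partition named community labels over terms from
#'   [spinglass_partition()].
#' @return list with `profiles` (community x sample matrix of mean scaled
#'   expression), `gene_order` (data.frame `community`, `gene` in heatmap
#'   display order) and `n_genes` (genes per community).
#' @export
community_profiles <- function(scaled, annotations, partition) {
  term2genes <- invert_annotations(annotations)
  labs <- sort(unique(as.integer(partition)))
  rows <- list(); profiles <- list(); n_genes <- integer()
  for (l in labs) {
    terms <- names(partition)[partition == l]
    genes <- unique(unlist(term2genes[intersect(terms, names(term2genes))],
                           use.names = FALSE))
    genes <- intersect(genes, rownames(scaled))
    if (length(genes) == 0L) {
      warning(sprintf("community %d has no annotated genes in the matrix", l))
      next
    }
    sub <- scaled[genes, , drop = FALSE]
    ord <- if (length(genes) > 2L) {
      stats::hclust(stats::dist(sub), method = "average")$order
    } else seq_along(genes)
    rows[[as.character(l)]] <- data.frame(community = l, gene = genes[ord])
    profiles[[as.character(l)]] <- colMeans(sub)
    n_genes[as.character(l)] <- length(genes)
  }
  if (length(profiles) == 0L) {
    stop("no overlap between annotated genes and the expression matrix")
  }
  prof <- do.call(rbind, profiles)
  rownames(prof) <- names(profiles)
  list(profiles = prof,
       gene_order = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       n_genes = n_genes)
}
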