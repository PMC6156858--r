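# Synthetic-data generators with planted ground truth. Every input class the
# pipeline consumes (screen plates, dose-response series, ontology,
# annotations + DE table, count matrix) can be generated here, so all
# downstream stages are testable without external data. All generators are
# pure functions of their arguments including `seed`.

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

term_ids <- function(n) sprintf("SYN:%07d", seq_len(n))

# Well labels for common plate geometries (A1..H12 for 96-well); anything
# non-standard degenerates to a single row.
well_labels <- function(wells_per_plate) {
  geom <- list(`6` = c(2L, 3L), `12` = c(3L, 4L), `24` = c(4L, 6L),
               `48` = c(6L, 8L), `96` = c(8L, 12L), `384` = c(16L, 24L))
  g <- geom[[as.character(wells_per_plate)]]
  if (is.null(g)) g <- c(1L, as.integer(wells_per_plate))
  as.vector(t(outer(LETTERS[seq_len(g[1])], seq_len(g[2]), paste0)))
}

#' Simulate a plate-based viability screen with planted hits
#'
#' Emulates a one-compound-per-well library screen read out by a viability
#' assay. Each plate carries its own negative (vehicle) and positive
#' (cytotoxic QC) control wells; the compound well signal is
#' `neg_mean * (1 - true_inhibition/100 * pos_effect)` under multiplicative
#' log-normal noise of the given coefficient of variation, so that noiseless
#' plates round-trip the planted inhibition exactly through
#' [normalize_screen()].
#'
#' @param n_compounds number of library compounds (one well each).
#' @param wells_per_plate plate size; compound wells per plate are
#'   `wells_per_plate - n_neg - n_pos`, with the controls occupying the last
#'   wells of each plate.
#' @param n_neg,n_pos negative / positive control wells per plate (>= 2 each;
#'   the screened library used quadruplicates of both).
#' @param noise_cv coefficient of variation of the multiplicative well noise.
#'   The default 0.09 reproduces an assay window whose plate Z-factor
#'   averages about 0.6, the quality reported for the original screen.
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @param pos_effect fractional signal loss of the positive control (default
#'   0.8, i.e. about 20 percent residual viability, matching the VLX600 QC).
#' @param neg_mean expected signal of an untreated well, in assay units.
#' @param true_inhibition optional numeric vector (percent, in [0, 130]) of
#'   planted per-compound inhibition; when `NULL` a library is drawn in which
#'   a fraction `frac_hit` of compounds are hits.
#' @param frac_hit fraction of planted hits when `true_inhibition` is `NULL`
#'   (default 55/1280, the original screen's primary hit rate).
#' @param hit_range,nonhit_range uniform ranges (percent inhibition) for
#'   planted hits and non-hits.
#' @param hit_threshold percent-inhibition threshold defining `is_true_hit`
#'   (default 70).
#'
#' @return A list with `plates` (long-format data.frame: `plate_id`, `well`,
#'   `role` in compound/neg/pos, `compound_id`, `intensity`) and `truth`
#'   (data.frame: `compound_id`, `true_inhibition`, `is_true_hit`).
#' @export
gen_screen_plates <- function(n_compounds, wells_per_plate = 96L,
                              n_neg = 4L, n_pos = 4L, noise_cv = 0.09,
                              seed = 1L, pos_effect = 0.8, neg_mean = 1000,
                              true_inhibition = NULL,
                              frac_hit = 55 / 1280,
                              hit_range = c(85, 120),
                              nonhit_range = c(0, 40),
                              hit_threshold = 70) {
  stop_if_not_count(n_compounds, "n_compounds")
  stop_if_not_count(n_neg, "n_neg", min = 2L)
  stop_if_not_count(n_pos, "n_pos", min = 2L)
  stop_if_not_count(wells_per_plate, "wells_per_plate",
                    min = n_neg + n_pos + 1L)
  if (!is.numeric(noise_cv) || noise_cv < 0) stop("`noise_cv` must be >= 0")
  if (neg_mean <= 0) stop("`neg_mean` must be positive")
  stop_if_not_fraction(pos_effect, "pos_effect", open_lo = TRUE)

  with_seed(seed, {
    compound_id <- sprintf("cmpd_%04d", seq_len(n_compounds))
    if (is.null(true_inhibition)) {
      n_hit <- max(1L, round(frac_hit * n_compounds))
      hit_idx <- sample.int(n_compounds, n_hit)
      true_inhibition <- stats::runif(n_compounds, nonhit_range[1],
                                      nonhit_range[2])
      true_inhibition[hit_idx] <- stats::runif(n_hit, hit_range[1],
                                               hit_range[2])
    } else {
      if (length(true_inhibition) != n_compounds)
        stop("`true_inhibition` must have one value per compound")
      if (any(true_inhibition < 0 | true_inhibition > 130))
        stop("`true_inhibition` must lie in [0, 130]")
    }
    truth <- data.frame(compound_id = compound_id,
                        true_inhibition = true_inhibition,
                        is_true_hit = true_inhibition > hit_threshold)

    cmpd_per_plate <- wells_per_plate - n_neg - n_pos
    n_plates <- ceiling(n_compounds / cmpd_per_plate)
    labels <- well_labels(wells_per_plate)
    plates <- vector("list", n_plates)
    pos_mean <- neg_mean * (1 - pos_effect)
    for (p in seq_len(n_plates)) {
      idx <- ((p - 1L) * cmpd_per_plate + 1L):min(p * cmpd_per_plate,
                                                  n_compounds)
      expected <- c(
        neg_mean * (1 - truth$true_inhibition[idx] / 100 * pos_effect),
        rep(neg_mean, n_neg), rep(pos_mean, n_pos))
    role <- c(rep("compound", length(idx)), rep("neg", n_neg),
              rep("pos", n_pos))
      noise <- if (noise_cv > 0) {
        sdlog <- sqrt(log1p(noise_cv^2))
        stats::rlnorm(length(expected), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(1, length(expected))
      plates[[p]] <- data.frame(
        plate_id = sprintf("plate_%03d", p),
        well = c(labels[seq_along(idx)],
                 labels[(wells_per_plate - n_neg - n_pos + 1L):
                          wells_per_plate]),
        role = role,
        compound_id = c(compound_id[idx], rep(NA_character_, n_neg + n_pos)),
        intensity = expected * noise)
    }
    list(plates = do.call(rbind, plates), truth = truth)
  })
}

# Four-parameter logistic response; at dose 0 the value is the hill-sign
# limit (top for hill > 0, bottom for hill < 0).
fourpl <- function(d, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (d / ic50)^hill)
}

#' Simulate a dose-response viability series from a 4PL curve
#'
#' Viability at dose `d` is `bottom + (top - bottom)/(1 + (d/ic50)^hill)`
#' plus Gaussian noise, emulating the 0-15 micromolar confirmation assays.
#'
#' @param params_4pl numeric vector or list with elements `top`, `bottom`,
#'   `ic50` (> 0, micromolar) and `hill` (non-zero).
#' @param doses non-negative doses in micromolar.
#' @param noise_sd Gaussian noise standard deviation, in viability percent.
#' @param seed integer seed.
#' @param compound_id,cell_line metadata columns carried into the output.
#' @return data.frame with columns `compound_id`, `cell_line`, `dose_uM`,
#'   `viability`.
#' @export
gen_dose_response <- function(params_4pl, doses, noise_sd = 0, seed = 1L,
                              compound_id = "cmpd", cell_line = "cells") {
  p <- as.list(params_4pl)
  if (is.null(names(p)) || !all(c("top", "bottom", "ic50", "hill") %in%
                                names(p))) {
    names(p) <- c("top", "bottom", "ic50", "hill")
  }
  if (p$ic50 <= 0) stop("`ic50` must be positive")
  if (p$hill == 0) stop("`hill` must be non-zero")
  if (any(doses < 0)) stop("doses must be non-negative")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  with_seed(seed, {
    v <- fourpl(doses, p$top, p$bottom, p$ic50, p$hill)
    if (noise_sd > 0) v <- v + stats::rnorm(length(doses), sd = noise_sd)
    data.frame(compound_id = compound_id, cell_line = cell_line,
               dose_uM = doses, viability = v)
  })
}

#' Generate a random rooted ontology DAG
#'
#' Terms are organized in levels 1..`depth` under a single root; every
#' non-root term gets one parent on the level above it and up to
#' `max_parents - 1` extra parents on any shallower level, so the result is
#' always a rooted DAG with edges directed child -> parent.
#'
#' @param n_terms total number of terms including the root.
#' @param max_parents maximum parents per term (>= 1).
#' @param depth number of levels below the root.
#' @param seed integer seed.
#' @return An [ontology()] object.
#' @export
gen_ontology <- function(n_terms, max_parents = 2L, depth = 4L, seed = 1L) {
  stop_if_not_count(n_terms, "n_terms")
  stop_if_not_count(max_parents, "max_parents")
  stop_if_not_count(depth, "depth")
  ids <- term_ids(n_terms)
  nms <- stats::setNames(sprintf("synthetic term %d", seq_len(n_terms)), ids)
  if (n_terms == 1L) {
    return(ontology(data.frame(child = character(), parent = character()),
                    term_names = nms))
  }
  with_seed(seed, {
    depth <- min(depth, n_terms - 1L)
    level <- integer(n_terms)            # root at level 0
    level[2:(depth + 1L)] <- seq_len(depth)  # a spine guarantees occupancy
    if (n_terms > depth + 1L) {
      level[(depth + 2L):n_terms] <- sample.int(depth, n_terms - depth - 1L,
                                                replace = TRUE)
    }
    child <- parent <- character()
    for (i in 2:n_terms) {
      above <- which(level == level[i] - 1L & seq_len(n_terms) < i)
      pick <- above[sample.int(length(above), 1L)]
      extra <- integer()
      if (max_parents > 1L) {
        shallower <- setdiff(which(level < level[i] & seq_len(n_terms) < i),
                             pick)
        k <- sample.int(max_parents, 1L) - 1L
        if (k > 0L && length(shallower) > 0L) {
          extra <- shallower[sample.int(length(shallower),
                                        min(k, length(shallower)))]
        }
      }
      ps <- c(pick, extra)
      child <- c(child, rep(ids[i], length(ps)))
      parent <- c(parent, ids[ps])
    }
    ontology(data.frame(child = child, parent = parent,
                        stringsAsFactors = FALSE), term_names = nms)
  })
}

#' Generate gene annotations and a differential-expression table with
#' planted term enrichment
#'
#' Genes are annotated directly to leaf-ward (non-root) terms; a set of
#' `planted_terms` is guaranteed at least `planted_min_genes` annotated genes
#' and its genes are over-represented among the differentially expressed
#' (DE) genes at the requested odds. Adjusted p-values are constructed so
#' that exactly the DE genes pass `padj < alpha`.
#'
#' @param onto an [ontology()] object.
#' @param n_genes number of genes.
#' @param frac_de fraction of genes planted as DE (`frac_de * n_genes >= 1`).
#' @param planted_terms term ids (must exist in `onto`) to enrich.
#' @param enrichment_odds sampling-odds multiplier (> 0) for DE membership of
#'   genes annotated to a planted term; 1 is the null.
#' @param lfc_mean,lfc_sd mean and sd (log2 units) of the absolute planted
#'   log2 fold changes; signs are random.
#' @param seed integer seed.
#' @param max_terms_per_gene direct annotations per gene are uniform on
#'   1..`max_terms_per_gene`.
#' @param planted_min_genes minimum direct annotations per planted term.
#' @param alpha significance level the constructed `padj` values respect.
#' @return A list with `annotations` (gene -> direct term ids, before
#'   ancestor propagation), `de` (data.frame `gene_id`, `log2fc`, `pvalue`,
#'   `padj`), `planted_terms` and `de_genes` (the planted DE gene ids).
#' @export
gen_annotations_and_de <- function(onto, n_genes, frac_de = 0.1,
                                   planted_terms = character(),
                                   enrichment_odds = 1,
                                   lfc_mean = 2, lfc_sd = 0.5, seed = 1L,
                                   max_terms_per_gene = 3L,
                                   planted_min_genes = 30L,
                                   alpha = 0.05) {
  stopifnot(inherits(onto, "ontology"))
  stop_if_not_count(n_genes, "n_genes")
  if (enrichment_odds <= 0) stop("`enrichment_odds` must be positive")
  if (!all(planted_terms %in% onto$terms)) {
    stop("planted_terms not in ontology: ",
         paste(setdiff(planted_terms, onto$terms), collapse = ", "))
  }
  n_de <- round(frac_de * n_genes)
  if (n_de < 1) stop("`frac_de * n_genes` must be >= 1")

  candidates <- setdiff(onto$terms, onto$root)
  if (length(candidates) == 0L) candidates <- onto$terms
  genes <- gene_ids(n_genes)
  with_seed(seed, {
    k <- sample.int(max_terms_per_gene, n_genes, replace = TRUE)
    ann <- lapply(k, function(ki)
      candidates[sample.int(length(candidates), min(ki, length(candidates)))])
    names(ann) <- genes
    # top up planted terms so each carries enough genes to be testable
    for (t in planted_terms) {
      has <- vapply(ann, function(ts) t %in% ts, logical(1))
      deficit <- planted_min_genes - sum(has)
      if (deficit > 0L) {
        pool <- which(!has)
        add <- pool[sample.int(length(pool), min(deficit, length(pool)))]
        for (g in add) ann[[g]] <- c(ann[[g]], t)
      }
    }
    planted_genes <- names(ann)[vapply(ann, function(ts)
      any(ts %in% planted_terms), logical(1))]
    w <- ifelse(genes %in% planted_genes, enrichment_odds, 1)
    de_genes <- genes[sample.int(n_genes, n_de, prob = w)]

    is_de <- genes %in% de_genes
    padj <- numeric(n_genes)
    padj[is_de] <- stats::runif(sum(is_de), 0, alpha * 0.9)
    padj[!is_de] <- alpha + (1 - alpha) * stats::runif(sum(!is_de),
                                                       0.01, 1)
    pvalue <- padj * stats::runif(n_genes, 0.2, 1)
    log2fc <- stats::rnorm(n_genes, 0, 0.25)
    log2fc[is_de] <- sample(c(-1, 1), sum(is_de), replace = TRUE) *
      abs(stats::rnorm(sum(is_de), lfc_mean, lfc_sd))
    list(annotations = ann,
         de = data.frame(gene_id = genes, log2fc = log2fc,
                         pvalue = pvalue, padj = padj),
         planted_terms = planted_terms,
         de_genes = de_genes)
  })
}

#' Generate a negative-binomial count matrix with planted fold changes
#'
#' Per-gene baseline means are log-normal; counts are negative-binomial with
#' the given dispersion. Genes in `de_gene_ids` have their mean multiplied by
#' `2^lfc` in the second condition, emulating differential expression between
#' parental and adapted cultures.
#'
#' @param n_genes number of genes (ids `g00001`...).
#' @param n_conditions number of conditions (>= 2; the planted shift applies
#'   to condition 2 only).
#' @param n_replicates biological replicates per condition (>= 2; the study
#'   design used triplicates).
#' @param nb_dispersion negative-binomial dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`.
#' @param de_gene_ids gene ids carrying the planted shift.
#' @param lfc planted log2 fold change, scalar or one value per DE gene.
#' @param seed integer seed.
#' @param base_meanlog,base_sdlog log-normal parameters of baseline means.
#' @return Integer matrix genes x samples with a `condition` attribute
#'   (factor, one level per condition) and sample names `cond<i>_rep<j>`.
#' @export
gen_counts <- function(n_genes, n_conditions = 2L, n_replicates = 3L,
                       nb_dispersion = 0.05, de_gene_ids = character(),
                       lfc = 0, seed = 1L,
                       base_meanlog = log(200), base_sdlog = 1) {
  stop_if_not_count(n_genes, "n_genes")
  stop_if_not_count(n_conditions, "n_conditions", min = 2L)
  stop_if_not_count(n_replicates, "n_replicates", min = 2L)
  if (nb_dispersion <= 0) stop("`nb_dispersion` must be positive")
  genes <- gene_ids(n_genes)
  if (!all(de_gene_ids %in% genes)) stop("unknown ids in `de_gene_ids`")
  if (!length(lfc) %in% c(1L, length(de_gene_ids)) && length(de_gene_ids)) {
    stop("`lfc` must be scalar or one value per DE gene")
  }
  with_seed(seed, {
    mu0 <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
    shift <- rep(1, n_genes)
    if (length(de_gene_ids)) {
      shift[match(de_gene_ids, genes)] <- 2^lfc
    }
    cond <- rep(seq_len(n_conditions), each = n_replicates)
    samples <- sprintf("cond%d_rep%d", cond,
                       rep(seq_len(n_replicates), n_conditions))
    m <- matrix(0L, n_genes, length(samples),
                dimnames = list(genes, samples))
    for (s in seq_along(samples)) {
      mu <- if (cond[s] == 2L) mu0 * shift else mu0
      m[, s] <- stats::rnbinom(n_genes, mu = mu, size = 1 / nb_dispersion)
    }
    attr(m, "condition") <- factor(sprintf("cond%d", cond))
    m
  })
}

#' Write / read a count matrix as TSV (genes in rows, sample id header)
#'
#' @param counts integer matrix genes x samples.
#' @param path file path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  cond <- sub("_rep[0-9]+$", "", colnames(m))
  if (length(unique(cond)) > 1L) attr(m, "condition") <- factor(cond)
  m
}

#' Write / read screen plates as long-format CSV
#'
#' Columns: `plate_id`, `well`, `role` (compound/neg/pos), `compound_id`,
#' `intensity`.
#'
#' @param plates data.frame as produced by [gen_screen_plates()].
#' @param path file path.
#' @export
write_plates <- function(plates, path) {
  utils::write.csv(plates, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_plates
#' @export
read_plates <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    plate_id = "character", well = "character", role = "character",
    compound_id = "character", intensity = "numeric"))
  df$compound_id[df$compound_id == ""] <- NA_character_
  df
}
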