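#' Ontology container
#'
#' A rooted directed acyclic graph of terms with edges running child to
#' parent, as in the Gene Ontology `is_a` hierarchy. The single node with no
#' parents is the root.
#'
#' @param edges data.frame with columns `child`, `parent` (term ids), one row
#'   per `is_a` relation. May have zero rows for a single-term ontology, in
#'   which case `term_names` must name the lone root.
#' @param term_names named character vector mapping term id to a
#'   human-readable name; ids absent from it fall back to the id itself.
#'
#' @return An object of class `ontology`: a list with elements `terms`
#'   (character vector of ids), `names` (named character), `edges` (the
#'   child/parent data.frame), `graph` (an [igraph::graph] with edges directed
#'   child -> parent) and `root` (the root term id).
#' @export
ontology <- function(edges, term_names = NULL) {
  if (nrow(edges) == 0L) {
    if (is.null(term_names) || length(term_names) == 0L) {
      stop("an edgeless ontology needs `term_names` to define its root")
    }
    terms <- names(term_names)
    if (length(terms) != 1L) stop("an edgeless ontology must have one term")
  } else {
    edges <- data.frame(child = as.character(edges$child),
                        parent = as.character(edges$parent),
                        stringsAsFactors = FALSE)
    terms <- unique(c(edges$child, edges$parent))
  }
  if (!is.null(term_names)) {
    terms <- unique(c(terms, names(term_names)))
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges else data.frame(child = character(),
                                           parent = character()),
    directed = TRUE,
    vertices = data.frame(name = terms, stringsAsFactors = FALSE))
  if (!igraph::is_dag(g)) stop("ontology edges contain a cycle")
  roots <- terms[igraph::degree(g, mode = "out") == 0L]
  if (length(roots) != 1L) {
    stop(sprintf("ontology must have exactly one root; found %d (%s)",
                 length(roots), paste(utils::head(roots, 5), collapse = ", ")))
  }
  nm <- stats::setNames(terms, terms)
  if (!is.null(term_names)) nm[names(term_names)] <- term_names
  structure(list(terms = terms, names = nm, edges = edges,
                 graph = g, root = roots),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms, %d is_a edges, root %s\n",
              length(x$terms), nrow(x$edges), x$root))
  invisible(x)
}

#' Ancestors of a term
#'
#' Transitive closure along child -> parent edges, excluding the term itself.
#' The root has no ancestors.
#'
#' @param term a term id present in the ontology.
#' @param onto an [ontology()] object.
#' @return Character vector of ancestor term ids (possibly empty).
#' @export
ancestors <- function(term, onto) {
  stopifnot(inherits(onto, "ontology"))
  if (!term %in% onto$terms) stop(sprintf("unknown term '%s'", term))
  anc <- igraph::subcomponent(onto$graph, term, mode = "out")$name
  setdiff(anc, term)
}

#' Write / read an ontology as a minimal OBO file
#'
#' Only `[Term]` stanzas with `id:`, `name:` and `is_a:` lines are emitted or
#' understood; this is the fragment of OBO the pipeline's interfaces need.
#'
#' @param onto an [ontology()] object.
#' @param path file path.
#' @return `write_obo` returns `path` invisibly; `read_obo` returns an
#'   [ontology()].
#' @export
write_obo <- function(onto, path) {
  stopifnot(inherits(onto, "ontology"))
  parents <- split(onto$edges$parent, onto$edges$child)
  lines <- c("format-version: 1.2", "")
  for (t in onto$terms) {
    lines <- c(lines, "[Term]",
               paste0("id: ", t),
               paste0("name: ", onto$names[[t]]),
               if (!is.null(parents[[t]]))
                 paste0("is_a: ", sort(parents[[t]])),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_obo
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  idx <- which(lines == "[Term]")
  if (length(idx) == 0L) stop("no [Term] stanzas in ", path)
  ends <- c(idx[-1] - 1L, length(lines))
  child <- parent <- character()
  nms <- character()
  for (i in seq_along(idx)) {
    block <- lines[idx[i]:ends[i]]
    id <- sub("^id: ", "", grep("^id: ", block, value = TRUE)[1])
    nm <- sub("^name: ", "", grep("^name: ", block, value = TRUE)[1])
    isa <- sub("^is_a: *", "", grep("^is_a: ", block, value = TRUE))
    isa <- sub(" *!.*$", "", isa)  # tolerate trailing "! name" comments
    nms[id] <- if (is.na(nm)) id else nm
    if (length(isa)) {
      child <- c(child, rep(id, length(isa)))
      parent <- c(parent, isa)
    }
  }
  ontology(data.frame(child = child, parent = parent,
                      stringsAsFactors = FALSE), term_names = nms)
}

#' Write / read an ontology as a two-column edge list
#'
#' Tab-separated `child`, `parent` pairs with a header row.
#'
#' @inheritParams write_obo
#' @export
write_edgelist <- function(onto, path) {
  stopifnot(inherits(onto, "ontology"))
  utils::write.table(onto$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  ontology(df)
}

#' Write / read gene-to-term annotations
#'
#' Tab-separated `gene`, `term` pairs with a header row. The in-memory form
#' used throughout the package is a named list mapping each gene to its
#' character vector of term ids.
#'
#' @param ann named list, gene -> character vector of term ids.
#' @param path file path.
#' @export
write_annotations <- function(ann, path) {
  df <- data.frame(gene = rep(names(ann), lengths(ann)),
                   term = unlist(ann, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  split(df$term, factor(df$gene, levels = unique(df$gene)))
}

# Invert a gene -> terms map into term -> genes.
invert_annotations <- function(ann) {
  df <- data.frame(gene = rep(names(ann), lengths(ann)),
                   term = unlist(ann, use.names = FALSE))
  split(df$gene, df$term)
}
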