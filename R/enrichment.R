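# Hypergeometric over-representation analysis against GMT collections,
# Benjamini-Hochberg adjustment, and curated-class annotation of partners.

#' Read / write GMT gene-set collections
#'
#' GMT: one tab-separated line per term — term id, description, then
#' genes. Duplicate genes within a term are deduplicated; empty terms are
#' dropped with a warning; lines with fewer than three fields abort with
#' the line number.
#'
#' @param path GMT file.
#' @return List of class `gene_set_collection`: `terms` (named list of
#'   gene vectors), `descriptions`, `universe` (union of all term genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  terms <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, " (need >= 3 fields)", call. = FALSE)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) { warning("dropping empty term: ", f[1L]); next }
    terms[[f[1L]]] <- genes
    desc[f[1L]] <- f[2L]
  }
  gene_set_collection(terms, desc)
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$terms), function(t) {
    paste(c(t, collection$descriptions[[t]] %||% "na",
            collection$terms[[t]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param terms Named list of gene vectors.
#' @param descriptions Optional named character vector.
#' @param universe Background gene set; defaults to the union of all term
#'   genes (reference-set convention).
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(terms, descriptions = NULL, universe = NULL) {
  if (any(lengths(terms) == 0L)) stop("term with no genes", call. = FALSE)
  if (is.null(universe)) universe <- unique(unlist(terms, use.names = FALSE))
  structure(list(terms = terms,
                 descriptions = descriptions %||%
                   stats::setNames(rep("na", length(terms)), names(terms)),
                 universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation analysis
#'
#' For each term with overlap `k` against the query (`n` genes after
#' restriction to the universe of size `N`; term size `K`), the p-value is
#' the upper hypergeometric tail `P(X >= k)`, identical to the one-sided
#' Fisher exact test on the 2x2 table. Terms are BH-adjusted across the
#' collection; significance uses `q <= alpha_fdr` in `"fdr"` mode or the
#' raw `p <= alpha_fdr` in `"raw"` mode (some collections are convention-
#' ally gated on the raw p).
#'
#' @param query Character vector of query genes.
#' @param collection A `gene_set_collection`.
#' @param alpha_fdr Significance threshold (default 0.05).
#' @param mode `"fdr"` (default) or `"raw"`.
#' @return Data frame `term_id`, `k`, `K`, `n`, `N`, `enrichment_ratio`,
#'   `p_value`, `q_value`, `significant`, sorted by p; attribute
#'   `n_query_dropped` counts query genes outside the universe.
#' @export
ora_hypergeometric <- function(query, collection, alpha_fdr = 0.05,
                               mode = c("fdr", "raw")) {
  mode <- match.arg(mode)
  N <- length(collection$universe)
  q0 <- unique(query)
  query <- intersect(q0, collection$universe)
  if (!length(query)) stop("no query gene in the universe", call. = FALSE)
  n <- length(query)
  rows <- lapply(names(collection$terms), function(t) {
    genes <- intersect(collection$terms[[t]], collection$universe)
    K <- length(genes)
    k <- length(intersect(query, genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = t, k = k, K = K, n = n, N = N,
               enrichment_ratio = (k / n) / (K / N),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- if (mode == "fdr") out$q_value <= alpha_fdr
                     else out$p_value <= alpha_fdr
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_query_dropped") <- length(q0) - n
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity, preserving input order.
#' Validates the input and delegates to [stats::p.adjust()].
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}
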