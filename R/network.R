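# Network assembly: the enzyme-partner graph, the unique/common partner
# partition (Lists A and B), connector tiers, Venn-style membership cells
# and standard graph exports.

#' Classify partners as unique or common and assign connector tiers
#'
#' A partner's enzyme degree is the number of distinct target enzymes it
#' binds. Partners with degree 1 are *unique* (List A); partners with
#' degree >= `common_threshold` are *common* connectors, sub-tiered into
#' `tier2` (exactly two enzymes) and `tier3plus` (three or more). List B is
#' the full partner set.
#'
#' @param edges Edge data frame (`enzyme`, `partner`).
#' @param common_threshold Minimum enzyme degree for the common class
#'   (default 2).
#' @return Data frame `partner`, `enzyme_degree`, `class`, `connector_tier`
#'   with attribute `summary`: list `list_a` (unique partners), `list_b`
#'   (all partners), `n_unique`, `n_common`, `n_total`.
#' @export
classify_partners <- function(edges, common_threshold = 2) {
  if (nrow(edges) == 0L) {
    out <- data.frame(partner = character(), enzyme_degree = integer(),
                      class = character(), connector_tier = character(),
                      stringsAsFactors = FALSE)
    attr(out, "summary") <- list(list_a = character(), list_b = character(),
                                 n_unique = 0L, n_common = 0L, n_total = 0L)
    return(out)
  }
  deg <- tapply(edges$enzyme, edges$partner,
                function(e) length(unique(e)))
  out <- data.frame(partner = names(deg),
                    enzyme_degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out$class <- ifelse(out$enzyme_degree >= common_threshold, "common", "unique")
  out$connector_tier <- ifelse(out$enzyme_degree >= 3, "tier3plus",
                               ifelse(out$enzyme_degree == 2, "tier2", "none"))
  out <- out[order(-out$enzyme_degree, out$partner), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    list_a = out$partner[out$class == "unique"],
    list_b = out$partner,
    n_unique = sum(out$class == "unique"),
    n_common = sum(out$class == "common"),
    n_total = nrow(out))
  out
}

#' Venn-style partition of partners by enzyme membership pattern
#'
#' Assigns every partner to exactly one membership pattern (the sorted set
#' of enzymes it binds) and tabulates occupied cells only, so up to the
#' practical enzyme-count limit no 2^n enumeration is done.
#'
#' @param edges Edge data frame.
#' @param enzymes Enzyme universe (defaults to enzymes present in `edges`).
#' @return Data frame `pattern` (ampersand-joined enzyme set), `n_enzymes`,
#'   `size`; cell sizes sum to the partner total.
#' @export
venn_partition <- function(edges, enzymes = NULL) {
  if (is.null(enzymes)) enzymes <- sort(unique(edges$enzyme))
  if (length(enzymes) > 30L) stop("too many enzymes for a Venn partition",
                                  call. = FALSE)
  pat <- tapply(edges$enzyme, edges$partner,
                function(e) paste(sort(unique(e)), collapse = "&"))
  tab <- table(unlist(pat))
  out <- data.frame(pattern = names(tab),
                    n_enzymes = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    size = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$n_enzymes, out$pattern), , drop = FALSE]
}

#' Build an igraph network from enzyme-partner edges
#'
#' Nodes carry a `role` attribute (`enzyme` / `partner`); edges carry
#' `n_sources` and `localization_pass` when present. Enzyme-enzyme edges
#' are flagged with `is_enzyme_enzyme`.
#'
#' @param edges Edge data frame.
#' @param enzymes Enzyme symbols (defaults to `unique(edges$enzyme)`).
#' @return An `igraph` object.
#' @export
build_network <- function(edges, enzymes = unique(edges$enzyme)) {
  nodes <- data.frame(
    name = c(enzymes, setdiff(unique(c(edges$enzyme, edges$partner)), enzymes)),
    stringsAsFactors = FALSE)
  nodes$role <- ifelse(nodes$name %in% enzymes, "enzyme", "partner")
  eattr <- edges[, intersect(c("enzyme", "partner", "n_sources",
                               "localization_pass", "is_enzyme_enzyme"),
                             names(edges)), drop = FALSE]
  igraph::graph_from_data_frame(eattr, directed = FALSE, vertices = nodes)
}

#' Export / import a network in a standard format
#'
#' Supported formats: `"sif"` (simple interaction format, relation `pp`),
#' `"graphml"` (via igraph, attributes preserved) and `"tsv"` (edge table).
#' Exports round-trip: re-importing yields an isomorphic network with the
#' same attributes.
#'
#' @param network An igraph object from [build_network()].
#' @param path Output file.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `path` invisibly (export); an igraph object (import).
#' @export
export_network <- function(network, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "sif") {
    el <- igraph::as_edgelist(network)
    lines <- if (nrow(el)) paste(el[, 1L], "pp", el[, 2L], sep = "\t") else character()
    writeLines(lines, path)
  } else if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    df <- igraph::as_data_frame(network, what = "edges")
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(igraph::make_empty_graph(directed = FALSE))
    f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    igraph::graph_from_data_frame(data.frame(from = f[, 1L], to = f[, 3L]),
                                  directed = FALSE)
  } else if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(df, directed = FALSE)
  }
}

#' JSON summary of a classified network
#'
#' @param edges Edge data frame.
#' @param path Optional path to write JSON to.
#' @return List `n_enzymes`, `n_partners`, `n_unique`, `n_common`, `tiers`.
#' @export
network_summary <- function(edges, path = NULL) {
  cls <- classify_partners(edges)
  s <- attr(cls, "summary")
  out <- list(n_enzymes = length(unique(edges$enzyme)),
              n_partners = s$n_total,
              n_unique = s$n_unique, n_common = s$n_common,
              tiers = as.list(table(cls$connector_tier)))
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  out
}
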