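# Consensus selection (round 1): an enzyme-partner pair is kept when it is
# asserted by at least `min_sources` independent databases. Duplicate
# assertions within one source count once; pair orientation never matters.

#' Aggregate multi-source records into consensus edges
#'
#' Collapses normalized records into one edge per (enzyme, partner) pair,
#' counting the distinct sources that assert the pair, and keeps edges
#' supported by at least `min_sources` databases. Pairs are orientation-
#' invariant; edges are stored as (enzyme, partner). Edges between two
#' target enzymes are retained and flagged in `is_enzyme_enzyme` so they can
#' be reported separately. Self-interactions are excluded unless
#' `keep_self = TRUE`.
#'
#' @param records Normalized record table (gene-symbol namespace).
#' @param enzymes Character vector of target-enzyme symbols.
#' @param min_sources Minimum number of distinct supporting sources
#'   (default 3).
#' @param keep_self Keep enzyme self-interactions? Default `FALSE`.
#' @param per Apply the threshold per `"pair"` (default) or per
#'   `"partner"`, i.e. counting sources across all enzymes a partner binds.
#' @return Data frame of consensus edges: `enzyme`, `partner`, `n_sources`,
#'   `sources` (semicolon-joined, sorted), `is_enzyme_enzyme`, sorted by
#'   enzyme then partner.
#' @export
aggregate_consensus <- function(records, enzymes, min_sources = 3,
                                keep_self = FALSE,
                                per = c("pair", "partner")) {
  per <- match.arg(per)
  if (length(enzymes) == 0L) stop("empty enzyme list", call. = FALSE)
  if (min_sources < 1) stop("`min_sources` must be >= 1", call. = FALSE)
  empty <- data.frame(enzyme = character(), partner = character(),
                      n_sources = integer(), sources = character(),
                      is_enzyme_enzyme = logical(), stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(empty)

  a <- records$id_a; b <- records$id_b
  inv <- !(a %in% enzymes) & (b %in% enzymes)
  enzyme <- ifelse(inv, b, a)
  partner <- ifelse(inv, a, b)
  sel <- enzyme %in% enzymes
  enzyme <- enzyme[sel]; partner <- partner[sel]
  src <- records$source_name[sel]
  if (!keep_self) {
    ok <- enzyme != partner
    enzyme <- enzyme[ok]; partner <- partner[ok]; src <- src[ok]
  }
  # enzyme-enzyme pairs: canonical orientation is lexicographic
  both <- partner %in% enzymes
  swap <- both & partner < enzyme
  tmp <- enzyme[swap]; enzyme[swap] <- partner[swap]; partner[swap] <- tmp
  if (length(enzyme) == 0L) return(empty)

  key <- paste(enzyme, partner, sep = "\r")
  by_pair <- tapply(src, key, function(s) sort(unique(s)), simplify = FALSE)
  pairs <- do.call(rbind, strsplit(names(by_pair), "\r", fixed = TRUE))
  out <- data.frame(enzyme = pairs[, 1L], partner = pairs[, 2L],
                    n_sources = vapply(by_pair, length, 0L),
                    sources = vapply(by_pair, paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  if (per == "partner") {
    # sources pooled across every enzyme the partner binds
    pooled <- tapply(src, partner, function(s) length(unique(s)))
    out$n_sources_partner <- unname(pooled[out$partner])
    out <- out[out$n_sources_partner >= min_sources, , drop = FALSE]
  } else {
    out <- out[out$n_sources >= min_sources, , drop = FALSE]
  }
  out$is_enzyme_enzyme <- out$partner %in% enzymes
  out <- out[order(out$enzyme, out$partner), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize raw retrieval before consensus filtering
#'
#' Counts distinct partners per target enzyme and the grand total of
#' distinct (enzyme, partner) pairs, i.e. the size of the raw retrieval
#' prior to any consensus or localization selection.
#'
#' @inheritParams aggregate_consensus
#' @return List with `per_enzyme` (data frame `enzyme`, `n_partners`) and
#'   `grand_total` (distinct pair count).
#' @export
summarize_retrieval <- function(records, enzymes) {
  all_edges <- aggregate_consensus(records, enzymes, min_sources = 1)
  counts <- table(factor(all_edges$enzyme, levels = sort(enzymes)))
  list(per_enzyme = data.frame(enzyme = names(counts),
                               n_partners = as.integer(counts),
                               stringsAsFactors = FALSE),
       grand_total = nrow(all_edges))
}

#' Write / read consensus edges as TSV
#'
#' Schema: `enzyme`, `partner`, `n_sources`, `sources` (semicolon-joined),
#' `is_enzyme_enzyme`, plus `localization_pass` when present.
#'
#' @param edges Consensus edge data frame.
#' @param path Output file.
#' @return `path`, invisibly (writer); the edge data frame (reader).
#' @export
write_consensus_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_consensus_edges
#' @export
read_consensus_edges <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
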