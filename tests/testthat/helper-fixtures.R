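# Shared fixtures and independent oracles, built in code at test time.

# independent nested-loop consensus counter: for every (enzyme, partner)
# pair, walk all records and collect the set of sources asserting it
brute_consensus <- function(records, enzymes, min_sources) {
  seen <- list()
  for (i in seq_len(nrow(records))) {
    a <- records$id_a[i]; b <- records$id_b[i]
    if (a %in% enzymes && a != b) {
      e <- a; p <- b
    } else if (b %in% enzymes && a != b) {
      e <- b; p <- a
    } else next
    if (p %in% enzymes && p < e) { tmp <- e; e <- p; p <- tmp }
    key <- paste(e, p, sep = "|")
    seen[[key]] <- union(seen[[key]], records$source_name[i])
  }
  keys <- names(seen)[vapply(seen, length, 0L) >= min_sources]
  if (!length(keys))
    return(data.frame(enzyme = character(), partner = character(),
                      n_sources = integer(), stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  out <- data.frame(enzyme = parts[, 1], partner = parts[, 2],
                    n_sources = vapply(seen[keys], length, 0L),
                    stringsAsFactors = FALSE)
  out <- out[order(out$enzyme, out$partner), ]
  rownames(out) <- NULL
  out
}

# random record table over n_src sources for oracle-equivalence checks
random_records <- function(n, enzymes, partners, n_src = 13, seed = 1) {
  set.seed(seed)
  src <- sprintf("src%02d", seq_len(n_src))
  pool <- c(enzymes, partners)
  a <- sample(pool, n, replace = TRUE)
  b <- sample(pool, n, replace = TRUE)
  data.frame(source_name = sample(src, n, replace = TRUE),
             id_a = a, id_b = b,
             id_namespace = "gene_symbol",
             confidence = runif(n), evidence_type = NA_character_,
             publication_count = 1L, stringsAsFactors = FALSE)
}

make_records <- function(...) {
  rows <- list(...)
  if (!length(rows))
    return(data.frame(source_name = character(), id_a = character(),
                      id_b = character(), id_namespace = character(),
                      confidence = numeric(), evidence_type = character(),
                      publication_count = integer(), stringsAsFactors = FALSE))
  data.frame(source_name = vapply(rows, `[[`, "", 1),
             id_a = vapply(rows, `[[`, "", 2),
             id_b = vapply(rows, `[[`, "", 3),
             id_namespace = "gene_symbol",
             confidence = NA_real_, evidence_type = NA_character_,
             publication_count = NA_integer_, stringsAsFactors = FALSE)
}

edge_key <- function(df) sort(paste(df$enzyme, df$partner, sep = "|"))
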