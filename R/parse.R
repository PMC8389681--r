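# Parsers for per-source interaction exports: plain TSV edge tables and
# PSI-MITAB 2.5. Both produce the same record schema so downstream policy
# filtering and consensus aggregation are dialect-agnostic.

# canonical empty record table; `source_records` everywhere downstream
empty_records <- function() {
  data.frame(source_name = character(), id_a = character(), id_b = character(),
             id_namespace = character(), confidence = numeric(),
             evidence_type = character(), publication_count = integer(),
             stringsAsFactors = FALSE)
}

#' Parse one per-source interaction export
#'
#' Reads a plain TSV edge table (`source, id_a, id_b, confidence[, evidence,
#' n_pubs]`) or a 15-column PSI-MITAB 2.5 file into a uniform record table.
#' Malformed lines are skipped, counted and reported via a warning and the
#' `"n_malformed"` attribute; an empty file yields an empty table with a
#' warning rather than an error.
#'
#' @param path File to read.
#' @param registry_entry The [registry_entry()] describing the source; its
#'   `dialect` selects the parser and its `source_name` stamps the records.
#' @return A data frame of source records with columns `source_name`,
#'   `id_a`, `id_b`, `id_namespace`, `confidence`, `evidence_type`,
#'   `publication_count`, plus attribute `n_malformed`.
#' @export
parse_source_table <- function(path, registry_entry) {
  if (!inherits(registry_entry, "source_registry_entry"))
    stop("`registry_entry` must be a source_registry_entry", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    warning("empty source file: ", path, call. = FALSE)
    out <- empty_records()
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  out <- switch(registry_entry$dialect,
                tsv = parse_tsv_lines(lines, registry_entry$source_name),
                mitab25 = parse_mitab_lines(lines, registry_entry$source_name),
                stop("unknown dialect: ", registry_entry$dialect, call. = FALSE))
  if (attr(out, "n_malformed") > 0L)
    warning(sprintf("%s: skipped %d malformed line(s)", path,
                    attr(out, "n_malformed")), call. = FALSE)
  out
}

parse_tsv_lines <- function(lines, source_name) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) length(f) >= 3L && all(nzchar(f[2:3])), TRUE)
  # tolerate either a leading source column or bare (id_a, id_b, ...)
  rows <- lapply(fields[ok], function(f) {
    if (length(f) >= 4L || identical(f[1L], source_name)) {
      conf <- suppressWarnings(as.numeric(f[4L]))
      list(id_a = f[2L], id_b = f[3L], confidence = conf,
           evidence = if (length(f) >= 5L) f[5L] else NA_character_,
           n_pubs = if (length(f) >= 6L)
             suppressWarnings(as.integer(f[6L])) else NA_integer_)
    } else {
      list(id_a = f[1L], id_b = f[2L],
           confidence = suppressWarnings(as.numeric(f[3L])),
           evidence = NA_character_, n_pubs = NA_integer_)
    }
  })
  out <- data.frame(
    source_name = rep(source_name, length(rows)),
    id_a = vapply(rows, `[[`, "", "id_a"),
    id_b = vapply(rows, `[[`, "", "id_b"),
    id_namespace = rep("gene_symbol", length(rows)),
    confidence = vapply(rows, function(r) r$confidence %||% NA_real_, 0),
    evidence_type = vapply(rows, `[[`, "", "evidence"),
    publication_count = vapply(rows, `[[`, 0L, "n_pubs"),
    stringsAsFactors = FALSE)
  attr(out, "n_malformed") <- sum(!ok)
  out
}

# strip a "db:" prefix from a MITAB identifier column; the namespace is
# derived from the prefix (uniprotkb -> uniprot_ac, anything else -> symbol)
mitab_id <- function(field) {
  first <- strsplit(field, "|", fixed = TRUE)[[1L]][1L]
  if (is.na(first) || first == "-") return(c(NA_character_, NA_character_))
  m <- regmatches(first, regexec("^([^:]+):(.+)$", first))[[1L]]
  if (length(m) == 3L) {
    ns <- if (identical(m[2L], "uniprotkb")) "uniprot_ac" else "gene_symbol"
    c(m[3L], ns)
  } else c(first, "gene_symbol")
}

parse_mitab_lines <- function(lines, source_name) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) length(f) >= 15L, TRUE)
  rows <- lapply(fields[ok], function(f) {
    a <- mitab_id(f[1L]); b <- mitab_id(f[2L])
    if (is.na(a[1L]) || is.na(b[1L])) return(NULL)
    # evidence term is the text in parentheses of the interaction-type column
    ev <- regmatches(f[12L], regexec("\\(([^)]*)\\)", f[12L]))[[1L]]
    ev <- if (length(ev) == 2L) ev[2L] else NA_character_
    npub <- sum(grepl("pubmed:", strsplit(f[9L], "|", fixed = TRUE)[[1L]],
                      fixed = TRUE))
    conf <- regmatches(f[15L], regexec("[-a-z ]+:([0-9.eE+-]+)", f[15L]))[[1L]]
    conf <- if (length(conf) == 2L) suppressWarnings(as.numeric(conf[2L])) else NA_real_
    list(id_a = a[1L], id_b = b[1L], ns = a[2L], confidence = conf,
         evidence = ev, n_pubs = as.integer(npub))
  })
  bad_ids <- vapply(rows, is.null, TRUE)
  rows <- rows[!bad_ids]
  out <- data.frame(
    source_name = rep(source_name, length(rows)),
    id_a = vapply(rows, `[[`, "", "id_a"),
    id_b = vapply(rows, `[[`, "", "id_b"),
    id_namespace = vapply(rows, `[[`, "", "ns"),
    confidence = vapply(rows, function(r) r$confidence %||% NA_real_, 0),
    evidence_type = vapply(rows, `[[`, "", "evidence"),
    publication_count = vapply(rows, `[[`, 0L, "n_pubs"),
    stringsAsFactors = FALSE)
  attr(out, "n_malformed") <- sum(!ok) + sum(bad_ids)
  out
}

#' Apply per-source confidence policies
#'
#' A record is kept iff it satisfies every threshold of its own source's
#' registry entry: confidence strictly above `min_confidence`, evidence term
#' (when present) within `allowed_evidence`, and publication count at least
#' `min_publications`. Sources with no thresholds pass everything. Records
#' lacking a value required by a threshold are dropped.
#'
#' @param records Record table from [parse_source_table()].
#' @param registry Named list of [registry_entry()] objects.
#' @return Filtered record table.
#' @export
filter_by_source_policy <- function(records, registry) {
  if (nrow(records) == 0L) return(records)
  missing_src <- setdiff(unique(records$source_name), names(registry))
  if (length(missing_src))
    stop("source(s) not in registry: ", paste(missing_src, collapse = ", "),
         call. = FALSE)
  keep <- vapply(seq_len(nrow(records)), function(i) {
    e <- registry[[records$source_name[i]]]
    if (!is.null(e$min_confidence)) {
      conf <- records$confidence[i]
      if (is.na(conf) || conf <= e$min_confidence) return(FALSE)
    }
    if (!is.null(e$allowed_evidence)) {
      ev <- records$evidence_type[i]
      if (!is.na(ev) && !(ev %in% e$allowed_evidence)) return(FALSE)
      if (is.na(ev)) return(FALSE)
    }
    if (!is.null(e$min_publications)) {
      np <- records$publication_count[i]
      if (is.na(np) || np < e$min_publications) return(FALSE)
    }
    TRUE
  }, TRUE)
  records[keep, , drop = FALSE]
}

#' Normalize interactor identifiers to canonical gene symbols
#'
#' Resolves UniProt accessions and aliases to canonical symbols through a
#' three-column mapping table (`accession`, `alias`, `symbol`). An
#' identifier maps if it matches an accession, an alias, or is already a
#' canonical symbol. Records with an unmappable interactor are excluded and
#' reported via the `"unmapped"` attribute.
#'
#' @param records Record table.
#' @param mapping_table Data frame with columns `accession`, `alias`,
#'   `symbol` (either of the first two may be `NA` per row).
#' @return Record table with `id_a`/`id_b` in canonical symbols, namespace
#'   `gene_symbol`, and attribute `unmapped` (character vector of dropped
#'   identifiers).
#' @export
normalize_identifiers <- function(records, mapping_table) {
  req <- c("accession", "alias", "symbol")
  if (!all(req %in% names(mapping_table)))
    stop("mapping table needs columns accession, alias, symbol", call. = FALSE)
  lut <- c(
    stats::setNames(mapping_table$symbol, mapping_table$accession),
    stats::setNames(mapping_table$symbol, mapping_table$alias),
    stats::setNames(mapping_table$symbol, mapping_table$symbol))
  lut <- lut[!is.na(names(lut)) & nzchar(names(lut))]
  # conflicting duplicates (same key -> different symbols) are a config error
  dup <- split(unname(lut), names(lut))
  bad <- names(dup)[vapply(dup, function(v) length(unique(v)) > 1L, TRUE)]
  if (length(bad))
    stop("conflicting mapping rows for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  lut <- lut[!duplicated(names(lut))]
  a <- unname(lut[records$id_a]); b <- unname(lut[records$id_b])
  ok <- !is.na(a) & !is.na(b)
  unmapped <- unique(c(records$id_a[is.na(a)], records$id_b[is.na(b)]))
  out <- records[ok, , drop = FALSE]
  out$id_a <- a[ok]; out$id_b <- b[ok]
  out$id_namespace <- rep("gene_symbol", nrow(out))
  attr(out, "unmapped") <- unmapped
  out
}
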