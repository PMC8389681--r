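#' Source registry for interactome databases
#'
#' A registry entry describes one interaction database export: the file
#' dialect it ships in and the per-source confidence policy applied before
#' any record from that source is counted towards consensus. Policies mirror
#' the retrieval settings interactome browsers commonly expose: a minimum
#' interaction score, a restriction to physical-interaction evidence, or a
#' minimum number of supporting publications.
#'
#' @param source_name Registry key, e.g. `"hippie"`.
#' @param dialect One of `"tsv"` or `"mitab25"`.
#' @param min_confidence Optional minimum confidence score; records with a
#'   confidence at or below this value are dropped (strict inequality kept,
#'   matching "Score > x" policies).
#' @param allowed_evidence Optional character vector of evidence terms; a
#'   record with a non-missing evidence term outside this set is dropped.
#' @param min_publications Optional minimum publication count.
#' @return A list of class `source_registry_entry`.
#' @export
registry_entry <- function(source_name, dialect = c("tsv", "mitab25"),
                           min_confidence = NULL, allowed_evidence = NULL,
                           min_publications = NULL) {
  dialect <- match.arg(dialect)
  if (!is.character(source_name) || length(source_name) != 1L || !nzchar(source_name))
    stop("`source_name` must be a non-empty string", call. = FALSE)
  if (!is.null(min_confidence) &&
      (!is.numeric(min_confidence) || !is.finite(min_confidence) || min_confidence < 0))
    stop("`min_confidence` must be a non-negative finite number", call. = FALSE)
  if (!is.null(min_publications) &&
      (!is.numeric(min_publications) || min_publications < 0))
    stop("`min_publications` must be non-negative", call. = FALSE)
  structure(
    list(source_name = source_name, dialect = dialect,
         min_confidence = min_confidence,
         allowed_evidence = allowed_evidence,
         min_publications = min_publications),
    class = "source_registry_entry"
  )
}

#' Default 13-source interactome registry
#'
#' The shipped registry models thirteen public interactome browsers and the
#' per-source retrieval policies used when exporting from them: FunCoup
#' (confidence > 0.9), Mentha (physical interactions only), CORUM, ExoCarta,
#' APID (at least one publication), MINT (association / physical
#' association), SIGNOR, HuRI, IID, BioPlex (interaction probability > 0.9),
#' Wiki-Pi, HIPPIE (score > 0.6) and HINT. Sources without a stated policy
#' pass every record.
#'
#' @return A named list of [registry_entry()] objects, one per source.
#' @export
default_registry <- function() {
  entries <- list(
    registry_entry("funcoup",  min_confidence = 0.9),
    registry_entry("mentha",   allowed_evidence = c("physical interaction",
                                                    "physical association",
                                                    "direct interaction")),
    registry_entry("corum"),
    registry_entry("exocarta"),
    registry_entry("apid",     min_publications = 1),
    registry_entry("mint",     allowed_evidence = c("association",
                                                    "physical association")),
    registry_entry("signor"),
    registry_entry("huri"),
    registry_entry("iid"),
    registry_entry("bioplex",  min_confidence = 0.9),
    registry_entry("wikipi"),
    registry_entry("hippie",   min_confidence = 0.6),
    registry_entry("hint")
  )
  stats::setNames(entries, vapply(entries, `[[`, "", "source_name"))
}

#' Read a source registry from a JSON file
#'
#' The JSON document is an object keyed by source name; each value may carry
#' `dialect`, `min_confidence`, `allowed_evidence` and `min_publications`.
#'
#' @param path Path to the JSON registry.
#' @return Named list of [registry_entry()] objects.
#' @export
read_registry <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0L) stop("registry file is empty: ", path, call. = FALSE)
  out <- lapply(names(raw), function(nm) {
    e <- raw[[nm]]
    registry_entry(nm,
                   dialect = if (is.null(e$dialect)) "tsv" else e$dialect,
                   min_confidence = e$min_confidence,
                   allowed_evidence = e$allowed_evidence,
                   min_publications = e$min_publications)
  })
  stats::setNames(out, names(raw))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
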