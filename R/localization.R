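# Selection round 2: localization concordance. An enzyme-partner edge
# survives when the two proteins share at least one subcellular compartment
# (default "overlap" policy) or, under the stricter policy, one membrane
# compartment system.

#' Controlled compartment vocabulary
#'
#' Canonical compartment terms plus a synonym map (e.g. `"ERM"` expands to
#' `"endoplasmic reticulum membrane"`). Every term appearing in a
#' localization table must canonicalize through this vocabulary, otherwise
#' loading fails naming the offending term.
#'
#' @param extra_synonyms Optional named character vector of additional
#'   synonyms (name = synonym, value = canonical term).
#' @return List with `terms` (character) and `synonyms` (named character),
#'   class `compartment_vocabulary`.
#' @export
compartment_vocabulary <- function(extra_synonyms = NULL) {
  terms <- c("endoplasmic reticulum membrane", "golgi apparatus membrane",
             "cytoplasmic vesicle", "plasma membrane",
             "nucleus inner membrane", "mitochondrion outer membrane",
             "cytosol", "peroxisome", "lipid droplet", "nucleus",
             "nucleolus", "extracellular space")
  synonyms <- c("ERM" = "endoplasmic reticulum membrane",
                "ER membrane" = "endoplasmic reticulum membrane",
                "endoplasmic reticulum" = "endoplasmic reticulum membrane",
                "Golgi apparatus membrane" = "golgi apparatus membrane",
                "Golgi membrane" = "golgi apparatus membrane",
                "inner nuclear membrane" = "nucleus inner membrane",
                "cytoplasm" = "cytosol")
  if (!is.null(extra_synonyms)) {
    if (!all(extra_synonyms %in% terms))
      stop("extra synonyms must map to canonical terms", call. = FALSE)
    synonyms <- c(synonyms, extra_synonyms)
  }
  structure(list(terms = terms, synonyms = synonyms),
            class = "compartment_vocabulary")
}

canonical_term <- function(term, vocabulary) {
  term <- trimws(term)
  if (term %in% vocabulary$terms) return(term)
  if (term %in% names(vocabulary$synonyms))
    return(unname(vocabulary$synonyms[[term]]))
  NA_character_
}

is_membrane_term <- function(terms) any(grepl("membrane", terms, fixed = TRUE))

#' Load a protein localization table
#'
#' Reads a two-column TSV (`protein`, semicolon-joined compartment terms)
#' and canonicalizes every term through the vocabulary. Unknown terms abort
#' the load, naming the term and line. Proteins absent from the file simply
#' have no profile; how that is handled downstream is the filter policy's
#' business.
#'
#' @param path TSV file.
#' @param vocabulary A [compartment_vocabulary()].
#' @return Named list of localization profiles; each profile is a list with
#'   `protein`, `compartments` (character vector) and `is_membrane`.
#' @export
load_localization_table <- function(path, vocabulary = compartment_vocabulary()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty localization table: ", path, call. = FALSE)
    return(list())
  }
  if (startsWith(lines[1L], "protein\t")) lines <- lines[-1L]
  profiles <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L)
      stop("malformed localization line ", i, ": ", lines[i], call. = FALSE)
    raw_terms <- strsplit(f[2L], ";", fixed = TRUE)[[1L]]
    terms <- vapply(raw_terms, canonical_term, "", vocabulary = vocabulary)
    if (anyNA(terms))
      stop("unknown compartment term '", raw_terms[which(is.na(terms))[1L]],
           "' at line ", i, call. = FALSE)
    profiles[[f[1L]]] <- localization_profile(f[1L], unique(unname(terms)))
  }
  profiles
}

localization_profile <- function(protein, compartments) {
  structure(list(protein = protein, compartments = compartments,
                 is_membrane = is_membrane_term(compartments)),
            class = "localization_profile")
}

#' Membrane / soluble breakdown of a profile set
#'
#' Counts membrane-bound proteins (any membrane compartment term) versus
#' soluble ones and reports both as percentages of the annotated total.
#'
#' @param profiles Named profile list from [load_localization_table()].
#' @return List `n_membrane`, `n_soluble`, `n_total`, `percent_membrane`,
#'   `percent_soluble`.
#' @export
membrane_summary <- function(profiles) {
  mem <- vapply(profiles, `[[`, TRUE, "is_membrane")
  n <- length(mem)
  list(n_membrane = sum(mem), n_soluble = sum(!mem), n_total = n,
       percent_membrane = 100 * sum(mem) / max(n, 1L),
       percent_soluble = 100 * sum(!mem) / max(n, 1L))
}

#' Are two localization profiles concordant?
#'
#' Under the default `"overlap"` policy two profiles are concordant iff
#' their compartment sets intersect. The stricter `"membrane_system"`
#' policy additionally requires the shared compartment to be a membrane
#' term when the enzyme is membrane-bound.
#'
#' @param enzyme_profile,partner_profile [localization_profile] objects.
#' @param policy `"overlap"` (default) or `"membrane_system"`.
#' @return Logical scalar.
#' @export
profiles_concordant <- function(enzyme_profile, partner_profile,
                                policy = c("overlap", "membrane_system")) {
  policy <- match.arg(policy)
  shared <- intersect(enzyme_profile$compartments,
                      partner_profile$compartments)
  if (policy == "overlap") return(length(shared) > 0L)
  if (enzyme_profile$is_membrane) is_membrane_term(shared)
  else length(shared) > 0L
}

#' Apply the localization-concordance filter to consensus edges
#'
#' Round-2 selection: keeps edges whose enzyme and partner profiles are
#' concordant under `policy`. Edges whose partner (or enzyme) has no
#' profile are handled per `missing`: dropped, kept, or kept with
#' `localization_pass = NA` (default, so annotation gaps stay visible).
#' Dropped edges are reported via the `"dropped"` attribute together with
#' the two compartment sets.
#'
#' @param edges Consensus edge data frame.
#' @param profiles Named profile list from [load_localization_table()].
#' @param policy Passed to [profiles_concordant()].
#' @param missing One of `"keep_with_flag"` (default), `"drop"`, `"keep"`.
#' @return Subset of `edges` with a `localization_pass` column (`TRUE` or
#'   `NA` for retained missing-profile edges).
#' @export
apply_localization_filter <- function(edges, profiles,
                                      policy = c("overlap", "membrane_system"),
                                      missing = c("keep_with_flag", "drop", "keep")) {
  policy <- match.arg(policy)
  missing <- match.arg(missing)
  if (nrow(edges) == 0L) {
    edges$localization_pass <- logical(0)
    return(edges)
  }
  pass <- rep(NA, nrow(edges))
  for (i in seq_len(nrow(edges))) {
    pe <- profiles[[edges$enzyme[i]]]
    pp <- profiles[[edges$partner[i]]]
    if (!is.null(pe) && !is.null(pp))
      pass[i] <- profiles_concordant(pe, pp, policy)
  }
  keep <- ifelse(is.na(pass),
                 missing %in% c("keep", "keep_with_flag"),
                 pass)
  dropped <- edges[!keep, c("enzyme", "partner"), drop = FALSE]
  if (nrow(dropped)) {
    dropped$enzyme_compartments <- vapply(dropped$enzyme, function(p) {
      pr <- profiles[[p]]; if (is.null(pr)) "" else paste(pr$compartments, collapse = ";")
    }, "")
    dropped$partner_compartments <- vapply(dropped$partner, function(p) {
      pr <- profiles[[p]]; if (is.null(pr)) "" else paste(pr$compartments, collapse = ";")
    }, "")
  }
  out <- edges[keep, , drop = FALSE]
  out$localization_pass <- pass[keep]
  if (missing == "keep") out$localization_pass[is.na(out$localization_pass)] <- TRUE
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
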