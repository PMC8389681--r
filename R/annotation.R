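# Curated annotation: modifying-protein classes (kinases, phosphatases,
# ubiquitin ligases, deubiquitinases, proteases), cancer-driver and
# common-essential flags, and the shipped tables for the cholesterol
# synthesis pathway.

#' The seventeen cholesterol synthesis enzymes
#'
#' Gene symbols of the enzymes catalyzing the multistep transformation of
#' cholesterol precursors, from HMG-CoA reductase down to the terminal
#' reductases.
#'
#' @return Character vector of 17 gene symbols.
#' @export
cholesterol_enzymes <- function() {
  c("HMGCR", "MVK", "PMVK", "MVD", "FDPS", "FDFT1", "SQLE", "LSS",
    "DHCR24", "CYP51A1", "TM7SF2", "MSMO1", "NSDHL", "HSD17B7", "EBP",
    "SC5D", "DHCR7")
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "sterolppi")
  if (!nzchar(path)) stop("missing package data file: ", file, call. = FALSE)
  path
}

#' Shipped enzyme localization table
#'
#' Curated NextProt-style compartment assignments for the 17 pathway
#' enzymes: roughly 70% are membrane proteins (endoplasmic reticulum
#' membrane and related systems) while MVK, PMVK, MVD, FDPS and LSS are
#' soluble (cytosol, peroxisome, lipid droplet).
#'
#' @return Path to the TSV (load with [load_localization_table()]).
#' @export
enzyme_localization_path <- function() extdata("enzyme_localization.tsv")

#' Load a modifying-protein class map
#'
#' Two-column TSV `symbol`, `class` with classes among `protein_kinase`,
#' `protein_phosphatase`, `ubiquitin_ligase`, `deubiquitinase`, `protease`,
#' `other_modifier`. The shipped map carries the literature-described core
#' of modifying partners of the pathway enzymes (e.g. PRKACA, GSK3B,
#' AMFR, MARCH6, MYLIP, SYVN1, ITCH, USP20, CTSL) and is user-editable.
#'
#' @param path Map TSV; defaults to the shipped core map.
#' @return Named character vector symbol -> class.
#' @export
load_class_map <- function(path = extdata("modifying_class_map.tsv")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  classes <- c("protein_kinase", "protein_phosphatase", "ubiquitin_ligase",
               "deubiquitinase", "protease", "other_modifier")
  if (!all(df$class %in% classes))
    stop("unknown modifying class in map: ",
         paste(setdiff(df$class, classes), collapse = ", "), call. = FALSE)
  df <- df[!duplicated(df$symbol), , drop = FALSE]
  stats::setNames(df$class, df$symbol)
}

#' Classify partners by modifying-protein class
#'
#' Looks each partner up in the class map; unmapped partners get class
#' `"none"`. The summary reports how many partners can act as modifying
#' proteins, the percentage of the partner total (rounded to the nearest
#' percent), and the per-class distribution.
#'
#' @param partners Character vector of partner symbols.
#' @param class_map Named vector from [load_class_map()].
#' @return Data frame `partner`, `class`; attribute `summary`: list
#'   `n_modifying`, `n_total`, `percent_modifying`, `by_class`.
#' @export
classify_modifying <- function(partners, class_map) {
  partners <- unique(partners)
  cls <- unname(class_map[partners])
  cls[is.na(cls)] <- "none"
  out <- data.frame(partner = partners, class = cls, stringsAsFactors = FALSE)
  n_mod <- sum(cls != "none")
  attr(out, "summary") <- list(
    n_modifying = n_mod, n_total = length(partners),
    percent_modifying = round(100 * n_mod / max(length(partners), 1L)),
    by_class = as.list(table(cls[cls != "none"])))
  out
}

#' Shipped cancer-driver table
#'
#' Cancer Gene Census-style table (`symbol`,
#' `somatic_mutation_frequency`) for driver genes among the pathway's
#' partner lists, with pan-cancer somatic mutation frequencies in percent.
#'
#' @return Path to the TSV.
#' @export
cancer_driver_path <- function() extdata("cancer_drivers.tsv")

#' Flag partners as cancer drivers and common-essential genes
#'
#' Flags are derived only from the supplied tables (symbol column
#' required); somatic mutation frequencies, when present in the driver
#' table, are carried through verbatim. Duplicated table rows are
#' harmless.
#'
#' @param partners Character vector of symbols.
#' @param driver_table Data frame with `symbol` and optionally
#'   `somatic_mutation_frequency`; or a path to such a TSV.
#' @param essential_table Data frame (or TSV path) with `symbol`.
#' @return Data frame `gene`, `is_cancer_driver`,
#'   `somatic_mutation_frequency`, `is_common_essential`.
#' @export
flag_annotations <- function(partners, driver_table = NULL,
                             essential_table = NULL) {
  as_table <- function(x) {
    if (is.null(x)) return(data.frame(symbol = character()))
    if (is.character(x) && length(x) == 1L && file.exists(x))
      return(utils::read.delim(x, stringsAsFactors = FALSE))
    x
  }
  drv <- as_table(driver_table); ess <- as_table(essential_table)
  drv <- drv[!duplicated(drv$symbol), , drop = FALSE]
  partners <- unique(partners)
  freq <- if ("somatic_mutation_frequency" %in% names(drv))
    drv$somatic_mutation_frequency[match(partners, drv$symbol)]
  else rep(NA_real_, length(partners))
  data.frame(gene = partners,
             is_cancer_driver = partners %in% drv$symbol,
             somatic_mutation_frequency = freq,
             is_common_essential = partners %in% ess$symbol,
             stringsAsFactors = FALSE)
}
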