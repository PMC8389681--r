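# End-to-end orchestration: synthetic generation (or file ingestion) ->
# policy filtering -> consensus -> localization -> network -> DEG ->
# co-expression -> survival screen -> enrichment/annotation, with a
# deterministic report bundle and manifest.

#' Pipeline configuration
#'
#' All thresholds of the analysis live here, none in code. Defaults are the
#' study profile: consensus support >= 3 sources, overlap localization
#' policy, DEG gates FC >= 3 and p <= 0.01, correlation cut-offs 0.4/0.6,
#' strict survival filter p < 0.001 with HR <= 0.5 or >= 2 and >= 200
#' cases, ORA FDR <= 0.05.
#'
#' @param synth A [synth_config()] describing the synthetic inputs.
#' @param min_sources Consensus threshold.
#' @param localization_policy,missing_profile Passed to
#'   [apply_localization_filter()].
#' @param fc_threshold,alpha DEG gates.
#' @param r_cutoffs Correlation band boundaries `c(low, high)`.
#' @param criteria A [screen_criteria()].
#' @param alpha_fdr ORA significance threshold.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            min_sources = 3,
                            localization_policy = "overlap",
                            missing_profile = "keep_with_flag",
                            fc_threshold = 3, alpha = 0.01,
                            r_cutoffs = c(0.4, 0.6),
                            criteria = screen_criteria(),
                            alpha_fdr = 0.05) {
  stopifnot(min_sources >= 1, fc_threshold > 0, alpha > 0, alpha < 1)
  structure(list(synth = synth, min_sources = min_sources,
                 localization_policy = localization_policy,
                 missing_profile = missing_profile,
                 fc_threshold = fc_threshold, alpha = alpha,
                 r_cutoffs = r_cutoffs, criteria = criteria,
                 alpha_fdr = alpha_fdr),
            class = "pipeline_config")
}

#' Run the full pipeline on synthetic inputs
#'
#' Stages run in fixed order: generate -> parse -> policy filter ->
#' identifier normalization -> consensus -> localization filter -> network
#' classification -> DEG calling -> DEG-conditioned co-expression ->
#' survival screen -> enrichment and annotation. The same config and seed
#' always produce the same bundle. Intermediate files are written under
#' `workdir` (a temporary directory by default).
#'
#' @param config A [pipeline_config()].
#' @param workdir Scratch directory for the generated source files.
#' @param dialect Source-file dialect to exercise (`"tsv"` or `"mitab25"`).
#' @return List of class `report_bundle` with elements `consensus_edges`,
#'   `filtered_edges`, `partner_classes`, `network_summary`, `deg_table`,
#'   `coexpression`, `survival_screen`, `enrichment`, `modifying_classes`,
#'   `annotation_flags`, `retrieval`, `truth`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         workdir = tempfile("sterolppi_run"),
                         dialect = "tsv") {
  sc <- config$synth
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  gen <- stage("ingest", gen_interactome_sources(sc))
  paths <- stage("ingest", write_source_tables(gen, workdir, dialect))
  registry <- attr(paths, "registry")
  records <- stage("ingest", do.call(rbind, lapply(names(paths), function(s)
    parse_source_table(paths[[s]], registry[[s]]))))
  records <- stage("policy", filter_by_source_policy(records, registry))
  records <- stage("normalize", normalize_identifiers(records, gen$mapping))

  retrieval <- stage("consensus", summarize_retrieval(records, gen$truth$enzymes))
  consensus <- stage("consensus",
                     aggregate_consensus(records, gen$truth$enzymes,
                                         min_sources = config$min_sources))

  loc <- stage("localization", gen_localization_profiles(sc, gen$truth))
  loc_path <- file.path(workdir, "localization.tsv")
  utils::write.table(loc$table, loc_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  profiles <- stage("localization", load_localization_table(loc_path))
  filtered <- stage("localization",
                    apply_localization_filter(consensus, profiles,
                                              policy = config$localization_policy,
                                              missing = config$missing_profile))

  classes <- stage("network", classify_partners(filtered))
  net_sum <- stage("network", network_summary(filtered))

  # expression: enzymes + consensus partners, planted effects from config
  genes <- unique(c(gen$truth$enzymes, gen$truth$partners))
  cohorts <- list(); degs <- list()
  for (i in seq_along(sc$cohort_specs)) {
    cs <- sc$cohort_specs[[i]]
    rho <- sc$planted_rho
    if (!is.null(rho)) rho <- rho[rho$cohort_id == cs$cohort_id, , drop = FALSE]
    co <- stage("deg", gen_expression_cohort(
      cs$cohort_id, genes, cs$n_tumor, cs$n_normal,
      planted_fc = sc$planted_fc, planted_rho = rho,
      seed = sc$seed + seed_offset[["expression"]] + i))
    cohorts[[cs$cohort_id]] <- co
    degs[[cs$cohort_id]] <- stage("deg", call_degs(co, config$fc_threshold,
                                                   config$alpha))
  }
  deg_table <- do.call(rbind, degs)
  rownames(deg_table) <- NULL

  tasks <- stage("coexpression", select_coexpression_tasks(deg_table, filtered))
  coexpr <- stage("coexpression", coexpression_table(tasks, cohorts))

  sv <- sc$survival_spec
  surv <- stage("survival", gen_survival_cohort(
    sv$n_samples, sv$baseline_hazard, sv$hr, sv$censoring_rate,
    seed = sc$seed + seed_offset[["survival"]]))
  unit <- data.frame(cohort_id = "SURV1", time = surv$time_months,
                     event = surv$event, score = surv$score,
                     stringsAsFactors = FALSE)
  screen <- stage("survival",
                  screen_prognostic(list(planted_hr_unit = unit),
                                    config$criteria))

  query <- unique(filtered$partner)
  if (length(query) < 5) query <- gen$truth$partners
  gs <- stage("enrichment", gen_geneset_collection(
    query = query,
    n_terms = sc$geneset_spec$n_terms,
    term_size_range = sc$geneset_spec$term_size_range,
    universe_size = sc$geneset_spec$universe_size,
    planted_overlap = min(sc$geneset_spec$planted_overlap, length(query)),
    seed = sc$seed + seed_offset[["geneset"]]))
  enrich <- stage("enrichment", ora_hypergeometric(
    query, gs$collection, alpha_fdr = config$alpha_fdr))

  # synthetic partners are unknown to the shipped curated map, so the
  # planted class map (modifying_fraction of partners) is merged over it
  class_map <- c(load_class_map(),
                 gen_modifying_class_map(query, sc$modifying_fraction,
                                         seed = sc$seed + seed_offset[["modifying"]]))
  mods <- stage("annotation", classify_modifying(query, class_map))
  flags <- stage("annotation", flag_annotations(query, cancer_driver_path()))

  bundle <- list(consensus_edges = consensus, filtered_edges = filtered,
                 partner_classes = classes, network_summary = net_sum,
                 deg_table = deg_table, coexpression = coexpr,
                 survival_screen = screen, enrichment = enrich,
                 modifying_classes = mods, annotation_flags = flags,
                 retrieval = retrieval,
                 truth = c(gen$truth,
                           list(concordant_edges = loc$concordant_edges,
                                planted_geneset_term = gs$planted_term)),
                 manifest = list(seed = sc$seed,
                                 min_sources = config$min_sources,
                                 n_consensus = nrow(consensus),
                                 n_filtered = nrow(filtered)))
  class(bundle) <- "report_bundle"
  bundle
}

#' Write a report bundle to a directory
#'
#' Writes every tabular stage output under deterministic file names plus a
#' `manifest.json` holding the seed, stage row counts and per-file MD5
#' checksums. Refuses to overwrite an existing bundle directory unless
#' `force = TRUE`.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param directory Output directory.
#' @param force Overwrite an existing bundle? Default `FALSE`.
#' @return Path of the manifest JSON, invisibly.
#' @export
write_report <- function(bundle, directory, force = FALSE) {
  if (dir.exists(directory) && file.exists(file.path(directory, "manifest.json"))
      && !force)
    stop("bundle directory already exists (use force = TRUE): ", directory,
         call. = FALSE)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  tables <- c("consensus_edges", "filtered_edges", "partner_classes",
              "deg_table", "coexpression", "survival_screen", "enrichment",
              "modifying_classes", "annotation_flags")
  files <- character(); rows <- integer()
  for (t in tables) {
    path <- file.path(directory, paste0(t, ".tsv"))
    utils::write.table(bundle[[t]], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[t] <- path
    rows[t] <- nrow(bundle[[t]])
  }
  write_truth(bundle$truth["planted_consensus_edges"],
              file.path(directory, "truth.json"))
  manifest <- list(manifest = bundle$manifest,
                   row_counts = as.list(rows),
                   checksums = as.list(tools::md5sum(unname(files))))
  mpath <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
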