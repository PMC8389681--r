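# Synthetic-data module: multi-source interactomes, localization tables,
# expression cohorts, survival cohorts and gene-set collections with
# planted, recorded ground truth. Every generator is a pure function of
# (config, seed); each draws from its own stream derived from the master
# seed by a fixed offset, so adding one generator never perturbs another.

seed_offset <- c(interactome = 101L, localization = 202L, expression = 303L,
                 survival = 404L, geneset = 505L, modifying = 606L)

#' Configuration of the synthetic study
#'
#' Bundles the generator parameters: the interactome (number of enzymes,
#' partners and sources, the per-source detection probability for true
#' edges, the spurious-edge rate, and how many true edges are guaranteed
#' consensus support), the localization concordance fraction, expression
#' cohorts with planted fold changes and correlations, the survival cohort
#' with its planted hazard ratio, and the gene-set collection with its
#' planted enriched term.
#'
#' @param seed Master seed (integer).
#' @param n_enzymes Number of target enzymes (<= 17 reuses the pathway
#'   symbols).
#' @param n_partners Partner pool size.
#' @param n_sources Number of source databases (default 13).
#' @param detection_prob Per-source probability that a true edge is
#'   reported.
#' @param noise_edge_rate Expected spurious edges per source.
#' @param n_true_edges Number of true enzyme-partner edges.
#' @param n_consensus_edges How many true edges are planted with
#'   guaranteed support from at least `min_sources` sources.
#' @param min_sources Consensus threshold the noise is kept below.
#' @param concordant_fraction Fraction of consensus partners sharing a
#'   compartment with their enzymes.
#' @param modifying_fraction Fraction of partners planted as modifying
#'   proteins (kinases, phosphatases, ligases, deubiquitinases, proteases);
#'   default 0.25, the fraction typical of the pathway's curated partner
#'   lists.
#' @param cohort_specs List of lists `cohort_id`, `n_tumor`, `n_normal`.
#' @param planted_fc Named numeric vector gene -> linear fold change.
#' @param planted_rho Data frame `gene_a`, `gene_b`, `cohort_id`, `rho`.
#' @param survival_spec List `n_samples`, `baseline_hazard` (per month),
#'   `hr` (high- vs low-expression group), `censoring_rate`.
#' @param geneset_spec List `n_terms`, `term_size_range` (length-2),
#'   `universe_size`, `planted_overlap` (or `NULL` for no planted term).
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_enzymes = 17L, n_partners = 60L,
                         n_sources = 13L, detection_prob = 0.9,
                         noise_edge_rate = 30, n_true_edges = 80L,
                         n_consensus_edges = 10L, min_sources = 3L,
                         concordant_fraction = 0.5,
                         modifying_fraction = 0.25,
                         cohort_specs = list(list(cohort_id = "COH1",
                                                  n_tumor = 100L,
                                                  n_normal = 100L)),
                         planted_fc = NULL, planted_rho = NULL,
                         survival_spec = list(n_samples = 1000L,
                                              baseline_hazard = 0.02,
                                              hr = 0.4,
                                              censoring_rate = 0.2),
                         geneset_spec = list(n_terms = 50L,
                                             term_size_range = c(10L, 40L),
                                             universe_size = 500L,
                                             planted_overlap = 10L)) {
  if (detection_prob < 0 || detection_prob > 1)
    stop("configuration error: detection_prob must lie in [0, 1]", call. = FALSE)
  if (concordant_fraction < 0 || concordant_fraction > 1)
    stop("configuration error: concordant_fraction must lie in [0, 1]", call. = FALSE)
  if (modifying_fraction < 0 || modifying_fraction > 1)
    stop("configuration error: modifying_fraction must lie in [0, 1]", call. = FALSE)
  if (noise_edge_rate < 0)
    stop("configuration error: noise_edge_rate must be >= 0", call. = FALSE)
  if (!is.null(planted_rho) && any(abs(planted_rho$rho) >= 1))
    stop("configuration error: planted_rho values must lie in (-1, 1)", call. = FALSE)
  if (survival_spec$hr <= 0)
    stop("configuration error: planted_hr must be > 0", call. = FALSE)
  if (n_sources < min_sources)
    stop("configuration error: n_sources must be >= min_sources", call. = FALSE)
  if (n_consensus_edges > n_true_edges)
    stop("configuration error: n_consensus_edges exceeds n_true_edges", call. = FALSE)
  structure(list(seed = as.integer(seed), n_enzymes = n_enzymes,
                 n_partners = n_partners, n_sources = n_sources,
                 detection_prob = detection_prob,
                 noise_edge_rate = noise_edge_rate,
                 n_true_edges = n_true_edges,
                 n_consensus_edges = n_consensus_edges,
                 min_sources = min_sources,
                 concordant_fraction = concordant_fraction,
                 modifying_fraction = modifying_fraction,
                 cohort_specs = cohort_specs, planted_fc = planted_fc,
                 planted_rho = planted_rho, survival_spec = survival_spec,
                 geneset_spec = geneset_spec),
            class = "synth_config")
}

synth_enzymes <- function(n) {
  if (n <= 17L) cholesterol_enzymes()[seq_len(n)]
  else c(cholesterol_enzymes(), sprintf("ENZ%02d", seq_len(n - 17L)))
}

#' Generate per-source interactome edge tables with planted truth
#'
#' True enzyme-partner edges are sampled once; each source reports a true
#' edge with probability `detection_prob`, except the planted consensus
#' edges which are forced into at least `min_sources` sources. Spurious
#' (noise) edges are disjoint from the true set and each is confined to at
#' most `min_sources - 1` sources, so the consensus stage can never promote
#' noise — the recorded truth is an exact oracle. Confidence scores are
#' drawn above each source's policy threshold so policy filtering does not
#' interact with the planted design.
#'
#' @param config A [synth_config()].
#' @param registry Source registry; defaults to the first `n_sources`
#'   entries of [default_registry()].
#' @return List: `tables` (named list of per-source data frames `source`,
#'   `id_a`, `id_b`, `confidence`, `evidence`, `n_pubs`), `truth` (planted
#'   truth: `true_edges`, `true_consensus_edges`, `planted_consensus_edges`,
#'   `noise_edges`, `enzymes`, `partners`, `support`), `mapping` (accession/
#'   alias/symbol table for identifier normalization), `registry`.
#' @export
gen_interactome_sources <- function(config, registry = NULL) {
  set.seed(config$seed + seed_offset[["interactome"]])
  if (is.null(registry)) {
    reg <- default_registry()
    if (config$n_sources <= length(reg)) reg <- reg[seq_len(config$n_sources)]
    else {
      extra <- lapply(sprintf("src%02d", seq_len(config$n_sources - length(reg))),
                      registry_entry)
      reg <- c(reg, stats::setNames(extra, vapply(extra, `[[`, "", "source_name")))
    }
    registry <- reg
  }
  src_names <- names(registry)
  enzymes <- synth_enzymes(config$n_enzymes)
  partners <- sprintf("PTN%03d", seq_len(config$n_partners))

  grid <- expand.grid(enzyme = enzymes, partner = partners,
                      stringsAsFactors = FALSE)
  true_idx <- sample(nrow(grid), config$n_true_edges)
  true_edges <- grid[true_idx, , drop = FALSE]
  rownames(true_edges) <- NULL
  planted_idx <- seq_len(config$n_consensus_edges)

  support <- vector("list", nrow(true_edges))
  for (i in seq_len(nrow(true_edges))) {
    hit <- src_names[stats::runif(length(src_names)) < config$detection_prob]
    if (i %in% planted_idx && length(hit) < config$min_sources) {
      need <- config$min_sources - length(hit)
      hit <- c(hit, sample(setdiff(src_names, hit), need))
    }
    support[[i]] <- sort(hit)
  }

  # spurious pairs, disjoint from true edges, each in < min_sources sources
  mean_assign <- mean(seq_len(max(config$min_sources - 1L, 1L)))
  n_noise <- round(config$noise_edge_rate * length(src_names) / mean_assign)
  noise_pool <- setdiff(seq_len(nrow(grid)), true_idx)
  n_noise <- min(n_noise, length(noise_pool))
  noise_edges <- grid[sample(noise_pool, n_noise), , drop = FALSE]
  rownames(noise_edges) <- NULL
  noise_support <- lapply(seq_len(nrow(noise_edges)), function(i) {
    k <- sample.int(max(config$min_sources - 1L, 1L), 1L)
    sort(sample(src_names, k))
  })

  draw_conf <- function(entry, n) {
    lo <- entry$min_confidence %||% 0
    stats::runif(n, lo + 1e-6, 1)
  }
  tables <- lapply(src_names, function(s) {
    ti <- which(vapply(support, function(h) s %in% h, TRUE))
    ni <- which(vapply(noise_support, function(h) s %in% h, TRUE))
    df <- rbind(true_edges[ti, , drop = FALSE],
                noise_edges[ni, , drop = FALSE])
    n <- nrow(df)
    entry <- registry[[s]]
    ev <- if (!is.null(entry$allowed_evidence)) entry$allowed_evidence[1L]
          else "physical association"
    out <- data.frame(source = rep(s, n), id_a = df$enzyme, id_b = df$partner,
                      confidence = if (n) round(draw_conf(entry, n), 4) else numeric(),
                      evidence = rep(ev, n),
                      n_pubs = if (n) 1L + stats::rpois(n, 1) else integer(),
                      stringsAsFactors = FALSE)
    # randomize pair orientation: consensus must be orientation-invariant
    if (n) {
      flip <- stats::runif(n) < 0.5
      tmp <- out$id_a[flip]; out$id_a[flip] <- out$id_b[flip]; out$id_b[flip] <- tmp
    }
    out
  })
  names(tables) <- src_names

  n_support <- vapply(support, length, 0L)
  proteins <- c(enzymes, partners)
  mapping <- data.frame(
    accession = sprintf("SYNAC%04d", seq_along(proteins)),
    alias = paste0(proteins, "_ALT"),
    symbol = proteins, stringsAsFactors = FALSE)

  truth <- list(
    true_edges = true_edges,
    planted_consensus_edges = true_edges[planted_idx, , drop = FALSE],
    true_consensus_edges =
      true_edges[n_support >= config$min_sources, , drop = FALSE],
    noise_edges = noise_edges,
    support = stats::setNames(support,
                              paste(true_edges$enzyme, true_edges$partner)),
    enzymes = enzymes, partners = partners)
  list(tables = tables, truth = truth, mapping = mapping, registry = registry)
}

#' Write generated source tables to disk
#'
#' Each source is written either as a plain TSV edge table or as a
#' 15-column PSI-MITAB 2.5 file (identifiers swapped to the synthetic
#' UniProt-style accessions of the mapping table, confidence in column 15,
#' evidence term in the interaction-type column).
#'
#' @param gen Output of [gen_interactome_sources()].
#' @param dir Output directory (created if needed).
#' @param dialect `"tsv"` or `"mitab25"`.
#' @return Named vector of file paths; the registry entries to parse them
#'   with are attached as attribute `"registry"`.
#' @export
write_source_tables <- function(gen, dir, dialect = c("tsv", "mitab25")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  acc <- stats::setNames(gen$mapping$accession, gen$mapping$symbol)
  paths <- vapply(names(gen$tables), function(s) {
    df <- gen$tables[[s]]
    if (dialect == "tsv") {
      path <- file.path(dir, paste0(s, ".tsv"))
      utils::write.table(
        data.frame(source = df$source, id_a = df$id_a, id_b = df$id_b,
                   confidence = df$confidence, evidence = df$evidence,
                   n_pubs = df$n_pubs),
        path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    } else {
      path <- file.path(dir, paste0(s, ".mitab"))
      lines <- vapply(seq_len(nrow(df)), function(i) {
        pubs <- paste0("pubmed:", 10000000 + seq_len(df$n_pubs[i]),
                       collapse = "|")
        paste(c(paste0("uniprotkb:", acc[[df$id_a[i]]]),
                paste0("uniprotkb:", acc[[df$id_b[i]]]),
                "-", "-", "-", "-",
                'psi-mi:"MI:0004"(affinity chromatography technology)',
                "-", pubs, "taxid:9606(human)", "taxid:9606(human)",
                sprintf('psi-mi:"MI:0915"(%s)', df$evidence[i]),
                sprintf('psi-mi:"MI:0469"(%s)', s), "-",
                sprintf("score:%0.4f", df$confidence[i])),
              collapse = "\t")
      }, "")
      writeLines(lines, path)
    }
    path
  }, "")
  reg <- gen$registry
  for (s in names(reg)) reg[[s]]$dialect <- dialect
  attr(paths, "registry") <- reg
  paths
}

#' Generate localization profiles with a planted concordant subset
#'
#' Enzymes draw compartments from one half of the controlled vocabulary; a
#' `concordant_fraction` of the partners appearing in the planted consensus
#' edges share at least one compartment with every enzyme they bind, while
#' the remaining partners draw only from the other, disjoint half — so the
#' concordant subset of edges is exactly recoverable and recorded in the
#' returned truth.
#'
#' @param config A [synth_config()].
#' @param truth Truth list from [gen_interactome_sources()].
#' @return List: `table` (data frame `protein`, `compartments`
#'   semicolon-joined), `concordant_edges` (data frame of edges whose
#'   profiles overlap), `concordant_partners`.
#' @export
gen_localization_profiles <- function(config, truth) {
  set.seed(config$seed + seed_offset[["localization"]])
  pool_a <- c("endoplasmic reticulum membrane", "golgi apparatus membrane",
              "plasma membrane", "nucleus inner membrane", "cytosol",
              "peroxisome")
  pool_b <- c("nucleus", "nucleolus", "extracellular space",
              "mitochondrion outer membrane", "cytoplasmic vesicle",
              "lipid droplet")
  enz_comp <- lapply(truth$enzymes, function(e)
    sample(pool_a, sample(1:2, 1L)))
  names(enz_comp) <- truth$enzymes

  cons <- truth$true_consensus_edges
  cons_partners <- unique(cons$partner)
  n_conc <- round(config$concordant_fraction * length(cons_partners))
  conc_partners <- if (n_conc > 0)
    sample(cons_partners, n_conc) else character()

  part_comp <- lapply(truth$partners, function(p) {
    if (p %in% conc_partners) {
      enzs <- unique(cons$enzyme[cons$partner == p])
      shared <- unique(vapply(enzs, function(e) sample(enz_comp[[e]], 1L), ""))
      unique(c(shared, sample(pool_a, 1L)))
    } else {
      sample(pool_b, sample(1:2, 1L))
    }
  })
  names(part_comp) <- truth$partners

  all_comp <- c(enz_comp, part_comp)
  tab <- data.frame(protein = names(all_comp),
                    compartments = vapply(all_comp, paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  concordant_edges <- cons[cons$partner %in% conc_partners, , drop = FALSE]
  rownames(concordant_edges) <- NULL
  list(table = tab, concordant_edges = concordant_edges,
       concordant_partners = conc_partners)
}

#' Generate a tumor/normal expression cohort with planted effects
#'
#' Values are homoscedastic normal on the log2(TPM+1)-like scale around a
#' per-gene baseline drawn from U(2, 8). A gene with a planted fold change
#' has its tumor mean shifted by `log2(fc)`; a planted pair is drawn from a
#' bivariate normal with the target correlation (within each sample group);
#' all other genes are independent.
#'
#' @param cohort_id Cohort label.
#' @param genes Gene symbols for the matrix rows.
#' @param n_tumor,n_normal Group sizes (>= 3).
#' @param planted_fc Named vector gene -> linear fold change (tumor vs
#'   normal).
#' @param planted_rho Data frame `gene_a`, `gene_b`, `rho` (rows for this
#'   cohort).
#' @param seed Integer seed for this cohort.
#' @param sd Residual standard deviation on the log2 scale (default 0.5,
#'   which puts the sampling error of a median log2 fold change at
#'   n = 100/100 near 0.09, i.e. planted fold changes are recovered within
#'   about +/- 0.2 log2 units).
#' @return An [expression_cohort()].
#' @export
gen_expression_cohort <- function(cohort_id, genes, n_tumor, n_normal,
                                  planted_fc = NULL, planted_rho = NULL,
                                  seed = 1L, sd = 0.5) {
  if (n_tumor < 3L || n_normal < 3L)
    stop("configuration error: need n_tumor, n_normal >= 3", call. = FALSE)
  if (!is.null(planted_rho) && any(abs(planted_rho$rho) >= 1))
    stop("configuration error: |rho| must be < 1", call. = FALSE)
  set.seed(seed)
  n <- n_tumor + n_normal
  groups <- c(rep("tumor", n_tumor), rep("normal", n_normal))
  samples <- sprintf("%s_S%04d", cohort_id, seq_len(n))
  mu <- stats::runif(length(genes), 2, 8)
  names(mu) <- genes
  shift <- rep(0, length(genes)); names(shift) <- genes
  if (!is.null(planted_fc)) {
    hit <- intersect(names(planted_fc), genes)
    shift[hit] <- log2(planted_fc[hit])
  }
  mat <- matrix(stats::rnorm(length(genes) * n, mean = 0, sd = sd),
                nrow = length(genes), dimnames = list(genes, samples))
  if (!is.null(planted_rho) && nrow(planted_rho)) {
    for (i in seq_len(nrow(planted_rho))) {
      ga <- planted_rho$gene_a[i]; gb <- planted_rho$gene_b[i]
      rho <- planted_rho$rho[i]
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
      mat[ga, ] <- sd * z1
      mat[gb, ] <- sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    }
  }
  mat <- mat + mu + outer(shift, as.numeric(groups == "tumor"))
  expression_cohort(cohort_id, mat, stats::setNames(groups, samples))
}

#' Generate a survival cohort with a planted hazard ratio
#'
#' Half the samples form the high-score group, half the low group; event
#' times are exponential with hazard `baseline_hazard` (low) and
#' `baseline_hazard * hr` (high). Censoring is administrative-uniform on
#' `[0, t_max]` with `t_max` solved numerically so the expected censoring
#' fraction matches `censoring_rate`. Scores are drawn so a median split
#' recovers the groups exactly.
#'
#' @param n_samples Cohort size (>= 10).
#' @param baseline_hazard Events per month in the low group.
#' @param hr Planted hazard ratio, high vs low group (> 0).
#' @param censoring_rate Expected fraction censored, in `[0, 1)`.
#' @param seed Integer seed.
#' @return Data frame `sample`, `time_months`, `event`, `group`, `score`.
#' @export
gen_survival_cohort <- function(n_samples = 1000L, baseline_hazard = 0.02,
                                hr = 0.4, censoring_rate = 0.2, seed = 1L) {
  if (n_samples < 10L) stop("configuration error: n_samples must be >= 10",
                            call. = FALSE)
  if (hr <= 0) stop("configuration error: hr must be > 0", call. = FALSE)
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("configuration error: censoring_rate must lie in [0, 1)", call. = FALSE)
  set.seed(seed)
  n_low <- floor(n_samples / 2); n_high <- n_samples - n_low
  group <- c(rep("low", n_low), rep("high", n_high))
  rate <- ifelse(group == "high", baseline_hazard * hr, baseline_hazard)
  t_event <- stats::rexp(n_samples, rate = rate)
  if (censoring_rate > 0) {
    # P(censored) = P(T > C) with C ~ U(0, c), T ~ Exp(l): (1-exp(-l c))/(l c)
    cens_frac <- function(cmax) {
      mean(vapply(rate, function(l) (1 - exp(-l * cmax)) / (l * cmax), 0))
    }
    cmax <- stats::uniroot(function(cm) cens_frac(cm) - censoring_rate,
                           lower = 1e-6, upper = 1e6, tol = 1e-8)$root
    c_time <- stats::runif(n_samples, 0, cmax)
    time <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
  } else {
    time <- t_event
    event <- rep(1L, n_samples)
  }
  score <- ifelse(group == "high", stats::runif(n_samples, 0.6, 1),
                  stats::runif(n_samples, 0, 0.4))
  data.frame(sample = sprintf("SV%05d", seq_len(n_samples)),
             time_months = time, event = event, group = group,
             score = score, stringsAsFactors = FALSE)
}

#' Generate a gene-set collection with one planted enriched term
#'
#' Builds a synthetic universe, samples uniform background terms, and (when
#' `planted_overlap` is not `NULL`) plants one term sharing exactly
#' `planted_overlap` genes with the query list, padded with non-query
#' genes.
#'
#' @param query Character vector: the query gene list the term is planted
#'   against.
#' @param n_terms Number of background terms.
#' @param term_size_range Length-2 integer range of term sizes.
#' @param universe_size Universe size (includes the query genes).
#' @param planted_overlap Overlap of the planted term with `query`, or
#'   `NULL` for a null collection.
#' @param seed Integer seed.
#' @return List: `collection` (a `gene_set_collection`), `planted_term`
#'   (term id or `NA`), `planted_overlap`.
#' @export
gen_geneset_collection <- function(query, n_terms = 50L,
                                   term_size_range = c(10L, 40L),
                                   universe_size = 500L,
                                   planted_overlap = 10L, seed = 1L) {
  if (universe_size < max(term_size_range))
    stop("configuration error: universe smaller than largest term", call. = FALSE)
  if (!is.null(planted_overlap) &&
      (planted_overlap > length(query) || planted_overlap > max(term_size_range)))
    stop("configuration error: planted overlap exceeds term or list size",
         call. = FALSE)
  set.seed(seed)
  filler <- sprintf("BGG%04d", seq_len(universe_size - length(query)))
  universe <- c(query, filler)
  terms <- list()
  for (i in seq_len(n_terms)) {
    sz <- sample(seq(term_size_range[1L], term_size_range[2L]), 1L)
    terms[[sprintf("TERM%03d", i)]] <- sample(universe, sz)
  }
  planted_term <- NA_character_
  if (!is.null(planted_overlap)) {
    planted_term <- "TERM_PLANTED"
    sz <- max(term_size_range[1L], planted_overlap)
    terms[[planted_term]] <- c(sample(query, planted_overlap),
                               sample(filler, sz - planted_overlap))
  }
  list(collection = gene_set_collection(terms, universe = universe),
       planted_term = planted_term, planted_overlap = planted_overlap)
}

#' Generate a planted modifying-protein class map
#'
#' Assigns `round(fraction * length(partners))` randomly chosen partners a
#' modifying-protein class drawn from the five functional classes; the rest
#' stay unmapped. The assigned set is the ground truth for the
#' classification summary.
#'
#' @param partners Character vector of partner symbols.
#' @param fraction Fraction of partners planted as modifying.
#' @param seed Integer seed.
#' @return Named character vector symbol -> class (compatible with
#'   [classify_modifying()]).
#' @export
gen_modifying_class_map <- function(partners, fraction = 0.25, seed = 1L) {
  if (fraction < 0 || fraction > 1)
    stop("configuration error: fraction must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  classes <- c("protein_kinase", "protein_phosphatase", "ubiquitin_ligase",
               "deubiquitinase", "protease")
  n_mod <- round(fraction * length(partners))
  chosen <- if (n_mod > 0) sample(partners, n_mod) else character()
  stats::setNames(sample(classes, n_mod, replace = TRUE), chosen)
}

#' Write the planted truth to JSON
#'
#' @param truth Truth list (from the generators or [run_pipeline()]).
#' @param path Output JSON file.
#' @return `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}
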