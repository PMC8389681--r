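test_that("generators are pure functions of config and seed", {
  cfg <- synth_config(seed = 42)
  g1 <- gen_interactome_sources(cfg)
  g2 <- gen_interactome_sources(cfg)
  expect_identical(g1, g2)
  s1 <- gen_survival_cohort(seed = 42); s2 <- gen_survival_cohort(seed = 42)
  expect_identical(s1, s2)
  q <- sprintf("Q%02d", 1:20)
  expect_identical(gen_geneset_collection(q, seed = 9),
                   gen_geneset_collection(q, seed = 9))
  # written GMT is byte-identical across runs
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_gmt(gen_geneset_collection(q, seed = 9)$collection, p1)
  write_gmt(gen_geneset_collection(q, seed = 9)$collection, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("config validation names the offending field", {
  expect_error(synth_config(detection_prob = 1.5), "detection_prob")
  expect_error(synth_config(concordant_fraction = -0.1), "concordant_fraction")
  expect_error(synth_config(survival_spec = list(n_samples = 100,
                                                 baseline_hazard = 0.02,
                                                 hr = -1,
                                                 censoring_rate = 0)),
               "planted_hr")
  expect_error(gen_survival_cohort(n_samples = 5), "n_samples")
  expect_error(gen_expression_cohort("C", c("A", "B"), 2, 10), "n_tumor")
  expect_error(gen_expression_cohort("C", c("A", "B"), 10, 10,
                                     planted_rho = data.frame(gene_a = "A",
                                                              gene_b = "B",
                                                              rho = 1)),
               "rho")
  expect_error(gen_geneset_collection(sprintf("Q%d", 1:5),
                                      planted_overlap = 100), "overlap")
})

test_that("zero-noise full-detection sources contain exactly the true edges", {
  cfg <- synth_config(seed = 3, detection_prob = 1, noise_edge_rate = 0)
  gen <- gen_interactome_sources(cfg)
  truth_keys <- edge_key(gen$truth$true_edges)
  for (tab in gen$tables) {
    e <- ifelse(tab$id_a %in% gen$truth$enzymes, tab$id_a, tab$id_b)
    p <- ifelse(tab$id_a %in% gen$truth$enzymes, tab$id_b, tab$id_a)
    expect_setequal(paste(e, p, sep = "|"), truth_keys)
  }
  expect_equal(nrow(gen$truth$true_consensus_edges),
               nrow(gen$truth$true_edges))
})

test_that("planted consensus edges reach the threshold and noise stays below", {
  cfg <- synth_config(seed = 1, detection_prob = 0.15, noise_edge_rate = 50,
                      n_consensus_edges = 10)
  gen <- gen_interactome_sources(cfg)
  planted <- gen$truth$planted_consensus_edges
  support <- gen$truth$support[paste(planted$enzyme, planted$partner)]
  expect_true(all(vapply(support, length, 0L) >= cfg$min_sources))
  # no noise pair is asserted by min_sources or more sources
  noise_counts <- table(paste(gen$truth$noise_edges$enzyme,
                              gen$truth$noise_edges$partner))
  records <- do.call(rbind, gen$tables)
  for (i in seq_len(nrow(gen$truth$noise_edges))) {
    ne <- gen$truth$noise_edges[i, ]
    hit <- sum((records$id_a == ne$enzyme & records$id_b == ne$partner) |
               (records$id_b == ne$enzyme & records$id_a == ne$partner))
    expect_lt(hit, cfg$min_sources)
  }
})

test_that("downstream consensus recovers exactly the planted truth", {
  cfg <- synth_config(seed = 1, detection_prob = 1, noise_edge_rate = 50,
                      n_consensus_edges = 10)
  gen <- gen_interactome_sources(cfg)
  dir <- withr::local_tempdir()
  paths <- write_source_tables(gen, dir, "tsv")
  reg <- attr(paths, "registry")
  rec <- do.call(rbind, lapply(names(paths), function(s)
    parse_source_table(paths[[s]], reg[[s]])))
  rec <- filter_by_source_policy(rec, reg)
  rec <- normalize_identifiers(rec, gen$mapping)
  cons <- aggregate_consensus(rec, gen$truth$enzymes, min_sources = 3)
  expect_equal(edge_key(cons), edge_key(gen$truth$true_consensus_edges))
})

test_that("MITAB dialect round-trips through parsing and normalization", {
  cfg <- synth_config(seed = 6, detection_prob = 1, noise_edge_rate = 5,
                      n_enzymes = 4, n_partners = 15, n_true_edges = 12,
                      n_consensus_edges = 4)
  gen <- gen_interactome_sources(cfg)
  dir <- withr::local_tempdir()
  paths <- write_source_tables(gen, dir, "mitab25")
  reg <- attr(paths, "registry")
  rec <- do.call(rbind, lapply(names(paths), function(s)
    parse_source_table(paths[[s]], reg[[s]])))
  expect_true(all(rec$id_namespace == "uniprot_ac"))
  rec <- normalize_identifiers(rec, gen$mapping)
  expect_length(attr(rec, "unmapped"), 0L)
  cons <- aggregate_consensus(rec, gen$truth$enzymes, min_sources = 3)
  expect_equal(edge_key(cons), edge_key(gen$truth$true_consensus_edges))
})

test_that("null expression cohorts have unit median fold change", {
  co <- gen_expression_cohort("C", sprintf("G%02d", 1:20), 50, 50, seed = 2)
  fcs <- vapply(rownames(co$mat), function(g) compute_fold_change(co, g)$fc, 0)
  expect_true(all(abs(log2(fcs)) < 0.5))
  expect_lt(abs(mean(log2(fcs))), 0.1)
})

test_that("planted correlations land within the sampling band of rho", {
  co <- gen_expression_cohort("C", c("A", "B"), 200, 3,
    planted_rho = data.frame(gene_a = "A", gene_b = "B", rho = 0.9),
    seed = 5)
  r <- pearson_coexpression(co, "A", "B")$r
  expect_lt(abs(r - 0.9), 0.05)
})

test_that("planted DEGs pass both gates at FC = 4", {
  co <- gen_expression_cohort("C", sprintf("G%02d", 1:10), 100, 100,
                              planted_fc = c(G01 = 4), seed = 11)
  degs <- call_degs(co)
  g1 <- degs[degs$gene == "G01", ]
  expect_gte(g1$fc, 3)
  expect_lte(g1$p_value, 0.01)
  expect_true(g1$is_deg)
  expect_false(any(degs$is_deg[degs$gene != "G01"]))
})

test_that("survival generator honours censoring settings and plants the HR", {
  no_cens <- gen_survival_cohort(200, hr = 1, censoring_rate = 0, seed = 4)
  expect_true(all(no_cens$event == 1L))
  cens <- gen_survival_cohort(2000, hr = 1, censoring_rate = 0.3, seed = 4)
  expect_lt(abs(mean(cens$event == 0L) - 0.3), 0.05)
  # null HR: Cox estimate near 1 at n = 1000
  nul <- gen_survival_cohort(1000, hr = 1, censoring_rate = 0, seed = 7)
  hr <- cox_hr_binary(nul$time_months, nul$event, nul$group)$hr
  expect_gt(hr, 0.85); expect_lt(hr, 1.18)
  # planted HR = 0.4 recovered within the simulation envelope
  eff <- gen_survival_cohort(1000, hr = 0.4, censoring_rate = 0, seed = 3)
  hr2 <- cox_hr_binary(eff$time_months, eff$event, eff$group)$hr
  expect_gt(hr2, 0.32); expect_lt(hr2, 0.50)
  # median split on the score reproduces the generated groups
  expect_equal(unname(median_split(eff$score) == "high"),
               eff$group == "high")
})

test_that("geneset generator plants the requested overlap", {
  q <- sprintf("Q%03d", 1:30)
  gs <- gen_geneset_collection(q, planted_overlap = 10, seed = 2)
  expect_equal(length(intersect(gs$collection$terms[[gs$planted_term]], q)), 10L)
  null_gs <- gen_geneset_collection(q, planted_overlap = NULL, seed = 2)
  expect_true(is.na(null_gs$planted_term))
})
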