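test_that("TSV source tables parse with field mapping and malformed-line counting", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("hippie\tP04035\tP55072\t0.73",
               "hippie\tHMGCR\tVCP\t0.81\tphysical association\t3",
               "brokenline",
               "hippie\tA\tB\t0.5"), path)
  expect_warning(rec <- parse_source_table(path, registry_entry("hippie")),
                 "malformed")
  expect_equal(nrow(rec), 3L)
  expect_equal(attr(rec, "n_malformed"), 1L)
  expect_equal(rec$confidence[1], 0.73)
  expect_equal(rec$id_a[1], "P04035")
  expect_equal(rec$evidence_type[2], "physical association")
  expect_equal(rec$publication_count[2], 3L)
})

test_that("MITAB 2.5 lines resolve prefixed identifiers, score and evidence", {
  path <- withr::local_tempfile(fileext = ".mitab")
  line <- paste(c("uniprotkb:Q14534", "uniprotkb:P04035", "-", "-", "-", "-",
                  'psi-mi:"MI:0004"(affinity chromatography technology)', "-",
                  "pubmed:123|pubmed:456", "taxid:9606(human)", "taxid:9606(human)",
                  'psi-mi:"MI:0915"(physical association)',
                  'psi-mi:"MI:0469"(mint)', "-", "intact-miscore:0.62"),
                collapse = "\t")
  writeLines(line, path)
  rec <- parse_source_table(path, registry_entry("mint", dialect = "mitab25"))
  expect_equal(rec$id_a, "Q14534")
  expect_equal(rec$id_namespace, "uniprot_ac")
  expect_equal(rec$confidence, 0.62)
  expect_equal(rec$evidence_type, "physical association")
  expect_equal(rec$publication_count, 2L)
})

test_that("empty source file yields empty record set with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), path)
  expect_warning(rec <- parse_source_table(path, registry_entry("hint")), "empty")
  expect_equal(nrow(rec), 0L)
})

test_that("per-source policies gate on confidence, evidence and publications", {
  reg <- default_registry()
  rec <- make_records(list("hippie", "A", "B"), list("hippie", "C", "D"),
                      list("bioplex", "E", "F"), list("corum", "G", "H"),
                      list("apid", "I", "J"), list("mentha", "K", "L"))
  rec$confidence <- c(0.59, 0.61, 0.95, NA, NA, NA)
  rec$evidence_type <- c(NA, NA, NA, NA, NA, "physical interaction")
  rec$publication_count <- c(NA, NA, NA, NA, 2L, NA)
  kept <- filter_by_source_policy(rec, reg)
  # hippie 0.59 dropped (score > 0.6), 0.61 kept; bioplex 0.95 kept (> 0.9);
  # corum has no thresholds; apid needs >= 1 publication; mentha physical ok
  expect_setequal(kept$id_a, c("C", "E", "G", "I", "K"))
  expect_error(filter_by_source_policy(make_records(list("nosuch", "A", "B")), reg),
               "not in registry")
})

test_that("identifier normalization maps accessions and aliases to symbols", {
  map <- data.frame(accession = c("P04035", "P55072", NA),
                    alias = c(NA, NA, "GSK3β"),
                    symbol = c("HMGCR", "VCP", "GSK3B"),
                    stringsAsFactors = FALSE)
  rec <- make_records(list("s1", "P04035", "GSK3β"),
                      list("s1", "HMGCR", "UNKNOWNID"))
  out <- normalize_identifiers(rec, map)
  expect_equal(nrow(out), 1L)
  expect_equal(out$id_a, "HMGCR")
  expect_equal(out$id_b, "GSK3B")
  expect_equal(attr(out, "unmapped"), "UNKNOWNID")
  bad <- rbind(map, data.frame(accession = "P04035", alias = NA, symbol = "OTHER"))
  expect_error(normalize_identifiers(rec, bad), "conflicting")
})

test_that("consensus keeps pairs asserted by >= min_sources distinct sources", {
  rec <- make_records(list("mentha", "HMGCR", "VCP"), list("iid", "VCP", "HMGCR"),
                      list("hippie", "HMGCR", "VCP"), list("hint", "HMGCR", "AUP1"),
                      list("hint", "AUP1", "HMGCR"))
  out <- aggregate_consensus(rec, enzymes = "HMGCR", min_sources = 3)
  expect_equal(nrow(out), 1L)
  expect_equal(out$partner, "VCP")
  expect_equal(out$n_sources, 3L)
  expect_equal(out$sources, "hippie;iid;mentha")
  # duplicate assertions within one source count once
  one <- aggregate_consensus(rec, "HMGCR", min_sources = 2)
  expect_false("AUP1" %in% one$partner)
})

test_that("pair orientation never affects the consensus output", {
  rec1 <- make_records(list("a", "E1", "P1"), list("b", "E1", "P1"),
                       list("c", "E1", "P1"))
  rec2 <- rec1; rec2$id_a <- rec1$id_b; rec2$id_b <- rec1$id_a
  expect_identical(aggregate_consensus(rec1, "E1"),
                   aggregate_consensus(rec2, "E1"))
})

test_that("self-interactions are excluded by default but retainable", {
  rec <- make_records(list("a", "E1", "E1"), list("b", "E1", "E1"),
                      list("c", "E1", "E1"))
  expect_equal(nrow(aggregate_consensus(rec, "E1")), 0L)
  kept <- aggregate_consensus(rec, "E1", keep_self = TRUE)
  expect_equal(nrow(kept), 1L)
})

test_that("enzyme-enzyme edges are kept and flagged separately", {
  rec <- make_records(list("a", "SQLE", "HMGCR"), list("b", "HMGCR", "SQLE"),
                      list("c", "SQLE", "HMGCR"))
  out <- aggregate_consensus(rec, c("HMGCR", "SQLE"), min_sources = 3)
  expect_equal(nrow(out), 1L)
  expect_true(out$is_enzyme_enzyme)
})

test_that("consensus equals a brute-force counter on random fixtures and is monotone", {
  enz <- sprintf("E%02d", 1:5); par <- sprintf("P%03d", 1:40)
  for (seed in 1:5) {
    rec <- random_records(300, enz, par, seed = seed)
    for (k in c(1, 2, 3, 5)) {
      mine <- aggregate_consensus(rec, enz, min_sources = k)
      oracle <- brute_consensus(rec, enz, min_sources = k)
      expect_equal(mine[, c("enzyme", "partner", "n_sources")], oracle,
                   ignore_attr = TRUE)
    }
    prev <- NULL
    for (k in 1:13) {
      cur <- edge_key(aggregate_consensus(rec, enz, min_sources = k))
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("aggregation is idempotent on already-aggregated output", {
  enz <- sprintf("E%02d", 1:5)
  rec <- random_records(200, enz, sprintf("P%03d", 1:30), seed = 7)
  once <- aggregate_consensus(rec, enz, min_sources = 2)
  rerec <- data.frame(source_name = "merged", id_a = once$enzyme,
                      id_b = once$partner, id_namespace = "gene_symbol",
                      confidence = NA_real_, evidence_type = NA_character_,
                      publication_count = NA_integer_)
  again <- aggregate_consensus(rerec, enz, min_sources = 1)
  expect_equal(edge_key(again), edge_key(once))
})

test_that("retrieval summary counts distinct partners per enzyme and overall", {
  rec <- make_records(list("a", "E1", "P1"), list("a", "E1", "P2"),
                      list("b", "E1", "P3"), list("b", "E1", "P4"),
                      list("a", "E1", "P5"), list("a", "E2", "P1"),
                      list("b", "E2", "P2"), list("c", "E2", "P3"))
  s <- summarize_retrieval(rec, c("E1", "E2"))
  expect_equal(s$per_enzyme$n_partners, c(5L, 3L))
  expect_equal(s$grand_total, 8L)
  empty <- summarize_retrieval(make_records()[0, ], c("E1", "E2"))
  expect_equal(empty$grand_total, 0L)
  expect_equal(empty$per_enzyme$n_partners, c(0L, 0L))
})
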