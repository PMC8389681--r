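# sterolppi

Consensus sub-interactome mapping of the cholesterol synthesis enzymes,
with cancer-context expression, survival and enrichment analysis.

## What it does

The seventeen enzymes of the cholesterol biosynthesis pathway (HMGCR, MVK,
PMVK, MVD, FDPS, FDFT1, SQLE, LSS, DHCR24, CYP51A1, TM7SF2, MSMO1, NSDHL,
HSD17B7, EBP, SC5D, DHCR7) are regulated through physical protein–protein
interactions, and this regulation is rewired in cancer. Public interactome
databases disagree on which partners are real, so `sterolppi` implements a
multi-source consensus pipeline for mapping each enzyme's direct-partner
set and annotating it in the tumor context:

1. **Consensus selection.** Per-source exports (PSI-MITAB 2.5 or TSV) are
   parsed, filtered by each database's confidence policy (HIPPIE score
   > 0.6, BioPlex probability > 0.9, FunCoup confidence > 0.9, APID ≥ 1
   publication, Mentha physical interactions, …), normalized to canonical
   gene symbols, and an edge is kept when at least *k* independent sources
   assert it (default *k* = 3).
2. **Localization filter.** Edges survive when the enzyme and partner
   share at least one subcellular compartment term.
3. **Network classification.** Partners split into *unique* (one enzyme;
   List A) and *common* connectors (≥ 2 enzymes; List B = all partners),
   with tiers at exactly two and at three-plus enzymes; exports to SIF,
   GraphML and TSV.
4. **Differential expression + co-expression.** A gene is a DEG when its
   tumor/normal median fold change satisfies FC ≥ 3 with p ≤ 0.01
   (Mann–Whitney on log2(TPM+1) values). In cohorts where an enzyme is a
   DEG, each retained edge gets a Pearson R over tumor samples, banded as
   average (0.4 ≤ |R| < 0.6) or strong (|R| ≥ 0.6), negatives flagged.
5. **Survival screen.** Median-split Kaplan–Meier, log-rank and
   binary-covariate Cox (Breslow ties, Newton on the partial likelihood),
   for single genes and mean-expression signatures; the strict prognostic
   filter keeps units with p < 0.001, HR ≤ 0.5 or HR ≥ 2 and ≥ 200 cases.
   An HR of 0.4 for the high-expression group reads as a 2.5-fold lower
   mortality hazard.
6. **Enrichment + annotation.** Hypergeometric ORA against GMT collections
   with BH-FDR, curated modifying-protein classes (kinases, phosphatases,
   ubiquitin ligases, deubiquitinases, proteases), cancer-driver and
   essentiality flags.

A synthetic-data module generates all inputs (multi-source interactomes,
localization tables, expression and survival cohorts, gene-set collections)
with planted, recorded ground truth, so the whole pipeline is verifiable
end to end without network access. See the methods vignette
(`vignettes/sterol-interactome-methods.Rmd`) for the models, parameter
choices and limitations.

## Worked example

```r
library(sterolppi)
cfg <- pipeline_config(synth = synth_config(
  seed = 1, detection_prob = 1, noise_edge_rate = 10,
  n_enzymes = 6, n_partners = 25, n_true_edges = 30, n_consensus_edges = 8,
  cohort_specs = list(list(cohort_id = "COH1", n_tumor = 30, n_normal = 30)),
  survival_spec = list(n_samples = 300, baseline_hazard = 0.02, hr = 0.4,
                       censoring_rate = 0.1)))
bundle <- run_pipeline(cfg)

head(bundle$consensus_edges, 2)
#>   enzyme partner n_sources                                            sources
#> 1  FDFT1  PTN004        13 apid;bioplex;corum;exocarta;funcoup;hint;hippie;...
#> 2  FDFT1  PTN006        13 apid;bioplex;corum;exocarta;funcoup;hint;hippie;...

bundle$network_summary
#> $n_enzymes: 6   $n_partners: 8   $n_unique: 3   $n_common: 5
#> $tiers: none 3, tier2 3, tier3plus 2

subset(bundle$survival_screen, select = c(unit, hr, logrank_p, passes_strict))
#>              unit        hr   logrank_p passes_strict
#> 1 planted_hr_unit 0.3734131 3.33936e-14          TRUE

head(bundle$enrichment[, c("term_id", "k", "K", "p_value", "q_value")], 1)
#>        term_id k  K      p_value      q_value
#> 1 TERM_PLANTED 8 10 4.913783e-16 2.506030e-14
```

At full detection with bounded noise, the 30 consensus edges equal the
planted truth exactly; 16 edges survive the localization filter — the
planted concordant subset. The Cox fit recovers the planted hazard ratio
(0.37 against a true 0.4, the strict filter passes), and the planted
gene-set term ranks first at q ≈ 2.5e−14.

The shipped 17-enzyme localization table reproduces the pathway's
membrane/soluble split:

```r
unlist(membrane_summary(load_localization_table(enzyme_localization_path())))
#> n_membrane  n_soluble  n_total  percent_membrane  percent_soluble
#>         12          5       17          70.58824         29.41176
```

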