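---
title: "Methods: consensus sub-interactome mapping of the cholesterol synthesis enzymes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus sub-interactome mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sterolppi)
```

## The problem

The seventeen enzymes of the cholesterol biosynthesis pathway (HMGCR through
DHCR7) are regulated post-translationally through physical protein–protein
interactions: kinases, phosphatases, ubiquitin ligases, deubiquitinases and
proteases bind the enzymes and change their stability and activity. In
cancer these regulatory interactions are rewired, so mapping each enzyme's
*sub-interactome* — its set of direct physical partners — in a cancer-aware
way is a prerequisite for prioritizing the pathway's drug targets.

Public interactome databases disagree substantially: any single resource
mixes curation depth, detection methods and confidence conventions.
`sterolppi` therefore treats partner discovery as a *consensus* problem over
a registry of heterogeneous sources, followed by orthogonal filters and
cancer-context annotation:

1. **Consensus selection** — an enzyme–partner edge is retained when at
   least *k* independent source databases assert it (default *k* = 3).
2. **Localization concordance** — surviving edges must connect proteins
   with overlapping subcellular compartment annotations.
3. **Network classification** — partners are split into *unique* (bound to
   one enzyme; "List A") and *common* connectors (two or more enzymes;
   together with the unique ones, "List B"), with connector tiers at
   exactly two and at three-plus enzymes.
4. **Differential expression and co-expression** — in each tumor cohort
   where an enzyme is differentially expressed (median fold change ≥ 3,
   p ≤ 0.01), each of its retained edges is scored by the Pearson
   correlation of the two genes over tumor samples and banded as average
   (0.4 ≤ |R| < 0.6) or strong (|R| ≥ 0.6), with negative correlations
   flagged.
5. **Prognostic screening** — genes and multi-gene signatures are
   median-split and screened by Kaplan–Meier/log-rank and a
   binary-covariate Cox model; a strict filter keeps units with
   p < 0.001, HR ≤ 0.5 or HR ≥ 2, and ≥ 200 cases.
6. **Enrichment and annotation** — hypergeometric over-representation
   against GMT collections with BH-FDR, plus curated modifying-protein
   classes, cancer-driver and essentiality flags.

Because the original partner retrievals depend on moving database versions,
the package ships a synthetic-data module that generates all inputs with
*planted, recorded* ground truth, so every stage has a recovery test that
does not rely on any network resource.

## Consensus model and its assumptions

Each source export is parsed (plain TSV or PSI-MITAB 2.5) into a uniform
record schema, filtered by the source's own confidence policy (e.g. HIPPIE
score > 0.6, BioPlex interaction probability > 0.9, FunCoup confidence
> 0.9, APID ≥ 1 publication, Mentha physical interactions only), and
normalized to canonical gene symbols through an accession/alias mapping
table. Records that cannot be mapped are dropped *and reported* — silent
pass-through of mixed namespaces would corrupt every downstream join.

Consensus counts *browsers, not experiments*: two databases indexing the
same primary publication still count as two sources. This mirrors how the
multi-browser retrieval is done in practice and is deliberately simple; the
alternative (IMEx-level deduplication) is out of scope. Duplicate
assertions within one source count once; pair orientation is canonicalized
so A–B and B–A are the same edge; enzyme self-loops are excluded by
default; enzyme–enzyme edges are retained but flagged, since connectors
between pathway enzymes are biologically informative (a candidate
metabolon) and discarding them silently would lose information. The
threshold is applied per (enzyme, partner) pair by default; a
`per = "partner"` flag pools sources across enzymes instead, because the
published procedure is ambiguous on this point and we prefer exposing the
choice to guessing it.

## Localization concordance

"Similar localization profiles" is operationalized as **non-empty
compartment intersection** after canonicalizing terms through a controlled
vocabulary with synonyms ("ERM" → "endoplasmic reticulum membrane"). A
stricter `membrane_system` policy (the shared term must itself be a
membrane compartment when the enzyme is membrane-bound) is available behind
a flag. No GO-graph reasoning is performed: the filter stays flat and
auditable at the annotation granularity of NextProt-style tables.
Partners with *no* profile are kept with a flag by default
(`keep_with_flag`) rather than dropped: annotation coverage gaps should be
visible, not destructive.

The shipped enzyme table encodes the well-known split of the pathway:
about 70% of the enzymes are membrane proteins (ER membrane and related
systems) and 30% (MVK, PMVK, MVD, FDPS, LSS) are soluble
(cytosol/peroxisome/lipid droplet). Per-enzyme compartment assignments are
curated, plausible NextProt-style sets consistent with that split.

```{r}
prof <- load_localization_table(enzyme_localization_path())
unlist(membrane_summary(prof))
```

## Expression, fold change and co-expression

Fold change is the ratio of pseudo-counted **medians on the linear scale**,
recovered from the log2(TPM+1) matrix:
`fc = (median(2^x_tumor − 1) + 1) / (median(2^x_normal − 1) + 1)`.
Medians match the convention of the public tumor/normal portals this
emulates and are robust to the heavy tails of expression data. The DEG gate
is `max(fc, 1/fc) ≥ 3` **and** p ≤ 0.01; the significance test is a
two-sided Mann–Whitney on the log2 values (the portal's exact test is
undocumented; a Welch-t alternative sits behind a flag, and in practice the
FC gate dominates selection). BH q-values are reported but not used for the
gate, which follows the raw-p convention of the original cut-offs.

Correlation banding is a deterministic, total function of R with
**closed lower bounds**: |R| < 0.4 → none, 0.4 ≤ |R| < 0.6 → average,
|R| ≥ 0.6 → strong. The published band description stops at 0.7 with no
category above it; treating |R| ≥ 0.7 as anything other than "strong" would
discard pairs, so "strong" extends upward. A coefficient exactly at a
cut-off belongs to the higher band ("cut-off level 0.4" implies 0.4
passes). R ≤ −0.4 sets the negative flag. Correlations are computed over
tumor samples only by default (`scope = "all"` pools groups), and only in
cohorts where the enzyme itself passed the DEG gate.

## Survival screening

The Kaplan–Meier estimator, the two-group log-rank test and the
binary-covariate Cox model are implemented in the package (the `survival`
package is used in the test suite as an independent cross-check, never as
the implementation). Groups come from a **median split** with ties assigned
to the low group — deterministic, and consistent with a 50/50 intent. The
Cox partial likelihood is maximized by Newton iteration with **Breslow**
tie handling (Efron behind a flag), converging when the absolute score
drops below 1e−8, with a step clamp and an explicit flagged result for
monotone likelihoods (complete separation) instead of a crash. Confidence
intervals are Wald intervals from the observed information.

The default screen adjusts log-rank p-values by BH within a cohort and
keeps q ≤ 0.05. The strict filter intentionally uses the **raw** p < 0.001
together with HR ≤ 0.5 or HR ≥ 2 and n ≥ 200 — the three conditions are a
published selection rule, stated separately from the FDR-adjusted default
maps. An HR of 0.4 for the high-expression group reads as a 2.5-fold
(1/0.4) lower mortality hazard. Signature scores are per-sample means of
log2-scale expression over the signature genes present (principal-component
alternatives are out of scope).

## Enrichment and annotation

ORA p-values are upper hypergeometric tails, identical to one-sided Fisher
exact tests (the test suite verifies equality to 1e−10). The universe
defaults to the union of all collection genes — the reference-set
convention of common ORA servers — and is configurable because the original
background set is unstated. Per-collection raw-p gating (p ≤ 0.05 without
FDR) is available for collections conventionally reported that way.

The shipped modifying-protein class map carries the literature-described
core of modifying partners of the pathway enzymes, mapped to canonical
symbols (AMPK → PRKAA1, PP2A → PPP2CA, gp78 → AMFR, MEK5 → MAP2K5,
GSK3β → GSK3B, IDOL → MYLIP, PKC → PRKCA, Itch → ITCH; plus CTSL, RNF145,
USP20, MARCH6, PRKACA, SYVN1). It is an editable table, not an automated
family inference. The cancer-driver table ships the driver genes reported
among the pathway's partner lists with their pan-cancer somatic mutation
frequencies; essentiality flags are derived from any user-supplied
symbol table. All flags derive from tables, never from hard-coded gene
lists in code.

## The synthetic-data module

The generators emulate the study's input classes with planted effects:

* **Interactomes** — true enzyme–partner edges are sampled once; each
  source reports a true edge with probability `detection_prob` (default
  0.9); a designated subset is forced into ≥ `min_sources` sources; noise
  edges (default rate 30 per source) are disjoint from the true set and
  confined to at most `min_sources − 1` sources. That last constraint is a
  deliberate design choice: it keeps the recorded truth an *exact* oracle
  for the consensus stage rather than a probabilistic one.
* **Expression** — homoscedastic normal noise on the log2(TPM+1)-like
  scale around gene baselines drawn from U(2, 8), residual sd 0.5. With
  medians over 100/100 samples this puts the sampling error of a log2 fold
  change near 0.09, so planted fold changes are recovered within about
  ±0.2 log2 units. Planted pairs are bivariate normal with the target ρ.
  Negative-binomial count noise, batch effects and normalization from raw
  counts are deliberately *not* simulated: the machinery under test
  (medians, rank tests, Pearson R) only needs the location/correlation
  structure, and passing tests therefore demonstrate correctness of the
  statistics, not robustness to TCGA-scale artefacts.
* **Survival** — exponential event times (baseline hazard 0.02/month, i.e.
  median survival near 35 months in the low group), hazard multiplied by
  the planted HR in the high group, administrative-uniform censoring on
  [0, t_max] with t_max solved numerically to hit the requested censoring
  fraction. Scores are drawn so that a median split reproduces the groups
  exactly.
* **Gene sets** — uniform background terms plus one planted term with an
  exact overlap against the query list.

Every generator draws from its own stream derived from the master seed by
a fixed offset, so identical configs give byte-identical outputs and adding
one generator never perturbs another's draws.

## Worked pipeline run

```{r}
cfg <- pipeline_config(synth = synth_config(
  seed = 1, detection_prob = 1, noise_edge_rate = 10,
  n_enzymes = 6, n_partners = 25, n_true_edges = 30, n_consensus_edges = 8,
  cohort_specs = list(list(cohort_id = "COH1", n_tumor = 30, n_normal = 30)),
  survival_spec = list(n_samples = 300, baseline_hazard = 0.02, hr = 0.4,
                       censoring_rate = 0.1)))
bundle <- run_pipeline(cfg)
bundle$manifest
bundle$network_summary
subset(bundle$survival_screen,
       select = c(unit, hr, logrank_p, passes_strict))
head(bundle$enrichment, 3)
```

At full detection with bounded noise the consensus table equals the planted
truth exactly, the localization filter returns the planted concordant
subset, the planted HR of 0.4 is recovered by the Cox fit, and the planted
term ranks first in the enrichment table.

## Numerical choices, problem sizes and limitations

* Tolerances: Cox convergence |score| < 1e−8 (≤ 50 iterations); Pearson
  agreement with the textbook formula is tested to 1e−12; ORA against
  Fisher to 1e−10.
* Tie-breaks: median-split ties to the low group; band boundaries closed
  below; Breslow ties in Cox by default.
* Degenerate inputs: constant genes get p = 1; zero-variance correlation
  pairs return a flagged degenerate result; one-event or separated
  survival data return flagged results rather than errors.
* The test and acceptance simulations use the sizes the recovery
  properties are stated at — 100/100 samples for DEG recovery, 200 samples
  for correlation banding, 1000 samples for HR recovery and 1000 null
  replicates of 200 samples for log-rank calibration — which keep the full
  suite within a couple of minutes on one CPU.
* Known limitations: consensus treats overlapping browsers as independent;
  the localization filter cannot rescue unannotated partners; the
  co-expression stage is pairwise Pearson only (no partial correlations);
  the survival module is univariate (no multivariate Cox, competing risks
  or time-varying covariates); and the shipped modifying-class map covers
  the literature-described core rather than an exhaustive family census.
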