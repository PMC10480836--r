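---
title: "Methods: spatial eQTL networks, trait enrichment and comorbidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial eQTL networks, trait enrichment and comorbidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(grntraits)
```

# The model

`grntraits` implements a de-novo discovery pipeline for traits that share
molecular machinery with an index condition (asthma is the worked example
throughout). The pipeline chains five analyses:

1. **Spatial eQTL GRN.** A SNP is a *spatial eQTL* for a gene when (a) the
   restriction fragment containing the SNP is captured in physical contact
   with a fragment overlapping the gene, and (b) the SNP's allele dosage is
   associated with the gene's expression. The genome is digested in silico
   with the enzymes used to prepare the contact libraries (HindIII, cutting
   A^AGCTT; MboI, cutting ^GATC); contacts between adjacent fragments of the
   same chromosome are ignored, no maximum interaction distance is applied,
   and a SNP-gene contact counts only when it is captured in at least two
   replicates within one cell line. Each supported pair is tested by OLS of
   expression on dosage plus covariates with a two-sided t-test on the
   dosage coefficient; Benjamini-Hochberg correction is applied jointly
   over all tested pairs in the tissue and edges with adjusted p <= 0.05
   are kept. Edges are classified *cis* (same chromosome, < 1 Mb),
   *trans-intra* (same chromosome, >= 1 Mb) or *trans-inter* (different
   chromosomes).
2. **Index-condition network (level 0).** Seed SNPs are selected from a
   GWAS-catalog-style table by exact, case-sensitive trait-label match at
   p <= 1e-5. Level 0 comprises the GRN genes targeted by seed SNPs
   *plus every GRN eQTL regulating those genes*, including eQTLs associated
   with other traits — this deliberate superset is what makes cross-trait
   discovery possible.
3. **Protein-interaction expansion (levels 1-4).** Scored interaction edges
   are filtered per query protein to its top-5 partners, then to scores
   >= 0.700; unscored curated pairs bypass the filter. Level k holds the
   proteins at shortest-path distance exactly k from the level-0 genes in
   the undirected union of both edge sets, so levels are disjoint and a
   level-0 gene reachable again by a longer path stays at level 0. Each
   level's eQTL set is fetched back from the GRN.
4. **Trait enrichment with a Monte Carlo veto.** For each trait observed
   among a level's eQTLs the tail probability P(X >= x) of a
   hypergeometric draw is computed (population M = unique catalog SNPs,
   n = catalog SNPs with the trait, N = level eQTLs, x = level eQTLs with
   the trait), corrected across traits within the level. Because network
   topology alone can make some traits enrich under *any* seed set, the
   level-0 gene set is replaced by random same-size draws from the GRN gene
   universe and the whole expansion + enrichment is recomputed; a trait
   passes only if its corrected p < 0.05 *and* its frequency of
   significance across random sets is below the Monte Carlo threshold
   (default 0.05).
5. **Disease mapping and comorbidity replication.** Per-level genes are
   joined through curated gene-disease associations (text-mined sources are
   excluded) and the UMLS CUI → ICD-10 → ICD-10-AM relational composition.
   Independently, long-format hospital diagnosis records are screened for
   codes co-occurring with the index code: exclusive 2x2 counts give the
   odds ratio OR = C~AB~·H / (C~A~·C~B~), relative risk
   RR = C~AB~ / (N·P~A~·P~B~), and comorbidity score
   log2((C~AB~+1)/(P~A~·P~B~·N+1)); two-sided Fisher tests are
   BH-corrected across codes. The overlap between comorbidity-significant
   codes and gene-disease codes is tested with a one-sided Fisher test over
   a stated universe of terms.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `fdr` | 0.05 | BH cutoff on eQTL adjusted p-values |
| `p_max` | 1e-5 | GWAS association cutoff for seed SNPs |
| `top_k`, `min_score` | 5, 0.700 | scored-edge filter (partners per protein; confidence floor) |
| `depth` | 4 | protein-interaction expansion levels |
| `mc_iters`, `mc_alpha` | 200, 0.05 | Monte Carlo iterations and veto threshold |
| `min_patients` | 6 | minimum carriers of a candidate diagnosis code |
| `max_age` | 100 | patients strictly older are excluded |
| `code_level` | "3" | ICD codes compared at the 3-character category |

The cis window is fixed at 1 Mb (the field's convention). The replicate
rule is read as "at least two replicates within at least one cell line":
replicate support is evidence about a single library, so summing across
cell lines would conflate library-specific noise.

# Design choices where the design was open

- **Cut offsets.** Only fragment adjacency matters downstream, so any fixed
  convention works; we use the canonical recognition-site chemistry
  (HindIII after offset 1, MboI before the site) and resolve overlapping
  sites by left-to-right scanning.
- **Distance anchor.** The annotation schema carries no strand, so the
  cis/trans distance anchor is the annotated interval start.
- **Correction flavour.** Enrichment sources describe the correction both
  as FDR and as Bonferroni; BH is the default and
  `correction = "bonferroni"` preserves the alternative reading.
- **Monte Carlo pass rule.** The veto is formalized as the empirical
  frequency of the trait being significant at the same level across random
  gene sets; frequency-of-significance is the direct estimator of the
  topology-generic null the simulation is meant to remove. Each iteration
  re-expands the full network from the random seed set (the filtered
  scored-edge table is cached; the null definition is unaffected).
- **Eq-consistency in the comorbidity statistics.** C~A~ and C~B~ are
  exclusive ("index only" / "candidate only"), the convention under which
  the OR formula is the standard cross-product ratio; the RR reading
  observed/expected = C~AB~/(N·P~A~·P~B~) is the only one consistent with
  the score's expected count P~A~·P~B~·N. An OR confidence interval cannot
  overlap 0, so the CI exclusion rule is applied on the log-OR scale
  (interval containing 0, i.e. OR interval containing 1).
- **Exclusion ordering.** Codes below `min_patients` are excluded before
  testing; the BH family is formed over all tested codes; the CI exclusion
  then prunes the final table. Forming the family before the CI rule keeps
  the correction conservative.
- **Expansion frontier.** Levels expand from level-0 *genes* only, not from
  the full eQTL-target closure; the level language ("first neighbors of
  level-0 proteins") is about proteins, and the eQTLs are re-attached per
  level afterwards.
- **Untestable pairs** (constant dosage or zero-variance expression) are
  flagged and excluded from the BH family rather than given degenerate
  p-values.
- **Identifier namespaces.** Gene and protein identifiers are taken as one
  shared namespace; unmapped identifiers simply find no edges.

# What the synthetic generator emulates

The generator plants every signal the pipeline is meant to recover and
writes a machine-readable truth ledger, so each stage has a recovery test:

- a genome whose background is scrubbed of both recognition motifs, with
  sites inserted at a controlled density (insertions are spaced so they
  cannot create extra occurrences of either motif — neither motif
  self-overlaps or contains the other);
- Hardy-Weinberg genotypes at MAF drawn from \[0.05, 0.5\] (the
  common-variant floor), log-normal expression baselines to mimic TPM
  skew, planted `beta * dosage` effects, and a sex covariate whose effect
  scales with `noise_sd` so the zero-noise limit is exact;
- contacts supporting every planted pair in all replicates of at least one
  cell line, plus flagged background: null pairs emitted in exactly two
  replicates (true negatives that enter the regression), single-replicate
  junk (must be filtered), and adjacent-fragment rows (must be ignored);
- a GWAS catalog with three planted traits — the index trait, a
  *level-0-specific* trait (one eQTL per index gene; random gene sets
  rarely assemble it) and a *hub confounder* trait riding on the neighbors
  of a high-degree protein (random gene sets reach it easily, so the Monte
  Carlo veto must reject it) — over a background of catalog-only SNPs;
- protein chains realizing levels 1-4 exactly, decoy edges below the
  confidence cutoff, a six-partner protein exercising the top-5 rule, and
  the hub wired through unscored curated edges;
- patient records realizing a planted odds ratio through conditional code
  rates, ages uniform on \[0, 110\] so the over-100 exclusion fires, a
  rare code below the minimum-patient filter, and a filler wellness code
  for otherwise diagnosis-free patients (which surfaces as a *negative*
  association, exercising that side of the screen);
- gene-disease and code-mapping tables that route eight level-2..4 genes to
  the planted comorbid codes, with an unmapped CUI, a category fanning out
  to two full codes, and a text-mined record the source filter must drop.

What it does **not** emulate: linkage disequilibrium, population
stratification, isoform structure, realistic contact-frequency decay,
longitudinal or sex-structured diagnosis patterns. Passing tests therefore
demonstrate the pipeline's logic and error control, not performance on
real GTEx/Hi-C/registry data.

## Default study conditions

Defaults: 2 chromosomes x 2.5 Mb (so all three interaction classes are
realizable under the 1 Mb window), 200 genes, 400 SNPs, 150 planted eQTLs
(beta 2, noise SD 0.5, i.e. effect/noise = 4) across 200 samples, 2 cell
lines x 3 replicates, 10% contact background, 5 index genes, a 30-neighbor
hub, ~1,600 catalog-only SNPs, 20,000 patients with planted OR 5 at 5%
index prevalence. These sizes give essentially deterministic recovery of
planted effects (per-pair |t| ~ 17), a sharp Monte Carlo contrast (the hub
trait is reachable from roughly three quarters of random seed sets, the
level-0-specific trait from a few percent), and keep a full pipeline run
in seconds. Tests and the acceptance script use 200 Monte Carlo
iterations; the veto frequencies sit far from the 0.05 threshold, so the
verdicts are stable at that resolution.

# Numerical choices

- The hypergeometric tail is summed in log space (`lchoose`), returns
  exactly 1 at x = 0, warns and returns 0 for impossible observations
  (x > min(n, N)), and drops terms with more failures than the population
  allows. It agrees with exact draw counting to 1e-12 for all populations
  up to 25 and with `phyper` beyond.
- Ties at the top-k boundary of the scored-edge filter break by score
  descending, then partner identifier ascending — deterministic output.
- Haldane's +0.5 is added to all four 2x2 cells only when a cell is zero.
- Coordinates are 0-based half-open internally; GTF-like inputs (1-based
  inclusive) are converted at read time. A position equal to a fragment
  start belongs to that fragment.
- All output TSVs use one fixed dialect (header, tab, UTF-8, '.' decimal,
  no quoting) so manifest hashes are reproducible; every source of
  randomness flows from named seeds.

# Known limitations

- The comorbidity screen is cross-sectional; directionality (which
  diagnosis came first) is out of scope.
- Seed SNPs are matched by exact label; ontology-aware trait collapsing is
  deliberately not performed, mirroring the exact-term seed search.
- The overlap test's term universe is a required parameter — there is no
  principled default, and results scale with it.
- Sex-stratified comorbidity is not implemented (the screen reports
  totals).
- Real-scale inputs (millions of contacts, 40M variants) would need a
  chunked eQTL-testing path; the per-pair OLS here is written for clarity
  at synthetic scale.
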