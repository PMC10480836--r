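# grntraits

Network-based discovery of complex traits and diseases that share molecular
machinery with an index condition. The package is written for statistical
geneticists and systems-biology researchers who want to go from variant-level
GWAS hits to tissue-specific regulatory context, protein-interaction
neighborhoods, and health-record corroboration — and for methodologists who
want every stage of that chain testable against planted truth.

## What it computes

1. **Spatial eQTL gene regulatory network (GRN).** A SNP is a *spatial eQTL*
   of a gene when the restriction fragment carrying the SNP is captured in
   chromatin contact (≥ 2 replicates within one cell line; adjacent
   fragments ignored) with a fragment overlapping the gene, and OLS of
   expression on allele dosage (plus covariates) is significant after
   Benjamini–Hochberg correction (adjusted p ≤ 0.05). Edges are classified
   cis (< 1 Mb), trans-intrachromosomal (≥ 1 Mb) or trans-interchromosomal.
2. **Index-condition network and PPIN expansion.** Level 0 = GRN genes
   targeted by index-trait SNPs plus *all* eQTLs regulating them; levels
   1–4 = proteins exactly k curated interaction edges away (scored edges
   filtered to each query protein's top-5 partners at confidence ≥ 0.700).
3. **Trait enrichment with a Monte Carlo veto.** Per level and trait, the
   hypergeometric tail

   P(X ≥ x) with population M (unique catalog SNPs), successes n (catalog
   SNPs with the trait), draws N (level eQTLs), observed x

   is corrected across traits; traits that also come out significant when
   the level-0 genes are replaced by random same-size gene sets
   (frequency ≥ 0.05 over the simulation) are vetoed as topology-generic.
4. **Disease mapping and comorbidity.** Per-level genes are mapped through
   curated gene–disease associations and UMLS CUI → ICD-10 → ICD-10-AM
   tables; hospital diagnosis records are screened for codes co-occurring
   with the index code using OR = C_AB·H/(C_A·C_B),
   RR = C_AB/(N·P_A·P_B), comorbidity score log2((C_AB+1)/(P_A·P_B·N+1)),
   Fisher tests with BH q-values, and a Fisher overlap test between the
   two disease-term sets.

A seeded synthetic-data generator (`synth_generate()`) emulates every input
with planted eQTLs, PPIN levels, trait SNP sets and comorbid code pairs,
and writes a truth ledger so each stage has a recovery test.

## Worked example

```r
library(grntraits)

res <- run_all(list(out_dir = "demo", seed = 1, mc_seed = 1001,
                    mc_iters = 200))
summary(res$grn)
#> Spatial eQTL GRN: synthetic
#>   edges: 152 (151 SNPs regulating 145 genes)
#>   cis: 50  trans-intra: 24  trans-inter: 78
#>   pairs tested: 276 (untestable: 0)

res$verdict
#>              trait level x  N  n    M       pvalue   adj_pvalue mc_frequency passes
#> 1           Asthma     0 5 10 10 1625 6.680257e-10 1.336051e-09         0.01   TRUE
#> 2 Eosinophil count     0 5 10 40 1625 1.613502e-06 1.613502e-06         0.01   TRUE
```

All 150 planted eQTL pairs are recovered among the 152 edges (the two
extras are the false-positive residue the 5% FDR allows for). Of the three
traits planted on the network, the index trait and the level-0-specific
trait pass; the third ("Body mass index", planted on the neighbors of a
hub protein) is strongly enriched at level 2 (adjusted p ≈ 9e-17) but is
vetoed because random gene sets reach the hub in 74% of Monte Carlo
iterations — exactly the topology bias the veto exists to remove.

```r
print(res$comorbidity)
#> Comorbidity screen vs J45.9: 18217 patients (prevalence 4.858%)
#>   3 codes retained; 3 significant at q < 0.05
res$overlap$p
#> [1] 0.0004507385
```

The two planted comorbid codes come out with odds ratios 5.31 and 4.33
(planted OR = 5; q < 1e-34), the filler wellness code appears as a
negative association, and their overlap with the gene–disease terms gives
Fisher p ≈ 4.5e-4.

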