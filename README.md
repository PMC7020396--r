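# gwaspath

Pathway association analysis of GWAS summary statistics.

Genome-wide association studies test hundreds of thousands of SNPs one at a
time, and genes of small effect rarely clear a genome-wide FDR threshold.
`gwaspath` recovers that signal at the pathway level: it keeps **every**
SNP–trait association regardless of significance, collapses linked SNPs
into tagSNPs using linkage-disequilibrium (LD) data, transfers the tagSNP
allele effects and p-values to nearby genes, and asks whether the genes of
a metabolic pathway sit unusually high in the effect-ranked gene list. It
is aimed at quantitative geneticists working with TASSEL-style GLM/MLM
output in crops (it was designed with maize-scale panels in mind) but works
with any species for which a GFF3 annotation and a pathway–gene membership
file exist.

## Method

1. **Load & filter.** Markers must be biallelic and carry a marker R²
   (coefficient of determination of the SNP/trait association); LD rows
   must be intra-chromosomal with a non-missing r².
2. **Linkage groups & tagSNPs.** An edge joins two SNPs when LD r² > a
   cutoff (default 0.8). Components of size 1 are unlinked SNPs, size 2
   singly-linked pairs, size ≥ 3 blocks. One tagSNP represents each group:
   pairs by larger |effect| (downstream SNP on a tie; opposite signs →
   lower p; opposite signs with equal p are *problematic* and dropped),
   blocks by the majority effect sign (ties broken by the sign of the
   block's common SNP).
3. **Gene assignment.** Genes within a physical window (default 1000 bp)
   of a tagSNP inherit its effect and p-value; genes hit by several
   tagSNPs are resolved by majority sign, then lowest p / greatest
   |effect|.
4. **Enrichment.** Genes are ranked by effect (direction chosen by the
   analyst). For pathway *P* with hit set *H* in a ranking of *N* genes,
   the running sum steps

   ```
   S_i = S_{i-1} + |e_i| / Σ_{g∈H}|e_g|   if gene i ∈ H
   S_i = S_{i-1} − 1 / (N − |H|)          otherwise
   ```

   and the enrichment score is `ES = max_i S_i` (a weighted
   Kolmogorov–Smirnov statistic; `S_N = 0` by construction). A null
   distribution of ES is built by resampling the gene-effect vector with
   replacement (default 1000 replicates), giving
   `z = (ES_obs − mean(null)) / sd(null)`, `p = 1 − Φ(z)`, and Storey/BH
   q-values for FDR control. Each pathway is drawn as a rugplot of its
   running sum.

## Worked example

```r
library(gwaspath)

ds <- simulate_gwas_dataset(seed = 42)        # 600 SNPs, 250 genes, 20 pathways,
                                              # pathway PWY0001 planted at +2 SD
paths <- write_gwas_dataset(ds, "example_data")
res <- run_gwas_pathway_analysis(
  paths[["stats"]], paths[["effects"]], paths[["ld"]],
  paths[["gff"]], paths[["pathways"]],
  trait = "trait1", n_perm = 1000, seed = 1,
  filter_mode = "q", filter_threshold = 0.05, outdir = "results_demo")
print(res)
```

```
GWAS pathway-association analysis
  markers: 600 (non-biallelic dropped: 0, missing R2: 0)
  tagSNPs: 355 (problematic pairs dropped: 0)
  genes assigned: 250
  pathways scored: 20; passing q filter: 1

Top pathways:
  pathway_id n_genes     ES        z            p            q
1    PWY0001      10 0.9125 4.048475 2.577624e-05 0.0005155247
```

The 600 simulated SNPs collapse to 355 tagSNPs (the generator plants LD
blocks of 1–4 SNPs per gene); all 250 genes inherit an effect. Only the
planted pathway survives the q ≤ 0.05 filter: its ten genes crowd the top
of the effect ranking, so the running sum peaks at ES = 0.91, about 4
standard deviations above the bootstrap null mean. `results_demo/`
contains the results table, the gene-assignment and tagSNP tables, the
serialised running sums, a run log with every filter count, and one
rugplot per significant pathway.

Each stage is also exported on its own (`read_gwas_stats()`,
`merge_markers()`, `linkage_groups()`, `tag_snps()`, `assign_genes()`,
`pathway_enrichment()`, ...), and
`inst/scripts/run_pathway_analysis.R` wraps the pipeline for shell use
with YAML-config support.

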