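---
title: "Methods: from SNP associations to pathway enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from SNP associations to pathway enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwaspath)
```

## The problem and the model

Single-marker GWAS tests leave most of a polygenic trait's architecture
below the significance threshold. `gwaspath` aggregates the full spectrum
of SNP–trait associations at the level of metabolic pathways. The chain of
inference is: SNPs → linkage groups → tagSNPs → genes → pathways. Each
step deliberately *reduces dimensionality before testing*: linked SNPs are
statistically redundant, so each linkage group contributes one tagSNP, and
each gene one effect value, before any pathway statistic is computed.

The pathway statistic is a weighted Kolmogorov–Smirnov running sum over
the effect-ranked gene list. With `N` ranked genes and hit set `H`
(pathway genes present in the ranking), rank `i` contributes
`+|e_i| / Σ_{g∈H} |e_g|` when gene `i` is a pathway member and
`−1/(N−|H|)` otherwise; the enrichment score is the maximum of the
cumulative sum. Both the rises and the falls are normalised to total 1, so
the sum always closes at 0 (the tests assert `|S_N| < 1e−9`) and
`ES ∈ [−1, 1]`. The weight exponent is 1: rises are proportional to the
absolute gene effect, which favours pathways whose members carry *large*
effects near the top of the ranking over pathways that merely appear early.

Significance comes from a resampling null: the observed gene-effect vector
is resampled with replacement (a bootstrap of effects over fixed gene
labels), genes are re-ranked, and every pathway's ES recomputed. With null
mean `μ` and sample standard deviation `σ` (N−1 denominator),
`z = (ES_obs − μ)/σ` and `p = 1 − Φ(z)`. This normal approximation is the
method's main distributional assumption; the running-sum maximum is mildly
right-skewed, so tail p-values are approximate rather than exact (see
*Limitations*).

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `r2_cutoff` | 0.8 | r² | LD above which two SNPs are linked (strictly `>`). 0.8 is the conventional LD-block threshold; raising it fragments groups (the group count is monotone in the cutoff). |
| `window` | 1000 | bp | Maximum SNP-to-gene distance for effect transfer; distance is 0 inside the gene, else the gap to the nearest gene boundary, strand ignored. Widening the window never removes a gene. |
| `min_genes` | 5 | genes | Minimum *assigned* genes a pathway needs (counted after intersection with the ranking), guarding against small-sample ES inflation. |
| `n_perm` | 1000 | replicates | Null resamples. 200 is adequate for rank-based screening (the validation suite uses it); 1000 stabilises tail z-scores. |
| `direction` | increase | — | Whether "best" means the most positive (`increase`) or most negative (`decrease`) effect, letting the two trait tails be tested separately. |
| `null_mode` | bootstrap | — | `bootstrap` (with replacement) is the primary null; `permutation` (without) is offered for sensitivity analysis. |
| `workers` | 1 | processes | Replicates are distributed by index with per-replicate seeds drawn up front, so results are bit-identical for any worker count. |

## Rule details and degenerate inputs

Several election rules needed decisions beyond their one-line statements:

* **Marker effect from two allele rows.** TASSEL reports one free allele
  effect with the other allele as reference, but nothing marks which is
  which. We take the first allele row (file order) with a nonzero effect;
  if both are nonzero, the first row. Deterministic and matches the
  reference-allele convention whenever the reference row is 0.
* **Blocks are connected components.** A "block" is defined by SNPs linked
  to one SNP in common, which describes a star. Chains and overlapping
  stars are not addressed by that picture, so blocks are implemented as
  connected components of size ≥ 3, with the common SNP = the
  highest-degree member (tie → smallest position). On a star graph this is
  exactly the star definition, and it is independent of input order.
* **Zero effects** count as neither positive nor negative in the sign
  tallies. A pair with effects (0, 0) is "equal, same sign", so the
  downstream SNP wins; a pair with one zero effect is treated under the
  same-sign branch (signs are opposite only when the product is strictly
  negative). A block tie whose common SNP has effect 0 falls back to the
  largest |effect|, then smallest position.
* **Pair with opposite signs and equal p** admits no defensible choice:
  the pair is *problematic*, dropped and counted, and the conservation
  identity `Σ n_linked + 2 × problematic pairs = total SNPs` is asserted
  in the tests.
* **ES is not floored at 0.** When every prefix sum is negative the
  maximum (≤ 0) is reported as-is so that the null normalisation remains
  well-defined; such pathways simply score deeply non-significant.
* **Degenerate null (sd = 0)**, e.g. all effects identical: p is set to 1
  when the observed ES does not exceed the null mean, else the smallest
  positive double; the row is flagged `degenerate_null`.
* **All pathway-gene effects zero**: rises fall back to uniform `1/|H|`
  (logged), keeping the statistic defined.
* **Ties everywhere else** (equal effects in rankings, equal distances,
  equal p) resolve by gene id or marker position in C-locale order, so
  every output is reproducible byte-for-byte across platforms.

q-values use Storey's smoother estimate of π₀ (λ grid 0.05–0.95, df-3
smoothing spline evaluated at λ = 0.95) when at least 100 pathways are
scored; below that, or if the estimate is non-finite or ≤ 0, the
Benjamini–Hochberg step-up (π₀ = 1) is used. Both are monotone in p-rank.

## What the synthetic generator does and does not emulate

`simulate_gwas_dataset()` writes the same five files the pipeline reads
from a real TASSEL + GFF3 + pathway-database workflow. It emulates the
features the method's logic depends on: biallelic markers with one free
allele effect; clean LD blocks (within-block r² ~ U(0.81, 0.99), bridges
between neighbouring blocks ~ U(0, 0.79), bounds kept clear of the 0.8
cutoff so the true partition is recoverable); genes spaced so each SNP
block maps to exactly one gene; p-values monotone in |effect| with small
noise; and an optional planted pathway whose SNP effects are shifted by
`mu_shift` (default 2σ). The default dimensions — 2 chromosomes, 250
genes, 600 SNPs, 20 disjoint pathways of 10 genes — keep a full analysis
under a few seconds while leaving a 230-gene background.

It does **not** emulate: LD decaying continuously with distance (blocks
are exact), allele-frequency-dependent effect sizes, population structure
or confounding (p-values are a clean function of effect), overlapping
pathways, or genes with no SNP. Passing tests on this generator therefore
show that the *rules and statistics* are implemented correctly and that a
strong planted signal is recovered under exchangeable-null conditions —
not that the method is robust to confounded or structure-ridden real GWAS
data, which must be handled upstream by the association model.

## Validation design

The test suite checks, among others: every tie-break branch with
hand-derived winners; the running sum against an explicit-loop oracle on
1000 random instances; the linkage partition against a union-find oracle
on 200 random graphs (≤ 50 SNPs); recovery of the generator's true block
partition; planted-pathway recovery (smallest p in ≥ 95 of 100 generator
seeds at `n_perm = 200`); the pooled fraction of null pathway p-values
below 0.05 staying within binomial 99% bounds over 50 seeds; byte-identity
of outputs across repeated runs and worker counts; and the worked
four-gene example, whose top-pathway ES is exactly 1.0 by hand:

```{r toy}
toy <- toy_dataset()
ranked <- rank_genes(toy$assignments, "increase")
running_sum(ranked, c("g1", "g2"))[c("S", "es", "peak_rank")]
```

## Limitations

* The normal approximation to the null ES is an approximation: the
  bootstrap ES distribution is right-skewed, so nominal tail p-values run
  slightly liberal (the type-I check bounds, but does not eliminate, this).
* Effects are transferred, not modelled: a gene's value is a single
  tagSNP's effect, so allelic heterogeneity within a gene collapses to one
  number.
* Pathways sharing genes are scored independently; no joint or
  conditional analysis is attempted.
* LD must be supplied precomputed; the package does not compute r² from
  genotypes, nor reconcile annotation versions.
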