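# Synthetic GWAS input generator. Emulates the file set a TASSEL GLM/MLM
# run plus a pairwise LD scan would produce for a diploid panel: association
# statistics, biallelic allele effects, intra-chromosome LD with clean block
# structure, a GFF3 gene annotation, and a pathway membership table, with an
# optional pathway of genes carrying a shifted effect distribution
# (planted signal) and a ground-truth manifest.

#' Simulate a complete GWAS pathway-analysis input set
#'
#' Genes are laid out evenly along the chromosomes; every gene receives one
#' linkage block of one or more SNPs placed inside its span, and additional
#' unlinked SNPs are placed mid-way between genes (farther than any
#' realistic window, so they stay unassigned). SNP effects are drawn from
#' `Normal(0, sigma)`, except SNPs of genes in the planted pathway, which
#' are drawn from `Normal(mu_shift, sigma)`. Association p-values are a
#' monotone function of `|effect|` with small lognormal jitter; pairwise LD
#' is `Uniform(0.81, 0.99)` within a block and `Uniform(0, 0.79)` between
#' neighbouring blocks, so with the default linkage cutoff of 0.8 the true
#' block partition is recovered exactly.
#'
#' @param n_chromosomes Number of chromosomes; default 2.
#' @param n_genes Number of genes; default 250.
#' @param n_snps Total number of SNPs (>= `n_genes`); default 600.
#' @param n_pathways Number of (disjoint) pathways; default 20.
#' @param genes_per_pathway Genes per pathway; default 10.
#' @param planted_pathway Logical: should the first pathway carry shifted
#'   effects? Default TRUE.
#' @param sigma Effect standard deviation; default 1.
#' @param mu_shift Mean effect of planted-pathway SNPs; default `2 * sigma`.
#' @param max_block_size Largest LD block (SNPs per gene); default 4.
#' @param frac_multiallelic Fraction of markers given a third allele row (to
#'   exercise the biallelic filter); default 0.
#' @param frac_missing_r2 Fraction of markers with a missing marker
#'   R-squared; default 0.
#' @param trait Trait name written to the tables; default `"trait1"`.
#' @param seed RNG seed; the whole dataset is a deterministic function of it.
#' @return An object of class `gwas_dataset`: list with data frames
#'   `stats`, `effects`, `ld`, `genes`, `pathways` (in the same column
#'   layout the readers emit/consume) and `manifest` (ground truth: planted
#'   pathway id, SNP-to-gene and SNP-to-block maps, true effects).
#' @seealso [write_gwas_dataset()], [toy_dataset()]
#' @export
simulate_gwas_dataset <- function(n_chromosomes = 2, n_genes = 250,
                                  n_snps = 600, n_pathways = 20,
                                  genes_per_pathway = 10,
                                  planted_pathway = TRUE, sigma = 1,
                                  mu_shift = 2 * sigma, max_block_size = 4,
                                  frac_multiallelic = 0, frac_missing_r2 = 0,
                                  trait = "trait1", seed = 1) {
  if (n_snps < n_genes) stop("n_snps must be at least n_genes")
  if (n_pathways * genes_per_pathway > n_genes) {
    stop("n_pathways * genes_per_pathway exceeds n_genes")
  }
  set.seed(seed)

  gene_len <- 2000L
  gene_gap <- 10000L
  genes_per_chr <- ceiling(n_genes / n_chromosomes)
  gene_chr <- rep(paste0("chr", seq_len(n_chromosomes)),
                  each = genes_per_chr)[seq_len(n_genes)]
  gene_idx_on_chr <- stats::ave(seq_len(n_genes), gene_chr, FUN = seq_along)
  gene_start <- 5000L + (gene_idx_on_chr - 1L) * gene_gap
  gene_end <- gene_start + gene_len - 1L
  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  genes <- data.frame(gene_id = gene_id, chromosome = gene_chr,
                      start = gene_start, end = gene_end,
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)

  # pathways: disjoint sets over a random shuffle of the gene pool
  shuffled <- sample(gene_id)
  pw_id <- sprintf("PWY%04d", seq_len(n_pathways))
  pathways <- data.frame(
    pathway_id = rep(pw_id, each = genes_per_pathway),
    pathway_name = rep(sprintf("pathway %d", seq_len(n_pathways)),
                       each = genes_per_pathway),
    gene_id = shuffled[seq_len(n_pathways * genes_per_pathway)],
    stringsAsFactors = FALSE)
  planted_id <- if (planted_pathway) pw_id[1] else NA_character_
  planted_genes <- if (planted_pathway) {
    pathways$gene_id[pathways$pathway_id == planted_id]
  } else character(0)

  # SNP allocation: one per gene, extras grow random genes' blocks (up to
  # max_block_size), remainder become intergenic unlinked SNPs
  block_size <- rep(1L, n_genes)
  extra <- n_snps - n_genes
  n_intergenic <- min(extra, max(0L, round(0.3 * extra)))
  grow <- extra - n_intergenic
  while (grow > 0L) {
    candidates <- which(block_size < max_block_size)
    if (length(candidates) == 0) { n_intergenic <- n_intergenic + grow; break }
    g <- candidates[sample.int(length(candidates), 1L)]
    block_size[g] <- block_size[g] + 1L
    grow <- grow - 1L
  }

  snp_rows <- vector("list", n_genes + 1L)
  for (g in seq_len(n_genes)) {
    k <- block_size[g]
    offs <- sort(sample.int(gene_len, k)) - 1L
    mu <- if (gene_id[g] %in% planted_genes) mu_shift else 0
    snp_rows[[g]] <- data.frame(
      chromosome = genes$chromosome[g], position = genes$start[g] + offs,
      effect = stats::rnorm(k, mu, sigma), gene = gene_id[g], block = g,
      stringsAsFactors = FALSE)
  }
  if (n_intergenic > 0L) {
    host <- sample.int(n_genes, n_intergenic, replace = TRUE)
    snp_rows[[n_genes + 1L]] <- data.frame(
      chromosome = genes$chromosome[host],
      position = genes$end[host] + gene_gap %/% 2L +
        sample.int(1000L, n_intergenic, replace = TRUE),
      effect = stats::rnorm(n_intergenic, 0, sigma),
      gene = NA_character_, block = NA_integer_, stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, snp_rows[!vapply(snp_rows, is.null, logical(1))])
  snps <- snps[radix_order(snps$chromosome, snps$position), , drop = FALSE]
  # de-duplicate any coinciding positions (possible for intergenic SNPs)
  dup <- duplicated(paste(snps$chromosome, snps$position))
  snps <- snps[!dup, , drop = FALSE]
  snps$marker <- sprintf("S%s_%d", sub("^chr", "", snps$chromosome), snps$position)
  snps$site <- stats::ave(seq_len(nrow(snps)), snps$chromosome, FUN = seq_along)

  # p-values: monotone in |effect| with small lognormal jitter, clamped
  p_raw <- 2 * stats::pnorm(-abs(snps$effect) / sigma)
  p <- pmin(pmax(p_raw * exp(stats::rnorm(nrow(snps), 0, 0.05)), 1e-300), 1)
  snps$p_value <- p
  snps$marker_r2 <- round(stats::runif(nrow(snps), 0.01, 0.4), 4)
  if (frac_missing_r2 > 0) {
    miss <- stats::runif(nrow(snps)) < frac_missing_r2
    snps$marker_r2[miss] <- NA_real_
  }

  # biallelic effects: one free allele with the SNP effect, reference at 0
  pairs <- t(vapply(seq_len(nrow(snps)),
                    function(i) sample(c("A", "C", "G", "T"), 2),
                    character(2)))
  effects <- data.frame(
    marker = rep(snps$marker, each = 2L),
    trait = trait,
    allele = as.vector(t(pairs)),
    effect = as.vector(rbind(snps$effect, 0)),
    stringsAsFactors = FALSE)
  if (frac_multiallelic > 0) {
    tri <- snps$marker[stats::runif(nrow(snps)) < frac_multiallelic]
    if (length(tri) > 0) {
      effects <- rbind(effects, data.frame(
        marker = tri, trait = trait, allele = "N",
        effect = stats::rnorm(length(tri), 0, sigma / 10),
        stringsAsFactors = FALSE))
      effects <- effects[radix_order(match(effects$marker, snps$marker)), ,
                         drop = FALSE]
    }
  }

  stats_df <- data.frame(marker = snps$marker, chromosome = snps$chromosome,
                         position = snps$position, trait = trait,
                         p_value = snps$p_value, marker_r2 = snps$marker_r2,
                         stringsAsFactors = FALSE)

  # LD: all within-block pairs high, neighbouring-block bridges low
  ld_rows <- list()
  li <- 0L
  for (chr in unique(snps$chromosome)) {
    s <- snps[snps$chromosome == chr, , drop = FALSE]
    blocks <- unique(s$block[!is.na(s$block)])
    for (b in blocks) {
      idx <- which(s$block %in% b)
      if (length(idx) >= 2L) {
        cmb <- utils::combn(idx, 2L)
        li <- li + 1L
        ld_rows[[li]] <- data.frame(
          locus = chr, position_a = s$position[cmb[1, ]],
          position_b = s$position[cmb[2, ]],
          site_a = s$site[cmb[1, ]], site_b = s$site[cmb[2, ]],
          ld_r2 = round(stats::runif(ncol(cmb), 0.81, 0.99), 4),
          stringsAsFactors = FALSE)
      }
    }
    if (length(blocks) >= 2L) {
      bl <- sort(blocks)
      a_idx <- vapply(bl[-length(bl)], function(b) max(which(s$block %in% b)), integer(1))
      b_idx <- vapply(bl[-1L], function(b) min(which(s$block %in% b)), integer(1))
      li <- li + 1L
      ld_rows[[li]] <- data.frame(
        locus = chr, position_a = s$position[a_idx],
        position_b = s$position[b_idx],
        site_a = s$site[a_idx], site_b = s$site[b_idx],
        ld_r2 = round(stats::runif(length(a_idx), 0, 0.79), 4),
        stringsAsFactors = FALSE)
    }
  }
  ld <- do.call(rbind, ld_rows)
  ld$dist_bp <- abs(ld$position_b - ld$position_a)
  ld <- ld[radix_order(ld$locus, ld$position_a, ld$position_b), , drop = FALSE]
  rownames(ld) <- NULL

  manifest <- list(
    seed = seed, trait = trait, planted_pathway = planted_id,
    mu_shift = mu_shift, sigma = sigma,
    snp_truth = data.frame(marker = snps$marker, gene = snps$gene,
                           block = snps$block, effect = snps$effect,
                           stringsAsFactors = FALSE),
    block_sizes = block_size)

  structure(list(stats = stats_df, effects = effects, ld = ld, genes = genes,
                 pathways = pathways, manifest = manifest),
            class = "gwas_dataset")
}

#' Write a simulated dataset to disk in the dialects the readers consume
#'
#' Produces `stats.tsv`, `effects.tsv`, `ld.tsv` (TASSEL-style headers),
#' `genes.gff3`, `pathways.tsv` and `manifest.json` under `dir`.
#'
#' @param dataset A `gwas_dataset` from [simulate_gwas_dataset()] or
#'   [toy_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the file paths.
#' @export
write_gwas_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(stats = file.path(dir, "stats.tsv"),
             effects = file.path(dir, "effects.tsv"),
             ld = file.path(dir, "ld.tsv"),
             gff = file.path(dir, "genes.gff3"),
             pathways = file.path(dir, "pathways.tsv"),
             manifest = file.path(dir, "manifest.json"))

  s <- dataset$stats
  stats_out <- data.frame(Trait = s$trait, Marker = s$marker,
                          Chr = s$chromosome, Pos = s$position,
                          p = s$p_value, marker_R2 = s$marker_r2,
                          check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NaN")
  }
  write_tsv(stats_out, paths[["stats"]])

  e <- dataset$effects
  write_tsv(data.frame(Trait = e$trait, Marker = e$marker, Allele = e$allele,
                       Effect = e$effect, stringsAsFactors = FALSE),
            paths[["effects"]])

  l <- dataset$ld
  write_tsv(data.frame(Locus1 = l$locus, Position1 = l$position_a,
                       Site1 = l$site_a, Locus2 = l$locus,
                       Position2 = l$position_b, Site2 = l$site_b,
                       Dist_bp = l$dist_bp, `R^2` = l$ld_r2,
                       check.names = FALSE, stringsAsFactors = FALSE),
            paths[["ld"]])

  g <- dataset$genes
  gff <- c("##gff-version 3",
           sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                   g$chromosome, g$start, g$end, g$strand, g$gene_id, g$gene_id))
  writeLines(gff, paths[["gff"]])

  p <- dataset$pathways
  write_tsv(data.frame(pathway_id = p$pathway_id, pathway_name = p$pathway_name,
                       gene_id = p$gene_id, stringsAsFactors = FALSE),
            paths[["pathways"]])

  manifest <- dataset$manifest
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}

#' The four-gene worked example
#'
#' A tiny in-memory dataset used throughout the documentation and tests:
#' four genes with effects 3, 2, 1, 0.5 (one unlinked SNP inside each gene),
#' pathway `PWY1` holding the two best-ranked genes and `PWY2` the two
#' worst. Under `direction = "increase"` the running sum of `PWY1` steps by
#' (+0.6, +0.4, -0.5, -0.5), so its enrichment score is exactly 1.0 with the
#' peak at rank 2 and hatch marks at ranks 1 and 2.
#'
#' @return A `gwas_dataset` with the extra elements `assignments` (the gene
#'   assignments the pipeline derives from it) and `expected` (the
#'   hand-computed running sum, ES, peak rank and hit ranks for `PWY1`).
#' @export
toy_dataset <- function() {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    chromosome = "chr1",
    start = c(1000L, 11000L, 21000L, 31000L),
    end = c(2999L, 12999L, 22999L, 32999L),
    strand = "+", stringsAsFactors = FALSE)
  eff <- c(3, 2, 1, 0.5)
  stats <- data.frame(
    marker = paste0("M", 1:4), chromosome = "chr1",
    position = genes$start + 500L, trait = "toy",
    p_value = c(0.001, 0.01, 0.05, 0.20), marker_r2 = c(0.30, 0.20, 0.10, 0.05),
    stringsAsFactors = FALSE)
  effects <- data.frame(
    marker = rep(stats$marker, each = 2L), trait = "toy",
    allele = rep(c("A", "T"), 4L),
    effect = as.vector(rbind(eff, 0)), stringsAsFactors = FALSE)
  # LD present but below any sensible cutoff: all four SNPs stay unlinked
  ld <- data.frame(
    locus = "chr1",
    position_a = stats$position[1:3], position_b = stats$position[2:4],
    site_a = 1:3, site_b = 2:4, ld_r2 = c(0.10, 0.05, 0.12),
    stringsAsFactors = FALSE)
  ld$dist_bp <- abs(ld$position_b - ld$position_a)
  pathways <- data.frame(
    pathway_id = rep(c("PWY1", "PWY2"), each = 2L),
    pathway_name = rep(c("top pathway", "bottom pathway"), each = 2L),
    gene_id = c("g1", "g2", "g3", "g4"), stringsAsFactors = FALSE)
  assignments <- data.frame(
    gene_id = genes$gene_id, chromosome = "chr1", effect = eff,
    p_value = stats$p_value, n_linked_snps = 1L, tag_marker = stats$marker,
    n_tags = 1L, stringsAsFactors = FALSE)
  expected <- list(
    steps = c(0.6, 0.4, -0.5, -0.5),
    S = c(0.6, 1.0, 0.5, 0.0),
    es = 1.0, peak_rank = 2L, hit_ranks = 1:2, pathway_id = "PWY1")
  structure(list(stats = stats, effects = effects, ld = ld, genes = genes,
                 pathways = pathways, assignments = assignments,
                 expected = expected,
                 manifest = list(planted_pathway = "PWY1", trait = "toy")),
            class = "gwas_dataset")
}
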