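# Transfer of tagSNP effects and p-values to genes within a physical
# distance window, with majority/tie rules when several tagSNPs hit the
# same gene.

#' Find genes within a physical window of one tagSNP
#'
#' Distance from a SNP to a gene is 0 when the SNP position lies inside the
#' gene's (1-based, inclusive) span, otherwise the distance to the nearest
#' gene boundary. Strand is ignored; the window is symmetric.
#'
#' @param position SNP position (bp).
#' @param chromosome SNP chromosome.
#' @param genes Gene table from [read_gene_annotations()].
#' @param window Maximum SNP-to-gene distance in bp (>= 0); default 1000.
#' @return Character vector of gene ids with distance `<= window`.
#' @export
genes_near_snp <- function(position, chromosome, genes, window = 1000) {
  stopifnot(window >= 0)
  g <- genes[genes$chromosome == chromosome, , drop = FALSE]
  d <- pmax(g$start - position, position - g$end, 0L)
  g$gene_id[d <= window]
}

#' Resolve the effect transferred to a gene hit by several tagSNPs
#'
#' With one candidate its effect and p-value transfer verbatim. Otherwise
#' positive and negative effects are counted (zeros count as neither): a
#' negative majority transfers the most negative effect with its p-value, a
#' positive majority the largest positive effect; equal effect values within
#' the winning sign are broken by the lowest p-value. When the sign counts
#' tie, the effect with the greatest absolute value is transferred; an exact
#' absolute-value tie is broken by lowest p-value, then the positive effect,
#' then the smallest marker position. `n_linked_snps` is the total number of
#' SNPs represented by all contributing tagSNPs.
#'
#' @param candidates Data frame with one row per contributing tagSNP and
#'   columns `effect`, `p_value`, `n_linked`, `position` (and optionally
#'   `marker`).
#' @return A list with `effect`, `p_value`, `n_linked_snps`, and `which`
#'   (row index of the winning candidate).
#' @export
resolve_gene_effect <- function(candidates) {
  stopifnot(nrow(candidates) >= 1L)
  e <- candidates$effect
  p <- candidates$p_value
  pos <- candidates$position
  if (nrow(candidates) == 1L) {
    i <- 1L
  } else {
    n_pos <- sum(e > 0)
    n_neg <- sum(e < 0)
    if (n_neg > n_pos) {
      i <- radix_order(e, p, pos)[1]            # most negative, then lowest p
    } else if (n_pos > n_neg) {
      i <- radix_order(-e, p, pos)[1]           # largest positive, then lowest p
    } else {
      i <- radix_order(-abs(e), p, -sign(e), pos)[1]  # greatest |effect|
    }
  }
  list(effect = e[i], p_value = p[i],
       n_linked_snps = sum(candidates$n_linked), which = i)
}

#' Assign tagSNP effects to genes
#'
#' Every tagSNP is matched against all genes on its chromosome within
#' `window` bp (a tagSNP near several genes contributes to each of them);
#' genes hit by more than one tagSNP are resolved with
#' [resolve_gene_effect()]. Genes with no nearby tagSNP are absent from the
#' output.
#'
#' @param tags TagSNP table from [tag_snps()].
#' @param genes Gene table from [read_gene_annotations()].
#' @param window Maximum SNP-to-gene distance in bp; default 1000.
#' @return A data frame sorted by `gene_id` with columns `gene_id`,
#'   `chromosome`, `effect`, `p_value`, `n_linked_snps`, `tag_marker` (the
#'   tagSNP whose effect/p were transferred) and `n_tags` (number of
#'   contributing tagSNPs). The per-gene contributing-tag tables are
#'   attached as attribute `contributing_tags`, a named list.
#' @export
assign_genes <- function(tags, genes, window = 1000) {
  stopifnot(window >= 0)
  empty <- data.frame(gene_id = character(), chromosome = character(),
                      effect = numeric(), p_value = numeric(),
                      n_linked_snps = integer(), tag_marker = character(),
                      n_tags = integer(), stringsAsFactors = FALSE)
  if (nrow(tags) == 0 || nrow(genes) == 0) {
    attr(empty, "contributing_tags") <- list()
    return(empty)
  }
  hits <- vector("list", length(unique(genes$chromosome)))
  k <- 0L
  for (chr in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == chr, , drop = FALSE]
    t <- tags[tags$chromosome == chr, , drop = FALSE]
    if (nrow(t) == 0) next
    # A SNP is within `window` of gene [s, e] iff its position falls in
    # [s - window, e + window]; a point-in-extended-interval overlap query
    # is exact for the 1-based inclusive distance definition.
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = t$position, width = 1L),
      IRanges::IRanges(start = g$start - as.integer(window),
                       end = g$end + as.integer(window)))
    if (length(ov) == 0) next
    k <- k + 1L
    hits[[k]] <- data.frame(
      gene_id = g$gene_id[S4Vectors::subjectHits(ov)],
      chromosome = chr,
      marker = t$marker[S4Vectors::queryHits(ov)],
      position = t$position[S4Vectors::queryHits(ov)],
      effect = t$effect[S4Vectors::queryHits(ov)],
      p_value = t$p_value[S4Vectors::queryHits(ov)],
      n_linked = t$n_linked[S4Vectors::queryHits(ov)],
      stringsAsFactors = FALSE)
  }
  if (k == 0L) {
    attr(empty, "contributing_tags") <- list()
    return(empty)
  }
  hits <- do.call(rbind, hits[seq_len(k)])
  per_gene <- split(hits, hits$gene_id)
  rows <- lapply(per_gene, function(cand) {
    res <- resolve_gene_effect(cand)
    data.frame(gene_id = cand$gene_id[1], chromosome = cand$chromosome[1],
               effect = res$effect, p_value = res$p_value,
               n_linked_snps = res$n_linked_snps,
               tag_marker = cand$marker[res$which], n_tags = nrow(cand),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[radix_order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contributing_tags") <- per_gene[out$gene_id]
  out
}
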