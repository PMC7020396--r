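# Independent brute-force oracles and small fixture builders. The oracles
# deliberately avoid the code paths (and libraries) the implementation
# uses: components via union-find instead of igraph, running sums via an
# explicit loop, gene lookup via an all-pairs distance scan.

# --- union-find connected components over marker ids ------------------------
oracle_components <- function(ids, edges_from, edges_to) {
  parent <- seq_along(ids)
  names(parent) <- ids
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(edges_from)) {
    a <- find(match(edges_from[k], ids))
    b <- find(match(edges_to[k], ids))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  split(ids, roots)
}

# --- explicit-loop running sum ----------------------------------------------
oracle_running_sum <- function(effects_ranked, hit) {
  n <- length(effects_ranked)
  denom_hit <- sum(abs(effects_ranked[hit]))
  n_hit <- sum(hit)
  s <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      acc <- acc + if (denom_hit == 0) 1 / n_hit else abs(effects_ranked[i]) / denom_hit
    } else {
      acc <- acc - 1 / (n - n_hit)
    }
    s[i] <- acc
  }
  s
}

# --- all-pairs SNP-to-gene distance scan ------------------------------------
oracle_genes_near <- function(position, chromosome, genes, window) {
  out <- character(0)
  for (i in seq_len(nrow(genes))) {
    if (genes$chromosome[i] != chromosome) next
    d <- if (position >= genes$start[i] && position <= genes$end[i]) 0
         else min(abs(position - genes$start[i]), abs(position - genes$end[i]))
    if (d <= window) out <- c(out, genes$gene_id[i])
  }
  out
}

# --- fixture builders --------------------------------------------------------
write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal marker table for rule tests
marker_row <- function(marker, position, effect, p = 0.5, chromosome = "chr1",
                       r2 = 0.1) {
  data.frame(marker = marker, chromosome = chromosome, position = position,
             trait = "t", p_value = p, marker_r2 = r2, effect = effect,
             alleles = "A/T", stringsAsFactors = FALSE)
}

marker_table <- function(...) {
  do.call(rbind, list(...))
}

# LD rows joining markers of a marker table by position
ld_row <- function(markers, a, b, r2, chromosome = "chr1") {
  pa <- markers$position[markers$marker == a]
  pb <- markers$position[markers$marker == b]
  data.frame(locus = chromosome, position_a = pa, position_b = pb,
             site_a = 1L, site_b = 2L, ld_r2 = r2, dist_bp = abs(pb - pa),
             stringsAsFactors = FALSE)
}

ld_table <- function(...) do.call(rbind, list(...))

# partition comparison that ignores grouping order
canonical_partition <- function(groups) {
  out <- sort(vapply(groups, function(v) paste(sort(v), collapse = ","),
                     character(1)))
  names(out) <- NULL
  out
}

# full in-memory analysis chain used by the statistical acceptance checks
run_chain <- function(ds, r2_cutoff = 0.8, window = 1000, min_genes = 5,
                      n_perm = 200, seed = 1, direction = "increase") {
  m <- merge_markers(ds$stats, ds$effects)
  g <- linkage_groups(m, ds$ld, r2_cutoff)
  tg <- tag_snps(g, m)
  asg <- assign_genes(tg, ds$genes, window)
  pathway_enrichment(asg, ds$pathways, direction = direction, n_perm = n_perm,
                     min_genes = min_genes, seed = seed)
}
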