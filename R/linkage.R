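# Linkage groups and tagSNP election.
#
# SNPs on the same chromosome are joined by an edge whenever their pairwise
# LD r2 strictly exceeds the cutoff. Connected components of size 1 are
# unlinked SNPs, size 2 are singly-linked pairs, size >= 3 are linkage
# blocks. Each non-problematic group elects one tagSNP whose effect, p-value
# and marker R2 represent the whole group downstream.

#' Build the thresholded LD adjacency
#'
#' An undirected edge joins two SNP positions on a locus iff their LD
#' r-squared strictly exceeds `r2_cutoff` (r2 equal to the cutoff does not
#' link). Edge endpoints are matched to markers by (chromosome, position);
#' LD rows whose endpoints have no corresponding marker record are ignored.
#'
#' @param ld Data frame from [read_ld_table()].
#' @param markers Marker table from [merge_markers()].
#' @param r2_cutoff LD r-squared linkage cutoff in `[0, 1]`; default 0.8.
#' @return A data frame of edges with columns `from`, `to` (marker ids) and
#'   `ld_r2`.
#' @export
ld_edges <- function(ld, markers, r2_cutoff = 0.8) {
  stopifnot(r2_cutoff >= 0, r2_cutoff <= 1)
  ld <- ld[ld$ld_r2 > r2_cutoff, , drop = FALSE]
  key <- paste(markers$chromosome, markers$position, sep = "\r")
  from <- match(paste(ld$locus, ld$position_a, sep = "\r"), key)
  to <- match(paste(ld$locus, ld$position_b, sep = "\r"), key)
  ok <- !is.na(from) & !is.na(to) & from != to
  data.frame(from = markers$marker[from[ok]], to = markers$marker[to[ok]],
             ld_r2 = ld$ld_r2[ok], stringsAsFactors = FALSE)
}

#' Partition markers into linkage groups
#'
#' Connected components of the thresholded LD graph over all markers:
#' singletons are `unlinked`, two-SNP components are `pair`s, larger
#' components are `block`s. Each block's common SNP — the SNP the others are
#' linked to — is the member of highest degree, ties broken by smallest
#' position. Members are listed in position order.
#'
#' @inheritParams ld_edges
#' @return An object of class `linkage_groups`: a list with `groups` (a list
#'   of per-group lists with fields `kind`, `members`, `common_snp`,
#'   `degree`) and `r2_cutoff`. Every marker appears in exactly one group.
#' @export
linkage_groups <- function(markers, ld, r2_cutoff = 0.8) {
  edges <- ld_edges(ld, markers, r2_cutoff)
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = markers$marker, stringsAsFactors = FALSE))
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  membership <- comp$membership[markers$marker]

  pos <- markers$position
  names(pos) <- markers$marker
  groups <- lapply(split(markers$marker, membership), function(ids) {
    ids <- ids[radix_order(pos[ids])]
    kind <- if (length(ids) == 1L) "unlinked" else if (length(ids) == 2L) "pair" else "block"
    common <- NA_character_
    if (kind == "block") {
      d <- deg[ids]
      cand <- ids[d == max(d)]
      common <- cand[radix_order(pos[cand])][1]
    }
    list(kind = kind, members = ids, common_snp = common, degree = unname(deg[ids]))
  })
  names(groups) <- NULL
  structure(list(groups = groups, r2_cutoff = r2_cutoff),
            class = "linkage_groups")
}

#' @export
print.linkage_groups <- function(x, ...) {
  kinds <- vapply(x$groups, `[[`, character(1), "kind")
  cat("Linkage groups (r2 cutoff ", x$r2_cutoff, "):\n", sep = "")
  cat("  unlinked SNPs: ", sum(kinds == "unlinked"),
      "\n  singly-linked pairs: ", sum(kinds == "pair"),
      "\n  blocks (>= 3 SNPs): ", sum(kinds == "block"), "\n", sep = "")
  invisible(x)
}

#' Elect the tagSNP of a singly-linked pair
#'
#' For two linked SNPs ordered by position: if the effect signs are not
#' opposite, the SNP with the larger absolute effect wins, and on an exact
#' tie the second (more downstream) SNP is used. If the signs are opposite,
#' the SNP with the lower p-value wins; opposite signs with equal p-values
#' admit no choice — the pair is problematic and is dropped from the
#' analysis.
#'
#' @param pair A two-row marker data frame (columns `marker`, `position`,
#'   `effect`, `p_value`) sorted by position.
#' @return The tagSNP's marker id, or `NA_character_` for a problematic pair.
#' @export
tag_snp_pair <- function(pair) {
  stopifnot(nrow(pair) == 2L, pair$position[1] < pair$position[2])
  e <- pair$effect
  if (e[1] * e[2] >= 0) {           # same sign (zero counts with either sign)
    if (abs(e[1]) > abs(e[2])) return(pair$marker[1])
    return(pair$marker[2])          # larger |effect|, or downstream on a tie
  }
  if (pair$p_value[1] == pair$p_value[2]) return(NA_character_)  # problematic
  pair$marker[which.min(pair$p_value)]
}

#' Elect the tagSNP of a linkage block
#'
#' Counts positive and negative effects among the block members (zero
#' effects count as neither). A positive majority elects the SNP with the
#' largest positive effect; a negative majority elects the SNP with the most
#' negative effect. On a tie the sign of the block's common SNP decides
#' which side wins, and the member with the largest-magnitude effect of that
#' sign is elected. When the common SNP's effect is zero (or the chosen side
#' is empty) the member with the largest absolute effect wins. All residual
#' ties go to the smallest position.
#'
#' @param members Marker data frame of the block members (columns `marker`,
#'   `position`, `effect`, `p_value`).
#' @param common_snp Marker id of the block's common SNP.
#' @return The tagSNP's marker id.
#' @export
tag_snp_block <- function(members, common_snp) {
  stopifnot(nrow(members) >= 3L, common_snp %in% members$marker)
  e <- members$effect
  n_pos <- sum(e > 0)
  n_neg <- sum(e < 0)
  pick <- function(idx, score) {
    idx[radix_order(-score, members$position[idx])][1]
  }
  if (n_pos > n_neg) {
    i <- pick(which(e > 0), e[e > 0])
  } else if (n_neg > n_pos) {
    i <- pick(which(e < 0), -e[e < 0])
  } else {
    common_effect <- e[match(common_snp, members$marker)]
    if (common_effect > 0 && n_pos > 0) {
      i <- pick(which(e > 0), e[e > 0])
    } else if (common_effect < 0 && n_neg > 0) {
      i <- pick(which(e < 0), -e[e < 0])
    } else {
      i <- pick(seq_along(e), abs(e))
    }
  }
  members$marker[i]
}

#' Collapse linkage groups to tagSNP records
#'
#' Applies the election rules to every group: unlinked SNPs are their own
#' tagSNP, pairs go through [tag_snp_pair()] (problematic pairs are dropped
#' and counted), blocks through [tag_snp_block()]. The tagSNP keeps its own
#' effect, p-value and marker R2; `n_linked` records how many SNPs the group
#' represents, so that the sum of `n_linked` over emitted tags plus the SNPs
#' in dropped problematic pairs equals the number of input markers.
#'
#' @param groups A `linkage_groups` object.
#' @param markers Marker table from [merge_markers()].
#' @return A data frame of tagSNP records (marker columns plus `n_linked`,
#'   `kind`, `group_id`), sorted by (chromosome, position). The number of
#'   problematic pairs is attached as attribute `n_problematic_pairs`.
#' @export
tag_snps <- function(groups, markers) {
  rownames(markers) <- markers$marker
  n_problematic <- 0L
  rows <- vector("list", length(groups$groups))
  for (gi in seq_along(groups$groups)) {
    grp <- groups$groups[[gi]]
    mem <- markers[grp$members, , drop = FALSE]
    tag <- switch(grp$kind,
      unlinked = grp$members,
      pair = tag_snp_pair(mem),
      block = tag_snp_block(mem, grp$common_snp))
    if (is.na(tag)) {
      n_problematic <- n_problematic + 1L
      next
    }
    rec <- markers[tag, , drop = FALSE]
    rec$n_linked <- length(grp$members)
    rec$kind <- grp$kind
    rec$group_id <- gi
    rows[[gi]] <- rec
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- cbind(markers[0, , drop = FALSE],
                 data.frame(n_linked = integer(), kind = character(),
                            group_id = integer()))
  }
  out <- out[radix_order(out$chromosome, out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_problematic_pairs") <- n_problematic
  out
}
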