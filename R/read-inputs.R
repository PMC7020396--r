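# Readers for the four input file families: TASSEL-style association
# statistics and allele effects, TASSEL-style pairwise LD, GFF3 gene
# annotations, and 3-column pathway definitions. All readers accept plain
# or gzip-compressed text.

#' Default column-name mappings for the TASSEL table dialects
#'
#' TASSEL output headers vary across versions, so every reader takes a
#' named character vector mapping internal field names to the column names
#' found in the file. This function returns the defaults for current TASSEL
#' GLM/MLM output.
#'
#' @return A list with elements `stats`, `effects` and `ld`, each a named
#'   character vector `internal_name = file_column_name`.
#' @export
#' @examples
#' tassel_columns()$stats
tassel_columns <- function() {
  list(
    stats = c(trait = "Trait", marker = "Marker", chr = "Chr", pos = "Pos",
              p = "p", marker_r2 = "marker_R2"),
    effects = c(trait = "Trait", marker = "Marker", allele = "Allele",
                effect = "Effect"),
    ld = c(locus1 = "Locus1", position1 = "Position1", site1 = "Site1",
           locus2 = "Locus2", position2 = "Position2", site2 = "Site2",
           dist = "Dist_bp", r2 = "R^2")
  )
}

#' Read a TASSEL-style association statistics table
#'
#' Parses the per-marker GLM/MLM association results: marker identifier,
#' chromosome, position, association p-value and marker R-squared (the
#' coefficient of determination of the SNP/trait association). Rows whose
#' p-value or position cannot be parsed, or whose p-value lies outside
#' (0, 1], are rejected with a warning. A missing marker R-squared
#' ("NA"/"NaN"/blank) is kept as `NA` here; such markers are removed later by
#' [merge_markers()], which is where the biallelic and R-squared filters live.
#'
#' @param path Path to a tab-delimited file (optionally gzipped).
#' @param trait Optional trait name; when given, only rows for that trait are
#'   returned (the file may contain several traits).
#' @param columns Named character vector mapping internal names
#'   (`trait`, `marker`, `chr`, `pos`, `p`, `marker_r2`) to file column names;
#'   see [tassel_columns()].
#' @return A data frame with columns `marker`, `chromosome`, `position`,
#'   `trait`, `p_value`, `marker_r2`, one row per (marker, trait).
#' @seealso [read_gwas_effects()], [merge_markers()]
#' @export
read_gwas_stats <- function(path, trait = NULL, columns = tassel_columns()$stats) {
  df <- read_tsv_chr(path)
  needed <- columns[c("marker", "chr", "pos", "p", "marker_r2")]
  if (!is.null(trait)) needed <- c(needed, columns["trait"])
  require_columns(df, needed, path)

  has_trait <- columns[["trait"]] %in% names(df)
  trait_col <- if (has_trait) df[[columns[["trait"]]]] else rep(NA_character_, nrow(df))
  if (!is.null(trait)) {
    keep <- trait_col == trait
    df <- df[keep, , drop = FALSE]
    trait_col <- trait_col[keep]
  }

  pos <- parse_numeric_cells(df[[columns[["pos"]]]], columns[["pos"]])
  p <- parse_numeric_cells(df[[columns[["p"]]]], columns[["p"]])
  r2 <- parse_numeric_cells(df[[columns[["marker_r2"]]]], columns[["marker_r2"]])

  out <- data.frame(
    marker = df[[columns[["marker"]]]],
    chromosome = df[[columns[["chr"]]]],
    position = as.integer(round(pos$values)),
    trait = trait_col,
    p_value = p$values,
    marker_r2 = ifelse(is.nan(r2$values), NA_real_, r2$values),
    stringsAsFactors = FALSE
  )

  bad <- pos$bad | p$bad | r2$bad
  # p must be a probability in (0, 1]; position at least 1
  invalid <- (!is.na(out$p_value) & (out$p_value <= 0 | out$p_value > 1)) |
    (!is.na(out$position) & out$position < 1) |
    is.na(out$p_value) | is.na(out$position)
  invalid <- invalid & !bad
  if (any(invalid)) {
    warning(sprintf("%d row(s) with p-value outside (0,1] or invalid position rejected",
                    sum(invalid)), call. = FALSE)
  }
  out <- out[!(bad | invalid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a TASSEL-style allele effects table
#'
#' Parses the per-allele effect estimates (the magnitude of the effect of
#' each SNP allele on the trait). No filtering happens here: markers with
#' other than two allele rows are removed later by [merge_markers()].
#'
#' @inheritParams read_gwas_stats
#' @param columns Named character vector mapping `trait`, `marker`, `allele`,
#'   `effect` to file column names.
#' @return A data frame with columns `marker`, `trait`, `allele`, `effect`,
#'   one row per (marker, allele), in file order.
#' @export
read_gwas_effects <- function(path, trait = NULL, columns = tassel_columns()$effects) {
  df <- read_tsv_chr(path)
  needed <- columns[c("marker", "allele", "effect")]
  if (!is.null(trait)) needed <- c(needed, columns["trait"])
  require_columns(df, needed, path)

  has_trait <- columns[["trait"]] %in% names(df)
  trait_col <- if (has_trait) df[[columns[["trait"]]]] else rep(NA_character_, nrow(df))
  if (!is.null(trait)) {
    keep <- trait_col == trait
    df <- df[keep, , drop = FALSE]
    trait_col <- trait_col[keep]
  }

  eff <- parse_numeric_cells(df[[columns[["effect"]]]], columns[["effect"]])
  out <- data.frame(
    marker = df[[columns[["marker"]]]],
    trait = trait_col,
    allele = df[[columns[["allele"]]]],
    effect = eff$values,
    stringsAsFactors = FALSE
  )
  drop <- eff$bad | is.na(out$effect)
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge association statistics with allele effects into one marker table
#'
#' Joins the statistics and effects tables for a single trait and applies the
#' two loading-stage filters: markers must be biallelic (exactly two allele
#' rows in the effects table; more or fewer are discarded) and must carry a
#' non-missing marker R-squared (later stages rely on it). Each retained
#' marker is collapsed to one row with a single signed effect: the effect of
#' the first allele row (in file order) whose effect is nonzero — TASSEL
#' conventionally reports one free allele effect with the other allele as
#' reference — or the first row when both are nonzero or both zero.
#'
#' @param stats Data frame from [read_gwas_stats()].
#' @param effects Data frame from [read_gwas_effects()].
#' @return A data frame of marker records sorted by (chromosome, position):
#'   columns `marker`, `chromosome`, `position`, `trait`, `p_value`,
#'   `marker_r2`, `effect`, `alleles` (e.g. `"A/T"`). Filter counts are
#'   attached as attribute `counts` (`n_non_biallelic`, `n_missing_r2`,
#'   `n_effects_without_stats`).
#' @export
merge_markers <- function(stats, effects) {
  orphan <- !(effects$marker %in% stats$marker)
  if (any(orphan)) {
    warning(sprintf("%d effect row(s) for marker(s) absent from the statistics table dropped",
                    sum(orphan)), call. = FALSE)
    effects <- effects[!orphan, , drop = FALSE]
  }

  n_alleles <- table(effects$marker)
  biallelic <- names(n_alleles)[n_alleles == 2L]
  n_non_biallelic <- sum(!(stats$marker %in% biallelic))

  keep_stats <- stats$marker %in% biallelic
  has_r2 <- !is.na(stats$marker_r2)
  n_missing_r2 <- sum(keep_stats & !has_r2)
  stats <- stats[keep_stats & has_r2, , drop = FALSE]

  if (nrow(stats) == 0) {
    out <- data.frame(marker = character(), chromosome = character(),
                      position = integer(), trait = character(),
                      p_value = numeric(), marker_r2 = numeric(),
                      effect = numeric(), alleles = character(),
                      stringsAsFactors = FALSE)
  } else {
    eff <- effects[effects$marker %in% stats$marker, , drop = FALSE]
    # first-nonzero-row convention, preserving file order within marker
    split_idx <- split(seq_len(nrow(eff)), eff$marker)
    marker_effect <- vapply(split_idx, function(i) {
      e <- eff$effect[i]
      nz <- which(e != 0)
      if (length(nz) == 0) e[1] else e[nz[1]]
    }, numeric(1))
    marker_alleles <- vapply(split_idx, function(i) {
      paste(eff$allele[i], collapse = "/")
    }, character(1))
    m <- match(stats$marker, names(split_idx))
    out <- data.frame(
      marker = stats$marker,
      chromosome = stats$chromosome,
      position = stats$position,
      trait = stats$trait,
      p_value = stats$p_value,
      marker_r2 = stats$marker_r2,
      effect = unname(marker_effect[m]),
      alleles = unname(marker_alleles[m]),
      stringsAsFactors = FALSE
    )
    out <- out[radix_order(out$chromosome, out$position), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "counts") <- list(
    n_non_biallelic = n_non_biallelic,
    n_missing_r2 = n_missing_r2,
    n_effects_without_stats = sum(orphan)
  )
  out
}

#' Read a TASSEL-style pairwise linkage-disequilibrium table
#'
#' Keeps only intra-locus rows (both locus columns equal; LD between
#' different chromosomes is never used) and only the needed columns: locus,
#' the two positions, the two site indices, the distance and the LD
#' R-squared. Rows with a missing R-squared are dropped and counted. The
#' distance is recomputed as `|position_b - position_a|` so the stored value
#' always satisfies that identity.
#'
#' @inheritParams read_gwas_stats
#' @param columns Named character vector mapping `locus1`, `position1`,
#'   `site1`, `locus2`, `position2`, `site2`, `dist`, `r2` to file columns.
#' @return A data frame with columns `locus`, `position_a`, `position_b`,
#'   `site_a`, `site_b`, `dist_bp`, `ld_r2`, sorted by locus. The number of
#'   rows dropped for missing R-squared is attached as attribute
#'   `n_dropped_na_r2`.
#' @export
read_ld_table <- function(path, columns = tassel_columns()$ld) {
  df <- read_tsv_chr(path)
  require_columns(df, columns, path)

  same_locus <- df[[columns[["locus1"]]]] == df[[columns[["locus2"]]]]
  df <- df[same_locus, , drop = FALSE]

  p1 <- parse_numeric_cells(df[[columns[["position1"]]]], columns[["position1"]])
  p2 <- parse_numeric_cells(df[[columns[["position2"]]]], columns[["position2"]])
  s1 <- parse_numeric_cells(df[[columns[["site1"]]]], columns[["site1"]])
  s2 <- parse_numeric_cells(df[[columns[["site2"]]]], columns[["site2"]])
  r2 <- parse_numeric_cells(df[[columns[["r2"]]]], columns[["r2"]])

  na_r2 <- is.na(r2$values) | is.nan(r2$values)
  n_dropped <- sum(na_r2)
  if (n_dropped > 0) {
    message(sprintf("read_ld_table: %d row(s) with missing LD R2 dropped", n_dropped))
  }
  keep <- !na_r2 & !p1$bad & !p2$bad & !s1$bad & !s2$bad &
    !is.na(p1$values) & !is.na(p2$values)

  out <- data.frame(
    locus = df[[columns[["locus1"]]]][keep],
    position_a = as.integer(round(p1$values[keep])),
    position_b = as.integer(round(p2$values[keep])),
    site_a = as.integer(round(s1$values[keep])),
    site_b = as.integer(round(s2$values[keep])),
    ld_r2 = r2$values[keep],
    stringsAsFactors = FALSE
  )
  out$dist_bp <- abs(out$position_b - out$position_a)
  out <- out[radix_order(out$locus, out$position_a, out$position_b), , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no intra-locus LD rows with a valid R2 value found", call. = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_dropped_na_r2") <- n_dropped
  out
}

#' Read gene features from a GFF3 annotation
#'
#' Extracts rows of feature type `gene`; all other feature types (mRNA,
#' exon, CDS, ...) are ignored. Coordinates are kept 1-based inclusive as in
#' GFF3. Every gene row must carry an `ID` attribute; a malformed line (not
#' nine tab-separated fields) or a gene without an ID is a fatal error
#' reported with its line number.
#'
#' @param path Path to a GFF3 file (optionally gzipped).
#' @return A data frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand`.
#' @export
read_gene_annotations <- function(path) {
  con <- file(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)

  n_fields <- lengths(fields)
  if (any(n_fields != 9L)) {
    bad <- line_no[which(n_fields != 9L)[1]]
    stop(sprintf("malformed GFF3 line %d in '%s': expected 9 tab-separated fields",
                 bad, path), call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  is_gene <- mat[, 3] == "gene"
  mat <- mat[is_gene, , drop = FALSE]
  gene_lines <- line_no[is_gene]

  no_id <- !grepl("(^|;)\\s*ID=[^;]", mat[, 9])
  ids <- sub(";.*$", "", sub("^(.*?;)??\\s*ID=", "", mat[, 9], perl = TRUE))
  if (any(no_id)) {
    stop(sprintf("gene at GFF3 line %d in '%s' has no ID attribute",
                 gene_lines[which(no_id)[1]], path), call. = FALSE)
  }
  out <- data.frame(
    gene_id = ids,
    chromosome = mat[, 1],
    start = as.integer(mat[, 4]),
    end = as.integer(mat[, 5]),
    strand = mat[, 7],
    stringsAsFactors = FALSE
  )
  if (anyNA(out$start) || anyNA(out$end) || any(out$start > out$end)) {
    bad <- gene_lines[which(is.na(out$start) | is.na(out$end) | out$start > out$end)[1]]
    stop(sprintf("invalid gene coordinates at GFF3 line %d in '%s'", bad, path),
         call. = FALSE)
  }
  if (anyDuplicated(out$gene_id)) {
    stop(sprintf("duplicate gene ID '%s' in '%s'",
                 out$gene_id[anyDuplicated(out$gene_id)], path), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Read pathway definitions
#'
#' The pathways file has one line per gene with three tab-separated columns:
#' pathway ID, pathway name, gene ID. A gene may belong to several pathways.
#' Duplicate (pathway, gene) lines are removed with a warning; a line with
#' fewer than three fields is a fatal error reported with its line number.
#'
#' @param path Path to the tab-delimited pathways file (optionally gzipped).
#' @param header Logical; does the first line hold column names? Default TRUE.
#' @return A data frame with columns `pathway_id`, `pathway_name`,
#'   `gene_id`, one row per retained (pathway, gene) pair.
#' @export
read_pathway_sets <- function(path, header = TRUE) {
  con <- file(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  first_data <- if (header) 2L else 1L
  if (length(lines) < first_data) {
    return(data.frame(pathway_id = character(), pathway_name = character(),
                      gene_id = character(), stringsAsFactors = FALSE))
  }
  data_lines <- lines[first_data:length(lines)]
  data_lines_no <- seq.int(first_data, length(lines))
  nonblank <- nzchar(trimws(data_lines))
  data_lines <- data_lines[nonblank]
  data_lines_no <- data_lines_no[nonblank]

  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop(sprintf("pathway file line %d in '%s' has fewer than 3 tab-separated fields",
                 data_lines_no[which(short)[1]], path), call. = FALSE)
  }
  out <- data.frame(
    pathway_id = vapply(fields, `[[`, character(1), 1L),
    pathway_name = vapply(fields, `[[`, character(1), 2L),
    gene_id = vapply(fields, `[[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(out[, c("pathway_id", "gene_id")])
  if (any(dup)) {
    warning(sprintf("%d duplicated (pathway, gene) line(s) removed", sum(dup)),
            call. = FALSE)
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' @noRd
#' Named list of gene-id character vectors, one per pathway, plus a names
#' lookup. Shared by the enrichment stage.
pathway_gene_sets <- function(pathways) {
  sets <- split(pathways$gene_id, pathways$pathway_id)
  names_map <- pathways$pathway_name[!duplicated(pathways$pathway_id)]
  names(names_map) <- pathways$pathway_id[!duplicated(pathways$pathway_id)]
  list(sets = sets, names = names_map)
}
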