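# End-to-end orchestration: load and filter inputs, collapse to tagSNPs,
# assign genes, score pathways, filter, write tables / rugplots / run log.
# Every intermediate is serialised so individual stages can be re-run.

#' Run the full GWAS pathway-association analysis
#'
#' Executes the four-stage pipeline: (1) load and filter the association
#' statistics, allele effects and LD tables; (2) partition SNPs into
#' linkage groups and elect tagSNPs; (3) transfer tagSNP effects to genes
#' within the physical window; (4) score pathways with the running-sum
#' enrichment statistic against a resampling null and filter the results.
#' When `outdir` is given, the results table, gene-assignment table, tagSNP
#' table, serialised rugplot data, per-pathway rugplots for the filtered
#' set, and a run log with the effective configuration and every filter
#' count are written there.
#'
#' Each input may be a file path (read with the package readers) or an
#' already-parsed data frame in the corresponding reader's column layout.
#'
#' @param stats Association statistics: path or data frame
#'   ([read_gwas_stats()]).
#' @param effects Allele effects: path or data frame ([read_gwas_effects()]).
#' @param ld Pairwise LD: path or data frame ([read_ld_table()]).
#' @param gff Gene annotation: GFF3 path or data frame
#'   ([read_gene_annotations()]).
#' @param pathways Pathway definitions: path or data frame
#'   ([read_pathway_sets()]).
#' @param trait Trait to analyse (required when the tables hold several).
#' @param r2_cutoff LD r-squared linkage cutoff; default 0.8.
#' @param window SNP-to-gene distance window in bp; default 1000.
#' @param min_genes Minimum assigned genes per pathway; default 5.
#' @param n_perm Resampling replicates for the null; default 1000.
#' @param direction `"increase"` or `"decrease"`.
#' @param filter_mode `"q"`, `"p"`, `"top_n"` or `"all"`; default `"q"`.
#' @param filter_threshold Threshold (or n for `"top_n"`); default 0.05.
#' @param seed Master RNG seed; default 1.
#' @param workers Parallel workers for the null; default 1.
#' @param null_mode `"bootstrap"` or `"permutation"`.
#' @param outdir Output directory, or `NULL` to skip writing.
#' @param plot_format Rugplot image format; default `"png"`.
#' @param make_plots Render rugplots when writing output? Default TRUE.
#' @return An object of class `gwas_pathway_analysis`: list with `markers`,
#'   `groups`, `tags`, `assignments`, `enrichment` (the
#'   [pathway_enrichment()] fit), `filtered` (results passing the filter),
#'   `counts` (all filter counts), `config` and `log` (character vector).
#' @export
run_gwas_pathway_analysis <- function(stats, effects, ld, gff, pathways,
                                      trait = NULL, r2_cutoff = 0.8,
                                      window = 1000, min_genes = 5,
                                      n_perm = 1000,
                                      direction = c("increase", "decrease"),
                                      filter_mode = c("q", "p", "top_n", "all"),
                                      filter_threshold = 0.05, seed = 1,
                                      workers = 1,
                                      null_mode = c("bootstrap", "permutation"),
                                      outdir = NULL, plot_format = "png",
                                      make_plots = TRUE) {
  direction <- match.arg(direction)
  filter_mode <- match.arg(filter_mode)
  null_mode <- match.arg(null_mode)
  config <- list(trait = trait, r2_cutoff = r2_cutoff, window = window,
                 min_genes = min_genes, n_perm = n_perm,
                 direction = direction, filter_mode = filter_mode,
                 filter_threshold = filter_threshold, seed = seed,
                 workers = workers, null_mode = null_mode,
                 plot_format = plot_format)
  log_lines <- c("gwaspath run", "effective configuration:",
                 sprintf("  %s = %s", names(config),
                         vapply(config, function(v)
                           paste(format(v), collapse = ","), character(1))))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage: %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  stats_df <- stage("load", if (is.character(stats)) read_gwas_stats(stats, trait) else stats)
  effects_df <- stage("load", if (is.character(effects)) read_gwas_effects(effects, trait) else effects)
  ld_df <- stage("load", if (is.character(ld)) read_ld_table(ld) else ld)
  genes_df <- stage("load", if (is.character(gff)) read_gene_annotations(gff) else gff)
  pathways_df <- stage("load", if (is.character(pathways)) read_pathway_sets(pathways) else pathways)

  markers <- stage("merge", merge_markers(stats_df, effects_df))
  mc <- attr(markers, "counts")
  log_lines <- c(log_lines,
    sprintf("markers retained: %d", nrow(markers)),
    sprintf("markers dropped as non-biallelic: %d", mc$n_non_biallelic),
    sprintf("markers dropped for missing R2: %d", mc$n_missing_r2),
    sprintf("effect rows without statistics: %d", mc$n_effects_without_stats))

  groups <- stage("linkage", linkage_groups(markers, ld_df, r2_cutoff))
  tags <- stage("linkage", tag_snps(groups, markers))
  n_prob <- attr(tags, "n_problematic_pairs")
  kinds <- vapply(groups$groups, `[[`, character(1), "kind")
  log_lines <- c(log_lines,
    sprintf("linkage groups: %d unlinked, %d pairs, %d blocks",
            sum(kinds == "unlinked"), sum(kinds == "pair"), sum(kinds == "block")),
    sprintf("problematic pairs dropped: %d", n_prob),
    sprintf("tagSNPs emitted: %d", nrow(tags)))

  assignments <- stage("gene-mapping", assign_genes(tags, genes_df, window))
  log_lines <- c(log_lines, sprintf("genes assigned: %d", nrow(assignments)))

  fit <- stage("enrichment",
               pathway_enrichment(assignments, pathways_df,
                                  direction = direction, n_perm = n_perm,
                                  min_genes = min_genes, seed = seed,
                                  workers = workers, null_mode = null_mode))
  log_lines <- c(log_lines,
    sprintf("pathways scored: %d", nrow(fit$results)),
    sprintf("pathways dropped below min_genes: %d", fit$n_dropped_min_genes))

  filtered <- stage("filter",
                    filter_pathways(fit$results, filter_mode, filter_threshold))
  log_lines <- c(log_lines,
    sprintf("pathways passing the %s filter: %d", filter_mode, nrow(filtered)))

  out <- structure(list(markers = markers, groups = groups, tags = tags,
                        assignments = assignments, enrichment = fit,
                        filtered = filtered,
                        counts = list(
                          n_markers = nrow(markers),
                          n_non_biallelic = mc$n_non_biallelic,
                          n_missing_r2 = mc$n_missing_r2,
                          n_problematic_pairs = n_prob,
                          n_tags = nrow(tags),
                          n_genes_assigned = nrow(assignments),
                          n_pathways_scored = nrow(fit$results),
                          n_pathways_dropped_min_genes = fit$n_dropped_min_genes,
                          n_pathways_filtered = nrow(filtered)),
                        config = config, log = log_lines),
                   class = "gwas_pathway_analysis")

  if (!is.null(outdir)) {
    stage("write", write_analysis(out, outdir, make_plots = make_plots))
  }
  out
}

#' Write the tables, rugplots and run log of an analysis
#'
#' @param x A `gwas_pathway_analysis` object.
#' @param outdir Output directory (created if needed).
#' @param make_plots Render rugplots for the filtered pathways? Default TRUE.
#' @return Invisibly, `x`.
#' @export
write_analysis <- function(x, outdir, make_plots = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  res <- x$enrichment$results
  write_tsv(data.frame(pathway_id = res$pathway_id,
                       pathway_name = res$pathway_name,
                       n_genes = res$n_genes, ES = res$ES,
                       null_mean = res$null_mean, null_sd = res$null_sd,
                       z = res$z, p = res$p, q = res$q,
                       stringsAsFactors = FALSE),
            "pathway_results.tsv")
  write_tsv(x$assignments, "gene_assignments.tsv")
  write_tsv(x$tags, "tag_snps.tsv")
  if (length(x$enrichment$running_sums) > 0) {
    write_tsv(rugplot_table(x$enrichment), "rugplot_data.tsv")
  }
  writeLines(x$log, file.path(outdir, "run_log.txt"))
  if (make_plots && nrow(x$filtered) > 0) {
    render_rugplots(x$enrichment, file.path(outdir, "rugplots"),
                    which = x$filtered$pathway_id,
                    format = x$config$plot_format)
  }
  invisible(x)
}

#' @export
print.gwas_pathway_analysis <- function(x, ...) {
  cat("GWAS pathway-association analysis\n")
  cat(sprintf("  markers: %d (non-biallelic dropped: %d, missing R2: %d)\n",
              x$counts$n_markers, x$counts$n_non_biallelic, x$counts$n_missing_r2))
  cat(sprintf("  tagSNPs: %d (problematic pairs dropped: %d)\n",
              x$counts$n_tags, x$counts$n_problematic_pairs))
  cat(sprintf("  genes assigned: %d\n", x$counts$n_genes_assigned))
  cat(sprintf("  pathways scored: %d; passing %s filter: %d\n",
              x$counts$n_pathways_scored, x$config$filter_mode,
              x$counts$n_pathways_filtered))
  if (nrow(x$filtered) > 0) {
    cat("\nTop pathways:\n")
    print(utils::head(x$filtered[, c("pathway_id", "n_genes", "ES", "z", "p", "q")], 5))
  }
  invisible(x)
}

#' Load a run configuration from a YAML file
#'
#' Reads a YAML mapping of [run_gwas_pathway_analysis()] argument names to
#' values and merges it with `overrides` (typically parsed command-line
#' flags), with the overrides taking precedence.
#'
#' @param path Path to a YAML file, or `NULL`.
#' @param overrides Named list of arguments that win over the file.
#' @return Named list of arguments for [run_gwas_pathway_analysis()].
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  config <- list()
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    config <- yaml::read_yaml(path)
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  config[names(overrides)] <- overrides
  config
}
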