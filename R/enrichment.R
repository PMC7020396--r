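# Pathway enrichment: effect-ranked gene list, weighted running-sum
# enrichment score (GSEA-style weighted Kolmogorov-Smirnov statistic with
# weight exponent 1), bootstrap null distribution, z / p / q per pathway.

#' Rank assigned genes by effect
#'
#' Genes are sorted "best to worst". For `direction = "increase"` (pathways
#' associated with raising the trait) best means the largest positive
#' effect, so the order is descending; for `direction = "decrease"` it is
#' ascending. Ties are broken by gene id in C-locale lexicographic order so
#' the ranking is fully deterministic.
#'
#' @param assignments Gene assignment table from [assign_genes()] (columns
#'   `gene_id`, `effect` are used).
#' @param direction `"increase"` or `"decrease"`: the trait tail of interest.
#' @return An object of class `ranked_genes`: list with `gene_id`, `effect`
#'   (aligned, best first) and `direction`.
#' @export
rank_genes <- function(assignments, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  stopifnot(nrow(assignments) >= 2L)
  ord <- if (direction == "increase") {
    radix_order(-assignments$effect, assignments$gene_id)
  } else {
    radix_order(assignments$effect, assignments$gene_id)
  }
  structure(list(gene_id = assignments$gene_id[ord],
                 effect = assignments$effect[ord],
                 direction = direction),
            class = "ranked_genes")
}

#' @noRd
#' Running sum over a ranked effect vector given a logical hit indicator.
#' Hit step: |e| / sum of |e| over hits; miss step: -1/(N - n_hits).
#' Falls back to uniform hit steps 1/n_hits when all hit effects are zero.
#' Returns the full cumulative sum (S_N = 0 by construction).
running_sum_vector <- function(effects, hit) {
  n <- length(effects)
  n_hit <- sum(hit)
  steps <- numeric(n)
  total <- sum(abs(effects[hit]))
  if (total == 0) {
    message("all pathway-gene effects are zero; using uniform hit weights")
    steps[hit] <- 1 / n_hit
  } else {
    steps[hit] <- abs(effects[hit]) / total
  }
  steps[!hit] <- -1 / (n - n_hit)
  cumsum(steps)
}

#' Weighted running-sum enrichment statistic for one pathway
#'
#' Walking the ranked gene list, the running sum rises at pathway genes by
#' the gene's absolute effect normalised so all rises total 1, and falls at
#' non-pathway genes by `1/(N - n_hits)` so all falls total 1 (hence the sum
#' returns to 0 at the last rank). The enrichment score (ES) is the maximum
#' of the running sum; when every prefix is negative the maximum is reported
#' unfloored so the null normalisation stays well-defined. If all pathway
#' genes have effect exactly 0, uniform rise steps `1/n_hits` are used (with
#' a message).
#'
#' @param ranked A `ranked_genes` object from [rank_genes()].
#' @param pathway_genes Character vector of the pathway's gene ids. Must
#'   share at least one gene with, and not cover all of, the ranking.
#' @return An object of class `running_sum`: list with `S` (cumulative sum
#'   per rank), `es` (max of `S`), `peak_rank` (first rank attaining the
#'   max) and `hit_ranks` (ranks of pathway genes).
#' @export
running_sum <- function(ranked, pathway_genes) {
  stopifnot(inherits(ranked, "ranked_genes"))
  hit <- ranked$gene_id %in% pathway_genes
  n_hit <- sum(hit)
  if (n_hit == 0) stop("pathway shares no gene with the ranked list")
  if (n_hit == length(hit)) stop("pathway contains every ranked gene")
  S <- running_sum_vector(ranked$effect, hit)
  peak <- which.max(S)
  structure(list(S = S, es = S[peak], peak_rank = peak,
                 hit_ranks = which(hit)),
            class = "running_sum")
}

#' Drop pathways with too few assigned genes
#'
#' A pathway is retained iff at least `min_genes` of its genes are present
#' in the gene-assignment table — membership is counted after intersecting
#' with the ranked universe, guarding against small-sample-size bias.
#'
#' @param pathways Pathway table from [read_pathway_sets()].
#' @param assignments Gene assignment table from [assign_genes()].
#' @param min_genes Minimum number of assigned genes (>= 1); default 5.
#' @return The pathway table restricted to retained pathways. The number of
#'   dropped pathways is attached as attribute `n_dropped`.
#' @export
filter_min_genes <- function(pathways, assignments, min_genes = 5) {
  stopifnot(min_genes >= 1)
  in_universe <- pathways$gene_id %in% assignments$gene_id
  n_by_pathway <- tapply(in_universe, pathways$pathway_id, sum)
  keep_ids <- names(n_by_pathway)[n_by_pathway >= min_genes]
  n_dropped <- length(n_by_pathway) - length(keep_ids)
  out <- pathways[pathways$pathway_id %in% keep_ids, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no pathway has enough assigned genes; result is empty", call. = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Null enrichment scores by resampling gene effects
#'
#' For each replicate the observed effect vector is resampled (with
#' replacement by default) and reassigned to the gene labels in a fixed
#' order; genes are re-ranked and the ES of every pathway recomputed.
#' Per-replicate RNG seeds are derived from the master seed up front, so the
#' null matrix is bit-identical for any number of workers and fully
#' reproducible given `seed`.
#'
#' @param assignments Gene assignment table from [assign_genes()].
#' @param pathway_sets Named list of pathway gene-id vectors (already
#'   filtered by [filter_min_genes()]).
#' @param n_perm Number of resampling replicates (>= 1); default 1000.
#' @param seed Master RNG seed.
#' @param direction Ranking direction, as in [rank_genes()].
#' @param workers Number of parallel workers (forked; results identical for
#'   any value); default 1.
#' @param null_mode `"bootstrap"` (sample effects with replacement, the
#'   default) or `"permutation"` (without replacement, for sensitivity
#'   analysis).
#' @return A numeric matrix, `n_perm` rows by one column per pathway.
#' @export
sample_null_es <- function(assignments, pathway_sets, n_perm = 1000, seed = 1,
                           direction = c("increase", "decrease"), workers = 1,
                           null_mode = c("bootstrap", "permutation")) {
  direction <- match.arg(direction)
  null_mode <- match.arg(null_mode)
  if (n_perm < 1) stop("n_perm must be >= 1")
  genes <- assignments$gene_id
  eff <- assignments$effect
  ord0 <- radix_order(genes)            # fixed gene-label order
  genes <- genes[ord0]
  eff <- eff[ord0]
  n <- length(genes)
  hit_mat <- vapply(pathway_sets, function(s) genes %in% s,
                    logical(n))         # n x P, by fixed gene order
  replace <- null_mode == "bootstrap"
  seeds <- replicate_seeds(seed, n_perm)

  one_rep <- function(r) {
    set.seed(seeds[r])
    e <- sample(eff, n, replace = replace)
    ord <- if (direction == "increase") radix_order(-e, genes) else radix_order(e, genes)
    e_ranked <- e[ord]
    h <- hit_mat[ord, , drop = FALSE]
    vapply(seq_len(ncol(h)), function(j) {
      max(running_sum_vector(e_ranked, h[, j]))
    }, numeric(1))
  }
  rows <- if (workers > 1) {
    parallel::mclapply(seq_len(n_perm), one_rep, mc.cores = workers)
  } else {
    lapply(seq_len(n_perm), one_rep)
  }
  out <- do.call(rbind, rows)
  colnames(out) <- names(pathway_sets)
  out
}

#' Normalise an observed ES against its null sample
#'
#' `z = (ES_obs - mean(null)) / sd(null)` with the sample (N-1) standard
#' deviation; `p` is the upper-tail standard normal probability of `z`. A
#' degenerate null (sd = 0) yields p = 1 when the observed ES does not
#' exceed the null mean and the smallest positive double otherwise, with
#' `degenerate = TRUE`.
#'
#' @param es_observed Observed enrichment score.
#' @param null_samples Numeric vector of null ES values (length >= 2).
#' @return A list with `z`, `p_value`, `null_mean`, `null_sd`, `degenerate`.
#' @export
score_pathway <- function(es_observed, null_samples) {
  stopifnot(length(null_samples) >= 2L)
  m <- mean(null_samples)
  s <- stats::sd(null_samples)
  if (s == 0) {
    p <- if (es_observed <= m) 1 else .Machine$double.xmin
    return(list(z = if (es_observed <= m) 0 else Inf, p_value = p,
                null_mean = m, null_sd = s, degenerate = TRUE))
  }
  z <- (es_observed - m) / s
  list(z = z, p_value = stats::pnorm(z, lower.tail = FALSE),
       null_mean = m, null_sd = s, degenerate = FALSE)
}

#' False-discovery-rate q-values
#'
#' Storey q-values with the smoother pi0 estimate (pi0(lambda) over the grid
#' 0.05..0.95, df-3 smoothing spline evaluated at the largest lambda) when
#' at least `min_storey` p-values are available; otherwise, or when the pi0
#' estimate fails (non-finite or <= 0), the Benjamini-Hochberg step-up
#' (pi0 = 1). q-values are monotone non-decreasing in p-value rank.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param min_storey Minimum number of tests for the Storey estimator;
#'   default 100.
#' @return Numeric vector of q-values, aligned with `p`.
#' @export
q_values <- function(p, min_storey = 100) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    stop("p-values must lie in [0, 1]")
  }
  pi0 <- 1
  if (length(p) >= min_storey) {
    lambda <- seq(0.05, 0.95, 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    est <- tryCatch({
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      stats::predict(fit, x = max(lambda))$y
    }, error = function(e) NA_real_)
    if (is.finite(est) && est > 0) pi0 <- min(est, 1)
  }
  pmin(pi0 * stats::p.adjust(p, method = "BH"), 1)
}

#' Filter scored pathways
#'
#' @param results Pathway results data frame (from a `pathway_enrichment`
#'   object's `results` element) with columns `p` and `q`.
#' @param mode `"p"` or `"q"` (keep values `<= threshold`), `"top_n"` (the n
#'   smallest p-values, ties by pathway id), or `"all"`.
#' @param threshold Significance threshold for modes `"p"`/`"q"` (default
#'   0.05) or the n for `"top_n"`.
#' @return The filtered results, sorted by ascending p-value.
#' @export
filter_pathways <- function(results, mode = c("q", "p", "top_n", "all"),
                            threshold = 0.05) {
  mode <- match.arg(mode)
  results <- results[radix_order(results$p, results$pathway_id), , drop = FALSE]
  out <- switch(mode,
    p = results[results$p <= threshold, , drop = FALSE],
    q = results[results$q <= threshold, , drop = FALSE],
    top_n = {
      n <- as.integer(threshold)
      if (n > nrow(results)) {
        warning(sprintf("top_n = %d exceeds the %d scored pathways; returning all",
                        n, nrow(results)), call. = FALSE)
        n <- nrow(results)
      }
      results[seq_len(n), , drop = FALSE]
    },
    all = results)
  rownames(out) <- NULL
  out
}

#' Score pathways against a resampling null
#'
#' The package's central fit: ranks the assigned genes by effect, computes
#' each retained pathway's observed enrichment score, builds a bootstrap
#' null by resampling the gene-effect vector, and reports per-pathway z,
#' upper-tail normal p and FDR q.
#'
#' @inheritParams sample_null_es
#' @param pathways Pathway table from [read_pathway_sets()].
#' @param min_genes Minimum assigned genes per pathway; default 5.
#' @return An object of class `pathway_enrichment`: a list with
#'   \describe{
#'     \item{results}{data frame sorted by ascending p with columns
#'       `pathway_id`, `pathway_name`, `n_genes`, `ES`, `null_mean`,
#'       `null_sd`, `z`, `p`, `q`, `degenerate_null`;}
#'     \item{running_sums}{named list of [running_sum()] objects;}
#'     \item{ranked}{the `ranked_genes` object;}
#'     \item{null_es}{the `n_perm` x pathways null ES matrix;}
#'     \item{params}{the effective parameters;}
#'     \item{n_dropped_min_genes}{pathways dropped by the gene minimum.}
#'   }
#' @export
#' @examples
#' toy <- toy_dataset()
#' fit <- pathway_enrichment(toy$assignments, toy$pathways,
#'                           min_genes = 2, n_perm = 50, seed = 1)
#' fit$results
pathway_enrichment <- function(assignments, pathways,
                               direction = c("increase", "decrease"),
                               n_perm = 1000, min_genes = 5, seed = 1,
                               workers = 1,
                               null_mode = c("bootstrap", "permutation")) {
  direction <- match.arg(direction)
  null_mode <- match.arg(null_mode)
  retained <- filter_min_genes(pathways, assignments, min_genes)
  n_dropped <- attr(retained, "n_dropped")
  ranked <- rank_genes(assignments, direction)
  ps <- pathway_gene_sets(retained)
  # a pathway covering the whole ranked universe has no miss step; drop it
  covers_all <- vapply(ps$sets, function(s) all(ranked$gene_id %in% s), logical(1))
  if (any(covers_all)) {
    warning(sprintf("%d pathway(s) containing every ranked gene dropped",
                    sum(covers_all)), call. = FALSE)
    ps$sets <- ps$sets[!covers_all]
  }
  if (length(ps$sets) == 0) {
    results <- data.frame(pathway_id = character(), pathway_name = character(),
                          n_genes = integer(), ES = numeric(),
                          null_mean = numeric(), null_sd = numeric(),
                          z = numeric(), p = numeric(), q = numeric(),
                          degenerate_null = logical(), stringsAsFactors = FALSE)
    return(structure(list(results = results, running_sums = list(),
                          ranked = ranked, null_es = NULL,
                          params = list(direction = direction, n_perm = n_perm,
                                        min_genes = min_genes, seed = seed,
                                        null_mode = null_mode),
                          n_dropped_min_genes = n_dropped),
                     class = "pathway_enrichment"))
  }

  sums <- lapply(ps$sets, function(s) running_sum(ranked, s))
  es_obs <- vapply(sums, `[[`, numeric(1), "es")
  null_es <- sample_null_es(assignments, ps$sets, n_perm = n_perm, seed = seed,
                            direction = direction, workers = workers,
                            null_mode = null_mode)
  scores <- lapply(seq_along(ps$sets), function(j) {
    score_pathway(es_obs[j], null_es[, j])
  })
  results <- data.frame(
    pathway_id = names(ps$sets),
    pathway_name = unname(ps$names[names(ps$sets)]),
    n_genes = vapply(sums, function(s) length(s$hit_ranks), integer(1)),
    ES = unname(es_obs),
    null_mean = vapply(scores, `[[`, numeric(1), "null_mean"),
    null_sd = vapply(scores, `[[`, numeric(1), "null_sd"),
    z = vapply(scores, `[[`, numeric(1), "z"),
    p = vapply(scores, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  results$q <- q_values(results$p)
  results$degenerate_null <- vapply(scores, `[[`, logical(1), "degenerate")
  results <- results[radix_order(results$p, results$pathway_id), , drop = FALSE]
  rownames(results) <- NULL

  structure(list(results = results, running_sums = sums, ranked = ranked,
                 null_es = null_es,
                 params = list(direction = direction, n_perm = n_perm,
                               min_genes = min_genes, seed = seed,
                               null_mode = null_mode),
                 n_dropped_min_genes = n_dropped),
            class = "pathway_enrichment")
}

#' @export
print.pathway_enrichment <- function(x, ...) {
  cat("Pathway enrichment of", length(x$ranked$gene_id), "ranked genes",
      sprintf("(direction: %s, %d resamples, %s null)\n",
              x$params$direction, x$params$n_perm, x$params$null_mode))
  cat(nrow(x$results), "pathway(s) scored;", x$n_dropped_min_genes,
      "dropped below the", x$params$min_genes, "assigned-gene minimum\n\n")
  print(utils::head(x$results[, c("pathway_id", "n_genes", "ES", "z", "p", "q")], 10))
  invisible(x)
}

#' @export
summary.pathway_enrichment <- function(object, alpha = 0.05, ...) {
  r <- object$results
  cat("Pathways scored:", nrow(r), "\n")
  cat("Significant at p <=", alpha, ":", sum(r$p <= alpha), "\n")
  cat("Significant at q <=", alpha, ":", sum(r$q <= alpha), "\n")
  if (nrow(r) > 0) {
    cat("Top pathway:", r$pathway_id[1],
        sprintf("(ES %.3f, z %.2f, p %.3g, q %.3g)\n", r$ES[1], r$z[1], r$p[1], r$q[1]))
  }
  invisible(r)
}
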