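# Ranking, running-sum statistic, resampling null, scoring, q-values.

asg_fixture <- function(effects, ids = sprintf("g%02d", seq_along(effects))) {
  data.frame(gene_id = ids, chromosome = "chr1", effect = effects,
             p_value = 0.1, n_linked_snps = 1L, tag_marker = ids,
             n_tags = 1L, stringsAsFactors = FALSE)
}

test_that("gene ranking respects direction and breaks ties by gene id", {
  a <- asg_fixture(c(3, -1, 2), ids = c("g1", "g2", "g3"))
  expect_equal(rank_genes(a, "increase")$gene_id, c("g1", "g3", "g2"))
  expect_equal(rank_genes(a, "decrease")$gene_id, c("g2", "g3", "g1"))
  tied <- asg_fixture(c(1, 1, 1), ids = c("b", "c", "a"))
  expect_equal(rank_genes(tied, "increase")$gene_id, c("a", "b", "c"))
})

test_that("running sum reproduces the worked example and closes at zero", {
  ranked <- rank_genes(asg_fixture(c(3, 2, 1, 0.5)), "increase")
  rs <- running_sum(ranked, c("g01", "g02"))
  expect_equal(rs$S, c(0.6, 1.0, 0.5, 0.0))
  expect_equal(rs$es, 1.0)
  expect_equal(rs$peak_rank, 2L)
  expect_equal(rs$hit_ranks, 1:2)

  # all-but-last hits with equal effects: increments total 1 before any fall
  ranked2 <- rank_genes(asg_fixture(rep(2, 5)), "increase")
  rs2 <- running_sum(ranked2, sprintf("g%02d", 1:4))
  expect_equal(rs2$es, 1.0)
  expect_equal(rs2$peak_rank, 4L)

  # single hit at the last rank: prefix sums follow the closed form
  ranked3 <- rank_genes(asg_fixture(c(4, 3, 2, 1)), "increase")
  rs3 <- running_sum(ranked3, "g04")
  expect_equal(rs3$S, c(-1/3, -2/3, -1, 0))
  expect_equal(rs3$es, 0)

  # zero-effect hits fall back to uniform weights with a message
  ranked4 <- rank_genes(asg_fixture(c(1, 0, 0, -1)), "increase")
  expect_message(rs4 <- running_sum(ranked4, c("g02", "g03")), "uniform")
  expect_equal(rs4$S, c(-0.5, 0, 0.5, 0))
})

test_that("running sum matches a loop oracle on random instances", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:80, 1)
    eff <- round(rnorm(n), 3)
    a <- asg_fixture(eff)
    ranked <- rank_genes(a, sample(c("increase", "decrease"), 1))
    n_hit <- sample(seq_len(n - 1), 1)
    hits <- sample(a$gene_id, n_hit)
    rs <- suppressMessages(running_sum(ranked, hits))
    hit <- ranked$gene_id %in% hits
    expect_equal(rs$S, oracle_running_sum(ranked$effect, hit), tolerance = 1e-12)
    expect_equal(rs$S[n], 0, tolerance = 1e-9)
    expect_equal(rs$es, max(rs$S))
    expect_gte(min(rs$S), -1 - 1e-9)
    expect_lte(rs$es, 1 + 1e-9)
  }
})

test_that("null resampling is reproducible and degenerates with constant effects", {
  a <- asg_fixture(rnorm(30))
  sets <- list(P1 = a$gene_id[1:5], P2 = a$gene_id[6:15])
  n1 <- sample_null_es(a, sets, n_perm = 20, seed = 5)
  n2 <- sample_null_es(a, sets, n_perm = 20, seed = 5)
  expect_identical(n1, n2)
  expect_equal(dim(n1), c(20L, 2L))
  n3 <- sample_null_es(a, sets, n_perm = 20, seed = 6)
  expect_false(identical(n1, n3))
  # one replicate works
  expect_equal(nrow(sample_null_es(a, sets, n_perm = 1, seed = 5)), 1L)
  expect_error(sample_null_es(a, sets, n_perm = 0, seed = 5), "n_perm")

  # identical effects: every null ES is the same; sd = 0 is degenerate
  a0 <- asg_fixture(rep(2, 10))
  null0 <- sample_null_es(a0, list(P = a0$gene_id[1:3]), n_perm = 10, seed = 1)
  expect_equal(length(unique(null0[, 1])), 1L)
  sc <- score_pathway(unique(null0[, 1]), null0[, 1])
  expect_true(sc$degenerate)
  expect_equal(sc$p_value, 1)
  sc_hi <- score_pathway(unique(null0[, 1]) + 1, null0[, 1])
  expect_equal(sc_hi$p_value, .Machine$double.xmin)
})

test_that("z and p follow the normal normalisation of the null", {
  null <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  sc <- score_pathway(mean(null), null)
  expect_equal(sc$z, 0)
  expect_equal(sc$p_value, 0.5)
  # z = 1.6449 -> p ~ 0.05
  sc2 <- score_pathway(mean(null) + 1.6449 * sd(null), null)
  expect_equal(sc2$p_value, 0.05, tolerance = 1e-4)
  # observed below every null sample -> z < 0, p > 0.5
  sc3 <- score_pathway(0.05, null)
  expect_lt(sc3$z, 0)
  expect_gt(sc3$p_value, 0.5)
  # sample (n-1) standard deviation is used
  expect_equal(score_pathway(0.6, null)$z, (0.6 - mean(null)) / sd(null))
})

test_that("q-values follow BH below the Storey threshold and stay monotone", {
  expect_equal(q_values(0.03), 0.03)
  expect_equal(q_values(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(q_values(rep(1, 5)), rep(1, 5))
  expect_error(q_values(c(0.5, 1.2)), "\\[0, 1\\]")

  # BH hand check on an unsorted vector
  p <- c(0.04, 0.01, 0.03, 0.02)
  expect_equal(q_values(p), rep(0.04, 4))

  # with many p-values the Storey estimator shrinks q below BH when the
  # distribution is signal-rich, and q stays monotone in p-rank
  set.seed(12)
  p_many <- c(runif(80, 0, 0.01), runif(120))
  q <- q_values(p_many)
  expect_true(all(q <= stats::p.adjust(p_many, "BH") + 1e-12))
  ord <- order(p_many)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_true(all(q >= 0 & q <= 1))
})

test_that("pathway filters subset and sort by significance", {
  res <- data.frame(pathway_id = sprintf("P%02d", 1:10),
                    pathway_name = "x", n_genes = 5L, ES = 0.5,
                    null_mean = 0.3, null_sd = 0.1,
                    z = 11:2, p = seq(0.01, 0.10, 0.01),
                    q = seq(0.02, 0.20, 0.02), stringsAsFactors = FALSE)
  res <- res[sample(nrow(res)), ]
  f <- filter_pathways(res, "q", 0.05)
  expect_equal(nrow(f), 2L)
  expect_equal(f$p, sort(f$p))
  expect_equal(nrow(filter_pathways(res, "p", 0.03)), 3L)
  top <- filter_pathways(res, "top_n", 2)
  expect_equal(top$pathway_id, c("P01", "P02"))
  expect_warning(all_of_them <- filter_pathways(res, "top_n", 99), "exceeds")
  expect_equal(nrow(all_of_them), 10L)
  expect_equal(nrow(filter_pathways(res, "all")), 10L)
})

test_that("the assigned-gene minimum counts members after intersection", {
  a <- asg_fixture(rnorm(6), ids = sprintf("g%02d", 1:6))
  pw <- data.frame(
    pathway_id = c(rep("P1", 10), rep("P2", 5)),
    pathway_name = "x",
    gene_id = c(sprintf("g%02d", 1:3), sprintf("off%02d", 1:7),
                sprintf("g%02d", 1:5)),
    stringsAsFactors = FALSE)
  # P1 defines 10 genes but only 3 are assigned -> dropped at min_genes 5
  kept <- filter_min_genes(pw, a, min_genes = 5)
  expect_equal(unique(kept$pathway_id), "P2")
  expect_equal(attr(kept, "n_dropped"), 1L)
  # min_genes 1 retains every pathway with at least one assigned gene
  expect_setequal(unique(filter_min_genes(pw, a, 1)$pathway_id), c("P1", "P2"))
  # a minimum beyond the universe empties the result with a warning
  expect_warning(none <- filter_min_genes(pw, a, 7), "empty")
  expect_equal(nrow(none), 0L)
})

test_that("z-scores are invariant to rescaling all effects by c > 0", {
  set.seed(41)
  a <- asg_fixture(rnorm(40))
  pw <- data.frame(pathway_id = rep(c("P1", "P2"), each = 8),
                   pathway_name = "x",
                   gene_id = a$gene_id[c(1:8, 21:28)], stringsAsFactors = FALSE)
  f1 <- pathway_enrichment(a, pw, n_perm = 100, seed = 3, min_genes = 2)
  a2 <- a
  a2$effect <- a$effect * 7.5
  f2 <- pathway_enrichment(a2, pw, n_perm = 100, seed = 3, min_genes = 2)
  expect_equal(f1$results$z, f2$results$z, tolerance = 1e-12)
  expect_equal(f1$results$ES, f2$results$ES, tolerance = 1e-12)
})

test_that("worker count does not change the null matrix", {
  a <- asg_fixture(rnorm(25))
  sets <- list(P1 = a$gene_id[1:6], P2 = a$gene_id[10:20])
  n1 <- sample_null_es(a, sets, n_perm = 40, seed = 9, workers = 1)
  n4 <- sample_null_es(a, sets, n_perm = 40, seed = 9, workers = 4)
  expect_identical(n1, n4)
})

test_that("the enrichment fit scores, sorts and annotates pathways", {
  set.seed(17)
  a <- asg_fixture(c(rnorm(30), rnorm(6, mean = 3)),
                   ids = sprintf("g%02d", 1:36))
  pw <- data.frame(
    pathway_id = c(rep("UP", 6), rep("BG", 8)), pathway_name = "x",
    gene_id = c(sprintf("g%02d", 31:36), sprintf("g%02d", 1:8)),
    stringsAsFactors = FALSE)
  fit <- pathway_enrichment(a, pw, n_perm = 200, seed = 2, min_genes = 5)
  expect_s3_class(fit, "pathway_enrichment")
  expect_equal(fit$results$pathway_id[1], "UP")
  expect_equal(fit$results$p, sort(fit$results$p))
  expect_equal(nrow(fit$null_es), 200L)
  # z recomputable from the stored null matrix
  j <- match("UP", colnames(fit$null_es))
  i <- match("UP", fit$results$pathway_id)
  expect_equal(fit$results$z[i],
               (fit$results$ES[i] - mean(fit$null_es[, j])) / sd(fit$null_es[, j]),
               tolerance = 1e-12)
  expect_output(print(fit), "Pathway enrichment")
  expect_output(summary(fit), "Top pathway")
})
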