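# Readers and the loading-stage filters.

stats_header <- "Trait\tMarker\tChr\tPos\tp\tmarker_R2"

test_that("association statistics parse, filter by trait, and reject bad cells", {
  path <- write_lines_tmp(c(
    stats_header,
    "t1\tM1\tchr1\t100\t0.01\t0.20",
    "t1\tM2\tchr1\t200\t0.05\t0.10",
    "t2\tMx\tchr2\t300\t0.20\t0.30",
    "t1\tM3\tchr2\t300\t0.20\t0.30"))
  all_rows <- read_gwas_stats(path)
  expect_equal(nrow(all_rows), 4L)
  t1 <- read_gwas_stats(path, trait = "t1")
  expect_equal(t1$marker, c("M1", "M2", "M3"))
  expect_equal(t1$p_value, c(0.01, 0.05, 0.20))
  expect_equal(t1$marker_r2, c(0.20, 0.10, 0.30))

  # a NaN R2 is kept as missing here; the filter lives in merge_markers
  path2 <- write_lines_tmp(c(
    stats_header,
    "t1\tM1\tchr1\t100\t0.01\t0.20",
    "t1\tM2\tchr1\t200\t0.05\tNaN",
    "t1\tM3\tchr2\t300\t0.20\t0.30"))
  rows <- read_gwas_stats(path2, trait = "t1")
  expect_equal(nrow(rows), 3L)
  expect_true(is.na(rows$marker_r2[2]))
  expect_equal(sum(!is.na(rows$marker_r2)), 2L)

  # unreadable numeric cell -> warned and rejected
  path3 <- write_lines_tmp(c(
    stats_header,
    "t1\tM1\tchr1\t100\tabc\t0.20",
    "t1\tM2\tchr1\t200\t0.05\t0.10"))
  expect_warning(rows3 <- read_gwas_stats(path3, trait = "t1"), "unreadable")
  expect_equal(rows3$marker, "M2")

  # header without a p column is a format error naming the column
  path4 <- write_lines_tmp(c("Trait\tMarker\tChr\tPos\tmarker_R2",
                             "t1\tM1\tchr1\t100\t0.2"))
  expect_error(read_gwas_stats(path4), "p")
})

test_that("allele effects parse with no premature filtering", {
  path <- write_lines_tmp(c(
    "Trait\tMarker\tAllele\tEffect",
    "t1\tM1\tA\t0.5",
    "t1\tM1\tT\t-0.5",
    "t1\tM2\tA\t0.1",
    "t1\tM2\tC\t0.2",
    "t1\tM2\tG\t0.3"))
  eff <- read_gwas_effects(path, trait = "t1")
  expect_equal(sum(eff$marker == "M1"), 2L)
  expect_equal(sum(eff$marker == "M2"), 3L)  # triallelic kept until merge

  empty <- write_lines_tmp("Trait\tMarker\tAllele\tEffect")
  expect_equal(nrow(read_gwas_effects(empty, trait = "t1")), 0L)
})

test_that("merge_markers applies the biallelic and R2 filters and the first-nonzero convention", {
  stats <- data.frame(
    marker = c("M1", "M2", "M3"), chromosome = "chr1",
    position = c(100L, 200L, 300L), trait = "t",
    p_value = c(0.01, 0.02, 0.03), marker_r2 = c(0.2, 0.3, NA),
    stringsAsFactors = FALSE)
  effects <- data.frame(
    marker = c("M1", "M1", "M2", "M2", "M2", "M3", "M3"), trait = "t",
    allele = c("A", "T", "A", "C", "G", "A", "T"),
    effect = c(0.5, 0, 0.1, 0.2, 0.3, 1, -1), stringsAsFactors = FALSE)
  m <- merge_markers(stats, effects)
  # M2 triallelic, M3 missing R2 -> only M1 survives both stated filters
  expect_equal(m$marker, "M1")
  expect_equal(m$effect, 0.5)            # first nonzero allele row
  counts <- attr(m, "counts")
  expect_equal(counts$n_non_biallelic, 1L)
  expect_equal(counts$n_missing_r2, 1L)

  # effects for a marker missing from stats are warned about and dropped
  effects2 <- rbind(effects, data.frame(marker = "M9", trait = "t",
                                        allele = "A", effect = 1,
                                        stringsAsFactors = FALSE))
  expect_warning(merge_markers(stats, effects2), "absent")

  # empty inputs -> empty output
  e <- merge_markers(stats[0, ], effects[0, ])
  expect_equal(nrow(e), 0L)

  # output size bound and sorting
  expect_lte(nrow(m), min(nrow(stats), 2L))
})

test_that("LD reader keeps only intra-locus rows and the named columns", {
  header <- "Locus1\tPosition1\tSite1\tLocus2\tPosition2\tSite2\tDist_bp\tR^2"
  path <- write_lines_tmp(c(
    header,
    "chr1\t100\t1\tchr1\t200\t2\t100\t0.93",
    "chr1\t100\t1\tchr2\t300\t3\t200\t0.80",
    "chr1\t200\t2\tchr1\t400\t4\t200\t0.50",
    "chr2\t100\t1\tchr1\t500\t5\t400\t0.70",
    "chr2\t500\t9\tchr2\t900\t10\t400\t0.60"))
  ld <- read_ld_table(path)
  expect_equal(nrow(ld), 3L)                      # 2 inter-locus rows dropped
  expect_true(all(ld$locus %in% c("chr1", "chr2")))
  expect_equal(ld$ld_r2[ld$position_a == 100 & ld$locus == "chr1"], 0.93)
  expect_equal(ld$dist_bp, abs(ld$position_b - ld$position_a))

  # NA R2 rows dropped with a reported count
  path2 <- write_lines_tmp(c(header, "chr1\t100\t1\tchr1\t200\t2\t100\tNA",
                             "chr1\t100\t1\tchr1\t300\t3\t200\t0.9"))
  expect_message(ld2 <- read_ld_table(path2), "1 row")
  expect_equal(nrow(ld2), 1L)
  expect_equal(attr(ld2, "n_dropped_na_r2"), 1L)

  # only inter-locus rows -> empty result with a warning
  path3 <- write_lines_tmp(c(header, "chr1\t100\t1\tchr2\t200\t2\t100\t0.9"))
  expect_warning(ld3 <- read_ld_table(path3), "no intra-locus")
  expect_equal(nrow(ld3), 0L)
})

test_that("GFF3 reader extracts gene rows and validates structure", {
  path <- write_lines_tmp(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t500\t.\t-\t.\tID=g1;Name=one",
    "chr1\tsrc\tmRNA\t100\t500\t.\t-\t.\tID=m1;Parent=g1",
    "chr1\tsrc\texon\t100\t200\t.\t-\t.\tParent=m1",
    "chr1\tsrc\texon\t300\t500\t.\t-\t.\tParent=m1",
    "chr2\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=g2",
    "chr2\tsrc\tmRNA\t1000\t2000\t.\t+\t.\tID=m2;Parent=g2",
    "chr2\tsrc\texon\t1000\t1500\t.\t+\t.\tParent=m2",
    "chr2\tsrc\texon\t1600\t2000\t.\t+\t.\tParent=m2"), ext = ".gff3")
  genes <- read_gene_annotations(path)
  expect_equal(genes$gene_id, c("g1", "g2"))
  # minus strand does not alter coordinates
  expect_equal(genes$start[1], 100L)
  expect_equal(genes$end[1], 500L)
  expect_equal(genes$strand[1], "-")

  # malformed line -> fatal with line number
  bad <- write_lines_tmp(c("chr1\tsrc\tgene\t100", "x"), ext = ".gff3")
  expect_error(read_gene_annotations(bad), "line 1")

  # gene without ID -> fatal
  noid <- write_lines_tmp("chr1\tsrc\tgene\t100\t500\t.\t+\t.\tName=only",
                          ext = ".gff3")
  expect_error(read_gene_annotations(noid), "no ID")
})

test_that("pathway reader groups lines, deduplicates, and flags short lines", {
  path <- write_lines_tmp(c(
    "PWY1\tfirst pathway\tgeneA",
    "PWY1\tfirst pathway\tgeneB",
    "PWY1\tfirst pathway\tgeneC",
    "PWY2\tsecond pathway\tgeneA",
    "PWY2\tsecond pathway\tgeneD"))
  pw <- read_pathway_sets(path, header = FALSE)
  expect_equal(length(unique(pw$pathway_id)), 2L)
  # the same gene may belong to two pathways
  expect_equal(sum(pw$gene_id == "geneA"), 2L)

  dup <- write_lines_tmp(c("PWY1\tp\tgeneA", "PWY1\tp\tgeneA", "PWY1\tp\tgeneB"))
  expect_warning(pw2 <- read_pathway_sets(dup, header = FALSE), "duplicated")
  expect_equal(nrow(pw2), 2L)

  short <- write_lines_tmp(c("PWY1\tp\tgeneA", "PWY1\tonlytwo"))
  expect_error(read_pathway_sets(short, header = FALSE), "line 2")
})

test_that("gzip-compressed inputs are read transparently", {
  lines <- c(stats_header, "t1\tM1\tchr1\t100\t0.01\t0.20")
  gz <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(gz, "wt")
  writeLines(lines, con)
  close(con)
  rows <- read_gwas_stats(gz, trait = "t1")
  expect_equal(rows$marker, "M1")
})

test_that("a written dataset round-trips through the readers field-for-field", {
  ds <- simulate_gwas_dataset(n_genes = 30, n_snps = 70, n_pathways = 4,
                              genes_per_pathway = 6, seed = 11)
  dir <- tempfile()
  paths <- write_gwas_dataset(ds, dir)
  stats2 <- read_gwas_stats(paths[["stats"]], trait = ds$manifest$trait)
  effects2 <- read_gwas_effects(paths[["effects"]], trait = ds$manifest$trait)
  ld2 <- read_ld_table(paths[["ld"]])
  genes2 <- read_gene_annotations(paths[["gff"]])
  pw2 <- read_pathway_sets(paths[["pathways"]])

  expect_equal(stats2$marker, ds$stats$marker)
  expect_equal(stats2$position, ds$stats$position)
  expect_equal(stats2$p_value, ds$stats$p_value, tolerance = 1e-12)
  expect_equal(stats2$marker_r2, ds$stats$marker_r2, tolerance = 1e-12)
  expect_equal(effects2$effect, ds$effects$effect, tolerance = 1e-12)
  expect_equal(ld2$ld_r2, ds$ld$ld_r2, tolerance = 1e-12)
  expect_equal(ld2$dist_bp, ds$ld$dist_bp)
  expect_equal(genes2, ds$genes)
  expect_equal(pw2, ds$pathways)

  # merged marker records survive the round trip too
  m1 <- merge_markers(ds$stats, ds$effects)
  m2 <- merge_markers(stats2, effects2)
  expect_equal(m1, m2, tolerance = 1e-12, ignore_attr = TRUE)
})
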