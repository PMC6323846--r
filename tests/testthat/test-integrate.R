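test_that("DEG selection uses a strict fold-change threshold", {
  expr <- tibble::tibble(gene_id = c("a", "b", "c"),
                         ratio = c(5.0, 5.1, 0.2))
  degs <- select_degs(expr)
  expect_equal(degs$gene_id, "b")
  expect_equal(nrow(select_degs(expr[0, ])), 0L)
  expect_error(select_degs(tibble::tibble(gene_id = "x", ratio = -1)))
})

test_that("set intersection returns Venn counts and membership", {
  v <- intersect_sets(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(unname(v$counts), c(1L, 1L, 2L))
  expect_equal(v$intersection, c("B", "C"))
  expect_equal(unname(intersect_sets(c("A"), c("B"))$counts), c(1L, 1L, 0L))
})

test_that("study-scale totals give the published Venn partition", {
  sc <- xlnr_study_counts()
  candidates <- sprintf("cand%04d", seq_len(sc$candidates))
  degs <- c(candidates[seq_len(sc$intersection)],
            sprintf("deg%04d", seq_len(sc$degs - sc$intersection)))
  v <- intersect_sets(candidates, degs)
  expect_equal(unname(v$counts), c(1897L, 21L, 51L))
})

test_that("Fisher p-values match closed-form enumerations", {
  f1 <- fisher_motif_presence(matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  expect_equal(f1$p_value, 1.0)
  f2 <- fisher_motif_presence(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_equal(f2$p_value, 2 / 252, tolerance = 1e-12)
  # degenerate margins: p = 1 by convention
  f3 <- fisher_motif_presence(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(f3$p_value, 1)
  # odds ratio is the sample odds ratio ad/bc
  f4 <- fisher_motif_presence(matrix(c(6, 2, 3, 4), 2, byrow = TRUE))
  expect_equal(f4$odds_ratio, 6 * 4 / (2 * 3))
  expect_true(is.infinite(
    fisher_motif_presence(matrix(c(3, 0, 1, 2), 2, byrow = TRUE))$odds_ratio))
})

test_that("the Fisher table is assembled from integration records", {
  rec <- tibble::tibble(
    gene_id = sprintf("g%d", 1:8),
    n_total = c(2L, 1L, 0L, 3L, 0L, 0L, 1L, 0L),
    in_intersection = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  f <- fisher_motif_presence(rec)
  expect_equal(unname(f$table), matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(f$row_percent, c(75, 25))
  expect_error(
    fisher_motif_presence(dplyr::mutate(rec, in_intersection = TRUE)),
    "non-empty")
})

test_that("correlations respect rank invariance and flag degenerate input", {
  rec <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20),
    ratio = exp(seq(0.1, 2, length.out = 20)),
    n_GGCTAA = 1:20,              # strictly increasing with ratio
    n_GGCTGA = rep(2L, 20)        # constant
  )
  res <- suppressWarnings(
    correlate_parameters(rec, parameters = c("n_GGCTAA", "n_GGCTGA")))
  expect_equal(res$spearman_rho[res$parameter == "n_GGCTAA"], 1)
  expect_true(is.na(res$spearman_rho[res$parameter == "n_GGCTGA"]))
  expect_warning(
    correlate_parameters(rec, parameters = c("n_GGCTGA")), "constant")
})

test_that("Spearman is transform-invariant while Pearson is not", {
  rec <- withr::with_seed(71, tibble::tibble(
    gene_id = sprintf("g%02d", 1:30),
    ratio = exp(rnorm(30, 1, 1)),
    n_GGCTAA = rbinom(30, 4, 0.5)
  ))
  log_res <- correlate_parameters(rec, "log", parameters = "n_GGCTAA")
  lin_res <- correlate_parameters(rec, "linear", parameters = "n_GGCTAA")
  expect_equal(log_res$spearman_rho, lin_res$spearman_rho)
  expect_false(isTRUE(all.equal(log_res$pearson_r, lin_res$pearson_r)))
})

test_that("tied-data Spearman agrees with the brute-force rank oracle", {
  for (i in 1:50) {
    d <- withr::with_seed(500 + i, tibble::tibble(
      gene_id = sprintf("g%02d", 1:20),
      ratio = exp(rnorm(20)),
      x = as.numeric(sample(0:3, 20, replace = TRUE))  # heavy ties
    ))
    res <- correlate_parameters(d, parameters = "x")
    expect_equal(res$spearman_rho, oracle_spearman(d$x, log(d$ratio)),
                 tolerance = 1e-12)
  }
})

test_that("integration records join counts, expression and best peak hit", {
  counts <- tibble::tibble(
    gene_id = c("a", "b"), n_GGCTAA = c(1L, 0L), n_GGCTGA = c(1L, 0L),
    n_GGCTAG = c(0L, 0L), n_monomer = 0L, n_dimer = 0L,
    n_total = c(2L, 0L), coex_GA_AA = c(TRUE, FALSE),
    coex_AA_AG = FALSE, coex_GA_AG = FALSE)
  expr <- tibble::tibble(gene_id = c("a", "b"), ratio = c(8, 1.2))
  hits <- tibble::tibble(window_id = c("w1", "w2"), gene_id = "a",
                         match_len = 50L, identity = 1,
                         orientation = "+", p_start = c(100L, 300L),
                         peak_rank = c(2L, 1L),
                         fold_enrichment = c(4, 9))
  g <- toy_genome()
  prom <- build_upstream1000(g)
  prom <- prom[prom$gene_id == "gplus", ]
  prom$gene_id <- "a"
  peaks <- tibble::tibble(contig = "chr1", start = c(4390L, 4090L),
                          end = c(4490L, 4190L), summit = c(4440L, 4140L),
                          fold_enrichment = c(9, 4), p_value = 1e-8,
                          rank = c(1L, 2L))
  rec <- build_integration_table(counts, expr, hits = hits, peaks = peaks,
                                 promoters = prom, degs = c("a"))
  a <- rec[rec$gene_id == "a", ]
  # duplicate hits collapse to the largest fold enrichment
  expect_equal(a$fold_enrichment, 9)
  expect_equal(a$P, 441L)        # summit 4440 in promoter [4000, 5000)
  expect_true(a$is_candidate)
  expect_true(a$in_intersection)
  b <- rec[rec$gene_id == "b", ]
  expect_true(is.na(b$fold_enrichment))
  expect_false(b$is_candidate)
})
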