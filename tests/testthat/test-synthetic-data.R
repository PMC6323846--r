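test_that("genome layout honours the 1000-bp upstream constraint", {
  g <- sim_genome(n_genes = 1, contig_length = 3000, seed = 7)
  expect_equal(nrow(g$genes), 1L)
  expect_gte(g$genes$start, 1000L)
  # start codon written into the sequence (reverse-complemented on -)
  s <- g$genes$start
  codon <- if (g$genes$strand == "+") {
    substr(as.character(g$contigs[[1]]), s + 1, s + 3)
  } else {
    substr(as.character(g$contigs[[1]]), s - 1, s + 1)
  }
  expect_equal(codon, if (g$genes$strand == "+") "ATG" else "CAT")
  expect_error(sim_genome(5, 3000), "too short")
})

test_that("genome generation is deterministic per seed", {
  g1 <- sim_genome(5, 20000, seed = 3)
  g2 <- sim_genome(5, 20000, seed = 3)
  expect_identical(as.character(g1$contigs), as.character(g2$contigs))
  expect_identical(g1$genes, g2$genes)
  g3 <- sim_genome(5, 20000, seed = 4)
  expect_false(identical(as.character(g1$contigs), as.character(g3$contigs)))
})

test_that("background base composition is uniform within binomial bounds", {
  g <- sim_genome(20, 50000, seed = 1)
  comp <- Biostrings::alphabetFrequency(g$contigs[[1]])[c("A", "C", "G", "T")]
  p <- comp / 50000
  tol <- 4 * sqrt(0.25 * 0.75 / 50000)
  expect_true(all(abs(p - 0.25) < tol))
})

test_that("planted motifs are found where they were written", {
  g <- sim_genome(2, 10000, seed = 2)
  plan <- tibble::tibble(gene_id = g$genes$gene_id[1],
                         motif_id = "GGCTAA", pos = 500L, strand = "+")
  out <- plant_motifs(g, plan, seed = 2)
  prom <- build_upstream1000(out$genome)
  pseq <- prom$seq[prom$gene_id == plan$gene_id]
  expect_equal(substr(pseq, 500, 505), "GGCTAA")
  hits <- scan_iupac(pseq, "GGCTAA")
  expect_true(499L %in% hits$position[hits$strand == "+"])
  expect_equal(out$truth$realization, "GGCTAA")
})

test_that("minus-strand plants appear as the reverse complement", {
  g <- sim_genome(2, 10000, seed = 5)
  plan <- tibble::tibble(gene_id = g$genes$gene_id[1],
                         motif_id = "GGCTAA", pos = 300L, strand = "-")
  out <- plant_motifs(g, plan, seed = 5)
  prom <- build_upstream1000(out$genome)
  pseq <- prom$seq[prom$gene_id == plan$gene_id]
  expect_equal(substr(pseq, 300, 305), "TTAGCC")
})

test_that("degenerate plants realize their IUPAC pattern", {
  g <- sim_genome(1, 5000, seed = 6)
  plan <- tibble::tibble(gene_id = g$genes$gene_id, motif_id = "CGGNTAAW",
                         pos = 100L, strand = "+")
  out <- plant_motifs(g, plan, seed = 6)
  written <- out$truth$realization
  expect_equal(nchar(written), 8L)
  expect_equal(length(oracle_scan_positions(written, "CGGNTAAW")), 1L)
  prom <- build_upstream1000(out$genome)
  expect_equal(substr(prom$seq, 100, 107), written)
})

test_that("conflicting overlapping plants raise an error", {
  g <- sim_genome(1, 5000, seed = 8)
  plan <- tibble::tibble(gene_id = g$genes$gene_id,
                         motif_id = c("GGCTAA", "GGCTGA"),
                         pos = c(500L, 503L), strand = "+")
  expect_error(plant_motifs(g, plan, seed = 8), "conflict")
  expect_error(
    plant_motifs(g, tibble::tibble(gene_id = g$genes$gene_id,
                                   motif_id = "GGCTAA", pos = 998L,
                                   strand = "+"), seed = 8),
    "does not fit")
})

test_that("planting is never lost: rescanned counts >= planted counts", {
  g <- sim_genome(20, 50000, seed = 9)
  plan <- random_plant_plan(g, seed = 9)
  out <- plant_motifs(g, plan, seed = 9)
  counts <- count_motifs(build_upstream1000(out$genome))
  planted <- dplyr::count(dplyr::filter(plan, motif_id == "GGCTAA"), gene_id)
  for (i in seq_len(nrow(planted))) {
    expect_gte(counts$n_GGCTAA[counts$gene_id == planted$gene_id[i]],
               planted$n[i])
  }
})

test_that("expression is an exact function of counts when sigma = 0", {
  counts <- tibble::tibble(gene_id = c("a", "b"),
                           n_GGCTAA = c(3L, 0L), n_GGCTGA = c(0L, 1L),
                           n_GGCTAG = c(0L, 0L))
  # all effects zero: ratio = exp(beta0) everywhere
  e0 <- sim_expression(counts, effect_model(beta0 = 0.7, beta_aa = 0,
                                            beta_ga = 0, beta_ag = 0,
                                            beta_coex = 0, sigma = 0))
  expect_equal(e0$ratio, rep(exp(0.7), 2))
  # nAA = 3 with beta_aa = ln 2 gives ratio 8
  e1 <- sim_expression(counts, effect_model(beta0 = 0, beta_aa = log(2),
                                            beta_ga = 0, beta_ag = 0,
                                            beta_coex = 0, sigma = 0))
  expect_equal(e1$ratio[1], 8)
  expect_equal(e1$ratio[2], 1)
  # coexistence term fires only when both AA and GA are present
  e2 <- sim_expression(
    tibble::tibble(gene_id = c("x", "y"), n_GGCTAA = c(1L, 1L),
                   n_GGCTGA = c(1L, 0L), n_GGCTAG = 0L),
    effect_model(beta0 = 0, beta_aa = 0, beta_ga = 0, beta_ag = 0,
                 beta_coex = 1, sigma = 0))
  expect_equal(e2$ratio, c(exp(1), 1))
})

test_that("motif totals correlate positively with noisy expression", {
  hits <- 0L
  for (s in 1:100) {
    counts <- withr::with_seed(1000 + s, tibble::tibble(
      gene_id = sprintf("g%02d", 1:72),
      n_GGCTAA = rbinom(72, 2, 0.4), n_GGCTGA = rbinom(72, 2, 0.4),
      n_GGCTAG = rbinom(72, 2, 0.2)))
    expr <- sim_expression(counts, effect_model(), seed = s)
    total <- counts$n_GGCTAA + counts$n_GGCTGA + counts$n_GGCTAG
    rho <- suppressWarnings(cor(total, expr$ratio, method = "spearman"))
    hits <- hits + (rho > 0)
  }
  expect_gte(hits, 95L)
})

test_that("fragment library matches its genomic coordinates", {
  g <- sim_genome(4, 20000, seed = 3)
  lib <- build_library(g, n_fragments = 1e4, mean_len = 100, sd_len = 15,
                       seed = 3)
  lens <- nchar(lib$fragments$insert)
  expect_equal(lens, lib$fragments$end - lib$fragments$start)
  expect_lt(abs(mean(lens) - 100), 1)          # CLT bound at n = 1e4
  expect_true(all(lens >= 30 & lens <= 300))
  contig <- as.character(g$contigs[[1]])
  idx <- withr::with_seed(1, sample(nrow(lib$fragments), 100))
  for (i in idx) {
    fr <- lib$fragments[i, ]
    ref <- substr(contig, fr$start + 1, fr$end)
    expected <- if (fr$strand == "+") ref else gselexmine:::dna_revcomp(ref)
    expect_equal(fr$insert, expected)
  }
  expect_equal(nrow(build_library(g, 1, seed = 1)$fragments), 1L)
  expect_error(build_library(g, 0), "positive")
})

test_that("simulation artifacts are byte-identical across equal seeds", {
  run <- function(dir) {
    g <- sim_genome(3, 15000, seed = 21)
    plan <- random_plant_plan(g, seed = 21)
    out <- plant_motifs(g, plan, seed = 21)
    counts <- count_motifs(build_upstream1000(out$genome))
    expr <- sim_expression(counts, seed = 21)
    lib <- build_library(out$genome, 200, seed = 21)
    write_simulation(out$genome, dir, expression = expr, truth = out$truth,
                     library = lib)
    dir
  }
  d1 <- run(withr::local_tempdir())
  d2 <- run(withr::local_tempdir())
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), info = f)
  }
})
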