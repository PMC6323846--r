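L5 <- gselexmine:::LINKER_5P
L3 <- gselexmine:::LINKER_3P

test_that("adapter trimming removes full and partial matches only", {
  insert <- strrep("ACGT", 15)
  reads <- tibble::tibble(
    read_id = c("full", "none", "short3p"),
    seq = c(paste0(L5, insert),                 # full 5' adapter
            insert,                             # no adapter
            paste0(insert, substr(L3, 1, 14)))  # 14 nt < min_overlap
  )
  out <- trim_adapters(reads, five_prime = L5, three_prime = L3)
  expect_equal(out$seq[1], insert)
  expect_equal(out$seq[2], insert)
  expect_equal(out$seq[3], paste0(insert, substr(L3, 1, 14)))
  # a 15-nt 3' adapter prefix is removed
  out2 <- trim_adapters(tibble::tibble(seq = paste0(insert,
                                                    substr(L3, 1, 15))),
                        five_prime = L5, three_prime = L3)
  expect_equal(out2$seq, insert)
  # reads shorter than min_length after trimming are flagged
  out3 <- trim_adapters(tibble::tibble(seq = paste0(L5, "ACGTACGT")),
                        five_prime = L5, three_prime = L3)
  expect_false(out3$kept)
  expect_error(trim_adapters(reads), "adapter")
})

test_that("mapping places unique reads and drops ambiguous ones", {
  contig <- withr::with_seed(51, random_seq(5000))
  dup <- substr(contig, 3001, 3040)
  substr(contig, 4001, 4040) <- dup           # duplicated 40-mer
  genome <- genome_model(
    c(chr1 = contig),
    tibble::tibble(gene_id = "g1", contig = "chr1", strand = "+",
                   start = 2000L))
  unique_read <- substr(contig, 1001, 1050)   # genome[1000, 1050)
  tags <- map_reads(tibble::tibble(read_id = "r1", seq = unique_read),
                    genome = genome)
  expect_equal(nrow(tags), 1L)
  expect_equal(tags$start, 1000L)
  expect_equal(tags$end, 1050L)
  expect_equal(tags$strand, "+")
  # reverse-complement read maps to the minus strand, same interval
  tags_rc <- map_reads(
    tibble::tibble(read_id = "r1",
                   seq = gselexmine:::dna_revcomp(unique_read)),
    genome = genome)
  expect_equal(tags_rc$start, 1000L)
  expect_equal(tags_rc$strand, "-")
  # ambiguous read (two loci) is discarded
  amb <- map_reads(tibble::tibble(read_id = "r2", seq = dup),
                   genome = genome)
  expect_equal(nrow(amb), 0L)
})

test_that("error-free reads round-trip through trim and map", {
  g <- sim_genome(4, 20000, seed = 52)
  lib <- build_library(g, 400, seed = 52)
  sel <- run_selection(lib, rounds = 1, pool_size = 2000, seed = 52)
  reads <- emit_reads(sel, lib, n_pairs = 1000, substitution_rate = 0,
                      seed = 52)
  t1 <- trim_adapters(reads$read1, five_prime = lib$linker_5p,
                      three_prime = lib$linker_3p)
  t2 <- trim_adapters(reads$read2,
                      five_prime = gselexmine:::dna_revcomp(lib$linker_3p),
                      three_prime = gselexmine:::dna_revcomp(lib$linker_5p))
  tags <- map_reads(t1, t2, g)
  expect_gt(sum(tags$paired), 900)
  # every concordant tag is a true fragment interval
  frag_keys <- paste(lib$fragments$contig, lib$fragments$start,
                     lib$fragments$end)
  merged <- tags[tags$paired, ]
  expect_true(all(paste(merged$contig, merged$start, merged$end)
                  %in% frag_keys))
})

test_that("the peak caller is silent when selected equals control", {
  tags <- withr::with_seed(53, tibble::tibble(
    contig = "chr1",
    start = sample(0:19950, 3000, replace = TRUE)))
  tags$end <- tags$start + 50L
  tags$strand <- "+"
  genome <- genome_model(
    c(chr1 = withr::with_seed(53, random_seq(20000))),
    tibble::tibble(gene_id = "g", contig = "chr1", strand = "+",
                   start = 10000L))
  peaks <- call_peaks(tags, tags, genome)
  expect_equal(nrow(peaks), 0L)
  expect_error(call_peaks(tags, tags[0, ], genome), "control")
})

test_that("a planted enriched region yields one peak with accurate FE", {
  contig_len <- 10000L
  region <- c(4000L, 4200L)
  genome <- genome_model(
    c(chr1 = withr::with_seed(54, random_seq(contig_len))),
    tibble::tibble(gene_id = "g", contig = "chr1", strand = "+",
                   start = 9000L))
  draw_tags <- function(n, w_region) {
    starts <- 0:(contig_len - 50L)
    w <- rep(1, length(starts))
    w[starts >= region[1] & starts < region[2]] <- w_region
    s <- sample(starts, n, replace = TRUE, prob = w)
    tibble::tibble(contig = "chr1", start = s, end = s + 50L, strand = "+")
  }
  withr::with_seed(54, {
    sel <- draw_tags(1e5, 10)
    ctl <- draw_tags(1e5, 1)
  })
  peaks <- call_peaks(sel, ctl, genome)
  expect_equal(nrow(peaks), 1L)
  expect_lt(peaks$start, region[2])
  expect_gt(peaks$end, region[1])
  expect_gte(peaks$summit, peaks$start)
  expect_lt(peaks$summit, peaks$end)
  # the planted density ratio is 10; sampling concentrates mass in the
  # region, so the measured FE must sit within +/-30% of it
  expect_lt(abs(peaks$fold_enrichment - 10) / 10, 0.3)
  expect_equal(peaks$rank, 1L)
})

test_that("summit windows follow the flank arithmetic and clip at ends", {
  genome <- genome_model(
    c(chr1 = withr::with_seed(55, random_seq(1000))),
    tibble::tibble(gene_id = "g", contig = "chr1", strand = "+",
                   start = 500L))
  peaks <- tibble::tibble(contig = "chr1", start = c(50L, 0L),
                          end = c(150L, 40L), summit = c(100L, 10L),
                          fold_enrichment = c(5, 4), p_value = 1e-9,
                          rank = c(1L, 2L))
  win <- extract_windows(peaks, genome)
  expect_equal(win$start[1], 76L)
  expect_equal(win$end[1], 126L)
  expect_equal(nchar(win$seq[1]), 50L)
  expect_false(win$clipped[1])
  expect_equal(win$seq[1],
               substr(as.character(genome$contigs[[1]]), 77, 126))
  # summit 10 bp from the contig start: clipped and flagged
  expect_true(win$clipped[2])
  expect_equal(win$start[2], 0L)
  # degenerate 1-bp window is permitted
  win1 <- extract_windows(peaks[1, ], genome, flank_left = 0,
                          flank_right = 0)
  expect_equal(win1$end - win1$start, 1L)
})
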