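# End-to-end pipeline: simulate -> select -> sequence -> trim/map/peaks ->
# annotate -> count -> integrate, with deterministic named sub-streams.

#' Run the full gSELEX-Seq + expression-mining pipeline on synthetic data
#'
#' Generates a genome with planted regulated promoters, runs affinity
#' selection and paired-end sequencing of the final round, processes the
#' reads into ranked peaks and summit windows, annotates the windows against
#' the upstream-1000 promoter set, and mines motif counts, fold enrichment
#' and summit positions against the synthetic expression table. The round-0
#' library intervals serve as the peak-calling control.
#'
#' @param n_genes,contig_length,n_contigs Genome layout (see
#'   [sim_genome()]).
#' @param n_regulated Number of promoters planted with high-affinity motif
#'   sites (at least one GGCTAA each).
#' @param n_fragments,mean_len Library size and mean insert length.
#' @param pool_size,rounds Selection pool size and number of rounds.
#' @param n_read_pairs,read_len,substitution_rate Sequencing of the final
#'   round.
#' @param affinity An [affinity_model()].
#' @param effects An [effect_model()].
#' @param deg_threshold DEG fold-change threshold (strict).
#' @param top_n_windows Number of top-ranked windows fed to
#'   [kmer_enrichment()].
#' @param seed Top-level seed; every stage derives its own sub-stream.
#' @param out_dir Optional directory; when given, all artifacts are written
#'   via [write_report()].
#' @return A `gselex_report`: list with the simulation truth and every
#'   stage's output (enrichment curve, peaks, windows, hits, candidate gene
#'   ids, DEG set, Venn counts, integration records, Fisher result,
#'   correlation table, k-mer ranking, and the parameters used).
#' @export
run_pipeline <- function(n_genes = 20, contig_length = 50000, n_contigs = 1,
                         n_regulated = 5, n_fragments = 5e4, mean_len = 100,
                         pool_size = 1e5, rounds = 3, n_read_pairs = 2e4,
                         read_len = 75, substitution_rate = 0.001,
                         affinity = affinity_model(),
                         effects = effect_model(), deg_threshold = 5,
                         top_n_windows = 100, seed = 1, out_dir = NULL) {
  genome <- sim_genome(n_genes, contig_length, n_contigs, seed = seed)
  regulated <- with_substream(seed, "regulated",
                              sample(genome$genes$gene_id, n_regulated))
  plan <- random_plant_plan(genome, gene_ids = regulated,
                            ensure_ggctaa = TRUE, seed = seed)
  planted <- plant_motifs(genome, plan, seed = seed)
  genome <- planted$genome
  promoters <- build_upstream1000(genome)
  counts <- count_motifs(promoters)
  expr <- sim_expression(counts, effects, seed = seed)

  library <- build_library(genome, n_fragments, mean_len = mean_len,
                           seed = seed)
  weights <- library_weights(library, genome, affinity)
  sel <- run_selection(library, affinity, rounds = rounds,
                       pool_size = pool_size, weights = weights, seed = seed)
  curve <- relative_binding(sel)
  reads <- emit_reads(sel, library, read_len = read_len,
                      n_pairs = n_read_pairs,
                      substitution_rate = substitution_rate, seed = seed)
  t1 <- trim_adapters(reads$read1, five_prime = library$linker_5p,
                      three_prime = library$linker_3p)
  t2 <- trim_adapters(reads$read2,
                      five_prime = dna_revcomp(library$linker_3p),
                      three_prime = dna_revcomp(library$linker_5p))
  tags <- map_reads(t1, t2, genome)
  control <- dplyr::mutate(
    dplyr::select(library$fragments, "contig", "start", "end", "strand"),
    paired = TRUE)
  peaks <- call_peaks(tags, control, genome)
  windows <- extract_windows(peaks, genome)
  hits <- assign_windows(windows, promoters)
  candidates <- unique(hits$gene_id)

  kmer <- if (nrow(windows) > 0) {
    kmer_enrichment(utils::head(windows$seq[order(windows$peak_rank)],
                                top_n_windows),
                    background = library$fragments$insert)
  } else NULL

  degs <- select_degs(expr, threshold = deg_threshold)
  venn <- intersect_sets(candidates, degs)
  records <- build_integration_table(counts, expr, hits = hits,
                                     peaks = peaks, promoters = promoters,
                                     degs = degs)
  deg_records <- records[records$gene_id %in% degs$gene_id, ]
  fisher <- tryCatch(fisher_motif_presence(deg_records),
                     error = function(e) NULL)
  correlations <- if (nrow(deg_records) >= 3) {
    suppressWarnings(correlate_parameters(deg_records))
  } else NULL

  report <- structure(list(
    genome = genome, truth = planted$truth, regulated = sort(regulated),
    promoters = promoters, counts = counts, expression = expr,
    library_size = n_fragments, enrichment_curve = curve,
    n_tags = nrow(tags), peaks = peaks, windows = windows, hits = hits,
    candidates = sort(candidates), degs = degs, venn = venn,
    records = records, fisher = fisher, correlations = correlations,
    kmer = kmer,
    params = list(n_genes = n_genes, contig_length = contig_length,
                  n_regulated = n_regulated, n_fragments = n_fragments,
                  pool_size = pool_size, rounds = rounds,
                  n_read_pairs = n_read_pairs, read_len = read_len,
                  substitution_rate = substitution_rate,
                  deg_threshold = deg_threshold,
                  top_n_windows = top_n_windows, seed = seed)
  ), class = "gselex_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.gselex_report <- function(x, ...) {
  cat("<gselex_report> seed ", x$params$seed, "\n", sep = "")
  cat("  genes: ", nrow(x$genome$genes), " (", length(x$regulated),
      " regulated); peaks: ", nrow(x$peaks), "; candidate promoters: ",
      length(x$candidates), "\n", sep = "")
  cat("  DEGs (> ", x$params$deg_threshold, "-fold): ", nrow(x$degs),
      "; intersection: ", x$venn$counts[["intersection"]], "\n", sep = "")
  recall <- mean(x$regulated %in% x$candidates)
  cat(sprintf("  planted-promoter recall: %.0f%%\n", 100 * recall))
  if (!is.null(x$kmer)) {
    cat("  top k-mer: ", x$kmer$kmer[1], "\n", sep = "")
  }
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Emits the simulation FASTA/TSV files, peaks (BED6 with score = fold
#' enrichment x 100, rounded, and a full TSV), summit windows (BED and
#' FASTA), hits, integration records, correlation and k-mer tables, the
#' enrichment curve, and a machine-readable JSON summary.
#'
#' @param report A `gselex_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_simulation(report$genome, out_dir, expression = report$expression,
                   truth = report$truth)
  pk <- report$peaks
  bed <- tibble::tibble(chrom = pk$contig, start = pk$start, end = pk$end,
                        name = sprintf("peak%04d", pk$rank),
                        score = round(pk$fold_enrichment * 100),
                        strand = ".")
  readr::write_tsv(bed, file.path(out_dir, "peaks.bed"), col_names = FALSE)
  readr::write_tsv(pk, file.path(out_dir, "peaks.tsv"))
  wn <- report$windows
  readr::write_tsv(tibble::tibble(chrom = wn$contig, start = wn$start,
                                  end = wn$end, name = wn$window_id,
                                  score = round(wn$fold_enrichment * 100),
                                  strand = "."),
                   file.path(out_dir, "windows.bed"), col_names = FALSE)
  if (nrow(wn) > 0) {
    fa <- Biostrings::DNAStringSet(wn$seq)
    names(fa) <- wn$window_id
    Biostrings::writeXStringSet(fa, file.path(out_dir, "windows.fa"))
  }
  readr::write_tsv(report$hits, file.path(out_dir, "hits.tsv"))
  readr::write_tsv(report$records, file.path(out_dir, "integration.tsv"))
  readr::write_tsv(report$enrichment_curve,
                   file.path(out_dir, "enrichment_curve.tsv"))
  if (!is.null(report$correlations)) {
    readr::write_tsv(report$correlations,
                     file.path(out_dir, "correlations.tsv"))
  }
  if (!is.null(report$kmer)) {
    readr::write_tsv(report$kmer, file.path(out_dir, "kmer_ranking.tsv"))
  }
  summary <- list(
    seed = report$params$seed,
    n_peaks = nrow(report$peaks),
    n_candidates = length(report$candidates),
    n_degs = nrow(report$degs),
    venn = as.list(report$venn$counts),
    planted_recall = mean(report$regulated %in% report$candidates),
    fisher_p = if (!is.null(report$fisher)) report$fisher$p_value else NA,
    top_kmer = if (!is.null(report$kmer)) report$kmer$kmer[1] else NA
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Simulate a planted regulon for correlation-structure studies
#'
#' Convenience generator for mining studies without the sequencing stages: a
#' genome whose promoters all receive binomially distributed canonical motif
#' sites, the measured motif counts, and an expression table drawn from the
#' effect model. Mirrors the scale of the published DEG set (72 genes) by
#' default.
#'
#' @param n_genes Number of genes.
#' @param effects An [effect_model()].
#' @param contig_length Genome contig length (default sized so that adjacent
#'   promoters never overlap).
#' @param seed Top-level seed.
#' @return A list: `genome`, `truth`, `promoters`, `counts`, `expression`,
#'   `records` (integration table without peak columns).
#' @export
sim_regulon <- function(n_genes = 72, effects = effect_model(),
                        contig_length = NULL, seed = 1) {
  if (is.null(contig_length)) contig_length <- 2200 * n_genes + 2200
  genome <- sim_genome(n_genes, contig_length, seed = seed)
  plan <- random_plant_plan(genome, seed = seed)
  planted <- plant_motifs(genome, plan, seed = seed)
  promoters <- build_upstream1000(planted$genome)
  counts <- count_motifs(promoters)
  expr <- sim_expression(counts, effects, seed = seed)
  records <- build_integration_table(counts, expr)
  list(genome = planted$genome, truth = planted$truth,
       promoters = promoters, counts = counts, expression = expr,
       records = records)
}
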