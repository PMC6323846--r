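# Affinity-weighted in vitro selection model and paired-end read emission.
#
# Selection and PCR re-amplification are collapsed into one multinomial
# draw per round: round k draws pool_size fragments with probability
# proportional to (previous-round abundance x fragment binding weight).
# Occupancy is linear in motif count (no saturation).

#' Fragment binding-affinity model
#'
#' Per-fragment binding weight is `background + sum(w_m * n_m)` over the
#' registry motifs, where `n_m` is the both-strand occurrence count of motif
#' `m` in the insert. Default weights are synthetic; only their ordering
#' (GGCTAA stronger than GGCTGA) reflects the measured affinity ordering of
#' the XlnR hexamer variants.
#'
#' @param background Background weight `b > 0` (arbitrary units).
#' @param GGCTAA,GGCTGA,GGCTAG,CGGNTAAW,TTAGSCTAA Per-occurrence motif
#'   weights (>= 0).
#' @return An `affinity_model` list.
#' @export
affinity_model <- function(background = 1, GGCTAA = 50, GGCTGA = 25,
                           GGCTAG = 10, CGGNTAAW = 25, TTAGSCTAA = 0) {
  w <- c(GGCTAA = GGCTAA, GGCTGA = GGCTGA, GGCTAG = GGCTAG,
         CGGNTAAW = CGGNTAAW, TTAGSCTAA = TTAGSCTAA)
  stopifnot(background > 0, all(w >= 0))
  structure(list(background = background, weights = w),
            class = "affinity_model")
}

#' Binding weight of fragment sequences
#'
#' @param seqs Character vector or `DNAStringSet` of insert sequences.
#' @param model An [affinity_model()].
#' @return Numeric weights, `background + sum_m w_m * count_m(seq)`.
#' @export
#' @examples
#' fragment_weight("AAGGCTAATT", affinity_model())
fragment_weight <- function(seqs, model = affinity_model()) {
  stopifnot(inherits(model, "affinity_model"))
  registry <- xlnr_motifs()
  set <- if (methods::is(seqs, "DNAStringSet")) seqs else
    Biostrings::DNAStringSet(as.character(seqs))
  w <- rep(model$background, length(set))
  for (i in seq_len(nrow(registry))) {
    wm <- model$weights[[registry$motif_id[i]]]
    if (wm == 0) next
    w <- w + wm * count_pattern(set, registry$pattern[i], both_strands = TRUE)
  }
  w
}

# Fast equivalent of fragment_weight() for a whole library: scan the genome
# once per motif and count motif sites fully inside each fragment interval.
# Both-strand counts are strand-symmetric, so counting on the genome forward
# strand equals counting on the (possibly reverse-complemented) insert.
library_weights <- function(library, genome, model = affinity_model()) {
  frags <- library$fragments
  registry <- xlnr_motifs()
  w <- rep(model$background, nrow(frags))
  for (cname in unique(frags$contig)) {
    idx <- which(frags$contig == cname)
    frag_rng <- IRanges::IRanges(start = frags$start[idx] + 1L,
                                 end = frags$end[idx])
    subject <- genome$contigs[[cname]]
    for (i in seq_len(nrow(registry))) {
      wm <- model$weights[[registry$motif_id[i]]]
      if (wm == 0) next
      pat <- registry$pattern[i]
      site_starts <- integer(0)
      site_width <- nchar(pat)
      for (p in unique(c(pat, dna_revcomp(pat)))) {
        m <- Biostrings::matchPattern(p, subject, fixed = "subject")
        site_starts <- c(site_starts, IRanges::start(m))
      }
      if (length(site_starts) == 0) next
      sites <- IRanges::IRanges(start = site_starts, width = site_width)
      w[idx] <- w[idx] +
        wm * IRanges::countOverlaps(frag_rng, sites, type = "any",
                                    minoverlap = site_width)
    }
  }
  w
}

#' Run multi-round affinity selection
#'
#' Each round draws `pool_size` fragments by multinomial sampling with
#' probability proportional to previous-round abundance times fragment
#' binding weight; the drawn multiset is the next round's pool
#' (re-amplification to `pool_size` is implicit in the draw). Round 0 is the
#' input library with abundance 1 per fragment.
#'
#' @param library A `fragment_library`.
#' @param model An [affinity_model()].
#' @param rounds Number of selection rounds (>= 1; the study used 3).
#' @param pool_size Pool size N per round.
#' @param weights Optional precomputed fragment weights (see
#'   [fragment_weight()]); computed from the inserts if `NULL`.
#' @param seed Top-level seed (sub-stream `"selection"`).
#' @return A `selex_rounds` object: list with `abundance` (integer matrix,
#'   fragments x rounds 0..R), `weights`, and `pool_size`.
#' @export
run_selection <- function(library, model = affinity_model(), rounds = 3,
                          pool_size = 1e5, weights = NULL, seed = 1) {
  if (rounds < 1) stop("rounds must be >= 1", call. = FALSE)
  if (pool_size < 1) stop("pool_size must be >= 1", call. = FALSE)
  n <- nrow(library$fragments)
  if (is.null(weights)) weights <- fragment_weight(library$fragments$insert,
                                                   model)
  stopifnot(length(weights) == n)
  if (all(weights == 0)) stop("degenerate model: all weights zero",
                              call. = FALSE)
  ab <- matrix(0L, nrow = n, ncol = rounds + 1,
               dimnames = list(library$fragments$fragment_id,
                               paste0("round", 0:rounds)))
  ab[, 1] <- 1L
  with_substream(seed, "selection", {
    for (k in seq_len(rounds)) {
      p <- as.numeric(ab[, k]) * weights
      ab[, k + 1] <- as.integer(rmultinom(1, pool_size, prob = p))
    }
  })
  structure(list(abundance = ab, weights = weights, pool_size = pool_size),
            class = "selex_rounds")
}

#' @export
print.selex_rounds <- function(x, ...) {
  cat("<selex_rounds> ", nrow(x$abundance), " fragments, rounds 0..",
      ncol(x$abundance) - 1L, ", pool size ", x$pool_size, "\n", sep = "")
  invisible(x)
}

#' Round-0-normalized relative binding of the selected pools
#'
#' The readout of the bead-display enrichment monitor: the mean pool binding
#' weight of each round, normalized so that round 0 equals exactly 1.
#'
#' @param rounds A `selex_rounds` object.
#' @return A tibble with `round` and `relative_binding` (round 0 == 1).
#' @export
relative_binding <- function(rounds) {
  stopifnot(inherits(rounds, "selex_rounds"))
  ab <- rounds$abundance
  mean_w <- colSums(ab * rounds$weights) / colSums(ab)
  tibble::tibble(round = seq_len(ncol(ab)) - 1L,
                 relative_binding = as.numeric(mean_w / mean_w[1]))
}

#' Emit paired-end reads from a selected pool
#'
#' Fragments are sampled proportionally to their abundance in the chosen
#' round. The sequenced template is `5' linker + insert + 3' linker`;
#' read 1 is its prefix and read 2 the prefix of its reverse complement,
#' both of length `read_len` (shorter if the template is shorter). Each base
#' is substituted with probability `substitution_rate` (uniform over the
#' three other bases); the quality string is flat.
#'
#' @param rounds A `selex_rounds` object.
#' @param library The `fragment_library` the pool was selected from.
#' @param round Which round to sequence (default: the last).
#' @param read_len Read length in bp.
#' @param n_pairs Number of read pairs (0 gives empty, valid output).
#' @param substitution_rate Per-base substitution probability.
#' @param seed Top-level seed (sub-stream `"reads"`).
#' @return A list with `read1` and `read2` tibbles (`read_id`, `seq`,
#'   `qual`, and the source `fragment_id` as simulation truth).
#' @export
emit_reads <- function(rounds, library, round = NULL, read_len = 75,
                       n_pairs = 1e4, substitution_rate = 0.001, seed = 1) {
  stopifnot(inherits(rounds, "selex_rounds"))
  if (is.null(round)) round <- ncol(rounds$abundance) - 1L
  ab <- rounds$abundance[, round + 1L]
  if (sum(ab) == 0) stop("round ", round, " pool is empty", call. = FALSE)
  if (n_pairs < 0) stop("n_pairs must be >= 0", call. = FALSE)
  with_substream(seed, "reads", {
    idx <- if (n_pairs == 0) integer(0) else
      sample.int(length(ab), n_pairs, replace = TRUE, prob = ab)
    template <- paste0(library$linker_5p, library$fragments$insert[idx],
                       library$linker_3p)
    r1 <- substr(template, 1, read_len)
    rc <- dna_revcomp(template)
    r2 <- substr(rc, 1, read_len)
    add_errors <- function(x) {
      if (substitution_rate <= 0 || length(x) == 0) return(x)
      nsub <- rbinom(length(x), nchar(x), substitution_rate)
      for (i in which(nsub > 0)) {
        pos <- sample.int(nchar(x[i]), nsub[i])
        for (p in pos) {
          orig <- substr(x[i], p, p)
          substr(x[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), orig), 1)
        }
      }
      x
    }
    r1 <- add_errors(r1)
    r2 <- add_errors(r2)
    ids <- sprintf("read%06d", seq_along(idx))
    list(
      read1 = tibble::tibble(read_id = ids, seq = r1,
                             qual = strrep("I", nchar(r1)),
                             fragment_id = library$fragments$fragment_id[idx]),
      read2 = tibble::tibble(read_id = ids, seq = r2,
                             qual = strrep("I", nchar(r2)),
                             fragment_id = library$fragments$fragment_id[idx])
    )
  })
}

#' Write reads to a FASTQ file
#'
#' @param reads A read tibble from [emit_reads()] (`read_id`, `seq`, `qual`).
#' @param path Output path (plain text FASTQ).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq,
                           "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ path.
#' @return A tibble with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(tibble::tibble(read_id = character(0), seq = character(0),
                          qual = character(0)))
  }
  stopifnot(length(lines) %% 4 == 0)
  i <- seq(1, length(lines), by = 4)
  tibble::tibble(read_id = sub("^@", "", lines[i]), seq = lines[i + 1],
                 qual = lines[i + 3])
}
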