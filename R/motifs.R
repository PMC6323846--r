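# IUPAC motif scanning and k-mer over-representation ranking.
#
# The registry holds the five binding-site motifs of the fungal Zn(II)2Cys6
# factor XlnR: the three canonical hexamers GGCTAA / GGCTGA / GGCTAG, the
# monomer site CGGNTAAW and the (palindromic) dimer site TTAGSCTAA.
# Supported IUPAC codes are A, C, G, T plus N (any), W (A/T), S (C/G).

IUPAC_SUPPORTED <- c("A", "C", "G", "T", "N", "W", "S")

IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  N = c("A", "C", "G", "T"), W = c("A", "T"), S = c("C", "G")
)

assert_iupac <- function(pattern) {
  bad <- setdiff(unique(strsplit(toupper(pattern), "")[[1]]), IUPAC_SUPPORTED)
  if (length(bad) > 0) {
    stop("unsupported IUPAC code(s) in pattern '", pattern, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  toupper(pattern)
}

# reverse complement of character sequences (IUPAC-aware: N->N, W->W, S->S)
dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Draw one concrete ACGT realization of an IUPAC pattern (degeneracies
# resolved uniformly at random under the caller's RNG state).
realize_iupac <- function(pattern) {
  pattern <- assert_iupac(pattern)
  paste(vapply(strsplit(pattern, "")[[1]], function(ch) {
    opts <- IUPAC_CLASSES[[ch]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

#' Registry of XlnR binding-site motifs
#'
#' The three canonical hexamer motifs plus the degenerate monomer and dimer
#' sites, as IUPAC patterns.
#'
#' @return A tibble with columns `motif_id`, `pattern` and `role`
#'   (`"canonical"`, `"monomer"` or `"dimer"`).
#' @export
#' @examples
#' xlnr_motifs()
xlnr_motifs <- function() {
  tibble::tibble(
    motif_id = c("GGCTAA", "GGCTGA", "GGCTAG", "CGGNTAAW", "TTAGSCTAA"),
    pattern  = c("GGCTAA", "GGCTGA", "GGCTAG", "CGGNTAAW", "TTAGSCTAA"),
    role     = c("canonical", "canonical", "canonical", "monomer", "dimer")
  )
}

#' Scan a sequence for an IUPAC motif
#'
#' Reports every occurrence of `pattern` on the forward sequence and, if
#' `both_strands`, every occurrence of its reverse complement on the forward
#' sequence (reported with strand `"-"`). Overlapping occurrences are all
#' reported. Ambiguity codes are interpreted in the pattern only; the subject
#' is matched literally, so non-ACGT subject letters never match.
#'
#' @param seq A single DNA sequence (character or [Biostrings::DNAString]).
#' @param pattern IUPAC pattern (A, C, G, T, N, W, S).
#' @param both_strands Scan the reverse-complement pattern as well?
#' @return A tibble with 0-based `position` (on the given sequence) and
#'   `strand`, ordered by position.
#' @export
#' @examples
#' scan_iupac("AAGGCTAATT", "GGCTAA")
#' scan_iupac("CGGATAAT", "CGGNTAAW")
scan_iupac <- function(seq, pattern, both_strands = TRUE) {
  pattern <- assert_iupac(pattern)
  subject <- Biostrings::DNAString(as.character(seq))
  hit_tbl <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  fixed = "subject")
    tibble::tibble(position = IRanges::start(m) - 1L, strand = strand)
  }
  out <- hit_tbl(pattern, "+")
  if (both_strands) {
    out <- dplyr::bind_rows(out, hit_tbl(dna_revcomp(pattern), "-"))
  }
  dplyr::arrange(out, .data$position, .data$strand)
}

# Vectorised both-strand occurrence counts of one pattern over many sequences.
count_pattern <- function(seqs, pattern, both_strands = TRUE) {
  if (length(seqs) == 0) return(integer(0))
  set <- if (methods::is(seqs, "DNAStringSet")) seqs else
    Biostrings::DNAStringSet(as.character(seqs))
  n <- Biostrings::vcountPattern(pattern, set, fixed = "subject")
  if (both_strands) {
    n <- n + Biostrings::vcountPattern(dna_revcomp(pattern), set,
                                       fixed = "subject")
  }
  as.integer(n)
}

#' Count XlnR motifs in promoter sequences
#'
#' Counts occurrences of each registry motif in each promoter (both strands
#' by default, overlapping occurrences included) and derives the pairwise
#' coexistence flags for the canonical hexamers.
#'
#' @param promoters A data frame with columns `gene_id` and `seq` (e.g. from
#'   [build_upstream1000()]).
#' @param motifs Motif registry, see [xlnr_motifs()].
#' @param both_strands Count on both strands?
#' @return A tibble with one row per gene: `n_GGCTAA`, `n_GGCTGA`,
#'   `n_GGCTAG`, `n_total` (sum of the three canonical counts), `n_monomer`,
#'   `n_dimer`, and logical flags `coex_GA_AA`, `coex_AA_AG`, `coex_GA_AG`.
#' @export
count_motifs <- function(promoters, motifs = xlnr_motifs(),
                         both_strands = TRUE) {
  stopifnot(all(c("gene_id", "seq") %in% names(promoters)))
  set <- Biostrings::DNAStringSet(promoters$seq)
  counts <- lapply(motifs$pattern, count_pattern, seqs = set,
                   both_strands = both_strands)
  names(counts) <- paste0("n_", motifs$motif_id)
  out <- tibble::tibble(gene_id = promoters$gene_id)
  out <- dplyr::bind_cols(out, tibble::as_tibble(counts))
  out$n_monomer <- out$n_CGGNTAAW
  out$n_dimer <- out$n_TTAGSCTAA
  out$n_CGGNTAAW <- NULL
  out$n_TTAGSCTAA <- NULL
  dplyr::mutate(
    out,
    n_total = .data$n_GGCTAA + .data$n_GGCTGA + .data$n_GGCTAG,
    coex_GA_AA = .data$n_GGCTGA > 0 & .data$n_GGCTAA > 0,
    coex_AA_AG = .data$n_GGCTAA > 0 & .data$n_GGCTAG > 0,
    coex_GA_AG = .data$n_GGCTGA > 0 & .data$n_GGCTAG > 0
  )
}

#' List individual motif matches in promoter sequences
#'
#' @inheritParams count_motifs
#' @return A long tibble with `gene_id`, `motif_id`, 1-based promoter
#'   `position` and `strand` of every occurrence.
#' @export
motif_matches <- function(promoters, motifs = xlnr_motifs(),
                          both_strands = TRUE) {
  stopifnot(all(c("gene_id", "seq") %in% names(promoters)))
  purrr::pmap(list(promoters$gene_id, promoters$seq), function(gid, s) {
    purrr::map2(motifs$motif_id, motifs$pattern, function(mid, pat) {
      hits <- scan_iupac(s, pat, both_strands = both_strands)
      if (nrow(hits) == 0) return(NULL)
      tibble::tibble(gene_id = gid, motif_id = mid,
                     position = hits$position + 1L, strand = hits$strand)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Rank k-mers over-represented in summit windows
#'
#' A defined stand-in for de novo motif discovery: each canonical k-mer (a
#' k-mer merged with its reverse complement) is scored by the log2 odds of
#' its pseudocounted frequency in the foreground windows versus a background
#' sequence set (typically the round-0 fragment pool).
#'
#' @param foreground Character vector or `DNAStringSet` of foreground
#'   sequences (e.g. the top-ranked 50-bp summit windows).
#' @param background Background sequences.
#' @param k K-mer length (default 6, the canonical hexamer length).
#' @param pseudocount Pseudocount applied to both frequencies.
#' @return A tibble with `kmer` (canonical representative), `fg_count`,
#'   `bg_count`, `bg_expected` (background frequency scaled to the foreground
#'   total), `log2_odds` and `rank` (1 = most over-represented).
#' @export
kmer_enrichment <- function(foreground, background, k = 6, pseudocount = 0.5) {
  stopifnot(length(foreground) >= 1, length(background) >= 1, k >= 1)
  as_set <- function(x) if (methods::is(x, "DNAStringSet")) x else
    Biostrings::DNAStringSet(as.character(x))
  fg <- as_set(foreground); bg <- as_set(background)
  if (min(Biostrings::width(fg)) < k) {
    stop("k exceeds the shortest foreground window length", call. = FALSE)
  }
  class_counts <- function(set) {
    freq <- Biostrings::oligonucleotideFrequency(set, width = k,
                                                 simplify.as = "collapsed")
    canon <- pmin(names(freq), dna_revcomp(names(freq)))
    tapply(freq, canon, sum)
  }
  fgc <- class_counts(fg)
  bgc <- class_counts(bg)
  kmers <- sort(unique(c(names(fgc), names(bgc))))
  fgn <- ifelse(is.na(fgc[kmers]), 0, fgc[kmers])
  bgn <- ifelse(is.na(bgc[kmers]), 0, bgc[kmers])
  denom <- pseudocount * 4^k
  score <- log2((fgn + pseudocount) / (sum(fgn) + denom)) -
    log2((bgn + pseudocount) / (sum(bgn) + denom))
  out <- tibble::tibble(
    kmer = kmers,
    fg_count = as.integer(fgn),
    bg_count = as.integer(bgn),
    bg_expected = as.numeric(bgn / sum(bgn) * sum(fgn)),
    log2_odds = as.numeric(score)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$log2_odds), .data$kmer)
  dplyr::mutate(out, rank = dplyr::row_number())
}
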