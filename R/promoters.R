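# Upstream-1000 promoter extraction and summit-window annotation.
#
# Promoter coordinates follow the upstream1000 convention: the promoter is
# read toward the start codon, and the base immediately 5' of the codon has
# position 1000 (or the truncated promoter length near a contig end).

#' Build the upstream-1000 promoter set
#'
#' For a plus-strand gene with 0-based start codon `s`, the promoter is
#' `genome[s-1000, s)` as-is; for a minus-strand gene it is the reverse
#' complement of `genome[s+1, s+1001)`. Promoters truncated by a contig end
#' are flagged and their actual length recorded.
#'
#' @param genome A `genome_model`.
#' @return A tibble with `gene_id`, `contig`, `strand`, genomic `start` /
#'   `end` (0-based half-open), `length`, `truncated` and `seq`
#'   (promoter-forward orientation).
#' @export
build_upstream1000 <- function(genome) {
  genes <- genome$genes
  stopifnot(nrow(genes) > 0)
  clen <- setNames(Biostrings::width(genome$contigs), names(genome$contigs))
  pos <- genes$strand == "+"
  start0 <- ifelse(pos, pmax(genes$start - 1000L, 0L), genes$start + 1L)
  end0 <- ifelse(pos, genes$start, pmin(genes$start + 1001L,
                                        clen[genes$contig]))
  seqs <- character(nrow(genes))
  for (cn in unique(genes$contig)) {
    idx <- which(genes$contig == cn)
    at <- IRanges::IRanges(start = start0[idx] + 1L, end = end0[idx])
    seqs[idx] <- as.character(Biostrings::extractAt(genome$contigs[[cn]], at))
  }
  seqs[!pos] <- dna_revcomp(seqs[!pos])
  tibble::tibble(
    gene_id = genes$gene_id, contig = genes$contig, strand = genes$strand,
    start = as.integer(start0), end = as.integer(end0),
    length = as.integer(end0 - start0),
    truncated = (end0 - start0) < 1000L, seq = seqs
  )
}

# Best ungapped segment on one alignment diagonal given a logical match
# vector: the longest segment with identity >= min_identity and length >=
# min_len; ties broken by identity, then leftmost. Returns NULL or
# list(start, len, identity) with start 1-based on the match vector.
best_ungapped_segment <- function(match_vec, min_len, min_identity) {
  L <- length(match_vec)
  if (L < min_len) return(NULL)
  cs <- c(0L, cumsum(match_vec))
  for (len in L:min_len) {
    starts <- seq_len(L - len + 1L)
    hits <- cs[starts + len] - cs[starts]
    ident <- hits / len
    ok <- ident >= min_identity
    if (any(ok)) {
      best <- starts[ok][which.max(ident[ok])]
      return(list(start = best, len = len,
                  identity = max(ident[ok])))
    }
  }
  NULL
}

#' Assign summit windows to candidate promoters
#'
#' Seeded ungapped local matcher standing in for a permissive blastn run:
#' for each window and promoter, exact 12-mer seeds (both orientations of
#' the window) define candidate alignment diagonals; on each diagonal the
#' best ungapped segment is scored. A hit is reported for every promoter
#' whose best segment has length >= `min_len` and identity >=
#' `min_identity`; a window may hit several promoters (e.g. a shared
#' intergenic region upstream of divergent genes) and all such hits are
#' reported.
#'
#' @param windows Window tibble from [extract_windows()] (needs `window_id`,
#'   `seq`; `fold_enrichment`/`peak_rank` are carried through if present).
#' @param promoters Promoter tibble from [build_upstream1000()].
#' @param min_len Minimum match length in bp.
#' @param min_identity Minimum match identity fraction.
#' @param seed_len Exact seed length defining candidate diagonals.
#' @return A tibble of hits: `window_id`, `gene_id`, `match_len`,
#'   `identity`, `orientation` (`"+"` window as-is, `"-"` reverse
#'   complement), promoter-forward `p_start` (1-based start of the matched
#'   segment) plus any carried window columns.
#' @export
assign_windows <- function(windows, promoters, min_len = 30,
                           min_identity = 0.9, seed_len = 12) {
  stopifnot(nrow(promoters) > 0)
  if (nrow(windows) == 0) {
    return(tibble::tibble(window_id = character(0), gene_id = character(0),
                          match_len = integer(0), identity = numeric(0),
                          orientation = character(0), p_start = integer(0)))
  }
  prom_chars <- strsplit(promoters$seq, "")
  hits <- list()
  for (orientation in c("+", "-")) {
    wseq <- if (orientation == "+") windows$seq else dna_revcomp(windows$seq)
    wchars <- strsplit(wseq, "")
    # all seed k-mers of all windows, tagged with (window, offset)
    offs <- lapply(nchar(wseq), function(L) {
      if (L >= seed_len) seq_len(L - seed_len + 1L) else integer(0)
    })
    wi <- rep.int(seq_along(wseq), lengths(offs))
    off <- unlist(offs, use.names = FALSE)
    if (length(wi) == 0) next
    seeds <- substr(rep(wseq, lengths(offs)), off, off + seed_len - 1L)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
    for (pi in seq_len(nrow(promoters))) {
      subject <- Biostrings::DNAString(promoters$seq[pi])
      m <- Biostrings::matchPDict(pd, subject)
      starts <- Biostrings::startIndex(m)
      counts <- lengths(starts)
      if (sum(counts) == 0) next
      si <- rep.int(seq_along(seeds), counts)
      pstart <- unlist(starts, use.names = FALSE)
      diag_tbl <- unique(data.frame(w = wi[si], d = pstart - off[si]))
      plen <- nchar(promoters$seq[pi])
      for (r in seq_len(nrow(diag_tbl))) {
        w <- diag_tbl$w[r]; d <- diag_tbl$d[r]
        wlen <- nchar(wseq[w])
        i1 <- max(1L, 1L - d + 1L)          # window positions aligned
        i2 <- min(wlen, plen - d)
        if (i2 - i1 + 1L < min_len) next
        mv <- wchars[[w]][i1:i2] == prom_chars[[pi]][(i1:i2) + d]
        seg <- best_ungapped_segment(mv, min_len, min_identity)
        if (is.null(seg)) next
        hits[[length(hits) + 1]] <- tibble::tibble(
          window_index = w, gene_id = promoters$gene_id[pi],
          match_len = as.integer(seg$len), identity = seg$identity,
          orientation = orientation,
          p_start = as.integer(i1 + seg$start - 1L + d)
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(window_id = character(0), gene_id = character(0),
                          match_len = integer(0), identity = numeric(0),
                          orientation = character(0), p_start = integer(0)))
  }
  out <- dplyr::bind_rows(hits)
  # best hit per (window, promoter): longest, then most identical
  out <- dplyr::ungroup(dplyr::slice_max(
    dplyr::group_by(out, .data$window_index, .data$gene_id),
    order_by = .data$match_len + .data$identity, n = 1, with_ties = FALSE))
  carry <- windows[out$window_index,
                   intersect(c("window_id", "contig", "start", "end",
                               "peak_rank", "fold_enrichment"),
                             names(windows))]
  dplyr::select(dplyr::bind_cols(carry, out), -"window_index")
}

#' Convert genomic positions to promoter-forward coordinates
#'
#' Maps a genomic position (e.g. a peak summit) into the 1..length
#' coordinate system of a promoter, in which the base immediately 5' of the
#' start codon has position `length` (1000 for a full promoter). Positions
#' outside the promoter interval give `NA` with a flag.
#'
#' @param promoters Promoter tibble from [build_upstream1000()] (one row per
#'   position to convert, e.g. after joining hits to promoters).
#' @param contig,position Genomic location (0-based) of each summit.
#' @return A tibble with `P` (1-based promoter coordinate or `NA`) and
#'   `in_promoter`.
#' @export
promoter_position <- function(promoters, contig, position) {
  stopifnot(nrow(promoters) == length(contig),
            length(contig) == length(position))
  inside <- promoters$contig == contig & position >= promoters$start &
    position < promoters$end
  P <- ifelse(promoters$strand == "+",
              position - promoters$start + 1L,
              promoters$end - position)
  tibble::tibble(P = ifelse(inside, as.integer(P), NA_integer_),
                 in_promoter = inside)
}

# Inverse of promoter_position(): genomic 0-based position of promoter
# coordinate P (used in round-trip tests).
promoter_to_genomic <- function(promoters, P) {
  ifelse(promoters$strand == "+",
         promoters$start + P - 1L,
         promoters$end - P)
}
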