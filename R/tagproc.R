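# Read processing: adapter trimming, exact seed-and-verify mapping,
# Poisson local-lambda peak calling and summit-window extraction.

#' Trim adapter sequences from reads
#'
#' Removes, for each read, the longest prefix (at least `min_overlap` bases,
#' exact match) that equals a suffix of a 5' adapter, then the longest
#' suffix that equals a prefix of a 3' adapter. Reads shorter than
#' `min_length` after trimming are flagged as discarded; reads with no
#' adapter match pass through unchanged.
#'
#' @param reads A data frame with a `seq` column (e.g. from [emit_reads()]).
#' @param five_prime,three_prime Character vectors of adapter sequences.
#' @param min_overlap Minimum exact overlap in bases.
#' @param min_length Minimum retained read length after trimming.
#' @return The input tibble with `seq` trimmed and a logical `kept` column.
#' @export
trim_adapters <- function(reads, five_prime = character(0),
                          three_prime = character(0), min_overlap = 15,
                          min_length = 20) {
  if (length(five_prime) == 0 && length(three_prime) == 0) {
    stop("at least one adapter is required", call. = FALSE)
  }
  seqs <- reads$seq
  if (length(seqs) > 0) {
    for (ad in five_prime) {
      la <- nchar(ad)
      hi <- min(la, max(nchar(seqs)))
      if (hi < min_overlap) next
      done <- rep(FALSE, length(seqs))
      for (k in hi:min_overlap) {
        cand <- !done & nchar(seqs) >= k
        if (!any(cand)) next
        hit <- cand & substr(seqs, 1, k) == substr(ad, la - k + 1, la)
        seqs[hit] <- substr(seqs[hit], k + 1, nchar(seqs[hit]))
        done <- done | hit
      }
    }
    for (ad in three_prime) {
      la <- nchar(ad)
      hi <- min(la, max(nchar(seqs)))
      if (hi < min_overlap) next
      done <- rep(FALSE, length(seqs))
      for (k in hi:min_overlap) {
        cand <- !done & nchar(seqs) >= k
        if (!any(cand)) next
        nc <- nchar(seqs)
        hit <- cand & substr(seqs, nc - k + 1, nc) == substr(ad, 1, k)
        seqs[hit] <- substr(seqs[hit], 1, nchar(seqs[hit]) - k)
        done <- done | hit
      }
    }
  }
  out <- reads
  out$seq <- seqs
  out$kept <- nchar(seqs) >= min_length
  tibble::as_tibble(out)
}

# Locate every exact-seed occurrence of `useq` (unique read sequences) in
# the genome, forward and reverse strand, allowing up to max_mismatches in
# the verification step (the seed prefix itself must match exactly).
# Returns a tibble: seq_index, contig, start (0-based), strand, mismatches.
locate_sequences <- function(useq, genome, max_mismatches = 0,
                             seed_width = 16) {
  keep <- nchar(useq) >= seed_width
  idx_all <- which(keep)
  if (length(idx_all) == 0) {
    return(tibble::tibble(seq_index = integer(0), contig = character(0),
                          start = integer(0), strand = character(0)))
  }
  contig_chr <- as.character(genome$contigs)
  hits <- list()
  for (strand in c("+", "-")) {
    qseq <- if (strand == "+") useq[idx_all] else dna_revcomp(useq[idx_all])
    seeds <- substr(qseq, 1, seed_width)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
    for (cn in names(contig_chr)) {
      m <- Biostrings::matchPDict(pd, genome$contigs[[cn]])
      starts <- Biostrings::startIndex(m)
      counts <- lengths(starts)
      if (sum(counts) == 0) next
      qi <- rep.int(seq_along(qseq), counts)
      pos1 <- unlist(starts, use.names = FALSE)
      qlen <- nchar(qseq)[qi]
      ok <- pos1 + qlen - 1L <= nchar(contig_chr[[cn]])
      qi <- qi[ok]; pos1 <- pos1[ok]; qlen <- qlen[ok]
      if (length(qi) == 0) next
      ref <- substr(rep(contig_chr[[cn]], length(qi)), pos1, pos1 + qlen - 1L)
      if (max_mismatches == 0) {
        good <- ref == qseq[qi]
        mm <- integer(sum(good))
      } else {
        mm_all <- mapply(function(a, b) {
          sum(utf8ToInt(a) != utf8ToInt(b))
        }, ref, qseq[qi], USE.NAMES = FALSE)
        good <- mm_all <= max_mismatches
        mm <- mm_all[good]
      }
      if (!any(good)) next
      hits[[length(hits) + 1]] <- tibble::tibble(
        seq_index = idx_all[qi[good]], contig = cn,
        start = as.integer(pos1[good] - 1L), strand = strand,
        len = as.integer(qlen[good])
      )
    }
  }
  dplyr::bind_rows(hits)
}

#' Map trimmed reads onto the synthetic genome
#'
#' Seed-and-verify exact search: the first `seed_width` bases of each read
#' must match the genome exactly; the full read is then verified with at
#' most `max_mismatches` substitutions. Reads with more than one equally
#' valid placement (either strand) are discarded as ambiguous. When mates
#' are given, concordantly mapped pairs (same contig, opposite strands,
#' implied fragment length at most `max_fragment`) are merged into a single
#' fragment interval; otherwise each uniquely mapped read contributes its
#' own tag.
#'
#' @param reads1 Tibble of trimmed reads (`read_id`, `seq`; rows with
#'   `kept == FALSE` are ignored).
#' @param reads2 Optional mate tibble (same `read_id` values).
#' @param genome A `genome_model`.
#' @param max_mismatches Maximum substitutions allowed at verification.
#' @param seed_width Exact seed prefix length.
#' @param max_fragment Maximum implied fragment length for a concordant pair.
#' @return A tibble of aligned tags: `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `paired`.
#' @export
map_reads <- function(reads1, reads2 = NULL, genome, max_mismatches = 0,
                      seed_width = 16, max_fragment = 2000) {
  keep_rows <- function(r) {
    if ("kept" %in% names(r)) r <- r[r$kept, ]
    r
  }
  reads1 <- keep_rows(reads1)
  all_seq <- reads1$seq
  n1 <- nrow(reads1)
  if (!is.null(reads2)) {
    reads2 <- keep_rows(reads2)
    all_seq <- c(all_seq, reads2$seq)
  }
  useq <- unique(all_seq)
  loc <- locate_sequences(useq, genome, max_mismatches = max_mismatches,
                          seed_width = seed_width)
  # unique-best placement per sequence
  if (nrow(loc) > 0) {
    tab <- table(loc$seq_index)
    uniq_idx <- as.integer(names(tab)[tab == 1])
    loc <- loc[loc$seq_index %in% uniq_idx, ]
  }
  place <- function(seqs) {
    i <- match(seqs, useq)
    j <- match(i, loc$seq_index)
    tibble::tibble(contig = loc$contig[j], start = loc$start[j],
                   end = loc$start[j] + loc$len[j], strand = loc$strand[j])
  }
  p1 <- place(reads1$seq)
  if (is.null(reads2)) {
    tags <- dplyr::filter(dplyr::mutate(p1, paired = FALSE),
                          !is.na(.data$contig))
    return(tags)
  }
  p2 <- place(reads2$seq)
  p2$read_id <- reads2$read_id
  m <- match(reads1$read_id, p2$read_id)
  p2 <- p2[m, ]
  concordant <- !is.na(p1$contig) & !is.na(p2$contig) &
    p1$contig == p2$contig & p1$strand != p2$strand &
    pmax(p1$end, p2$end) - pmin(p1$start, p2$start) <= max_fragment
  concordant[is.na(concordant)] <- FALSE
  merged <- tibble::tibble(
    contig = p1$contig[concordant],
    start = pmin(p1$start[concordant], p2$start[concordant]),
    end = pmax(p1$end[concordant], p2$end[concordant]),
    strand = p1$strand[concordant], paired = TRUE
  )
  single <- dplyr::bind_rows(
    dplyr::mutate(p1[!concordant, ], paired = FALSE),
    dplyr::mutate(p2[!concordant, setdiff(names(p2), "read_id")],
                  paired = FALSE)
  )
  single <- dplyr::filter(single, !is.na(.data$contig))
  dplyr::bind_rows(merged, single)
}

# expected number of tags overlapping a `window`-bp window under a uniform
# genome-wide layout of the given tags
mean_window_rate <- function(tags, window, genome_len) {
  if (nrow(tags) == 0) return(0)
  nrow(tags) * (window + mean(tags$end - tags$start)) / genome_len
}

#' Call enrichment peaks from selected vs control tags
#'
#' Sliding-window Poisson test: for each `window`-bp window (step `step`),
#' the selected-pool tag count is tested against a local lambda taken as the
#' maximum of (i) the library-size-scaled control count in the window,
#' (ii) the genome-wide mean scaled-control rate for a window, and (iii) a
#' pseudocount of 0.5. Significant windows (upper-tail Poisson
#' `p < p_threshold`) within `merge_gap` bp are merged into peaks. The peak
#' summit is the position of maximum per-base selected coverage (leftmost on
#' ties); fold enrichment is the ratio of per-million-scaled selected to
#' control coverage at the summit (each + 0.5). Peaks are ranked by fold
#' enrichment, rank 1 largest.
#'
#' @param tags_selected,tags_control Aligned-tag tibbles from [map_reads()]
#'   (control is required; typically the round-0 library intervals).
#' @param genome A `genome_model`.
#' @param window,step Sliding-window size and step in bp.
#' @param p_threshold Poisson upper-tail significance threshold.
#' @param merge_gap Maximum gap between significant windows merged into one
#'   peak.
#' @return A tibble of peaks: `contig`, `start`, `end`, `summit` (0-based),
#'   `fold_enrichment`, `p_value` (smallest constituent window p), `rank`.
#' @export
call_peaks <- function(tags_selected, tags_control, genome, window = 50,
                       step = 10, p_threshold = 1e-5, merge_gap = 50) {
  if (is.null(tags_control) || nrow(tags_control) == 0) {
    stop("control tags are required for fold-enrichment estimation",
         call. = FALSE)
  }
  if (nrow(tags_selected) == 0) {
    return(empty_peaks())
  }
  n_sel <- nrow(tags_selected)
  n_ctl <- nrow(tags_control)
  scale_ctl <- n_sel / n_ctl
  genome_len <- sum(Biostrings::width(genome$contigs))
  lambda_genome <- mean_window_rate(tags_control, window, genome_len) *
    scale_ctl
  peaks <- list()
  for (cn in names(genome$contigs)) {
    clen <- Biostrings::width(genome$contigs)[match(cn,
                                                    names(genome$contigs))]
    sel <- tags_selected[tags_selected$contig == cn, ]
    ctl <- tags_control[tags_control$contig == cn, ]
    if (nrow(sel) == 0) next
    sel_rng <- IRanges::IRanges(start = sel$start + 1L, end = sel$end)
    ctl_rng <- IRanges::IRanges(start = ctl$start + 1L, end = ctl$end)
    win_start <- seq(0L, max(0L, clen - window), by = step)
    wins <- IRanges::IRanges(start = win_start + 1L, width = window)
    k_sel <- IRanges::countOverlaps(wins, sel_rng)
    k_ctl <- IRanges::countOverlaps(wins, ctl_rng)
    lambda <- pmax(k_ctl * scale_ctl, lambda_genome, 0.5)
    pvals <- ppois(k_sel - 1, lambda, lower.tail = FALSE)
    sig <- which(pvals < p_threshold)
    if (length(sig) == 0) next
    merged <- IRanges::reduce(wins[sig], min.gapwidth = merge_gap + 1L)
    cov_sel <- as.integer(IRanges::coverage(sel_rng, width = clen))
    cov_ctl <- as.integer(IRanges::coverage(ctl_rng, width = clen))
    for (i in seq_along(merged)) {
      ps <- IRanges::start(merged)[i]; pe <- IRanges::end(merged)[i]
      local_cov <- cov_sel[ps:pe]
      summit1 <- ps + which.max(local_cov) - 1L   # leftmost maximum
      fe <- (cov_sel[summit1] * 1e6 / n_sel + 0.5) /
        (cov_ctl[summit1] * 1e6 / n_ctl + 0.5)
      in_peak <- sig[IRanges::start(wins)[sig] >= ps &
                       IRanges::end(wins)[sig] <= pe]
      peaks[[length(peaks) + 1]] <- tibble::tibble(
        contig = cn, start = ps - 1L, end = pe,
        summit = summit1 - 1L, fold_enrichment = fe,
        p_value = min(pvals[in_peak])
      )
    }
  }
  if (length(peaks) == 0) return(empty_peaks())
  out <- dplyr::bind_rows(peaks)
  out <- dplyr::arrange(out, dplyr::desc(.data$fold_enrichment),
                        .data$contig, .data$start)
  dplyr::mutate(out, rank = dplyr::row_number())
}

empty_peaks <- function() {
  tibble::tibble(contig = character(0), start = integer(0), end = integer(0),
                 summit = integer(0), fold_enrichment = numeric(0),
                 p_value = numeric(0), rank = integer(0))
}

#' Extract summit-flanking sequence windows from peaks
#'
#' Cuts the window `[summit - flank_left, summit + flank_right]` (inclusive,
#' 0-based; 50 bp with the defaults) from the plus strand of the genome.
#' Windows running over a contig end are clipped and flagged.
#'
#' @param peaks Peak tibble from [call_peaks()].
#' @param genome A `genome_model`.
#' @param flank_left,flank_right Flank sizes in bp around the 1-bp summit.
#' @return A tibble of windows: `window_id`, `contig`, `start`, `end`
#'   (0-based half-open), `seq`, `clipped`, source `peak_rank` and
#'   `fold_enrichment`.
#' @export
extract_windows <- function(peaks, genome, flank_left = 24, flank_right = 25) {
  if (nrow(peaks) == 0) {
    return(tibble::tibble(window_id = character(0), contig = character(0),
                          start = integer(0), end = integer(0),
                          seq = character(0), clipped = logical(0),
                          peak_rank = integer(0),
                          fold_enrichment = numeric(0)))
  }
  clen <- setNames(Biostrings::width(genome$contigs), names(genome$contigs))
  start <- peaks$summit - flank_left
  end <- peaks$summit + flank_right + 1L
  clipped <- start < 0 | end > clen[peaks$contig]
  start <- pmax(start, 0L)
  end <- pmin(end, clen[peaks$contig])
  seqs <- character(nrow(peaks))
  for (cn in unique(peaks$contig)) {
    idx <- which(peaks$contig == cn)
    at <- IRanges::IRanges(start = start[idx] + 1L, end = end[idx])
    seqs[idx] <- as.character(Biostrings::extractAt(genome$contigs[[cn]], at))
  }
  tibble::tibble(
    window_id = sprintf("window%04d", peaks$rank),
    contig = peaks$contig, start = as.integer(start), end = as.integer(end),
    seq = seqs, clipped = as.logical(clipped), peak_rank = peaks$rank,
    fold_enrichment = peaks$fold_enrichment
  )
}
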