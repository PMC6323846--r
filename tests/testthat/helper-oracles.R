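# Independent oracles used by the oracle-equivalence suites. These are
# deliberately naive and share no code path with the package internals.

ORACLE_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  N = c("A", "C", "G", "T"), W = c("A", "T"), S = c("C", "G")
)

# reverse complement built from first principles
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", W = "W", S = "S")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# position-by-position IUPAC match test
oracle_match_at <- function(seq_chars, pat_chars, i) {
  for (j in seq_along(pat_chars)) {
    if (!(seq_chars[i + j - 1] %in% ORACLE_CLASSES[[pat_chars[j]]])) {
      return(FALSE)
    }
  }
  TRUE
}

# naive per-position occurrence positions (0-based) on the forward sequence
oracle_scan_positions <- function(seq, pattern) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  L <- length(sc); m <- length(pc)
  if (L < m) return(integer(0))
  which(vapply(1:(L - m + 1), function(i) oracle_match_at(sc, pc, i),
               logical(1))) - 1L
}

# naive both-strand occurrence count
oracle_count <- function(seq, pattern, both_strands = TRUE) {
  n <- length(oracle_scan_positions(seq, pattern))
  if (both_strands) {
    n <- n + length(oracle_scan_positions(seq, oracle_revcomp(pattern)))
  }
  n
}

# regex-lookahead oracle (counts overlapping matches), vectorised over seqs
oracle_count_regex <- function(seqs, pattern, both_strands = TRUE) {
  to_regex <- function(p) {
    paste(vapply(strsplit(p, "")[[1]], function(ch) {
      cls <- ORACLE_CLASSES[[ch]]
      if (length(cls) == 1) cls else paste0("[", paste(cls, collapse = ""), "]")
    }, character(1)), collapse = "")
  }
  one <- function(p) {
    re <- paste0("(?=", to_regex(p), ")")
    vapply(gregexpr(re, seqs, perl = TRUE), function(g) {
      if (g[1] == -1) 0L else length(g)
    }, integer(1))
  }
  n <- one(pattern)
  if (both_strands) n <- n + one(oracle_revcomp(pattern))
  n
}

# Spearman rho via explicit average ranks and the product-moment formula
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    r[o] <- seq_along(v)
    for (val in unique(v)) {
      idx <- which(v == val)
      r[idx] <- mean(r[idx])
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# two-sided Fisher exact p by full hypergeometric enumeration via choose()
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == N) return(1)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(k) {
    choose(r1, k) * choose(r2, c1 - k) / choose(N, c1)
  }, numeric(1))
  pobs <- probs[a - lo + 1]
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# random ACGT sequence for fixtures
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small handmade genome: one 8-kb contig, a + gene at 5000 and a - gene at
# 1990 (their upstream-1000 regions share the 2000..2990 interval)
toy_genome <- function(seed = 42) {
  withr::with_seed(seed, {
    contig <- random_seq(8000)
    genome_model(
      c(chr1 = contig),
      tibble::tibble(gene_id = c("gplus", "gminus"),
                     contig = "chr1", strand = c("+", "-"),
                     start = c(5000L, 1990L))
    )
  })
}
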