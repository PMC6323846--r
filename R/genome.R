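# Synthetic genome / promoter / expression / fragment-library generator.
#
# Emulates the study inputs at desk scale: a multi-contig genome with
# annotated start codons, 1000-bp upstream promoters carrying planted motif
# occurrences, an expression table whose log-ratios depend on promoter motif
# content, and a linker-flanked ~100-bp fragment library.

# i.i.d. background sequence; GC content configurable
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

new_genome_model <- function(contigs, genes) {
  structure(list(contigs = contigs, genes = genes), class = "genome_model")
}

#' Construct a genome model from sequences and gene annotations
#'
#' @param contigs Named character vector or [Biostrings::DNAStringSet] of
#'   contig sequences (alphabet ACGT).
#' @param genes Data frame with `gene_id`, `contig`, `strand` (`"+"`/`"-"`)
#'   and `start` (0-based start-codon position).
#' @return A `genome_model` object.
#' @export
genome_model <- function(contigs, genes) {
  if (!methods::is(contigs, "DNAStringSet")) {
    contigs <- Biostrings::DNAStringSet(contigs)
  }
  stopifnot(!is.null(names(contigs)), all(Biostrings::width(contigs) > 0),
            all(c("gene_id", "contig", "strand", "start") %in% names(genes)),
            !anyDuplicated(genes$gene_id),
            all(genes$contig %in% names(contigs)),
            all(genes$strand %in% c("+", "-")))
  clen <- setNames(Biostrings::width(contigs), names(contigs))
  stopifnot(all(genes$start >= 0), all(genes$start < clen[genes$contig]))
  new_genome_model(contigs, tibble::as_tibble(genes))
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", length(x$contigs), " contig(s), total ",
      sum(Biostrings::width(x$contigs)), " bp, ", nrow(x$genes),
      " gene(s)\n", sep = "")
  invisible(x)
}

#' Generate a synthetic genome with annotated start codons
#'
#' Contig sequence is i.i.d. over ACGT. Genes are laid out at regular
#' spacing so that every gene has a full 1000-bp upstream region within its
#' contig; strands are drawn uniformly. An ATG start codon is written at
#' each annotated position (reverse-complemented for minus-strand genes).
#'
#' @param n_genes Number of genes (>= 1).
#' @param contig_length Length of each contig in bp.
#' @param n_contigs Number of contigs; genes are distributed round-robin.
#' @param promoter_spacing Distance between consecutive start codons on a
#'   contig; default places genes evenly.
#' @param gc GC content of the background sequence.
#' @param seed Top-level seed (sub-stream `"genome"`).
#' @return A `genome_model`: list with `contigs` (named
#'   [Biostrings::DNAStringSet]) and `genes` (tibble `gene_id`, `contig`,
#'   `strand`, `start` — the 0-based start-codon position).
#' @export
#' @examples
#' g <- sim_genome(n_genes = 4, contig_length = 12000, seed = 1)
#' g$genes
sim_genome <- function(n_genes, contig_length = 50000, n_contigs = 1,
                       promoter_spacing = NULL, gc = 0.5, seed = 1) {
  stopifnot(n_genes >= 1, contig_length >= 1, n_contigs >= 1)
  per_contig <- diff(round(seq(0, n_genes, length.out = n_contigs + 1)))
  if (is.null(promoter_spacing)) {
    promoter_spacing <- floor((contig_length - 1100) / max(per_contig))
  }
  if (promoter_spacing < 1 ||
      1000 + (max(per_contig) - 1) * promoter_spacing + 1003 > contig_length) {
    stop("contig_length too short for ", n_genes, " gene(s) with 1000-bp ",
         "upstream regions at spacing ", promoter_spacing, call. = FALSE)
  }
  with_substream(seed, "genome", {
    contigs <- character(n_contigs)
    genes <- vector("list", n_contigs)
    gid <- 0L
    for (ci in seq_len(n_contigs)) {
      contigs[ci] <- random_dna(contig_length, gc = gc)
      k <- per_contig[ci]
      if (k == 0) next
      starts <- 1000L + (seq_len(k) - 1L) * as.integer(promoter_spacing)
      strands <- sample(c("+", "-"), k, replace = TRUE)
      ids <- sprintf("gene%04d", gid + seq_len(k))
      gid <- gid + k
      # write the start codon into the background
      for (j in seq_len(k)) {
        s <- starts[j]
        codon <- if (strands[j] == "+") "ATG" else "CAT"
        if (strands[j] == "+") {
          substr(contigs[ci], s + 1, s + 3) <- codon
        } else {
          substr(contigs[ci], s - 1, s + 1) <- codon
        }
      }
      genes[[ci]] <- tibble::tibble(
        gene_id = ids, contig = sprintf("contig%02d", ci),
        strand = strands, start = starts
      )
    }
    names(contigs) <- sprintf("contig%02d", seq_len(n_contigs))
    new_genome_model(Biostrings::DNAStringSet(contigs),
                     dplyr::bind_rows(genes))
  })
}

# promoter-forward coordinate (1..len; len = base adjacent to the codon)
# to genomic 0-based position of the site's first promoter base
plant_genomic_interval <- function(gene, pos, motif_len) {
  if (gene$strand == "+") {
    start0 <- gene$start - 1001L + pos
    c(start = start0, end = start0 + motif_len)
  } else {
    end0 <- gene$start + 1002L - pos          # one past last genomic base
    c(start = end0 - motif_len, end = end0)
  }
}

#' Plant motif occurrences in promoter regions
#'
#' Writes a concrete realization of each requested IUPAC motif into the
#' genome at the given promoter coordinate (degeneracies resolved uniformly
#' at random under the seed). Promoter coordinates follow the
#' upstream-1000 convention: position 1000 is the base immediately 5' of the
#' start codon. Plant strand `"+"` writes the motif in promoter-forward
#' orientation; `"-"` writes its reverse complement.
#'
#' @param genome A `genome_model`.
#' @param plan Data frame with columns `gene_id`, `motif_id` (a registry
#'   motif or any supported IUPAC pattern), `pos` (1..1000 - motif length +
#'   1) and `strand`.
#' @param seed Top-level seed (sub-stream `"plant"`).
#' @return A list with the modified `genome` and `truth`, a tibble recording
#'   gene, motif, promoter position, strand and the realized sequence
#'   (promoter-forward orientation).
#' @export
plant_motifs <- function(genome, plan, seed = 1) {
  stopifnot(all(c("gene_id", "motif_id", "pos", "strand") %in% names(plan)))
  registry <- xlnr_motifs()
  contigs <- as.character(genome$contigs)
  occupied <- list()  # per contig: matrix of planted [start, end) intervals
  with_substream(seed, "plant", {
    truth <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      p <- plan[i, ]
      gene <- genome$genes[genome$genes$gene_id == p$gene_id, ]
      if (nrow(gene) != 1) stop("unknown gene_id: ", p$gene_id, call. = FALSE)
      pat <- if (p$motif_id %in% registry$motif_id) {
        registry$pattern[match(p$motif_id, registry$motif_id)]
      } else p$motif_id
      pat <- assert_iupac(pat)
      m <- nchar(pat)
      if (p$pos < 1 || p$pos + m - 1 > 1000) {
        stop("planted site for ", p$gene_id, " does not fit in promoter ",
             "positions 1..1000", call. = FALSE)
      }
      iv <- plant_genomic_interval(gene, p$pos, m)
      if (iv["start"] < 0 ||
          iv["end"] > nchar(contigs[[gene$contig]])) {
        stop("planted site for ", p$gene_id, " falls outside its contig",
             call. = FALSE)
      }
      prev <- occupied[[gene$contig]]
      if (!is.null(prev) &&
          any(iv["start"] < prev[, 2] & iv["end"] > prev[, 1])) {
        stop("conflicting overlapping plants at ", gene$contig, ":",
             iv["start"], call. = FALSE)
      }
      occupied[[gene$contig]] <- rbind(prev, iv)
      realization <- realize_iupac(pat)          # promoter-forward
      written <- if (p$strand == "-") dna_revcomp(realization) else realization
      # promoter-forward == genome-forward only for + strand genes
      genomic_seq <- if (gene$strand == "+") written else dna_revcomp(written)
      substr(contigs[[gene$contig]], iv["start"] + 1, iv["end"]) <- genomic_seq
      truth[[i]] <- tibble::tibble(
        gene_id = p$gene_id, motif_id = p$motif_id, pos = as.integer(p$pos),
        strand = p$strand, realization = written
      )
    }
    genome$contigs <- Biostrings::DNAStringSet(contigs)
    list(genome = genome, truth = dplyr::bind_rows(truth))
  })
}

#' Draw a random motif-planting plan
#'
#' Default planting scheme for simulations: each selected gene receives
#' binomially distributed numbers of GGCTAA, GGCTGA and GGCTAG sites at
#' non-overlapping random promoter positions and random strands. The
#' default is a single Bernoulli site per canonical hexamer (p = 0.5 for
#' GGCTAA/GGCTGA, p = 0.15 for the weak GGCTAG variant), which keeps
#' promoter classes balanced and makes the GGCTAA-and-GGCTGA coexistence
#' indicator the dominant expression correlate under the default
#' [effect_model()] — the qualitative ordering seen in the real regulon.
#'
#' @param genome A `genome_model`.
#' @param gene_ids Genes to plant into; default all genes.
#' @param size,prob Binomial(size, prob) per-motif site counts per gene.
#' @param prob_ag Success probability for GGCTAG (lower; the AG variant
#'   carries the weakest expression effect).
#' @param ensure_ggctaa Force at least one GGCTAA site per selected gene
#'   (used to mark "regulated" promoters in end-to-end runs).
#' @param seed Top-level seed (sub-stream `"plan"`).
#' @return A plan tibble suitable for [plant_motifs()].
#' @export
random_plant_plan <- function(genome, gene_ids = NULL, size = 1, prob = 0.5,
                              prob_ag = 0.15, ensure_ggctaa = FALSE,
                              seed = 1) {
  if (is.null(gene_ids)) gene_ids <- genome$genes$gene_id
  with_substream(seed, "plan", {
    rows <- lapply(gene_ids, function(gid) {
      n_aa <- rbinom(1, size, prob) + if (ensure_ggctaa) 1L else 0L
      n_ga <- rbinom(1, size, prob)
      n_ag <- rbinom(1, size, prob_ag)
      ids <- rep(c("GGCTAA", "GGCTGA", "GGCTAG"), c(n_aa, n_ga, n_ag))
      k <- length(ids)
      if (k == 0) return(NULL)
      # non-overlapping positions on a 12-bp grid, away from the ends
      slots <- sample(seq(50L, 950L, by = 12L), k)
      tibble::tibble(gene_id = gid, motif_id = ids, pos = slots,
                     strand = sample(c("+", "-"), k, replace = TRUE))
    })
    dplyr::bind_rows(rows)
  })
}

#' Effect model linking promoter motif content to expression log-ratios
#'
#' Parameters of the synthetic expression generator: the log expression
#' ratio of a gene is
#' `beta0 + beta_aa*nAA + beta_ga*nGA + beta_ag*nAG + beta_coex*[nAA>0 & nGA>0] + e`,
#' with Gaussian noise `e ~ N(0, sigma^2)`. The defaults are synthetic
#' choices (not measured values) that make the GGCTAA-and-GGCTGA
#' coexistence indicator the strongest correlate of expression, matching
#' the qualitative ordering reported for the real regulon.
#'
#' @param beta0 Baseline log-ratio.
#' @param beta_aa,beta_ga,beta_ag Per-occurrence log-ratio effects of
#'   GGCTAA, GGCTGA and GGCTAG sites.
#' @param beta_coex Extra effect when at least one GGCTAA and one GGCTGA
#'   site are both present.
#' @param sigma Gaussian noise SD of the log-ratio (>= 0).
#' @return An `effect_model` list.
#' @export
effect_model <- function(beta0 = 0, beta_aa = 0.5, beta_ga = 0.5,
                         beta_ag = 0.1, beta_coex = 0.8, sigma = 0.5) {
  stopifnot(sigma >= 0)
  structure(list(beta0 = beta0, beta_aa = beta_aa, beta_ga = beta_ga,
                 beta_ag = beta_ag, beta_coex = beta_coex, sigma = sigma),
            class = "effect_model")
}

#' Generate a synthetic differential-expression table
#'
#' Draws per-gene expression ratios (overproducer / disruptant scale) from
#' the [effect_model()] applied to measured promoter motif counts.
#'
#' @param counts Motif-count tibble from [count_motifs()] on the planted
#'   promoters.
#' @param model An [effect_model()].
#' @param seed Top-level seed (sub-stream `"expression"`).
#' @return A tibble with `gene_id` and `ratio` (> 0, linear scale).
#' @export
sim_expression <- function(counts, model = effect_model(), seed = 1) {
  stopifnot(inherits(model, "effect_model"),
            all(c("gene_id", "n_GGCTAA", "n_GGCTGA", "n_GGCTAG")
                %in% names(counts)))
  with_substream(seed, "expression", {
    lr <- model$beta0 +
      model$beta_aa * counts$n_GGCTAA +
      model$beta_ga * counts$n_GGCTGA +
      model$beta_ag * counts$n_GGCTAG +
      model$beta_coex * as.numeric(counts$n_GGCTAA > 0 & counts$n_GGCTGA > 0) +
      rnorm(nrow(counts), 0, model$sigma)
    tibble::tibble(gene_id = counts$gene_id, ratio = exp(lr))
  })
}

# Linker sequences flanking every library insert (template top strand):
# the 5' linker is the read-1 sequencing adapter; the 3' linker is the
# reverse complement of the read-2 adapter.
LINKER_5P <- "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG"
LINKER_3P <- "CTGTCTCTTATACACATCTCCGAGCCCACGAGAC"

new_fragment_library <- function(fragments, linker_5p, linker_3p) {
  structure(list(fragments = fragments, linker_5p = linker_5p,
                 linker_3p = linker_3p), class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("<fragment_library> ", nrow(x$fragments), " fragments, mean insert ",
      round(mean(nchar(x$fragments$insert)), 1), " bp\n", sep = "")
  invisible(x)
}

#' Build a linker-flanked genomic fragment library
#'
#' Fragment start positions are uniform over the genome; insert lengths are
#' Normal(`mean_len`, `sd_len`) truncated to `[30, 3*mean_len]` and rounded;
#' strands are uniform. Each insert is the genome substring at its interval
#' (reverse-complemented for minus-strand fragments). Every fragment has
#' initial abundance 1 (round 0 of selection).
#'
#' @param genome A `genome_model`.
#' @param n_fragments Number of fragments (> 0).
#' @param mean_len,sd_len Insert length distribution in bp (the real library
#'   was size-fractionated to roughly 100 bp).
#' @param linker_5p,linker_3p Linker sequences ligated to the insert ends.
#' @param seed Top-level seed (sub-stream `"library"`).
#' @return A `fragment_library`: `fragments` tibble (`fragment_id`,
#'   `contig`, `start`, `end` 0-based half-open, `strand`, `insert`) plus
#'   the two linker sequences.
#' @export
build_library <- function(genome, n_fragments, mean_len = 100, sd_len = 15,
                          linker_5p = LINKER_5P, linker_3p = LINKER_3P,
                          seed = 1) {
  if (n_fragments <= 0) stop("n_fragments must be positive", call. = FALSE)
  contig_len <- Biostrings::width(genome$contigs)
  if (mean_len >= min(contig_len)) {
    stop("mean_len must be smaller than the shortest contig", call. = FALSE)
  }
  with_substream(seed, "library", {
    lens <- round(rnorm(n_fragments, mean_len, sd_len))
    lens <- pmin(pmax(lens, 30L), 3L * mean_len)
    ci <- sample.int(length(contig_len), n_fragments, replace = TRUE,
                     prob = contig_len / sum(contig_len))
    start <- floor(runif(n_fragments) * (contig_len[ci] - lens + 1))
    strand <- sample(c("+", "-"), n_fragments, replace = TRUE)
    inserts <- character(n_fragments)
    for (u in unique(ci)) {
      idx <- which(ci == u)
      at <- IRanges::IRanges(start = start[idx] + 1L, width = lens[idx])
      seqs <- Biostrings::extractAt(genome$contigs[[u]], at)
      inserts[idx] <- as.character(seqs)
    }
    neg <- strand == "-"
    inserts[neg] <- dna_revcomp(inserts[neg])
    fragments <- tibble::tibble(
      fragment_id = sprintf("frag%06d", seq_len(n_fragments)),
      contig = names(genome$contigs)[ci],
      start = as.integer(start), end = as.integer(start + lens),
      strand = strand, insert = inserts
    )
    new_fragment_library(fragments, linker_5p, linker_3p)
  })
}

#' Write simulation artifacts to disk
#'
#' Writes the genome FASTA, gene table TSV, promoters FASTA, expression TSV,
#' planted-truth TSV and library FASTA into a directory. All outputs are
#' byte-deterministic for a fixed simulation seed.
#'
#' @param genome A `genome_model`.
#' @param out_dir Output directory (created if needed).
#' @param expression,truth,library Optional tables/objects to write.
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(genome, out_dir, expression = NULL, truth = NULL,
                             library = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(genome$contigs, file.path(out_dir, "genome.fa"))
  readr::write_tsv(genome$genes, file.path(out_dir, "genes.tsv"))
  proms <- build_upstream1000(genome)
  fa <- Biostrings::DNAStringSet(proms$seq)
  names(fa) <- proms$gene_id
  Biostrings::writeXStringSet(fa, file.path(out_dir, "upstream1000.fa"))
  if (!is.null(expression)) {
    readr::write_tsv(expression, file.path(out_dir, "expression.tsv"))
  }
  if (!is.null(truth)) {
    readr::write_tsv(truth, file.path(out_dir, "planted_truth.tsv"))
  }
  if (!is.null(library)) {
    ins <- Biostrings::DNAStringSet(library$fragments$insert)
    names(ins) <- library$fragments$fragment_id
    Biostrings::writeXStringSet(ins, file.path(out_dir, "library.fa"))
  }
  invisible(out_dir)
}
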