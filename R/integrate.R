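# Integrated mining: DEG selection, Venn intersection with gSELEX
# candidates, Fisher motif-presence test, and Spearman/Pearson correlation
# of motif counts / coexistence flags / fold enrichment / summit position
# against differential expression.

#' Select differentially expressed genes
#'
#' Genes whose expression ratio strictly exceeds the threshold ("more than
#' five-fold" with the default).
#'
#' @param expr Expression tibble (`gene_id`, `ratio`).
#' @param threshold Fold-change threshold (strict inequality).
#' @return The subset tibble of DEGs.
#' @export
select_degs <- function(expr, threshold = 5) {
  stopifnot(all(c("gene_id", "ratio") %in% names(expr)))
  if (nrow(expr) > 0) stopifnot(all(expr$ratio > 0), all(is.finite(expr$ratio)))
  dplyr::filter(expr, .data$ratio > threshold)
}

#' Venn intersection of gSELEX candidates and DEGs
#'
#' @param candidates Character vector of candidate gene ids (promoters with
#'   at least one assigned summit window).
#' @param degs Character vector (or DEG tibble with `gene_id`) of
#'   differentially expressed genes.
#' @return A list with `counts` (named: `candidates_only`, `degs_only`,
#'   `intersection`) and `intersection` (the shared gene ids).
#' @export
#' @examples
#' intersect_sets(c("A", "B", "C"), c("B", "C", "D"))
intersect_sets <- function(candidates, degs) {
  if (is.data.frame(degs)) degs <- degs$gene_id
  candidates <- unique(candidates)
  degs <- unique(degs)
  both <- intersect(candidates, degs)
  list(
    counts = c(candidates_only = length(setdiff(candidates, degs)),
               degs_only = length(setdiff(degs, candidates)),
               intersection = length(both)),
    intersection = sort(both)
  )
}

#' Fisher's exact test of canonical-motif presence
#'
#' Two-sided exact test of the 2x2 table whose rows split the DEGs into the
#' gSELEX-intersecting and non-intersecting subsets and whose columns are
#' presence/absence of at least one canonical hexamer (GGCTAA, GGCTGA or
#' GGCTAG) in the promoter. The two-sided p sums hypergeometric tables with
#' probability at most that of the observed table; the odds ratio is the
#' sample odds ratio `ad/bc`.
#'
#' @param records Integration tibble (see [build_integration_table()]) with
#'   logical `in_intersection` and the canonical motif counts; or a 2x2
#'   matrix `(a, b; c, d)` given directly.
#' @return A `motif_fisher` object: list with `table`, `row_percent`
#'   (percent motif-positive per row), `odds_ratio` and `p_value`.
#' @export
fisher_motif_presence <- function(records) {
  if (is.matrix(records)) {
    tab <- records
  } else {
    stopifnot(all(c("in_intersection", "n_total") %in% names(records)))
    if (!any(records$in_intersection) || all(records$in_intersection)) {
      stop("both intersection partitions must be non-empty", call. = FALSE)
    }
    present <- records$n_total > 0
    tab <- rbind(
      intersection = c(sum(present & records$in_intersection),
                       sum(!present & records$in_intersection)),
      other = c(sum(present & !records$in_intersection),
                sum(!present & !records$in_intersection))
    )
    colnames(tab) <- c("motif_present", "motif_absent")
  }
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else fisher.test(tab)$p.value
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  structure(list(
    table = tab,
    row_percent = unname(tab[, 1] / rowSums(tab) * 100),
    odds_ratio = or, p_value = p
  ), class = "motif_fisher")
}

#' @export
print.motif_fisher <- function(x, ...) {
  cat("<motif_fisher> canonical-motif presence\n")
  print(x$table)
  cat(sprintf("row %% with motif: %.1f vs %.1f; OR = %.3g; two-sided p = %.4g\n",
              x$row_percent[1], x$row_percent[2], x$odds_ratio, x$p_value))
  invisible(x)
}

#' @method tidy motif_fisher
#' @export
tidy.motif_fisher <- function(x, ...) {
  tibble::tibble(estimate = x$odds_ratio, p.value = x$p_value,
                 percent_row1 = x$row_percent[1],
                 percent_row2 = x$row_percent[2],
                 method = "Fisher's exact test (two-sided)")
}

#' Build the per-gene integration table
#'
#' Joins promoter motif counts, expression ratios and (when available) the
#' best promoter peak hit into one record per gene, mirroring the study's
#' per-gene parameter table: motif counts and coexistence flags for every
#' gene, fold enrichment and summit promoter position for genes whose
#' promoter received a peak (duplicate hits collapsed to the largest fold
#' enrichment), and the candidate/intersection membership flags.
#'
#' @param counts Motif counts from [count_motifs()].
#' @param expr Expression tibble (`gene_id`, `ratio`).
#' @param hits Window-to-promoter hits from [assign_windows()] (may be
#'   empty/`NULL`).
#' @param peaks Peak tibble from [call_peaks()] (used for summit positions).
#' @param degs Optional DEG gene ids (vector or tibble); when given, a
#'   logical `in_intersection` column marks DEGs that are also candidates.
#' @param promoters Promoter tibble from [build_upstream1000()].
#' @return A tibble with one row per gene in `expr`: counts, flags, `ratio`,
#'   `fold_enrichment`, `P` (summit promoter coordinate), `is_candidate`,
#'   `in_intersection` (candidate and DEG set intersection indicator is
#'   filled by the caller via [select_degs()]; here candidate membership).
#' @export
build_integration_table <- function(counts, expr, hits = NULL, peaks = NULL,
                                    promoters = NULL, degs = NULL) {
  rec <- dplyr::inner_join(expr, counts, by = "gene_id")
  rec$fold_enrichment <- NA_real_
  rec$P <- NA_integer_
  rec$is_candidate <- FALSE
  if (!is.null(hits) && nrow(hits) > 0) {
    best <- dplyr::ungroup(dplyr::slice_max(
      dplyr::group_by(hits, .data$gene_id),
      order_by = .data$fold_enrichment, n = 1, with_ties = FALSE))
    rec$is_candidate <- rec$gene_id %in% hits$gene_id
    m <- match(rec$gene_id, best$gene_id)
    rec$fold_enrichment <- best$fold_enrichment[m]
    if (!is.null(peaks) && !is.null(promoters) && nrow(peaks) > 0) {
      pk <- match(best$peak_rank, peaks$rank)
      prom <- promoters[match(best$gene_id, promoters$gene_id), ]
      pp <- promoter_position(prom, peaks$contig[pk], peaks$summit[pk])
      rec$P <- pp$P[m]
      # FE and P are reported jointly: drop FE where the summit itself
      # falls outside the promoter
      rec$fold_enrichment[is.na(rec$P)] <- NA_real_
    }
  }
  if (!is.null(degs)) {
    if (is.data.frame(degs)) degs <- degs$gene_id
    rec$in_intersection <- rec$is_candidate & rec$gene_id %in% degs
  }
  rec
}

#' Correlate binding parameters with differential expression
#'
#' Spearman's rank correlation (average ranks on ties, t-approximation
#' p-values) and Pearson's correlation of each binding-related parameter
#' against the expression ratio. Pearson is computed on `log(ratio)` by
#' default (ratios are multiplicative); Spearman is invariant to that
#' choice. Genes with missing fold enrichment / summit position are dropped
#' pairwise for those parameters; constant parameters are reported as `NA`
#' with a warning.
#'
#' @param records Integration tibble from [build_integration_table()].
#' @param expr_transform `"log"` or `"linear"` expression scale for Pearson.
#' @param parameters Which record columns to test.
#' @return A tibble: `parameter`, `n`, `spearman_rho`, `spearman_p`,
#'   `pearson_r`, `pearson_p`.
#' @export
correlate_parameters <- function(records,
                                 expr_transform = c("log", "linear"),
                                 parameters = c("n_GGCTGA", "n_GGCTAA",
                                                "n_GGCTAG", "n_total",
                                                "n_monomer", "n_dimer",
                                                "fold_enrichment", "P",
                                                "coex_GA_AA", "coex_AA_AG",
                                                "coex_GA_AG")) {
  expr_transform <- match.arg(expr_transform)
  parameters <- intersect(parameters, names(records))
  y_all <- if (expr_transform == "log") log(records$ratio) else records$ratio
  rows <- lapply(parameters, function(par) {
    x <- as.numeric(records[[par]])
    ok <- !is.na(x) & !is.na(y_all)
    x <- x[ok]; y <- y_all[ok]
    if (length(x) < 3 || length(unique(x)) < 2 || length(unique(y)) < 2) {
      if (length(x) >= 3) {
        warning("parameter '", par, "' is constant; correlation undefined",
                call. = FALSE)
      }
      return(tibble::tibble(parameter = par, n = length(x),
                            spearman_rho = NA_real_, spearman_p = NA_real_,
                            pearson_r = NA_real_, pearson_p = NA_real_))
    }
    sp <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    pe <- cor.test(x, y, method = "pearson")
    tibble::tibble(parameter = par, n = length(x),
                   spearman_rho = unname(sp$estimate),
                   spearman_p = sp$p.value,
                   pearson_r = unname(pe$estimate), pearson_p = pe$p.value)
  })
  dplyr::bind_rows(rows)
}
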