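#' Correlation between two mutant expression signatures
#'
#' Pearson correlation of per-gene log2 ratios from two mutant models over an
#' explicitly supplied gene set, with the two-sided p-value from the t
#' transform. The gene set must be passed deliberately — which genes enter the
#' correlation changes its meaning, so there is no silent default to all genes.
#'
#' @param M_A,M_B named numeric vectors of per-gene log2 ratios.
#' @param genes gene ids present in both vectors (length >= 3).
#' @return list with `pearson_r`, `p_r`, `n_genes`.
#' @export
signature_correlation <- function(M_A, M_B, genes) {
  genes <- as.character(genes)
  if (length(genes) < 3L) stop("need >= 3 genes", call. = FALSE)
  if (!all(genes %in% names(M_A)) || !all(genes %in% names(M_B)))
    stop("all genes must be present in both M vectors", call. = FALSE)
  a <- M_A[genes]; b <- M_B[genes]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant vector: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(a, b, method = "pearson")
  list(pearson_r = unname(ct$estimate), p_r = ct$p.value,
       n_genes = length(genes))
}

#' Overlap of two downregulated gene sets
#'
#' Significance of the overlap of the genes downregulated in each single
#' mutant, via [overlap_enrichment()] on a shared universe.
#'
#' @param down_A,down_B downregulated gene sets.
#' @param universe shared gene universe.
#' @return an `enrichment_result`.
#' @export
down_overlap <- function(down_A, down_B, universe) {
  overlap_enrichment(down_A, down_B, universe)
}

#' Rank-shift test of a gene set toward low log2 ratios
#'
#' One-sided Mann-Whitney (Wilcoxon rank-sum) test that the M values of the
#' set members are lower than those of the complement — a transparent
#' rank-based check that a set defined in one model is shifted toward
#' downregulation in another. Depends only on ranks, so any strictly
#' monotone transform of M leaves the p-value unchanged.
#'
#' @param set_genes nonempty strict subset of `names(M)`.
#' @param M named numeric vector of per-gene log2 ratios.
#' @return one-sided p-value.
#' @export
rank_shift_test <- function(set_genes, M) {
  set_genes <- unique(as.character(set_genes))
  if (length(set_genes) == 0L)
    stop("set_genes is empty", call. = FALSE)
  if (!all(set_genes %in% names(M)))
    stop("set_genes must be scored in M", call. = FALSE)
  comp <- setdiff(names(M), set_genes)
  if (length(comp) == 0L)
    stop("set_genes must be a strict subset of the scored genes",
         call. = FALSE)
  stats::wilcox.test(M[set_genes], M[comp], alternative = "less")$p.value
}

#' Concordance report for two mutant signatures
#'
#' Combines signature correlation, downregulated-set overlap enrichment, and
#' the two directional rank-shift tests into one summary.
#'
#' @param M_A,M_B named per-gene log2 ratio vectors over a common universe.
#' @param genes gene set for the correlation.
#' @param down_A,down_B downregulated gene sets in each model.
#' @return list of class `concordance_report`.
#' @export
concordance_report <- function(M_A, M_B, genes, down_A, down_B) {
  universe <- intersect(names(M_A), names(M_B))
  corr <- signature_correlation(M_A, M_B, genes)
  structure(list(
    n_genes = corr$n_genes,
    pearson_r = corr$pearson_r,
    p_r = corr$p_r,
    overlap = down_overlap(down_A, down_B, universe),
    shift_p_AinB = rank_shift_test(down_A, M_B[universe]),
    shift_p_BinA = rank_shift_test(down_B, M_A[universe])),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("signature concordance over %d genes: r = %.3f (p = %.3g)\n",
              x$n_genes, x$pearson_r, x$p_r))
  cat(sprintf("  down-set overlap fold %.2f (hypergeometric p = %.3g)\n",
              x$overlap$fold_enrichment, x$overlap$p_hyper))
  cat(sprintf("  rank shift: A-set in B p = %.3g; B-set in A p = %.3g\n",
              x$shift_p_AinB, x$shift_p_BinA))
  invisible(x)
}
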