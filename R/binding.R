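#' Overlap enrichment of a gene set among bound genes
#'
#' Builds the 2x2 table of set membership versus binding within a fixed gene
#' universe and reports the fold enrichment of the observed overlap over the
#' expectation under independence, a one-sided hypergeometric tail p-value
#' (enrichment direction), and a two-sided Fisher exact p-value.
#'
#' @param set_genes gene set of interest (subset of `universe`, nonempty).
#' @param bound_genes bound genes (subset of `universe`).
#' @param universe full gene universe (nonempty, unique ids).
#' @return list of class `enrichment_result`: `table` (2x2 integer matrix),
#'   `overlap`, `fold_enrichment`, `p_hyper`, `p_fisher`.
#' @examples
#' overlap_enrichment(paste0("g", 1:5), paste0("g", 1:5), paste0("g", 1:10))
#' @export
overlap_enrichment <- function(set_genes, bound_genes, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe is empty", call. = FALSE)
  set_genes <- unique(as.character(set_genes))
  bound_genes <- unique(as.character(bound_genes))
  if (length(set_genes) == 0L)
    stop("set_genes is empty; fold enrichment undefined", call. = FALSE)
  if (!all(set_genes %in% universe) || !all(bound_genes %in% universe))
    stop("set_genes and bound_genes must be subsets of the universe",
         call. = FALSE)
  N <- length(universe); S <- length(set_genes); B <- length(bound_genes)
  k <- length(intersect(set_genes, bound_genes))

  tab <- matrix(as.integer(c(k, B - k, S - k, N - S - B + k)), nrow = 2,
                dimnames = list(set = c("in", "out"),
                                bound = c("yes", "no")))
  fold <- if (B == 0L) NA_real_ else (k / S) / (B / N)
  p_hyper <- stats::phyper(k - 1, B, N - B, S, lower.tail = FALSE)
  p_fisher <- stats::fisher.test(tab)$p.value
  structure(list(table = tab, overlap = k, fold_enrichment = fold,
                 p_hyper = p_hyper, p_fisher = p_fisher),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("overlap %d, fold enrichment %.3g\n", x$overlap,
              x$fold_enrichment))
  cat(sprintf("  hypergeometric (one-sided) p = %.3g, Fisher (two-sided) p = %.3g\n",
              x$p_hyper, x$p_fisher))
  invisible(x)
}

#' Co-occupancy of two transcription factors
#'
#' Tests whether genes bound by factor A are enriched among genes bound by
#' factor B across an annotation table, and reports the co-occupancy rate
#' |A and B| / |A|.
#'
#' @param binding data.frame with columns `gene_id`, `bound_A`, `bound_B`
#'   (logical or 0/1); gene ids unique.
#' @return an `enrichment_result` with an extra `cooccupancy_rate` element.
#' @export
cooccupancy <- function(binding) {
  stopifnot(is.data.frame(binding), nrow(binding) > 0L,
            all(c("gene_id", "bound_A", "bound_B") %in% names(binding)))
  if (anyDuplicated(binding$gene_id))
    stop("gene ids must be unique", call. = FALSE)
  a <- binding$gene_id[as.logical(binding$bound_A)]
  b <- binding$gene_id[as.logical(binding$bound_B)]
  res <- overlap_enrichment(a, b, binding$gene_id)
  res$cooccupancy_rate <- res$overlap / length(a)
  res
}

#' ChIP fold enrichment over a negative-control region
#'
#' Immunoprecipitated over input signal at the target region, corrected by
#' the same quantity at a negative-control region:
#' (ip/input) / (ip_ctrl/input_ctrl). Scale-invariant: multiplying all four
#' signals by a common positive constant leaves the result unchanged.
#'
#' @param ip_signal,input_signal IP and input signal at the target region.
#' @param ip_ctrl,input_ctrl IP and input signal at the negative-control
#'   region.
#' @return nonnegative fold enrichment (vectorized).
#' @export
chip_fold <- function(ip_signal, input_signal, ip_ctrl, input_ctrl) {
  if (any(input_signal <= 0) || any(input_ctrl <= 0) || any(ip_ctrl <= 0))
    stop("input and control signals must be positive", call. = FALSE)
  if (any(ip_signal < 0))
    stop("IP signal must be nonnegative", call. = FALSE)
  (ip_signal / input_signal) / (ip_ctrl / input_ctrl)
}

#' Compare ChIP fold enrichments between two conditions
#'
#' Replicate fold enrichments are computed per replicate first and averaged
#' after (fold-then-average); this function then compares the two conditions
#' with a two-sided Welch t-test on log2 folds.
#'
#' @param wt_folds,ko_folds fold enrichments per replicate (each length >= 2,
#'   all positive).
#' @return list with `difference` (mean log2 ko minus mean log2 wt) and
#'   `p_value`.
#' @export
compare_binding <- function(wt_folds, ko_folds) {
  if (length(wt_folds) < 2L || length(ko_folds) < 2L)
    stop("need >= 2 replicate folds per condition", call. = FALSE)
  if (any(wt_folds <= 0) || any(ko_folds <= 0))
    stop("folds must be positive", call. = FALSE)
  lw <- log2(wt_folds); lk <- log2(ko_folds)
  diff <- mean(lk) - mean(lw)
  if (stats::sd(lw) == 0 && stats::sd(lk) == 0)
    p <- if (diff == 0) 1 else 0
  else
    p <- stats::t.test(lk, lw, var.equal = FALSE)$p.value
  list(difference = diff, p_value = p)
}
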