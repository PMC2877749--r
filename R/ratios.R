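#' Selection thresholds for ratio-based gene sets
#'
#' Collects the cutoffs used by the selection helpers. Defaults are the
#' study-standard values: co-downregulation at M < -0.6 in both single
#' mutants; differential expression at >1.5-fold down with nominal P < 0.01
#' (or adjusted P < 0.05); a control band of unregulated genes with
#' -1.1 < M < 1.1 and p > 0.2 in both single mutants; and a >3-fold
#' double-mutant cutoff for the redundancy screen.
#'
#' @param m_down log2-ratio cutoff for co-downregulation (strict, default -0.6).
#' @param fold_down linear fold cutoff for differential expression (default 1.5,
#'   i.e. R < 1/1.5).
#' @param p_de nominal p cutoff for differential expression (default 0.01).
#' @param control_m_abs half-width of the control |M| band (default 1.1).
#' @param control_p_min minimum nominal p for control genes (default 0.2).
#' @param fold_double double-mutant fold cutoff of the redundancy screen
#'   (default 3).
#' @param p_adj adjusted-p cutoff (default 0.05).
#' @return list of class `selection_thresholds`.
#' @export
selection_thresholds <- function(m_down = -0.6, fold_down = 1.5, p_de = 0.01,
                                 control_m_abs = 1.1, control_p_min = 0.2,
                                 fold_double = 3.0, p_adj = 0.05) {
  stopifnot(m_down < 0, fold_down > 1, fold_double > 1,
            p_de > 0, p_de < 1, control_p_min > 0, control_p_min < 1,
            p_adj > 0, p_adj < 1, control_m_abs > 0)
  structure(list(m_down = m_down, fold_down = fold_down, p_de = p_de,
                 control_m_abs = control_m_abs, control_p_min = control_p_min,
                 fold_double = fold_double, p_adj = p_adj),
            class = "selection_thresholds")
}

#' Per-gene expression ratios for one genotype contrast
#'
#' For every gene, estimates the log2 mutant/wild-type ratio M as the
#' difference of replicate means, the linear ratio R = 2^M, a two-sided Welch
#' t p-value on the replicate log2 values, the Welch standard error of M, and
#' Benjamini-Hochberg adjusted p-values across genes.
#'
#' When a gene has zero variance in both groups (noise-free simulations) the
#' t statistic is undefined; the p-value is then set to 0 if M != 0 and 1 if
#' M == 0, with a warning, so that noise-free pipelines remain runnable.
#'
#' @param expr an [expression_set()].
#' @param contrast length-2 character: c(mutant genotype, reference genotype),
#'   e.g. `c("mutA", "WT")`.
#' @return data.frame with columns `gene_id`, `contrast`, `M`, `R`, `se_M`,
#'   `p_nominal`, `p_adjusted`. The contrast label is `"<mut>_vs_<ref>"`.
#' @examples
#' sim <- make_fixture()
#' head(compute_ratios(sim$expr, c("mutA", "WT")))
#' @export
compute_ratios <- function(expr, contrast) {
  stopifnot(inherits(expr, "expression_set"),
            is.character(contrast), length(contrast) == 2L)
  mut <- contrast[1]; ref <- contrast[2]
  for (g in c(mut, ref))
    if (!g %in% expr$design$genotype)
      stop("genotype absent from design: ", g, call. = FALSE)
  xm <- expr$values[, expr$design$genotype == mut, drop = FALSE]
  xr <- expr$values[, expr$design$genotype == ref, drop = FALSE]
  n1 <- ncol(xm); n2 <- ncol(xr)
  if (n1 < 2L || n2 < 2L)
    stop("need >= 2 replicates per genotype (have ", n1, " and ", n2, ")",
         call. = FALSE)

  m1 <- rowMeans(xm); m2 <- rowMeans(xr)
  v1 <- apply(xm, 1, stats::var); v2 <- apply(xr, 1, stats::var)
  M <- m1 - m2
  se <- sqrt(v1 / n1 + v2 / n2)

  # Welch-Satterthwaite degrees of freedom
  df <- (v1 / n1 + v2 / n2)^2 /
    (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  t_stat <- M / se
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)

  degen <- se == 0
  if (any(degen)) {
    warning(sum(degen), " gene(s) with zero within-group variance; ",
            "p set to 0 (M != 0) or 1 (M == 0)", call. = FALSE)
    p[degen] <- ifelse(M[degen] != 0, 0, 1)
  }

  data.frame(gene_id = rownames(expr$values),
             contrast = paste0(mut, "_vs_", ref),
             M = M, R = 2^M, se_M = se,
             p_nominal = p,
             p_adjusted = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ratio table for the three standard mutant-vs-WT contrasts
#'
#' @param expr an [expression_set()] containing all four genotypes.
#' @return row-bound [compute_ratios()] tables for mutA, mutB and double
#'   versus WT.
#' @export
ratio_table <- function(expr) {
  do.call(rbind, lapply(c("mutA", "mutB", "double"), function(g)
    compute_ratios(expr, c(g, "WT"))))
}

get_contrast <- function(ratios, label) {
  out <- ratios[ratios$contrast == label, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("contrast missing from ratio table: ", label, call. = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Genes downregulated in both single mutants
#'
#' Selects genes with M strictly below `m_down` in both single-mutant
#' contrasts. A gene sitting exactly at the threshold is excluded.
#'
#' @param ratios a ratio table covering `mutA_vs_WT` and `mutB_vs_WT`.
#' @param thresholds a [selection_thresholds()].
#' @return character vector of gene ids, sorted.
#' @export
select_codown <- function(ratios, thresholds = selection_thresholds()) {
  a <- get_contrast(ratios, "mutA_vs_WT")
  b <- get_contrast(ratios, "mutB_vs_WT")
  stopifnot(identical(a$gene_id, b$gene_id))
  sort(a$gene_id[a$M < thresholds$m_down & b$M < thresholds$m_down])
}

#' Control set of unregulated genes
#'
#' Genes with |M| strictly inside the control band and nominal p above
#' `control_p_min` in both single-mutant contrasts — i.e. genes showing no
#' evidence of regulation by either factor.
#'
#' @inheritParams select_codown
#' @return character vector of gene ids, sorted.
#' @export
select_control <- function(ratios, thresholds = selection_thresholds()) {
  a <- get_contrast(ratios, "mutA_vs_WT")
  b <- get_contrast(ratios, "mutB_vs_WT")
  stopifnot(identical(a$gene_id, b$gene_id))
  w <- thresholds$control_m_abs
  ok <- abs(a$M) < w & abs(b$M) < w &
    a$p_nominal > thresholds$control_p_min &
    b$p_nominal > thresholds$control_p_min
  sort(a$gene_id[ok])
}

#' Downregulated genes in a single contrast
#'
#' Two selection modes: `fold_nominal` (linear R < 1/fold_down and nominal
#' p < p_de) and `adjusted` (BH-adjusted p < p_adj and M < 0).
#'
#' @param ratios a ratio table.
#' @param contrast contrast label, e.g. `"mutA_vs_WT"`.
#' @param mode `"fold_nominal"` or `"adjusted"`.
#' @param thresholds a [selection_thresholds()].
#' @return character vector of gene ids, sorted.
#' @export
select_de <- function(ratios, contrast, mode = c("fold_nominal", "adjusted"),
                      thresholds = selection_thresholds()) {
  mode <- match.arg(mode)
  x <- get_contrast(ratios, contrast)
  ok <- if (mode == "fold_nominal")
    x$R < 1 / thresholds$fold_down & x$p_nominal < thresholds$p_de
  else
    x$p_adjusted < thresholds$p_adj & x$M < 0
  sort(x$gene_id[ok])
}

#' Collapse probe-level ratios to gene level
#'
#' Within each contrast, keeps one probe per gene: the probe with the smallest
#' nominal p-value; ties broken by larger |M|, then by lexicographic probe id.
#'
#' @param ratios probe-keyed ratio table (gene_id column holds probe ids).
#' @param probe_map data.frame with columns `probe_id` and `gene_id` covering
#'   every probe in `ratios`.
#' @return gene-keyed ratio table with an extra `probe_id` column recording
#'   the winning probe.
#' @export
collapse_probes <- function(ratios, probe_map) {
  if (is.null(probe_map) || nrow(probe_map) == 0L)
    stop("probe_map must be nonempty", call. = FALSE)
  if (!all(ratios$gene_id %in% probe_map$probe_id))
    stop("probe_map does not cover all probes", call. = FALSE)
  x <- ratios
  x$probe_id <- x$gene_id
  x$gene_id <- probe_map$gene_id[match(x$probe_id, probe_map$probe_id)]
  # order so the desired winner is first within each (gene, contrast)
  x <- x[order(x$gene_id, x$contrast, x$p_nominal, -abs(x$M), x$probe_id), ,
         drop = FALSE]
  keep <- !duplicated(x[, c("gene_id", "contrast")])
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
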