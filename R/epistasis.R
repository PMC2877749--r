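#' Per-gene epistasis statistic against the multiplicative null
#'
#' The epistasis value of a gene is the deviation of the observed double-mutant
#' expression ratio from the product of the two single-mutant ratios:
#' \deqn{\varepsilon = R_{AB} - R_A \times R_B.}
#' A positive value means the double mutant is less perturbed than expected
#' from independent action of the two factors — for downregulated targets,
#' the signature of synergistic (interdependent) regulation.
#'
#' @param R_A,R_B,R_AB positive linear mutant/wild-type ratios (vectorized).
#' @param tol classification tolerance passed to [classify_gene()].
#' @return data.frame with `R_A`, `R_B`, `R_AB`, `expected_R_AB`, `epsilon`,
#'   `class_label`.
#' @examples
#' compute_epsilon(0.5, 0.5, 0.25)  # multiplicative: epsilon = 0
#' compute_epsilon(0.5, 0.5, 0.5)   # synergistic:    epsilon = +0.25
#' @export
compute_epsilon <- function(R_A, R_B, R_AB, tol = 0) {
  if (any(!is.finite(R_A) | !is.finite(R_B) | !is.finite(R_AB)) ||
      any(R_A <= 0 | R_B <= 0 | R_AB <= 0))
    stop("ratios must be positive and finite", call. = FALSE)
  expected <- R_A * R_B
  eps <- R_AB - expected
  data.frame(R_A = R_A, R_B = R_B, R_AB = R_AB,
             expected_R_AB = expected, epsilon = eps,
             class_label = classify_gene(eps, tol),
             stringsAsFactors = FALSE)
}

#' Classify a gene by the sign of its epistasis value
#'
#' @param epsilon epistasis value(s).
#' @param tol nonnegative tolerance; default 0 classifies by pure sign.
#' @return character: `synergistic_consistent` (epsilon > tol),
#'   `multiplicative` (|epsilon| <= tol) or `sub_multiplicative`
#'   (epsilon < -tol).
#' @export
classify_gene <- function(epsilon, tol = 0) {
  stopifnot(tol >= 0)
  ifelse(epsilon > tol, "synergistic_consistent",
         ifelse(epsilon < -tol, "sub_multiplicative", "multiplicative"))
}

#' Epistasis table for a gene set
#'
#' Looks up the three contrasts of each gene in a ratio table and applies
#' [compute_epsilon()] gene by gene. Also carries `log2_epsilon_additive`,
#' the deviation from additivity on the log2 scale
#' (M_AB - M_A - M_B), as an optional diagnostic; the primary statistic is
#' the linear-scale epsilon.
#'
#' @param ratios a ratio table with contrasts `mutA_vs_WT`, `mutB_vs_WT` and
#'   `double_vs_WT`.
#' @param genes character vector of gene ids (may be empty).
#' @param tol classification tolerance.
#' @return data.frame with one row per gene.
#' @export
epistasis_table <- function(ratios, genes, tol = 0) {
  cols <- c("gene_id", "R_A", "R_B", "R_AB", "expected_R_AB", "epsilon",
            "class_label", "log2_epsilon_additive")
  if (length(genes) == 0L) {
    out <- data.frame(gene_id = character(), R_A = numeric(),
                      R_B = numeric(), R_AB = numeric(),
                      expected_R_AB = numeric(), epsilon = numeric(),
                      class_label = character(),
                      log2_epsilon_additive = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  a <- get_contrast(ratios, "mutA_vs_WT")
  b <- get_contrast(ratios, "mutB_vs_WT")
  d <- get_contrast(ratios, "double_vs_WT")
  for (tab in list(a, b, d)) {
    missing <- setdiff(genes, tab$gene_id)
    if (length(missing) > 0L)
      stop("gene(s) missing a contrast: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  ia <- match(genes, a$gene_id); ib <- match(genes, b$gene_id)
  id <- match(genes, d$gene_id)
  out <- compute_epsilon(a$R[ia], b$R[ib], d$R[id], tol = tol)
  out <- cbind(gene_id = genes, out, stringsAsFactors = FALSE)
  out$log2_epsilon_additive <- d$M[id] - a$M[ia] - b$M[ib]
  rownames(out) <- NULL
  out[, cols]
}

#' Distribution-level epistasis tests
#'
#' Two complementary tests of whether a set of genes deviates from the
#' multiplicative null: (i) a two-sided two-sample Student t comparing the
#' experimental epsilon distribution with a control-set epsilon distribution
#' (pooled variance by default; Welch via `var_equal = FALSE`); (ii) a
#' two-sided paired Student t comparing, gene by gene, the observed
#' double-mutant ratio with the expected product of the single-mutant ratios.
#'
#' @param eps_experimental,eps_control epsilon values (each length >= 2).
#' @param observed_R_AB,expected_R_AB paired per-gene vectors (equal length
#'   >= 2) for the paired test.
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @return list of class `epistasis_test_summary`: `n_experimental`,
#'   `n_control`, `mean_eps_exp`, `mean_eps_ctrl`, `p_two_sample`, `p_paired`.
#' @export
test_epistasis <- function(eps_experimental, eps_control,
                           observed_R_AB, expected_R_AB, var_equal = TRUE) {
  stopifnot(length(eps_experimental) >= 2L, length(eps_control) >= 2L,
            length(observed_R_AB) == length(expected_R_AB),
            length(observed_R_AB) >= 2L)
  p2 <- stats::t.test(eps_experimental, eps_control,
                      var.equal = var_equal)$p.value
  diffs <- observed_R_AB - expected_R_AB
  if (all(diffs == 0)) {
    warning("all paired differences are zero; p_paired set to 1",
            call. = FALSE)
    pp <- 1
  } else if (stats::sd(diffs) == 0) {
    # constant nonzero difference: exactly reproduced effect
    pp <- 0
  } else {
    pp <- stats::t.test(observed_R_AB, expected_R_AB, paired = TRUE)$p.value
  }
  structure(list(n_experimental = length(eps_experimental),
                 n_control = length(eps_control),
                 mean_eps_exp = mean(eps_experimental),
                 mean_eps_ctrl = mean(eps_control),
                 p_two_sample = p2, p_paired = pp),
            class = "epistasis_test_summary")
}

#' @export
print.epistasis_test_summary <- function(x, ...) {
  cat(sprintf(
    "epistasis tests: %d experimental vs %d control genes\n",
    x$n_experimental, x$n_control))
  cat(sprintf("  mean epsilon  experimental %.4f  control %.4f\n",
              x$mean_eps_exp, x$mean_eps_ctrl))
  cat(sprintf("  two-sample t p = %.3g   paired t p = %.3g\n",
              x$p_two_sample, x$p_paired))
  invisible(x)
}

#' Redundancy screen on strongly double-mutant-downregulated genes
#'
#' Selecting genes already downregulated in the single mutants biases against
#' finding redundancy, so this screen starts instead from genes downregulated
#' more than `fold_double`-fold in the double mutant and inspects their
#' single-mutant behaviour. A gene is flagged `redundant_pattern` when both
#' single-mutant effects are small (inside the control |M| band) while the
#' double mutant is strongly reduced — the hallmark of two factors able to
#' substitute for one another.
#'
#' @param ratios a ratio table covering all three contrasts.
#' @param thresholds a [selection_thresholds()].
#' @return data.frame with `gene_id`, `M_A`, `M_B`, `R_AB`, `epsilon`,
#'   `redundant_pattern`; empty when no gene passes the double-mutant cutoff.
#' @export
redundancy_screen <- function(ratios, thresholds = selection_thresholds()) {
  d <- get_contrast(ratios, "double_vs_WT")
  genes <- d$gene_id[d$R < 1 / thresholds$fold_double]
  eps <- epistasis_table(ratios, genes)
  a <- get_contrast(ratios, "mutA_vs_WT")
  b <- get_contrast(ratios, "mutB_vs_WT")
  M_A <- a$M[match(genes, a$gene_id)]
  M_B <- b$M[match(genes, b$gene_id)]
  data.frame(gene_id = genes, M_A = M_A, M_B = M_B,
             R_AB = eps$R_AB, epsilon = eps$epsilon,
             redundant_pattern = abs(M_A) < thresholds$control_m_abs &
               abs(M_B) < thresholds$control_m_abs,
             stringsAsFactors = FALSE)
}
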