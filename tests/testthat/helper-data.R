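# Shared fixtures, built in code.

# Hand-built two-gene expression set with known group means.
tiny_expr <- function() {
  vals <- rbind(
    g1 = c(10.0, 10.2, 9.8,  9.0, 9.3, 8.7,  10.0, 10.1, 9.9,  8.0, 8.1, 7.9),
    g2 = c(8.0,  8.1,  7.9,  8.0, 8.1, 7.9,   7.0, 7.2, 6.8,   6.0, 6.2, 5.8))
  colnames(vals) <- paste0(rep(c("WT", "mutA", "mutB", "double"), each = 3),
                           "_", 1:3)
  design <- data.frame(sample_id = colnames(vals),
                       genotype = rep(c("WT", "mutA", "mutB", "double"),
                                      each = 3),
                       replicate = rep(1:3, 4))
  expression_set(vals, design)
}

# Single-architecture config used by the calibration studies.
mono_config <- function(arch, n_genes, seed, noise_sd_log2 = 0.2,
                        bio_sd_log2 = 0, synergy_s = 0.5, ...) {
  p <- stats::setNames(rep(0, 6),
                       c("unregulated", "A_only", "B_only",
                         "independent_both", "synergistic", "redundant"))
  p[arch] <- 1
  sim_config(n_genes = n_genes, class_proportions = p, seed = seed,
             noise_sd_log2 = noise_sd_log2, bio_sd_log2 = bio_sd_log2,
             synergy_s = synergy_s, ...)
}

noise_free_fixture <- function(seed = 424242) {
  cfg <- sim_config(
    n_genes = 150L, seed = seed, noise_sd_log2 = 0, bio_sd_log2 = 0,
    class_proportions = c(unregulated = 0.40, A_only = 0.12, B_only = 0.12,
                          independent_both = 0.12, synergistic = 0.14,
                          redundant = 0.10))
  suppressWarnings(simulate_dataset(cfg))
}

# Ratio-table row constructor for threshold tests.
ratio_row <- function(gene, contrast, M, p = 0.001, p_adj = p) {
  data.frame(gene_id = gene, contrast = contrast, M = M, R = 2^M,
             se_M = 0.1, p_nominal = p, p_adjusted = p_adj,
             stringsAsFactors = FALSE)
}

# Independent Welch t oracle: textbook formulas, scalar, no shortcuts.
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  t <- (mean(x) - mean(y)) / se
  df <- (v1 / n1 + v2 / n2)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

# Exhaustive hypergeometric tail oracle: enumerate every size-S subset of
# 1..N, bound set = 1..B, count subsets overlapping by >= k.
hyper_enum_oracle <- function(k, B, N, S) {
  subsets <- utils::combn(N, S)
  mean(colSums(subsets <= B) >= k)
}
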