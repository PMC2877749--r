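ARCH_CLASSES <- c("unregulated", "A_only", "B_only",
                  "independent_both", "synergistic", "redundant")
GENOTYPES <- c("WT", "mutA", "mutB", "double")

# architectures in which each factor truly participates
ARCH_A <- c("A_only", "independent_both", "synergistic", "redundant")
ARCH_B <- c("B_only", "independent_both", "synergistic", "redundant")

#' Simulation configuration
#'
#' Parameters of the four-genotype expression simulator. Defaults emulate a
#' small-animal islet microarray study: three array replicates per genotype,
#' each array a pool of several animals, log-normal measurement noise, and a
#' minority of genes downregulated by factor A and/or factor B with
#' single-mutant effects straddling the M < -0.6 selection threshold.
#'
#' @param n_genes number of genes to simulate.
#' @param replicates_per_genotype arrays per genotype (default 3).
#' @param pool_size animals averaged per array (default 3; realistic range 2-4).
#' @param class_proportions named numeric over the six regulatory architecture
#'   classes (`unregulated`, `A_only`, `B_only`, `independent_both`,
#'   `synergistic`, `redundant`); must be nonnegative and sum to 1.
#' @param effect_low,effect_high bounds in (0,1) for the linear single-mutant
#'   downregulation ratio; effects are drawn log-uniformly between them.
#' @param synergy_s synergy parameter in \[0,1\]: synergistic genes have
#'   \eqn{R_{AB} = (R_A R_B)^{1-s}}, so s = 0 reproduces independence and
#'   s = 1 full mutual buffering.
#' @param redundant_double_ratio double-mutant linear ratio of redundant genes
#'   (single mutants stay at 1).
#' @param noise_sd_log2 per-array measurement noise SD on the log2 scale.
#' @param bio_sd_log2 per-animal biological variation SD on the log2 scale.
#' @param binding_sens probability a gene whose architecture involves a factor
#'   is labelled bound by that factor.
#' @param binding_fpr probability an uninvolved gene is labelled bound.
#' @param seed integer seed governing all draws of one simulation.
#' @return a list of class `sim_config`.
#' @seealso [simulate_dataset()], [make_fixture()]
#' @export
sim_config <- function(n_genes = 2000L,
                       replicates_per_genotype = 3L,
                       pool_size = 3L,
                       class_proportions = c(unregulated = 0.76,
                                             A_only = 0.04,
                                             B_only = 0.04,
                                             independent_both = 0.06,
                                             synergistic = 0.08,
                                             redundant = 0.02),
                       effect_low = 0.2,
                       effect_high = 0.7,
                       synergy_s = 0.5,
                       redundant_double_ratio = 0.25,
                       noise_sd_log2 = 0.2,
                       bio_sd_log2 = 0.2,
                       binding_sens = 0.6,
                       binding_fpr = 0.1,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              replicates_per_genotype = as.integer(replicates_per_genotype),
              pool_size = as.integer(pool_size),
              class_proportions = class_proportions,
              effect_low = effect_low, effect_high = effect_high,
              synergy_s = synergy_s,
              redundant_double_ratio = redundant_double_ratio,
              noise_sd_log2 = noise_sd_log2, bio_sd_log2 = bio_sd_log2,
              binding_sens = binding_sens, binding_fpr = binding_fpr,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  p <- cfg$class_proportions
  if (is.null(names(p)) || !setequal(names(p), ARCH_CLASSES))
    stop("class_proportions must be named over the six architecture classes",
         call. = FALSE)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("class_proportions must be nonnegative and sum to 1", call. = FALSE)
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (cfg$replicates_per_genotype < 1L || cfg$pool_size < 1L)
    stop("replicates_per_genotype and pool_size must be >= 1", call. = FALSE)
  if (!(cfg$effect_low > 0 && cfg$effect_high < 1 &&
        cfg$effect_low <= cfg$effect_high))
    stop("need 0 < effect_low <= effect_high < 1", call. = FALSE)
  if (cfg$synergy_s < 0 || cfg$synergy_s > 1)
    stop("synergy_s must lie in [0,1]", call. = FALSE)
  if (cfg$redundant_double_ratio <= 0 || cfg$redundant_double_ratio >= 1)
    stop("redundant_double_ratio must lie in (0,1)", call. = FALSE)
  if (cfg$noise_sd_log2 < 0 || cfg$bio_sd_log2 < 0)
    stop("noise SDs must be nonnegative", call. = FALSE)
  for (f in c("binding_sens", "binding_fpr"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must lie in [0,1]", call. = FALSE)
  invisible(cfg)
}

# Run expr with a private RNG state seeded from `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Construct an expression set
#'
#' Bundles a genes x samples log2 intensity matrix with its sample design
#' (genotype and replicate index per sample).
#'
#' @param values numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param design data.frame with columns `sample_id`, `genotype` (one of
#'   WT/mutA/mutB/double) and `replicate`.
#' @return list of class `expression_set` with elements `values` and `design`.
#' @export
expression_set <- function(values, design) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("gene ids (rownames) must be present and unique", call. = FALSE)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("sample ids (colnames) must be present and unique", call. = FALSE)
  if (!all(is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  if (!identical(sort(colnames(values)), sort(as.character(design$sample_id))))
    stop("design sample_id must match matrix columns", call. = FALSE)
  if (!all(design$genotype %in% GENOTYPES))
    stop("design genotypes must be in {WT, mutA, mutB, double}", call. = FALSE)
  design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(values = values, design = design), class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("expression_set:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  print(table(x$design$genotype))
  invisible(x)
}

#' Simulate a four-genotype expression dataset with known architecture
#'
#' Each gene is assigned one of six regulatory architectures, true linear
#' mutant/wild-type ratios per genotype, and binding labels correlated with
#' its architecture. Every array value is the mean of `pool_size` animal-level
#' log2 draws (baseline + genotype effect + per-animal noise) plus per-array
#' measurement noise. Synergistic genes follow
#' \eqn{R_{AB} = (R_A R_B)^{1-s}}; redundant genes have unperturbed single
#' mutants and a strongly reduced double mutant; `independent_both` genes obey
#' the multiplicative null exactly, so their true epistasis is zero.
#'
#' @param config a [sim_config()].
#' @return list with `expr` (an [expression_set()]) and `truth` (data.frame
#'   with `gene_id`, `arch_class`, `true_R_A`, `true_R_B`, `true_R_AB`,
#'   `true_epsilon`, `bound_A`, `bound_B`).
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 50, seed = 7))
#' dim(sim$expr$values)
#' table(sim$truth$arch_class)
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  n <- cfg$n_genes
  gene_id <- sprintf("gene_%04d", seq_len(n))
  arch <- sample(ARCH_CLASSES, n, replace = TRUE,
                 prob = cfg$class_proportions[ARCH_CLASSES])
  baseline <- stats::runif(n, 6, 12)

  # log-uniform single-mutant effects wherever the factor acts directly;
  # redundant genes override both singles to 1.
  draw_effect <- function(k)
    exp(stats::runif(k, log(cfg$effect_low), log(cfg$effect_high)))
  true_R_A <- rep(1, n)
  true_R_B <- rep(1, n)
  ia <- arch %in% c("A_only", "independent_both", "synergistic")
  ib <- arch %in% c("B_only", "independent_both", "synergistic")
  true_R_A[ia] <- draw_effect(sum(ia))
  true_R_B[ib] <- draw_effect(sum(ib))

  true_R_AB <- true_R_A * true_R_B
  syn <- arch == "synergistic"
  true_R_AB[syn] <- (true_R_A[syn] * true_R_B[syn])^(1 - cfg$synergy_s)
  red <- arch == "redundant"
  true_R_AB[red] <- cfg$redundant_double_ratio
  true_epsilon <- true_R_AB - true_R_A * true_R_B

  bound_A <- stats::runif(n) < ifelse(arch %in% ARCH_A,
                                      cfg$binding_sens, cfg$binding_fpr)
  bound_B <- stats::runif(n) < ifelse(arch %in% ARCH_B,
                                      cfg$binding_sens, cfg$binding_fpr)

  effects <- cbind(WT = 0, mutA = log2(true_R_A),
                   mutB = log2(true_R_B), double = log2(true_R_AB))

  reps <- cfg$replicates_per_genotype
  design <- data.frame(
    sample_id = paste0(rep(GENOTYPES, each = reps), "_", seq_len(reps)),
    genotype = rep(GENOTYPES, each = reps),
    replicate = rep(seq_len(reps), times = 4L),
    stringsAsFactors = FALSE)

  values <- matrix(0, nrow = n, ncol = nrow(design),
                   dimnames = list(gene_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    mu <- baseline + effects[, design$genotype[j]]
    pooled <- mu
    if (cfg$bio_sd_log2 > 0) {
      animal <- matrix(stats::rnorm(n * cfg$pool_size, sd = cfg$bio_sd_log2),
                       nrow = n)
      pooled <- mu + rowMeans(animal)
    }
    arr <- pooled
    if (cfg$noise_sd_log2 > 0)
      arr <- arr + stats::rnorm(n, sd = cfg$noise_sd_log2)
    values[, j] <- arr
  }

  truth <- data.frame(gene_id = gene_id, arch_class = arch,
                      true_R_A = true_R_A, true_R_B = true_R_B,
                      true_R_AB = true_R_AB, true_epsilon = true_epsilon,
                      bound_A = bound_A, bound_B = bound_B,
                      stringsAsFactors = FALSE)
  list(expr = expression_set(values, design), truth = truth)
}

#' Small deterministic fixture dataset
#'
#' 120-gene dataset produced with a hard-coded seed and class proportions
#' chosen so every architecture class is represented. Identical on every call;
#' used throughout the tests and documentation.
#'
#' @return as [simulate_dataset()].
#' @export
make_fixture <- function() {
  cfg <- sim_config(
    n_genes = 120L, seed = 20090417L,
    class_proportions = c(unregulated = 0.50, A_only = 0.10, B_only = 0.10,
                          independent_both = 0.10, synergistic = 0.12,
                          redundant = 0.08))
  simulate_dataset(cfg)
}
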