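#' Run the full epistasis analysis pipeline
#'
#' Orchestrates the stages end to end: simulate (or load) a four-genotype
#' expression set, estimate per-gene ratios for the three mutant-vs-WT
#' contrasts, select the co-downregulated and control gene sets, compute the
#' per-gene epistasis table and distribution-level tests, run the redundancy
#' screen, the binding co-occupancy analysis (when binding labels are
#' available) and the signature-concordance report, writing every stage's
#' table plus a run manifest to the output directory. All outputs are a pure
#' function of the inputs, configuration and seed; files are written
#' atomically.
#'
#' @param out_dir output directory (created if needed).
#' @param sim a [sim_config()] for simulate mode, or NULL to read data from
#'   `matrix_path`/`design_path`.
#' @param matrix_path,design_path input TSVs (used when `sim` is NULL).
#' @param binding data.frame (`gene_id`, `bound_A`, `bound_B`) or NULL; in
#'   simulate mode defaults to the simulated truth labels.
#' @param thresholds a [selection_thresholds()].
#' @param seed top-level seed; in simulate mode it overrides `sim$seed`.
#' @param quiet suppress per-stage messages.
#' @return invisibly, a list with every stage result and the manifest.
#' @examples
#' \donttest{
#' res <- run_pipeline(tempfile("run"), sim = sim_config(n_genes = 200))
#' res$test_summary
#' }
#' @export
run_pipeline <- function(out_dir,
                         sim = NULL,
                         matrix_path = NULL, design_path = NULL,
                         binding = NULL,
                         thresholds = selection_thresholds(),
                         seed = 1L,
                         quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  inputs <- character()

  if (!is.null(sim)) {
    sim$seed <- as.integer(seed)
    validate_sim_config(sim)
    say("stage simulate: ", sim$n_genes, " genes")
    ds <- simulate_dataset(sim)
    expr <- ds$expr
    truth <- ds$truth
    write_expression(expr, file.path(out_dir, "matrix.tsv"),
                     file.path(out_dir, "design.tsv"))
    write_table(truth, file.path(out_dir, "truth.tsv"))
    if (is.null(binding))
      binding <- truth[, c("gene_id", "bound_A", "bound_B")]
  } else {
    if (is.null(matrix_path) || is.null(design_path))
      stop("need either a sim config or matrix_path + design_path",
           call. = FALSE)
    say("stage load: ", matrix_path)
    expr <- read_expression(matrix_path, design_path)
    truth <- NULL
    inputs <- c(matrix_path, design_path)
  }

  say("stage ratios: ", nrow(expr$values), " genes in")
  ratios <- ratio_table(expr)
  write_table(ratios, file.path(out_dir, "ratios.tsv"))

  codown <- select_codown(ratios, thresholds)
  control <- select_control(ratios, thresholds)
  say("stage select: ", length(codown), " co-down, ",
      length(control), " control genes")
  writeLines(codown, file.path(out_dir, "genes_codown.txt"))
  writeLines(control, file.path(out_dir, "genes_control.txt"))

  eps_exp <- epistasis_table(ratios, codown)
  eps_ctrl <- epistasis_table(ratios, control)
  write_table(eps_exp, file.path(out_dir, "epistasis_experimental.tsv"))
  write_table(eps_ctrl, file.path(out_dir, "epistasis_control.tsv"))

  test_summary <- NULL
  if (nrow(eps_exp) >= 2L && nrow(eps_ctrl) >= 2L) {
    test_summary <- test_epistasis(eps_exp$epsilon, eps_ctrl$epsilon,
                                   eps_exp$R_AB, eps_exp$expected_R_AB)
    write_json_file(unclass(test_summary),
                    file.path(out_dir, "epistasis_tests.json"))
    say("stage epistasis: paired t p = ",
        format(test_summary$p_paired, digits = 3))
  } else {
    say("stage epistasis: too few genes for distribution tests")
  }

  screen <- redundancy_screen(ratios, thresholds)
  write_table(screen, file.path(out_dir, "redundancy_screen.tsv"))
  say("stage redundancy: ", nrow(screen), " genes > ",
      thresholds$fold_double, "-fold down in double")

  enrich <- NULL
  if (!is.null(binding)) {
    enrich <- cooccupancy(binding)
    write_json_file(list(overlap = enrich$overlap,
                         fold_enrichment = enrich$fold_enrichment,
                         cooccupancy_rate = enrich$cooccupancy_rate,
                         p_hyper = enrich$p_hyper,
                         p_fisher = enrich$p_fisher),
                    file.path(out_dir, "cooccupancy.json"))
    say("stage enrich: co-occupancy fold ",
        format(enrich$fold_enrichment, digits = 3))
  }

  concord <- NULL
  a <- get_contrast(ratios, "mutA_vs_WT")
  b <- get_contrast(ratios, "mutB_vs_WT")
  M_A <- stats::setNames(a$M, a$gene_id)
  M_B <- stats::setNames(b$M, b$gene_id)
  down_A <- select_de(ratios, "mutA_vs_WT", "fold_nominal", thresholds)
  down_B <- select_de(ratios, "mutB_vs_WT", "fold_nominal", thresholds)
  # genome-wide signature correlation: the whole scored transcriptome is
  # passed explicitly as the correlation set
  corr_set <- names(M_A)
  if (length(corr_set) >= 3L && length(down_A) > 0L && length(down_B) > 0L &&
      length(down_A) < length(M_A) && length(down_B) < length(M_B)) {
    concord <- concordance_report(M_A, M_B, corr_set, down_A, down_B)
    write_json_file(list(n_genes = concord$n_genes,
                         pearson_r = concord$pearson_r,
                         p_r = concord$p_r,
                         overlap_fold = concord$overlap$fold_enrichment,
                         overlap_p_hyper = concord$overlap$p_hyper,
                         shift_p_AinB = concord$shift_p_AinB,
                         shift_p_BinA = concord$shift_p_BinA),
                    file.path(out_dir, "concordance.json"))
    say("stage concord: r = ", format(concord$pearson_r, digits = 3),
        " over ", concord$n_genes, " genes")
  } else {
    say("stage concord: skipped (too few downregulated genes)")
  }

  outputs <- list.files(out_dir, pattern = "\\.(tsv|txt|json)$")
  manifest <- list(
    tool = "epistrans",
    version = as.character(utils::packageVersion("epistrans")),
    seed = as.integer(seed),
    mode = if (!is.null(sim)) "simulate" else "load",
    thresholds = unclass(thresholds),
    input_checksums = as.list(tools::md5sum(inputs)),
    counts = list(genes = nrow(expr$values),
                  samples = ncol(expr$values),
                  codown = length(codown),
                  control = length(control),
                  redundancy_screen = nrow(screen)),
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  write_json_file(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(expr = expr, truth = truth, ratios = ratios,
                 codown = codown, control = control,
                 epistasis_experimental = eps_exp,
                 epistasis_control = eps_ctrl,
                 test_summary = test_summary,
                 redundancy = screen, cooccupancy = enrich,
                 concordance = concord, manifest = manifest))
}
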