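test_that("ratio estimates match hand arithmetic and a Welch oracle", {
  r <- compute_ratios(tiny_expr(), c("mutA", "WT"))
  g1 <- r[r$gene_id == "g1", ]
  expect_equal(g1$M, -1)
  expect_equal(g1$R, 0.5)
  orc <- welch_oracle(c(9.0, 9.3, 8.7), c(10.0, 10.2, 9.8))
  expect_equal(g1$p_nominal, orc$p, tolerance = 1e-12)
  expect_equal(g1$se_M, sqrt(var(c(9, 9.3, 8.7)) / 3 +
                             var(c(10, 10.2, 9.8)) / 3))

  # random matrices against stats::t.test gene by gene
  set.seed(42)
  sim <- simulate_dataset(sim_config(n_genes = 25, seed = 8))
  r <- compute_ratios(sim$expr, c("double", "WT"))
  vals <- sim$expr$values
  geno <- sim$expr$design$genotype
  for (g in sample(rownames(vals), 10)) {
    tt <- t.test(vals[g, geno == "double"], vals[g, geno == "WT"])
    row <- r[r$gene_id == g, ]
    expect_equal(row$p_nominal, tt$p.value, tolerance = 1e-12)
    expect_equal(row$M, unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
})

test_that("zero-difference and zero-variance cases are handled", {
  vals <- rbind(flat = rep(5, 8), shift = rep(c(5, 4), each = 4))
  colnames(vals) <- paste0(rep(c("WT", "mutA"), each = 4), "_", 1:4)
  design <- data.frame(sample_id = colnames(vals),
                       genotype = rep(c("WT", "mutA"), each = 4),
                       replicate = rep(1:4, 2))
  ex <- expression_set(vals, design)
  expect_warning(r <- compute_ratios(ex, c("mutA", "WT")), "zero")
  expect_equal(r$p_nominal[r$gene_id == "flat"], 1)
  expect_equal(r$M[r$gene_id == "flat"], 0)
  expect_equal(r$p_nominal[r$gene_id == "shift"], 0)
  expect_equal(r$M[r$gene_id == "shift"], -1)
})

test_that("replication and design preconditions are enforced", {
  ex <- tiny_expr()
  expect_error(compute_ratios(ex, c("mutC", "WT")), "absent")
  one_rep <- expression_set(ex$values[, c(1, 2, 4), drop = FALSE],
                            ex$design[c(1, 2, 4), ])
  expect_error(compute_ratios(one_rep, c("mutA", "WT")), "replicates")
})

test_that("exchanging group labels negates M and preserves the p-value", {
  sim <- simulate_dataset(sim_config(n_genes = 30, seed = 13))
  fwd <- compute_ratios(sim$expr, c("mutA", "WT"))
  rev <- compute_ratios(sim$expr, c("WT", "mutA"))
  expect_equal(fwd$M, -rev$M)
  expect_equal(fwd$p_nominal, rev$p_nominal)
})

test_that("BH adjustment is monotone in the p-value ranks and bounded by 1", {
  sim <- simulate_dataset(sim_config(n_genes = 400, seed = 17))
  r <- compute_ratios(sim$expr, c("mutB", "WT"))
  expect_true(all(r$p_adjusted >= r$p_nominal - 1e-15))
  expect_true(all(r$p_adjusted <= 1))
  o <- order(r$p_nominal)
  expect_true(all(diff(r$p_adjusted[o]) >= -1e-15))
  expect_equal(r$p_adjusted, p.adjust(r$p_nominal, "BH"))
})

test_that("co-down selection uses strict thresholds in both single mutants", {
  ratios <- rbind(
    ratio_row("both_down", "mutA_vs_WT", -0.7),
    ratio_row("both_down", "mutB_vs_WT", -0.8),
    ratio_row("boundary", "mutA_vs_WT", -0.6),
    ratio_row("boundary", "mutB_vs_WT", -0.9),
    ratio_row("one_only", "mutA_vs_WT", -0.9),
    ratio_row("one_only", "mutB_vs_WT", -0.1))
  expect_equal(select_codown(ratios), "both_down")
  expect_error(select_codown(ratios[ratios$contrast == "mutA_vs_WT", ]),
               "contrast missing")
})

test_that("control selection requires a quiet M band and large p in both", {
  ratios <- rbind(
    ratio_row("quiet",  "mutA_vs_WT", 0.05, p = 0.9),
    ratio_row("quiet",  "mutB_vs_WT", -0.1, p = 0.8),
    ratio_row("smallp", "mutA_vs_WT", 0.0,  p = 0.1),
    ratio_row("smallp", "mutB_vs_WT", 0.0,  p = 0.9),
    ratio_row("big_m",  "mutA_vs_WT", -1.2, p = 0.5),
    ratio_row("big_m",  "mutB_vs_WT", 0.0,  p = 0.5))
  expect_equal(select_control(ratios), "quiet")
})

test_that("differential-expression selection honours both modes", {
  ratios <- rbind(
    ratio_row("strong", "mutA_vs_WT", log2(0.5), p = 0.001, p_adj = 0.01),
    ratio_row("weak_fold", "mutA_vs_WT", log2(0.70), p = 1e-6, p_adj = 1e-5),
    ratio_row("weak_p", "mutA_vs_WT", log2(0.4), p = 0.05, p_adj = 0.2),
    ratio_row("up", "mutA_vs_WT", 1.0, p = 1e-6, p_adj = 0.001))
  expect_equal(select_de(ratios, "mutA_vs_WT", "fold_nominal"), "strong")
  # 0.70 > 1/1.5: excluded however small the p
  expect_false("weak_fold" %in%
                 select_de(ratios, "mutA_vs_WT", "fold_nominal"))
  expect_setequal(select_de(ratios, "mutA_vs_WT", "adjusted"),
                  c("strong", "weak_fold"))
  expect_error(select_de(ratios, "mutA_vs_WT", "bogus"))
})

test_that("probe collapse keeps the best probe with documented tie-breaks", {
  ratios <- rbind(
    ratio_row("p1", "mutA_vs_WT", -1.0, p = 0.001),
    ratio_row("p2", "mutA_vs_WT", -0.5, p = 0.5),
    ratio_row("p3", "mutA_vs_WT", 0.9, p = 0.2),
    ratio_row("p4", "mutA_vs_WT", -0.3, p = 0.2),
    ratio_row("p5", "mutA_vs_WT", 0.4, p = 0.2),
    ratio_row("p6", "mutA_vs_WT", -0.4, p = 0.2),
    ratio_row("p7", "mutB_vs_WT", -2.0, p = 0.9))
  map <- data.frame(probe_id = paste0("p", 1:7),
                    gene_id = c("gA", "gA", "gB", "gB", "gC", "gC", "gA"))
  out <- collapse_probes(ratios, map)
  # smallest p wins
  expect_equal(out$probe_id[out$gene_id == "gA" &
                              out$contrast == "mutA_vs_WT"], "p1")
  # tie on p broken by larger |M|
  expect_equal(out$probe_id[out$gene_id == "gB"], "p3")
  # tie on p and |M| broken lexicographically
  expect_equal(out$probe_id[out$gene_id == "gC"], "p5")
  # single-probe contrasts pass through
  expect_equal(out$probe_id[out$contrast == "mutB_vs_WT"], "p7")
  expect_error(collapse_probes(ratios, map[1:3, ]), "cover")
  expect_error(collapse_probes(ratios, map[0, ]), "nonempty")
})
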