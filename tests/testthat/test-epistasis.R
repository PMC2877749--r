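test_that("epsilon arithmetic and classification follow the multiplicative null", {
  e <- compute_epsilon(0.5, 0.5, 0.25)
  expect_equal(e$epsilon, 0)
  expect_equal(e$expected_R_AB, 0.25)
  expect_equal(e$class_label, "multiplicative")
  e <- compute_epsilon(0.5, 0.5, 0.5)
  expect_equal(e$epsilon, 0.25)
  expect_equal(e$class_label, "synergistic_consistent")

  # identity of the null over random positive ratios
  set.seed(1)
  ra <- runif(50, 0.05, 2); rb <- runif(50, 0.05, 2)
  expect_equal(compute_epsilon(ra, rb, ra * rb)$epsilon, rep(0, 50))

  expect_error(compute_epsilon(0, 0.5, 0.5), "positive")
  expect_error(compute_epsilon(0.5, 0.5, -1), "positive")

  expect_equal(classify_gene(c(0.25, 0, -0.2), tol = 0.05),
               c("synergistic_consistent", "multiplicative",
                 "sub_multiplicative"))
  expect_equal(classify_gene(0, tol = 0), "multiplicative")
})

test_that("epistasis table maps gene sets through the ratio table", {
  sim <- noise_free_fixture()
  r <- suppressWarnings(ratio_table(sim$expr))
  tr <- sim$truth

  ind <- tr$gene_id[tr$arch_class == "independent_both"]
  et <- epistasis_table(r, ind)
  expect_equal(et$epsilon, rep(0, length(ind)), tolerance = 1e-12)
  expect_equal(et$expected_R_AB, et$R_A * et$R_B, tolerance = 1e-14)

  syn <- tr$gene_id[tr$arch_class == "synergistic"]
  expect_true(all(epistasis_table(r, syn)$epsilon > 0))

  empty <- epistasis_table(r, character())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("gene_id", "epsilon", "class_label") %in% names(empty)))

  expect_error(epistasis_table(r, "no_such_gene"), "no_such_gene")
  # gene ordering does not change per-gene values
  perm <- sample(ind)
  et2 <- epistasis_table(r, perm)
  expect_equal(et2$epsilon[match(ind, et2$gene_id)], et$epsilon)
})

test_that("distribution tests agree with hand-computed t statistics", {
  exp_eps <- c(0.20, 0.30, 0.25)
  ctl_eps <- c(0.00, -0.05, 0.05)
  obs <- c(0.50, 0.40, 0.45)
  expd <- c(0.30, 0.25, 0.20)
  s <- test_epistasis(exp_eps, ctl_eps, obs, expd)

  # pooled-variance two-sample t computed from first principles
  n1 <- 3; n2 <- 3
  sp2 <- (sum((exp_eps - mean(exp_eps))^2) +
            sum((ctl_eps - mean(ctl_eps))^2)) / (n1 + n2 - 2)
  t2 <- (mean(exp_eps) - mean(ctl_eps)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_equal(s$p_two_sample, 2 * pt(abs(t2), n1 + n2 - 2, lower.tail = FALSE),
               tolerance = 1e-12)

  # paired t computed from the differences
  d <- obs - expd
  tp <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(s$p_paired, 2 * pt(abs(tp), length(d) - 1, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_equal(s$n_experimental, 3L)
  expect_equal(s$mean_eps_exp, 0.25)

  # identical samples: pooled t = 0, p = 1
  same <- c(0.1, 0.2, 0.3)
  expect_equal(test_epistasis(same, same, obs, expd)$p_two_sample, 1)
})

test_that("degenerate paired input returns p 1 with a warning", {
  expect_warning(
    s <- test_epistasis(c(0.1, 0.2), c(0, 0.05), c(0.5, 0.6), c(0.5, 0.6)),
    "zero")
  expect_equal(s$p_paired, 1)
})

test_that("redundancy screen flags the redundant architecture", {
  sim <- noise_free_fixture()
  r <- suppressWarnings(ratio_table(sim$expr))
  tr <- sim$truth
  screen <- redundancy_screen(r)

  expect_setequal(screen$gene_id, tr$gene_id[tr$true_R_AB < 1 / 3])

  red <- tr$gene_id[tr$arch_class == "redundant"]  # true_R_AB = 0.25 < 1/3
  rows <- screen[match(red, screen$gene_id), ]
  expect_true(all(rows$redundant_pattern))
  expect_equal(rows$epsilon, rep(0.25 - 1, length(red)), tolerance = 1e-12)

  syn_in <- intersect(screen$gene_id,
                      tr$gene_id[tr$arch_class == "synergistic"])
  if (length(syn_in) > 0) {
    rows <- screen[match(syn_in, screen$gene_id), ]
    expect_true(all(rows$epsilon > 0))
    # synergistic genes entering the screen have sizeable single-mutant effects
    expect_false(any(rows$redundant_pattern & rows$M_A > -0.1))
  }

  # no gene past the cutoff -> empty table
  weak <- selection_thresholds(fold_double = 1e6)
  expect_equal(nrow(redundancy_screen(r, weak)), 0L)
})

test_that("selecting co-down genes under the null inflates their epsilon", {
  # winner's curse: data-driven selection favours genes whose single-mutant
  # ratios are underestimated, so the expected product is too small and the
  # mean epsilon of selected genes exceeds the truth-selected mean.
  sel_means <- truth_means <- numeric(40)
  for (i in seq_len(40)) {
    ds <- simulate_dataset(mono_config("independent_both", 120, seed = 5000 + i,
                                       noise_sd_log2 = 0.35))
    r <- ratio_table(ds$expr)
    sel <- select_codown(r)
    if (length(sel) < 2) next
    sel_means[i] <- mean(epistasis_table(r, sel)$epsilon)
    truth_means[i] <- mean(epistasis_table(r, ds$truth$gene_id)$epsilon)
  }
  expect_gt(mean(sel_means), mean(truth_means))
  expect_gt(mean(sel_means), 0)
})

test_that("mean epsilon of synergistic genes is recovered with replication", {
  cfg <- mono_config("synergistic", 150, seed = 31,
                     replicates_per_genotype = 50, noise_sd_log2 = 0.2)
  sim <- simulate_dataset(cfg)
  r <- ratio_table(sim$expr)
  et <- epistasis_table(r, sim$truth$gene_id)
  est <- mean(et$epsilon)
  se <- sd(et$epsilon) / sqrt(nrow(et))
  expect_lt(abs(est - mean(sim$truth$true_epsilon)), 3 * se)
})
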