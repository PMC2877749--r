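---
title: "Measuring epistasis between transcriptional regulators from four-genotype expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring epistasis between transcriptional regulators from four-genotype expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistrans)
```

## The question and the model

When two transcription factors, A and B, bind many of the same genes, a
comparison of their single-mutant expression profiles cannot by itself say
whether they act independently, redundantly, or as an interdependent pair.
Epistasis analysis of transcriptomes answers this with a fourth genotype:
islet-style expression profiles are collected for wild type, each single
mutant, and the double mutant, and every gene's double-mutant behaviour is
compared with what the two single mutants predict.

The phenotype of a gene is its linear mutant/wild-type expression ratio
$R = 2^M$, where $M$ is the log2 ratio estimated from replicate arrays. If
the two factors act independently, their effects combine multiplicatively,
so the expected double-mutant ratio is the product of the single-mutant
ratios. The per-gene epistasis statistic is the deviation from that null:

$$\varepsilon \;=\; R_{AB} - R_A \times R_B .$$

For genes downregulated in both single mutants, $\varepsilon > 0$ means the
double mutant is *less* perturbed than independence predicts — the
signature of synergistic, interdependent regulation (each factor's
contribution is already compromised when the other is missing).
$\varepsilon < 0$, with both single mutants near wild type, is instead the
redundancy pattern: either factor alone suffices, and only the double
mutant collapses.

A worked example: a gene downregulated to 50% of wild type in each single
mutant has an expected double ratio of $0.5 \times 0.5 = 0.25$. If the
double mutant is observed at 0.25, $\varepsilon = 0$ (multiplicative); if
it is observed at 0.5, $\varepsilon = +0.25$.

```{r example}
compute_epsilon(0.5, 0.5, 0.25)
compute_epsilon(0.5, 0.5, 0.5)
```

## From arrays to ratios

`compute_ratios()` estimates, for each gene and contrast, $M$ as the
difference of replicate means on the log2 scale, the linear ratio $R = 2^M$,
a two-sided Welch two-sample t p-value on the replicate values, the Welch
standard error of $M$, and Benjamini–Hochberg adjusted p-values across
genes. Two deliberate simplifications are worth stating:

* **Welch t rather than a moderated (empirical-Bayes) t.** Variance
  moderation helps at three replicates per group, but it couples genes
  together and adds a dependency; the plain Welch test keeps each gene's
  inference self-contained and is isolated behind the `compute_ratios()`
  interface, so a moderated variant can be slotted in without touching
  anything downstream.
* **Zero within-group variance** (which arises in noise-free simulations)
  makes the t statistic undefined. The p-value is then set to 0 when
  $M \neq 0$ and 1 when $M = 0$, with a warning. This keeps noise-free
  pipelines runnable and makes selections collapse to pure $M$ thresholds,
  which the tests exploit.

Gene-set selections all use strict inequalities, because boundary behaviour
matters when thresholds sit exactly on round numbers:

* `select_codown()`: $M < -0.6$ in **both** single mutants — the
  experimental set for the epistasis analysis. A gene at exactly $-0.6$ is
  excluded.
* `select_control()`: $|M| < 1.1$ and nominal $p > 0.2$ in both single
  mutants — genes showing no evidence of regulation by either factor,
  used as the reference $\varepsilon$ distribution.
* `select_de()`: per-contrast downregulation, either $R < 1/1.5$ with
  nominal $p < 0.01$, or BH-adjusted $p < 0.05$ with $M < 0$. The
  $1.5$-fold cut ($M < -0.585$) is kept distinct from the $-0.6$ cut
  because the two are used in different analyses.
* `collapse_probes()`: where measurements are probe-level, the probe with
  the smallest nominal p wins within each contrast; ties go to the larger
  $|M|$, then the lexicographically smaller probe id.

## Epistasis statistics and their tests

`epistasis_table()` applies $\varepsilon = R_{AB} - R_A R_B$ gene by gene,
using point estimates of $R$ (no per-gene error propagation into
$\varepsilon$ — the statistic is deliberately the plain plug-in quantity,
assessed at the distribution level). A log2-scale additive deviation
$M_{AB} - M_A - M_B$ is carried as a clearly-labelled diagnostic column;
the primary statistic is linear-scale.

`test_epistasis()` reports two complementary p-values:

* a **two-sample Student t** (pooled variance; Welch behind a flag)
  comparing the $\varepsilon$ distribution of the experimental
  (co-downregulated) genes with that of the control set, and
* a **paired Student t** comparing, gene by gene, the observed $R_{AB}$
  with the expected product $R_A R_B$.

`classify_gene()` assigns per-gene labels by the sign of $\varepsilon$
with a tolerance defaulting to 0 — a convenience for browsing tables, not
a calibrated per-gene test; the inference is distribution-level.

`redundancy_screen()` starts from the double mutant rather than the single
mutants, because selecting on single-mutant downregulation is biased
*against* redundancy. All genes with $R_{AB} < 1/3$ are listed with their
single-mutant $M$ values and $\varepsilon$; a gene is flagged
`redundant_pattern` when both single-mutant effects sit inside the control
band ($|M| < 1.1$ — the same constant as the control set, rather than a new
one) while the double mutant is strongly reduced.

### Numerical and statistical caveats

Two properties of the paired test deserve explicit statement.

**Selection bias (winner's curse).** Selecting genes because their
*estimated* single-mutant ratios are low favours genes whose ratios are
underestimated; their expected product is then too small and their
estimated $\varepsilon$ is positively biased even under the null. The test
suite demonstrates this directly (selected-set mean $\varepsilon$ exceeds
the truth-selected mean under a pure multiplicative simulation). The
control-set comparison removes part, not all, of this effect — which is
why both tests are always reported and why conclusions should rest on
effect sizes like the mean $\varepsilon$ gap, not p-values alone.

**Convexity bias of the linear-scale comparison.** $M$ estimates are
unbiased, but $R = 2^M$ is convex in $M$, and the expected product
$2^{\hat M_A + \hat M_B}$ carries roughly three times the log-scale
sampling variance of the observed $2^{\hat M_{AB}}$ (the shared wild-type
baseline included). Under the null the expected product is therefore
biased slightly upward relative to the observed ratio — a deficit of order
$\sigma^2$ in the paired differences. At three replicates with per-array
noise of 0.2 log2 units this inflates the paired test's two-sided
false-positive rate at the 0.05 level to roughly 0.08–0.09 (measured by
simulation in the acceptance suite, which asserts nominal calibration and
therefore records this as a failure rather than hiding it). The effect
shrinks quadratically with noise and is negligible beside the signal sizes
the method targets (mean $\varepsilon$ of order 0.1, p-values tens of
orders of magnitude below 0.05), but the paired test should not be treated
as exactly calibrated at its nominal level on noisy, minimally replicated
data. Because $R = 2^M$ is part of the method's definition, no
bias-corrected back-transform is applied.

## Binding integration

`overlap_enrichment()` tests whether a gene set is enriched among bound
genes within an explicit universe: fold enrichment
$(k/|S|)/(|B|/|U|)$, a one-sided hypergeometric tail p-value (enrichment
is the directional claim of interest), and a two-sided Fisher exact
p-value; both are always reported. The universe must be supplied — the
sensible default in practice is the genes present in both the expression
table and the binding annotation. `cooccupancy()` applies the same
machinery to the two factors' binding labels and adds the co-occupancy
rate $|A \cap B|/|A|$.

`chip_fold()` implements the standard ChIP-qPCR quantification:
immunoprecipitated over input signal at the target region, divided by the
same quantity at a negative-control region. It is scale-invariant by
construction. With replicate measurements, folds are computed per
replicate and averaged afterwards (fold-then-average); the two orders
differ whenever replicate ratios differ, so the choice is fixed and
regression-tested. `compare_binding()` compares conditions with a Welch t
on log2 folds, since fold enrichments are ratio-scale quantities.

## Signature concordance

`signature_correlation()` computes the Pearson correlation of the two
single-mutant $M$ vectors over an explicitly supplied gene set; there is no
silent default, because the choice of set changes what the number means.
`down_overlap()` tests the overlap of the two downregulated sets, and
`rank_shift_test()` is a one-sided Mann–Whitney test that a set defined in
one model sits low in the other model's ranking — a transparent,
rank-based substitute for full gene-set enrichment analysis, and it is
never labelled as GSEA in any output. It depends only on ranks, so any
strictly monotone transform of $M$ leaves it unchanged.

## The synthetic-data generator

`simulate_dataset()` produces the four-genotype matrix together with the
ground truth that validation needs. Each gene gets one of six regulatory
architectures; the defaults make the unregulated class dominate (76%) and,
within the regulated minority, shared architectures (independent 6%,
synergistic 8%, redundant 2%) outweigh factor-exclusive ones (4% each),
because the system being emulated is two factors regulating a strikingly
similar gene set.

* Baseline log2 expression is Uniform(6, 12) per gene, an Affymetrix-like
  intensity range; its value is immaterial to every ratio-based stage.
* Single-mutant effects are log-uniform on [0.2, 0.7] (linear ratio), a
  range chosen to straddle the $M < -0.6$ selection threshold so that
  selection behaviour is actually exercised.
* Synergistic genes follow $R_{AB} = (R_A R_B)^{1-s}$ with $s = 0.5$ by
  default: $s = 0$ reproduces independence exactly, $s = 1$ is full
  buffering, and for downregulated effects any $s > 0$ gives
  $\varepsilon > 0$, matching the direction the method is built to detect.
* Redundant genes have both single mutants at ratio 1 and a double-mutant
  ratio of 0.25.
* Each array value is the mean of `pool_size` (default 3) animal-level
  draws — baseline + genotype effect + Normal(0, `bio_sd_log2`²) — plus
  array noise Normal(0, `noise_sd_log2`²), with both SDs defaulting to
  0.2 log2 units. Pooling real RNA averages roughly on the linear scale;
  averaging on the log scale is a documented simplification. The noise
  defaults are assumptions chosen to be plausible for pooled-array data,
  not estimates fitted to any real dataset.
* Binding labels are Bernoulli with sensitivity 0.6 for genes whose
  architecture involves the factor and false-positive rate 0.1 otherwise,
  so binding is enriched among regulated genes without being perfect.
* One seed drives a single generator stream for the whole dataset;
  determinism is whole-dataset (partial re-simulation is unsupported by
  design).

What the generator does **not** model: probe-level array structure,
normalization artifacts, correlated noise between genotypes, upregulation
architectures, and — importantly — correlation between a gene's A-effect
and B-effect magnitudes, which real co-regulated targets likely have.
That last gap is why the pipeline's signature-correlation stage passes the
whole scored transcriptome as the correlation set: genome-wide, the
shared-architecture cluster against the unregulated bulk produces the
concordance structure the statistic is meant to capture, whereas within
the regulated subset alone there is no magnitude correlation to recover in
synthetic data. Passing tests on this generator therefore demonstrate the
statistical machinery, not the biology of any real dataset.

## The pipeline

`run_pipeline()` chains the stages — simulate (or load TSV inputs),
ratios for the three contrasts, selections, epistasis tables and tests,
redundancy screen, co-occupancy enrichment, concordance — writing each
stage's table as TSV, summaries as JSON, and a manifest with the seed,
thresholds, input checksums and per-stage counts. Numeric cells are
serialized with 17 significant digits so a read-back reproduces the values
exactly, and files are written atomically (temp file, then rename). The
entire output is a pure function of inputs, configuration and seed, which
the tests check byte-for-byte.

Problem sizes used by the validation suite are deliberately modest — the
fixture has 120 genes, calibration studies use 100–150 genes with 200–1000
simulation replicates, and convergence checks use 50 replicates per
genotype — chosen so the full suite re-runs in well under a minute per
file while still giving the binomial and Kolmogorov–Smirnov checks enough
resolution.

## Known limitations

* The paired test's convexity bias (above) at high noise and minimal
  replication.
* Per-gene $\varepsilon$ values carry no confidence intervals; only
  distribution-level inference is supported.
* The multiplicative null is the only null model built in; additive or
  minimum-based nulls would need the diagnostic column or external
  computation.
* Normalization (RMA, quantile) and batch correction are out of scope:
  inputs are assumed to be normalized log2 intensities.
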