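# epistrans

Epistasis analysis of single- and double-mutant transcriptomes.

When two transcription factors bind largely the same genes, single-mutant
expression profiles alone cannot distinguish independent action, redundancy,
and interdependence. This package implements the four-genotype design that
can: expression profiles of wild type, each single mutant, and the double
mutant are combined into a per-gene epistasis statistic against the
multiplicative null,

ε = R_AB − R_A × R_B,

where R = 2^M is a gene's linear mutant/wild-type expression ratio and M its
log2 ratio estimated from replicate arrays. For genes downregulated in both
single mutants, ε > 0 means the double mutant is less perturbed than
independence predicts — synergy between the factors — while near-normal
single mutants with a collapsed double mutant (strongly negative ε) indicate
redundancy. Inference is distribution-level: the ε values of the
co-downregulated genes are compared with those of an unregulated control set
(two-sample Student t), and observed double-mutant ratios are compared with
the expected products gene by gene (paired Student t).

It is written for researchers analysing factorial knockout expression
studies (microarray or ratio-level RNA-seq summaries), and ships the
supporting stages such a study needs: Welch-t differential-expression ratios
with threshold selections, a redundancy screen seeded from the double
mutant, binding integration (hypergeometric/Fisher overlap enrichment,
co-occupancy, ChIP fold-enrichment normalization), signature-concordance
statistics, a synthetic-data generator with known regulatory architecture,
and a deterministic end-to-end pipeline.

## Worked example

```r
library(epistrans)

# a gene at 50% of wild type in each single mutant and 25% in the double
# is exactly multiplicative:
compute_epsilon(0.5, 0.5, 0.25)
#>   R_A R_B R_AB expected_R_AB epsilon    class_label
#> 1 0.5 0.5 0.25          0.25       0 multiplicative

# simulated four-genotype study: 2000 genes, 3 arrays per genotype
sim    <- simulate_dataset(sim_config(n_genes = 2000, seed = 1))
ratios <- ratio_table(sim$expr)

codown  <- select_codown(ratios)   # M < -0.6 in both single mutants
control <- select_control(ratios)  # |M| < 1.1 and p > 0.2 in both
length(codown)   #> 228
length(control)  #> 1095

eps <- epistasis_table(ratios, codown)
test_epistasis(eps$epsilon, epistasis_table(ratios, control)$epsilon,
               eps$R_AB, eps$expected_R_AB)
#> epistasis tests: 228 experimental vs 1095 control genes
#>   mean epsilon  experimental 0.1293  control -0.0275
#>   two-sample t p = 6.76e-31   paired t p = 2.62e-39

cooccupancy(sim$truth[, c("gene_id", "bound_A", "bound_B")])
#> overlap 128, fold enrichment 1.71
#>   hypergeometric (one-sided) p = 3.14e-13, Fisher (two-sided) p = 5.66e-13
```

The co-downregulated genes' mean ε is strongly positive while the control
set sits near zero: the simulated synergistic architecture is detected at
overwhelming significance. The binding labels of regulated genes are
co-enriched, as configured.

`run_pipeline(out_dir, sim = sim_config(...), seed = ...)` executes all
stages and writes each table (TSV), the test summaries (JSON) and a run
manifest; outputs are byte-identical across runs with the same
configuration and seed. See the methods vignette
(`vignettes/epistasis-methods.Rmd`) for the model, parameter meanings,
simulator assumptions and known caveats.

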