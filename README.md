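# cfescan

Analysis of deep-mutational-scanning **growth competitions** of
site-saturation (NNN) codon libraries — the experimental design used to map
*collateral fitness effects* (CFEs) of coding mutations: fitness costs that
arise not from loss of the protein's physiological function but from the
mutant protein's misbehaviour (misfolding, aggregation, mis-interaction)
while the cell grows without any selection on that function.

In the assay, a library carrying every single-codon substitution of a gene
(e.g. TEM-1 β-lactamase) is grown competitively for ~10 generations, and
deep sequencing of the population before induction and at the end measures
how each allele's frequency changed. `cfescan` covers the full path from
merged amplicon reads to condition-level statistics, plus a seeded forward
simulator of the whole experiment with known ground truth.

## The estimator

For allele *i*, with counts *c* and totals *c<sub>T</sub>* at the beginning
(*o*) and end (*f*) of the competition, enrichment is

> ε<sub>i</sub> = ((c<sub>if</sub> + 0.5) · c<sub>To</sub>) /
> ((c<sub>io</sub> + 0.5) · c<sub>Tf</sub>)

with a 0.5 pseudocount on mutant allele counts only. The reference is the
pooled class of **wild-type synonyms** (single-codon variants encoding the
wild-type amino acid), whose enrichment ε<sub>wt</sub> carries no
pseudocount. Fitness and the selection coefficient are

> w<sub>i</sub> = ln(r·ε<sub>i</sub>) / ln(r·ε<sub>wt</sub>),  s<sub>i</sub> = w<sub>i</sub> − 1

where *r* is the measured fold increase in the number of cells during the
competition (≈2¹⁰ for ten generations). The variance of *w* is the
delta-method propagation of multinomial counting noise,

> σ²<sub>w</sub> = w² [ ((1−f<sub>if</sub>)/c<sub>if</sub> + (1−f<sub>io</sub>)/c<sub>io</sub>) / ln²(r·ε<sub>i</sub>)
> + ((1−f<sub>wtf</sub>)/c<sub>wtf</sub> + (1−f<sub>wto</sub>)/c<sub>wto</sub>) / ln²(r·ε<sub>wt</sub>) ],  f = c/c<sub>T</sub>

from which 99% confidence intervals and two-tailed normal P-values follow.
A mutation is *called deleterious* only when s < 0 with P < 0.01 in **both**
replica experiments (the dual-replica criterion). Codon-level measurements
of one amino-acid substitution are combined by inverse-variance weighting.

Downstream, the package computes percent-deleterious statistics,
distributions of fitness effects (DFE), position × amino-acid landscape
matrices with domain annotations, per-position Wilcoxon signed-rank and
codon-pooled Welch t-tests between growth conditions, and Spearman
correlations of fitness effects with externally predicted folding-stability
changes (ΔΔG°, e.g. from ThermoMPNN — consumed as a table, never computed).

## Worked example

```r
library(cfescan)

cfg <- sim_config(n_positions = 12, depth_t0 = 2e5, depth_tf = 2e5,
                  n_replicas = 2, seed = 42,
                  dfe = dfe_spec(p_deleterious = 0.25))
sim <- simulate_experiment(cfg, condition = "lb37")
sim$fold
#> [1] 928.6      # realized fold increase in cell number; this is the r
                 # the estimator uses (nominal 2^10 = 1024 for a fully
                 # neutral library)

fit <- fit_counts(sim$counts, r = sim$fold)
dplyr::select(fit, replica, position, wt_codon, mut_codon, class, s, p)
#> # A tibble: 1,512 x 7
#>   replica position wt_codon mut_codon class           s      p
#> 1       1        1 TAT      AAA       missense -0.0216  0.0926
#> 2       1        1 TAT      CAA       missense  0.00756 0.560
#> 3       1        1 TAT      GAA       missense -0.00344 0.793
#> # ...

percent_deleterious(fit)          # dual-replica rule, missense unit = aa
#> [1] 13.2

agg   <- aggregate_substitutions(fit)
calls <- dual_replica_calls(fit)
dfe_summary(agg$s, deleterious = calls$deleterious)[c("mean_s", "median_deleterious_s")]
#> $mean_s                [1] -0.022
#> $median_deleterious_s  [1] -0.145
```

Here 13.2% of missense substitutions are deleterious under the
dual-replica rule (the simulated DFE planted deleterious effects on 25% of
substitutions; the weaker ones fall below the detection threshold at this
depth), the average selection coefficient across all substitutions is
−0.022, and the median effect among the significant-deleterious subset is
−0.145.

A whole run (simulate → fit → landscape → compare → stability) can be
driven from one YAML config with `run_pipeline()`, or from a shell via the
thin CLI at `inst/cli/cfescan.R`.

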