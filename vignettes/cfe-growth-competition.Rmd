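---
title: "Fitness estimation from growth-competition deep mutational scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitness estimation from growth-competition deep mutational scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfescan)
```

## The experiment and its model

A site-saturation (NNN) codon library of a gene is transformed into
bacteria, expression is induced in exponentially growing culture, and the
population competes for about ten generations. Sequencing the mutagenised
amplicons before induction and at the end gives, for every single-codon
allele, counts at two time points in each of two replica experiments
(different aliquots of the same library transformation). When the gene's
physiological function is not under selection — e.g. an antibiotic
resistance gene grown without the antibiotic — any fitness effect is a
*collateral* fitness effect (CFE) of the mutant protein itself.

The generative model `cfescan` assumes (and its simulator implements) is
exponential competition: an allele with selection coefficient $s$ grows by
the factor $r_0^{1+s}$ while a neutral genotype grows by the nominal fold
$r_0 = 2^{g}$ over $g$ generations, and sequencing draws multinomial
samples of the population composition at each time point.

## The estimator

With counts $c$ and totals $c_T$ at the beginning ($o$) and end ($f$),

$$\varepsilon_i=\frac{(c_{if}+0.5)\,c_{To}}{(c_{io}+0.5)\,c_{Tf}},\qquad
w_i=\frac{\ln(r\varepsilon_i)}{\ln(r\varepsilon_{wt})},\qquad s_i=w_i-1.$$

The 0.5 pseudocount applies to mutant allele counts at both time points —
never to totals and never to the pooled reference — so alleles that drop
out of the sequencing still receive a (floored) fitness value. The
reference class is the pool of wild-type *synonyms*: single-codon variants
encoding the wild-type amino acid. Pooling synonyms rather than using
unmutated reads protects the reference against template-switching (PCR
jumping) artifacts that regenerate apparent wild-type sequences; if no
synonym reads are observed at either time point the estimator refuses to
run rather than silently producing infinities.

### What $r$ means

$r$ is the *measured fold increase in the number of cells* during the
competition. This is not a free parameter of the estimator: if the
population truly grew by factor $R$ and allele frequencies are measured
exactly, then $r = R$ makes the estimator exact, because
$r\varepsilon_i = R\cdot(m_i/R) = m_i$ recovers each allele's own growth
multiplier $m_i = r_0^{1+s}$, and $w = \ln m_i/\ln m_{wt} = 1+s$. With a
library carrying substantial deleterious mass the realized population fold
is smaller than the nominal $2^{g}$, and using the nominal value instead
introduces a small multiplicative bias in $s$ (of order
$s\cdot\ln(R/2^g)/\ln r$). The simulator therefore records its realized
fold (`simulate_experiment()$fold`) and the examples use it; for real data
the measured fold (from ODs/cell counts) should be supplied, with
$2^{g}$ the conventional fallback. The estimator-recovery tests confirm
slope ≈ 1, intercept ≈ 0 of estimate on truth under this convention.

### Variance, intervals, calls

Counting noise propagates through the estimator by the delta method,
treating each count as binomial within its total:

$$\sigma^2_w=w^2\left[\frac{(1-f_{if})/c_{if}+(1-f_{io})/c_{io}}{\ln^2(r\varepsilon_i)}+\frac{(1-f_{wtf})/c_{wtf}+(1-f_{wto})/c_{wto}}{\ln^2(r\varepsilon_{wt})}\right],\quad f=c/c_T.$$

The $1/c$ terms for mutant alleles use the pseudocounted counts, which
both prevents division by zero and makes the formula the exact gradient
propagation of the pseudocounted estimator (the test suite checks this
against an independent numeric-gradient oracle, and against a 10,000-draw
binomial resampling oracle). Two-tailed P-values use the normal
approximation $z=s/\sigma_w$ — the closed form consistent with reporting a
variance and a 99% CI — and the interval is $w \pm z_{0.995}\sigma_w$.
Empirical coverage on a simulated neutral library of ~10,000 alleles at
depth $10^7$ is 99% within half a percent.

A mutation is **called deleterious** only if $s<0$ *and* $P<0.01$ in each
replica separately (strictest reading of the dual-replica rule); a cell of
the landscape matrix is **significant** if $P<0.01$ in both replicas with
consistent sign. Codon-level measurements of one amino-acid substitution
are pooled by inverse-variance weighting (the minimum-variance unbiased
combination); the combined variance is $1/\sum \sigma^{-2}$.

Percent-deleterious statistics can count amino-acid substitutions
(replica-level pooling across codons first; default) or codon-level
mutations — both units are exposed because published condition-level
percentages do not always state the unit. The missense denominator
excludes stop codons and wild-type synonyms and includes signal-sequence
positions; other classes are available via `class_filter`.

## The simulator

`sim_config()` + `simulate_experiment()` emulate the study design: an NNN
library (63 non-wild-type codons per position, one allele each, plus an
unmutated wild-type class), true selection coefficients from a
configurable DFE, deterministic exponential selection, and independent
multinomial sequencing draws per replica and time point. Defaults follow
the experimental design: $g=10$ generations ($r_0 = 1024$), two replicas,
depth $10^6$ per sample, and — where the experiment leaves values
unstated — a uniform codon balance, a 5% unmutated wild-type spike
(`wt_mass`), and protein-level effects (`s_unit = "aa"`: codons of one
substitution share $s_{true}$, since CFEs act through the protein).
Synonymous alleles are always neutral by construction: they *are* the
reference class. Deleterious draws are truncated at $s=-1$ (complete
growth arrest); death is not modelled. An optional single mid-competition
bottleneck (one dilution at about five generations) is off by default.

The simulator reproduces multinomial sampling noise and the estimator's
own nonlinearities, but not PCR/sequencing error beyond the fault
injection used to exercise the read filters, library imbalance, replica
batch effects, or PCR jumping. Passing recovery tests therefore
demonstrates estimator correctness under the stated noise model, not
robustness to every artifact of real libraries.

`emit_reads()` writes the corresponding error-free amplicon reads (plus
deliberately injected faults), and `count_reads()` inverts them with the
protocol's filters: any base below Q20 (Q = 20 itself passes the "below
20" rule), any N base, or mutations at more than one codon disqualify a
read. Filter precedence is fixed (low-quality → N → multi-codon); it only
affects the report attribution of multiply-faulty reads, never which
reads are kept. Round-tripping error-free reads reproduces the simulated
counts bit-exactly.

## Condition comparisons

Per-position shifts use the Wilcoxon signed-rank test on paired
substitution-level weighted-mean selection coefficients (pairing at the
amino-acid level matches "changes in fitness of mutations at a
position"). Zero differences are dropped; the exact null is used for
small samples without ties and the normal approximation with continuity
correction otherwise — the test suite verifies exactness against full
sign enumeration up to $n=12$. Per-substitution shifts use a Welch
two-sample t-test over codon × replica measurements (a glycine
substitution contributes 4 codons × 2 replicas = 8 measures per
condition); Welch is preferred over the equal-variance form because
codon-level samples need not share variance, and it reduces to Student
under equal variances. Following the source analyses, no multiple-testing
correction is applied to the raw $P<0.01$ flags; users can correct
downstream if they need family-wise control.

## Stability correlations

`spearman_fitness_stability()` rank-correlates substitution-level fitness
effects with an externally supplied ΔΔG° table (kcal/mol, positive =
destabilizing). Spearman is used because stability-fitness coupling is
expected to be a threshold (sigmoidal) relation, not linear; with the
stated sign conventions real coupling appears as negative ρ. All
substitutions with defined estimates enter — not only significant ones —
and substitutions missing from the table (including signal-sequence
positions, where folding ΔΔG is undefined) are dropped with a count.

## Numerical choices and degenerate inputs

- Degenerate reference $r\varepsilon_{wt}=1$ (zero denominator) raises an
  explicit error rather than returning ±∞, as does an unobserved synonym
  pool, a non-growing wild-type monoculture, or an empty codon space.
- Count products are computed in double precision (32-bit integer
  overflow is avoided by construction).
- Monoculture fitness uses $w=\ln(d\,O_f/O_o)_{mut}/\ln(d\,O_f/O_o)_{wt}$:
  one mid-assay dilution by factor $d\ge 1$ means the culture's realized
  growth is $d\,O_f/O_o$ when $O_f$ is measured post-dilution.
- `correlation_vs_frequency()` breaks frequency ties by label so repeated
  runs order identically.
- All randomness flows through explicit integer seeds
  (`withr::with_seed`); identical config + seed gives bit-identical
  simulator output, and `run_pipeline()` records the seed and an md5 per
  output file in its manifest.

## Problem sizes used by the test suite

The packaged tests run the full designs at sizes chosen to make the
statistical checks sharp while remaining quick on one core: neutral
libraries of 159 positions (~10,000 alleles) at depth $10^7$ for CI
coverage and dual-replica error control; 16 positions (~1,000 alleles) at
depth $10^6$ for truth recovery; 6–12 positions at depths
$2\times10^4$–$5\times10^5$ for landscape, comparison and counting
checks; 10,000 draws for resampling oracles. `scripts/acceptance.R`
recomputes all of these from a single `--seed`.

## Limitations

- Exactly two time points; no regression-based scoring over time courses.
- Fixed-window amplicons: no alignment, indels, or paired-end merging
  (upstream of this package in the real protocol).
- The dual-replica rule is implemented for two or more replicas but the
  study design it mirrors uses exactly two.
- Reproducing published condition-level percentages requires the study's
  deposited count tables, which are not distributed with the package; the
  corresponding check in the test suite reports its unavailability unless
  the tables are supplied locally (`options(cfescan.supplementary_dir=)`).
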