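# damidstates

Downstream analysis of **DamID-seq** chromatin profiling at the resolution of
individual **GATC fragments** — the genomic intervals between consecutive
DpnI GA^TC cut sites — aimed at calling protein-binding states, mapping how
they change between two conditions (e.g. wild-type vs tumour tissue, or two
developmental stages), and relating those changes to differential gene
expression. It is written for genomicists analysing DamID experiments on a
Polycomb-type factor, but nothing is specific to Polycomb beyond the
defaults.

## What it computes

Starting from a genome sequence and per-fragment Dam / Dam-fusion read
counts (two replicates per condition), the pipeline:

1. builds the GATC fragment index and assigns reads under strict containment
   (reads spanning a cut site are discarded);
2. forms the Dam-normalised log2 profile
   `v_i = log2((RPM_fusion_i + c) / (RPM_Dam_i + c))`, masking
   replicate-discordant and unobserved fragments;
3. segments each profile into *depleted / intermediate / enriched* binding
   states with a **three-state heterogeneous HMM**: Gaussian emissions
   `N(mu_j, sigma_j^2)` and distance-dependent transitions

   ```
   A(d)[j,j] = pi_j + (p0 - pi_j) exp(-d/L)
   A(d)[j,k] = (1 - A(d)[j,j]) pi_k / (1 - pi_j),   k != j
   ```

   so fragments a few hundred bases apart share states while fragments tens
   of kb apart are nearly independent — the appropriate chain for unevenly
   sized genomic bins. Fitting is Baum–Welch (generalised EM, log-space,
   compiled inner loops); decoding is exact Viterbi with posteriors as QC;
4. labels every fragment `gain` / `loss` / `no_change` between conditions,
   summarises per chromosome and genome-wide, and computes bound-state
   turnover (% of bound fragments lost to depleted, % bound de novo);
5. intersects TSS regulatory windows (−2.5 kb … +1.5 kb, strand-aware) with
   transition-labelled fragments and joins differential expression into the
   target groups **I** (up, gain), **II** (down, gain), **III** (up, loss),
   **IV** (down, loss), **m1/m2** (mixed);
6. computes profile QC: Pearson correlation matrices, average-linkage
   clustering (Newick export), lag-k autocorrelation over neighbouring
   fragments, and per-state fragment-size distributions.

A fully seeded synthetic-data generator (`sim_config()`,
`simulate_dataset()`) produces genomes, hidden state paths, overdispersed
negative-binomial counts and DE tables with the structure the analysis
assumes, so the entire pipeline is testable end to end. State calls are
serialised in a WIG dialect with the fixed encoding enriched = 1,
intermediate = 0, depleted = −1 (plus BED/TSV mirrors), and can be read back
from the same dialect.

## Worked example

```r
library(damidstates)
cfg <- sim_config(seed = 7, n_chroms = 2, chrom_length = 1e5, n_genes = 80)
res <- run_pipeline(run_config(sim = cfg, outdir = "damid_run"))

summary(res$fits$wt)
#> Heterogeneous 3-state HMM parameters
#>       depleted intermediate enriched
#> mu     -1.7118      -0.2527   1.3145
#> sigma   0.5814       0.3736   0.3866
#> pi      0.4602       0.2600   0.2797
#> p0 = 0.8420, L = 5908.7 bp
#> Fragments: 757 (732 unmasked)
#>            depleted intermediate enriched
#> count      332.0000      194.000 206.0000
#> proportion   0.4536        0.265   0.2814
#> Mean posterior probability of decoded state: 0.9786
#> Log-likelihood -865.446 in 17 iterations (converged)

res$summary$genome
#>   group   n pct_gain pct_loss pct_no_change
#>  genome 712 10.67416  4.91573      84.41011

round(unlist(res$turnover), 1)
#>    pct_lost pct_de_novo   n_bound_a   n_bound_b
#>         4.4        16.4       390.0       446.0

table(res$groups$group)
#>    I   II  III   IV   m1   m2 none
#>    3    1    4    4    2    2    8
```

Reading the output: the fitted emission means recover the generating
values (−1.5 / 0 / +1.5 log2 units) up to the library-depth offset of RPM
normalisation; 712 fragments are callable in both conditions, of which
~15 % changed state; 4.4 % of wild-type-bound fragments lost binding
entirely while 16.4 % of test-condition binding arose de novo; and the 24
significant DE genes with informative fragments split into the six target
groups. The run directory contains the state WIGs, transition and group
tables, the QC matrices and a JSON manifest recording parameters, seed and
state-recovery accuracy (here 0.96/0.97 against the generating truth).

Per-stage functions (`find_gatc_fragments()`, `assign_reads_strict()`,
`build_profile()`, `biohmm()`, `compare_states()`, `assign_groups()`, ...)
expose every step individually; `biohmm()` returns a classed fit with
`print`, `summary`, `coef`, `logLik`, `predict`, `plot`, `simulate`,
`residuals` and `fitted` methods. See the vignette
(`vignettes/damidstates-methods.Rmd`) for the models, assumptions and
design decisions.

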