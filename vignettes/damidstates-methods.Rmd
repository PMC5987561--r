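---
title: "Binding-state analysis of DamID-seq profiles: models and methods"
author: "damidstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-state analysis of DamID-seq profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damidstates)
```

## The measurement and its unit of resolution

DamID profiles protein–DNA contacts by fusing a chromatin protein (here, the
Polycomb-type reader abbreviated Pc throughout) to *E. coli* Dam
methyltransferase. Wherever the fusion protein touches chromatin, nearby GATC
motifs acquire adenine methylation, which is read out by DpnI digestion and
sequencing. Because DpnI cuts only at methylated GATC, the unit of resolution
is the **GATC fragment**: the genomic interval between two consecutive GA^TC
cut sites. Fragment lengths are highly uneven (hundreds of bases on average,
with a long tail), and this unevenness is a first-class feature of every
model in this package rather than a nuisance to be binned away.

A paired **Dam-only** sample controls for chromatin accessibility and
amplification bias; the signal of interest is the per-fragment log2 ratio of
the fusion sample over the Dam-only control.

## From counts to a normalised profile

`normalize_replicate()` computes, per fragment $i$,

$$v_i = \log_2 \frac{\mathrm{RPM}^{fusion}_i + c}{\mathrm{RPM}^{Dam}_i + c},$$

where each library is scaled to reads per million and $c$ is a pseudocount in
RPM units (default $c = 0.5$). The pseudocount keeps all values finite; RPM
scaling makes the profile invariant to sequencing depth. This is a
deliberately simple normalisation with one interpretable knob; GC or
mappability corrections used by some DamID pipelines are intentionally out of
scope. RPM rescaling shifts every value of a sample by a common constant
(the log2 realised depth ratio); this constant cancels in all
*within*-profile analyses (segmentation, transitions) but means absolute
profile values should not be compared across normalisation schemes. With
depth-matched libraries, `scale = "none"` skips the rescaling.

Replicate handling follows two rules:

* **Discordance masking** (`exclude_discordant()`): with two replicates and
  per-fragment differences $d_i$, a fragment is excluded iff
  $|d_i - \mathrm{median}(d)| > k \cdot \mathrm{MAD}(d)$, the MAD scaled as a
  robust sd estimate, default $k = 3$. A robust z-score on replicate
  differences is an explicit, single-knob criterion for "highly discordant
  between replicates"; it removes fragments whose replicates disagree far
  beyond the bulk of the distribution while tolerating global noise.
* **Unobserved fragments**: fragments with zero Dam-only counts in every
  replicate carry no usable accessibility baseline and are masked by
  `build_profile()`.

Unmasked fragments are averaged arithmetically across replicates
(`average_replicates()`). Masked fragments carry no value anywhere
downstream: they are skipped by the HMM (the physical distance between their
unmasked neighbours is used as-is, no imputation) and excluded from
condition comparisons.

## The three-state heterogeneous hidden Markov model

Binding states are called by a three-state HMM over each chromosome's
ordered fragments, with states *depleted* < *intermediate* < *enriched*. A
three-state model is used so that fragments of intermediate signal — which
can arise for biological or technical reasons — are not forced into either
extreme.

**Emissions** are Gaussian per state: $v_i \mid s_i = j \sim N(\mu_j,
\sigma_j^2)$, with $\mu$ strictly ascending (this fixes state identity) and
untied variances floored at `var_floor` $= 10^{-3}$ (log2 units)² to prevent
emission collapse onto a point mass.

**Transitions depend on physical distance.** Because fragments are unevenly
spaced, a homogeneous chain would correlate a 50 bp neighbour and a 20 kb
neighbour equally. Instead, for midpoint-to-midpoint distance $d$ the
transition matrix relaxes exponentially toward the stationary distribution
$\pi$:

$$A(d)_{jj} = \pi_j + (p_0 - \pi_j)\,e^{-d/L}, \qquad
  A(d)_{jk} = \bigl(1 - A(d)_{jj}\bigr)\frac{\pi_k}{1 - \pi_j} \;(k \ne j).$$

At $d = 0$ the self-transition probability is $p_0$; as $d \to \infty$ every
row tends to $\pi$, so distant fragments become independent. This kernel has
exactly the two properties the analysis relies on — nearby fragments share
states, distant fragments do not — and only two interpretable parameters:
$p_0$ (local persistence) and the decay length $L$ in bases. Note the
$L \to \infty$ limit is a chain with constant self-transition $p_0$, so a
fully frozen chromosome requires $p_0 = 1$ as well.

**Fitting** (`biohmm()`) is Baum–Welch with log-space forward–backward
recursions (underflow-safe on chromosome-length chains; the inner loops are
compiled). Chromosomes are independent chains sharing one parameter set —
fitting is genome-wide so that sparse chromosomes borrow strength, a choice
that is configurable by fitting per chromosome manually. The M-step is exact
for $\mu$ and $\sigma$; $\pi$, $p_0$ and $L$ maximise the expected
complete-data log-likelihood numerically ($p_0$ and $L$ by bounded 1-D
optimisation, $\pi$ by a guarded occupancy update), each accepted only if it
improves the objective. This generalised-EM scheme keeps the log-likelihood
trace non-decreasing, which the test suite asserts on every fit.
Initialisation is deterministic: $\mu$ at the 10th/50th/90th profile
percentiles, $\sigma$ at half the profile sd, $\pi$ uniform, $p_0 = 0.9$,
$L$ at the median inter-fragment distance. Components are relabelled in
ascending order of mean at every iteration (a likelihood-invariant
permutation), so the depleted/intermediate/enriched labels never depend on
initialisation. Convergence is declared when the relative log-likelihood
change drops below `tol` ($10^{-6}$) or after `max_iter` (500) iterations. A
fit whose means collapse within $10^{-3}$ of each other is flagged
`degenerate` rather than raising, since a constant profile is a legitimate
(if uninformative) input.

**Decoding.** `viterbi_decode()` returns the most probable state path; ties
are broken toward the lower state index, i.e. conservatively toward
*depleted*. `posterior_decode()` returns forward–backward posteriors as a
QC companion; on clean data the posterior argmax agrees with Viterbi on the
vast majority of fragments, and disagreement marks ambiguous regions. Both
are verified against exhaustive enumeration of all $3^n$ paths on short
chains (to $10^{-8}$), so the dynamic programming is exact, not approximate.

## Transition maps between conditions

`compare_states()` labels every fragment of the joint unmasked universe
(fragments without a call in *either* condition are dropped for both) as
`gain`, `loss` or `no_change` from reference A to test B:

* **full** mode ranks depleted(0) < intermediate(1) < enriched(2); gain iff
  the rank increases. This treats intermediate→enriched as a gain.
* **enriched_only** mode counts only transitions in and out of the enriched
  state, the conservative reading in which intermediate movements are noise.

Both modes ship because the pooled analysis does not dictate whether
intermediate→enriched counts as a gain; full mode is the default and
enriched_only covers the alternative.

`bound_state_turnover()` pools intermediate and enriched into a **bound**
set and reports the percentage of reference-bound fragments that drop to
depleted (`pct_lost`) and the percentage of test-bound fragments that arose
from depleted (`pct_de_novo`). Both rates deliberately count only crossings
of the bound/unbound boundary — an enriched→intermediate step stays inside
the bound set and is not "lost" — keeping the two rates exact mirror images
of each other.

`summarize_transitions()` reports per-chromosome and genome-wide label
percentages (count-weighted chromosome rows recombine exactly to the genome
row), and `cross_tabulate_transitions()` relates two comparisons (e.g.
tumour-vs-WT against late-vs-early development) on their shared fragments.

## Regulatory integration with differential expression

The presumptive regulatory region of a gene is the window from 2.5 kb
upstream to 1.5 kb downstream of its TSS, strand-reflected on the minus
strand and clipped at chromosome ends. The downstream bound is a parameter
(`downstream`) because a 1 kb variant of the same window is also in
circulation; the package defaults to 1.5 kb and lets the user run both.
Fragments overlapping a window by **at least one base** are that gene's
transcription-associated GATC fragments (taGATCf); no minimum overlap is
imposed. A gene with several annotated TSSs gets one window per TSS and is
classified from the union of their fragments.

A gene's region class is: `gain` if ≥ 1 taGATCf gained and none lost;
`loss` if ≥ 1 lost and none gained; `mixed` if both occurred; `no_change`
otherwise. Joined with DE direction (genes with adjusted p < 0.05, up iff
log2FC > 0) this yields the target groups: I (up, gain), II (down, gain),
III (up, loss), IV (down, loss), m1 (down, mixed), m2 (up, mixed); regions
with no change or no data map to none. `classify_region()` and
`assign_group()` are verified against brute-force enumeration of every
label multiset up to size 6, in both directions.

## Profile quality control

* `pearson_matrix()`: pairwise Pearson correlation over jointly unmasked
  fragments. On the synthetic study, within-condition replicate correlations
  exceed cross-condition ones, the same reproducibility signature used for
  real profiles.
* `cluster_profiles()`: agglomerative clustering with distance $1 - r$ and
  average linkage (no linkage is canonical for this application; average is
  the default and the method is a parameter). Dendrograms export as Newick.
* `lag_autocorrelation()`: correlation of values $k$ fragments apart, lag
  counted in *fragment index* over consecutive unmasked fragments (the
  natural reading of "neighbouring GATC fragments"), never across
  chromosome boundaries, pairs pooled across chromosomes. We compute it on
  averaged profiles by default; per-replicate use is a one-liner.
* `state_fragment_sizes()`: per-state fragment-length distributions, since
  systematic size differences between bound and unbound fragments are a
  known feature of such profiles.

## The synthetic-data generator

`simulate_dataset()` generates a complete two-condition study with the
statistical structure the analysis assumes, so every downstream stage is
testable without external data. The layers, and what they emulate:

1. **Genome** (`simulate_genome()`): random A/C/G/T sequence whose GATC
   motifs arrive as a Poisson process at `gatc_rate` per kb. The background
   is generated *free* of spontaneous GATCs (chance motifs are disrupted
   before planting), so `gatc_rate` is the total motif rate and directly
   controls fragment density. The default 4/kb matches the genome-wide GATC
   frequency of a uniform-composition genome, giving realistic uneven
   fragment lengths (approximately exponential, mean ≈ 250 bp).
2. **Hidden states** (`simulate_states()`): realised from exactly the
   distance-dependent kernel the HMM assumes, i.e. the generator and the
   model agree by construction. Defaults: stationary (0.55, 0.25, 0.20) —
   a Polycomb-like factor occupies a minority of the genome, with enriched
   rarest — `p0` 0.9, decay length 2 kb.
3. **Emission layer** (`simulate_profile()`): per-fragment log2 intensity
   $N(\mu_{s_i}, \texttt{state\_sd})$ with means (−1.5, 0, +1.5) and sd
   0.5. This is the latent Dam-normalised profile.
4. **Count layer** (`simulate_counts()`): negative-binomial reads with
   Dam-only mean `dam_mean_per_kb` × fragment length (default 300/kb,
   a deeply sequenced library) and fusion mean equal to the Dam mean times
   $2^{\mu_s}$; `dispersion` (NB size, default 20) controls overdispersion
   with the Poisson limit at infinity. Replicates are i.i.d.
5. **Second condition**: whole constant-state runs of the reference path are
   resampled to another state with probability `flip_prob` (default 0.1),
   producing blocky gain/loss regions with known truth.
6. **DE table** (`simulate_de_table()`): exact numbers of significantly up-
   and down-regulated genes (adjusted p < 0.05), TSSs uniform with a
   one-window margin from chromosome ends (clipping is tested separately),
   strands random, independent of the binding simulation — the integration
   logic, not a biological coupling, is what downstream tests exercise.

Everything is deterministic given the seed; each operation draws from its
own derived sub-seed so pieces are individually reproducible.

Two design points deserve emphasis. First, parameter-recovery experiments
fit the HMM on the **emission layer**: recovery of the generating means to
±0.1 is only meaningful there, because the count layer's RPM rescaling
shifts all values by the realised depth ratio (≈ 0.1–0.2 log2 units under
these defaults), which moves means without affecting state calls. The count
path is validated separately: the raw per-fragment log2 ratio recovers the
state means, and the *full* pipeline — counts to decoded states — recovers
≥ 95 % of true states. Second, the generator does **not** emulate
mappability, GC bias, replicate batch effects, PCR duplication or read-level
error; passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to artefacts of real
libraries, which is what the replicate-discordance mask and QC metrics are
for.

## Problem sizes, tolerances and determinism

The test suite runs the generator at chromosome lengths of 40–300 kb
(hundreds to ~1200 fragments) for pipeline-level checks, 2.6 Mb (~10⁴
fragments) for the stationary-frequency test, and a 5000-fragment fixture
for parameter recovery — sizes chosen so the whole suite completes in well
under a minute while estimates are comfortably inside their tolerances.
Exactness checks (enumeration oracles, WIG round-trips, hand-worked
examples) use tolerances of $10^{-8}$ or tighter; Monte-Carlo checks use
bounds a few sampling standard deviations wide. EM monotonicity is asserted
with $10^{-6}$ absolute slack for floating-point accumulation. The pipeline
writes byte-identical outputs on rerun with the same configuration, and the
state-WIG writer emits deterministic, timestamp-free files with the fixed
encoding enriched = 1, intermediate = 0, depleted = −1.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7, n_chroms = 2, chrom_length = 1e5, n_genes = 80)
res <- run_pipeline(run_config(sim = cfg, outdir = "damid_run"))

summary(res$fits$wt)          # fitted HMM: means, sds, occupancy
res$summary$genome            # % gain / loss / no change
unlist(res$turnover)          # bound-state turnover
table(res$groups$group)       # Polycomb-target groups I-IV / m1 / m2
plot(res$fits$wt, chrom = "chr1")
```

## Known limitations

* The normalisation is RPM + pseudocount only; profiles from pipelines with
  GC/mappability corrections will differ by more than a constant.
* The exact discordance criterion and normalisation of upstream DamID
  pipelines vary; ours are explicit substitutes with documented knobs, not
  reconstructions of any particular pipeline.
* One HMM parameter set genome-wide; chromosomes with genuinely different
  binding regimes would need per-chromosome fits.
* The transition kernel is a two-parameter exponential relaxation; it cannot
  represent distance laws with multiple scales.
* Statistical significance of transition enrichment is out of scope, as is
  motif/track enrichment of target groups and cross-assembly liftover: all
  inputs must share one genome assembly.
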