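---
title: "Promoter methylation and regulatory network rewiring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter methylation and regulatory network rewiring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methnet)
library(dplyr)
```

# The analysis in one paragraph

Promoter hyper-methylation tends to silence genes; when the silenced gene is
the *target* of transcription-factor regulation, methylation change can
rewire the regulatory network itself. `methnet` implements that integrative
analysis as a pipeline over five phenotypes (normal tissue and tumor stages
I--IV): (1) assign methylation array probes to genes by promoter location and
confirm each assignment by a significantly *negative* Spearman correlation
between probe beta values and gene expression; (2) classify the global
methylation landscape into unmethylated / hemi- / fully methylated states
and measure its cross-phenotype conservation; (3) identify differentially
methylated probes per tumor stage with a trimmed Wilcoxon rank-sum test;
(4) scan the ±100 bp window around each assigned probe against a PWM
library to define motif-permitted candidate regulators; (5) infer one
weighted regulatory network per phenotype with guided tree-ensemble
regression restricted to those candidates; and (6) subtract the normal
network from each tumor network, label edge gains and losses, keep targets
whose in-degree change is *consistent* with their promoter methylation
change (hypo → gain, hyper → loss), and rank targets by the number of
gained or lost regulations.

# Statistical components

## Probe--gene assignment

The promoter is the ±2 kb window around the TSS, with the boundary
inclusive (`|position − tss| ≤ 2000`); the window is strand-symmetric, so
gene strand is ignored. For a candidate pair the Spearman correlation $r$
(average ranks under ties) over the matched samples of one tumor stage is
tested with

$$t = \frac{r\sqrt{n-2}}{\sqrt{1-r^2}}, \qquad t \sim t_{n-2},$$

two-sided. p-values are Benjamini--Hochberg adjusted *within each stage*
across all candidates tested in that stage; a pair is confirmed if in at
least one stage the adjusted p is below `alpha` (default 0.05) **and**
$r < 0$. The per-stage adjustment family mirrors the per-stage decision
rule ("significant in one of the four tumor stages"); a pooled family is
available via `bh_family = "pooled"`. The normal phenotype is excluded by
default because the emulated cohort design has no matched normal
methylation/expression samples; `include_normal = TRUE` lifts this for
fully matched data. Constant vectors make the correlation undefined and
are flagged (`NA`) rather than raising an error; $|r| = 1$ is reported as
$t = \pm\infty$, $p = 0$.

## Methylation landscape

States are assigned from the *phenotype mean* beta per probe: below
`t_low = 0.25` unmethylated, above `t_high = 0.75` fully methylated,
boundaries inclusive to hemi-methylated. The thresholds are the standard
beta-value convention and fully configurable; the mean (not a per-sample
majority) keeps the classification a pure function of one summary value.
Conservation between two phenotypes is the fraction of shared, non-missing
probes with identical state. Phenotype-exclusive gene sets use an
"any assigned probe in the state of interest" rule, and the full Venn
partition is computed by membership strings (exact set algebra, no
approximation).

## Differential methylation

For each probe, samples of one tumor stage are compared with the normal
samples after trimming 10% of extreme values per side. **Trimming is
pooled by default**: the extremes of the *combined* stage + normal sample
are removed, then surviving group members are compared. Trimming each
group separately — the other natural reading — was evaluated and rejected:
it breaks exchangeability under the null and inflates the rank-sum type-I
rate from ~0.05 to ~0.11 at these group sizes, which would invalidate the
calibration property the test suite asserts. The per-group variant remains
available (`trim_scope = "per_group"`). The trim count is
`floor(frac * n)` so never more than the stated fraction is removed; ties
are resolved stably (lowest indices first).

The Wilcoxon rank-sum test uses exact null enumeration for combined sizes
up to 12 without ties and the tie- and continuity-corrected normal
approximation otherwise. A probe is significantly differential when the
BH-adjusted p (family: all probes in the stage comparison) is below 0.05
*and* the absolute trimmed mean difference exceeds 0.2. Note the two
branches of the test agree to ~0.03 at the crossover sizes (the exhaustive
worst case over all tie-free splits with 8--12 observations), not better;
this is a property of the normal approximation, not of the implementation.

## Motif scanning

The scanner replaces an external tool with an exact, self-contained
implementation. A motif's position frequencies are regularized as
$p'_{ib} = (f_{ib} + \kappa\,b_b)/(1+\kappa)$ with pseudocount
$\kappa = 0.01$ against the background $b$ (uniform by default), and
scored in bits, $s_{ib} = \log_2 (p'_{ib}/b_b)$. Every offset of the
±100 bp window (201 bp including the CpG site) is scored on both strands;
bases outside A/C/G/T contribute 0 (background-equivalent). p-values are
exact under the background model: the score distribution of a random
L-mer is computed by dynamic programming over score bins of width
$10^{-3}$ bits, so $P(S \ge s)$ is a lookup. Queries are offset by half a
bin per position, which guarantees an achievable score never falls off
the support (the consensus of a one-hot motif of length $L$ gets exactly
$4^{-L}$). Both-strand p-values are Bonferroni-combined (doubled, capped
at 1) before the fixed `1e-4` hit threshold. A TF becomes a candidate
regulator of a gene if any window of any assigned probe of that gene
carries a sub-threshold hit.

## Network inference

Each target gene's expression is regressed on its candidate TFs over one
phenotype's samples with a two-pass guided random forest: pass 1 collects
impurity importances `imp0`; pass 2 penalizes the split gain of feature
$f$ by $(1-\gamma) + \gamma\,\mathrm{imp0}_f/\max(\mathrm{imp0})$
($\gamma = 0.5$), which concentrates importance on features the baseline
already supports. Defaults — 500 trees, minimum leaf size 2 — follow the
tree-ensemble GRN literature; the acceptance surface is recovery of
planted edges on synthetic data, not numeric identity with any particular
implementation. Determinism is strict: per-target seeds derive from the
network seed and target id, samples and candidates are sorted before
fitting, so sample order and candidate order cannot change the result.

Raw importances are then q-norm normalized (q = 2). The **default scope is
global**: the whole TF × target matrix is divided by its q-norm. This was
a deliberate reversal of the per-target unit-norm variant after the
per-target version was shown to erase exactly the signal the downstream
gain/loss analysis needs: a methylation-silenced target's regression is
pure noise and reduces roughly an order of magnitude less variance than an
active one, but per-target rescaling gives both unit norm, making silenced
and active targets indistinguishable by weight. Global scaling keeps
networks comparable across phenotypes while preserving that fit-quality
signal. The per-target variant remains available
(`q_norm_scope = "per_target"`) and gives slightly better pure edge
*ranking* within a single network; both variants pass the edge-recovery
benchmark.

Finally, sparsity refinement keeps the top `ceiling(density × candidates)`
edges globally (ties broken by TF id, then target id). `density` encodes
the analyst's prior on true network density. The package default 0.05
reflects the sparsity of genome-scale candidate sets (thousands of PWMs ×
thousands of genes); the synthetic benchmarks use the value implied by
their own construction (~0.4 of candidate edges are genuinely active
there, because the candidate set is already heavily motif-restricted).

## Differential networks

The tumor-vs-normal differential network is the element-wise difference of
the two weight matrices over the union of candidate edges, ranked by
absolute difference with deterministic tie-breaks, truncated to the top
`k`; positive differences are gains, negative losses. The consistency
filter computes in-degrees on the sparsified networks (nonzero incoming
edges) and keeps a target only when in-degree increase coincides with
promoter hypo-methylation or decrease with hyper-methylation; equal
in-degrees never pass. A target's methylation direction comes from its
most significant assigned probe (smallest adjusted p, ties by largest
|Δmean|), falling back to the raw difference sign when nothing is
significant and `"none"` without an assigned probe. The filter is applied
*before* the top-`k` ranking by default (`order = "filter_first"`); the
reverse order is one switch away, since the original analysis order is
ambiguous. Gain is defined as `delta_w > 0`; with the methylation gate in
the generator this aligns gains with hypo-methylated, newly active
promoters.

# The synthetic cohort generator

The generator is first-class, tested code, and defines the study
conditions for every benchmark:

* **Cohort structure.** Five phenotypes with default sample counts
  27/37/102/111/25 (normal, I--IV) — the skew of archival tumor-staging
  cohorts, where mid-stage tumors dominate and normal tissue is scarce.
  All samples are matched between methylation and expression.
* **Beta landscape.** Each probe sits in a low (mean 0.1) or high
  (mean 0.85) mode of a Beta distribution with concentration 20 —
  reproducing the bimodal beta-value shape without modeling array
  chemistry. 15% of probes start in the high mode, giving the familiar
  "more than half unmethylated, ~15% fully methylated" landscape.
* **Planted couplings.** For planted probe--gene pairs, expression is a
  decreasing linear function of the promoter beta plus Gaussian noise,
  with the coefficient calibrated per mode so the within-phenotype
  correlation targets `coupling_strength` (default 0.8; this yields a
  median Spearman rho near −0.75 at n = 30).
* **Regulation and gating.** The first `n_tfs` genes double as TFs with
  near-one-hot motifs (length 8). Each target gene gets 1--3 planted TF
  regulators (2--4 in the rewiring benchmark) with coefficient
  ±`edge_effect_size`; every TF term is multiplied by the sigmoid gate
  `plogis((0.5 − beta)/0.1)` of the target's promoter beta, the smooth
  monotone embodiment of the assumption that promoter methylation reduces
  TF binding affinity.
* **Rewiring.** Per stage, a disjoint set of target promoters flips mode:
  "gain" targets are methylated everywhere except their stage (edges
  switch on), "loss" targets the reverse. The flipped promoters are
  simultaneously the planted differentially methylated probes.
* **Decoy motifs.** Each promoter window also carries consensus
  embeddings of non-regulator TFs (default 3), so the motif scan reports
  candidates that sequence affinity alone would suggest but no regulation
  backs — the premise that affinity does not imply binding, and the
  reason the inference step has genuine work to do.
* **Annotation detail.** Genes sit 10 kb apart on five autosomes, one
  promoter probe per gene within ±1.5 kb of the TSS; surplus probes are
  intergenic, and a slice of them is flagged masked or placed on chrX to
  exercise probe filtering.

What the generator does **not** emulate: array noise and batch effects,
copy-number or tumor-purity confounding, read-level RNA-seq, multi-modal
expression, overlapping promoters, and correlated TF activity. Passing
benchmarks therefore demonstrate correctness of the statistical machinery
under the stated generative assumptions, not performance on real tumor
cohorts.

# Numerical choices and degenerate inputs

* Seeds: every stochastic step takes an explicit integer seed; derived
  seeds stay below 2^31. Identical configuration ⇒ byte-identical outputs
  (the pipeline manifest records md5 checksums to prove it).
* Ties: average ranks in correlations; stable index-order trimming;
  lexicographic (TF, target) tie-breaks in edge ranking; (count, target
  id) in target ranking; (|Δmean|, probe id) in gene ranking.
* Degenerate inputs: constant expression or methylation vectors are
  flagged and excluded, zero-variance targets get all-zero importances,
  empty candidate sets and empty cohorts flow through with empty outputs,
  all-equal rank-sum inputs return p = 1.
* Problem sizes in the test and verification runs (chosen as cohort sizes
  a small simulation study would use): 500 probes × 400 genes for pair
  recovery (20 replicates), 200-probe null cohorts (50 replicates),
  40 TFs × 200 targets for edge recovery (10 replicates), 30 TFs ×
  150 genes with 24 flips/stage for rewiring recovery (10 replicates).

# Known limitations

* The guided-forest internals (number of trees, γ, leaf size) follow
  community defaults; the upstream method's exact constants are not
  published, so numeric identity with it is out of scope by design.
* The in-degree consistency filter admits unchanged-methylation targets
  through the raw-sign fallback; on synthetic nulls roughly half of such
  targets pass by chance. The count-based target ranking, not the filter
  alone, provides the final discrimination.
* p-values from the DP scanner are exact only under the 0-order
  background model; promoter CpG composition is not modeled
  (methylation-aware scoring is explicitly out of scope).
* With few candidate TFs per target, any per-target normalization makes
  noise columns look strong; the global q-norm default mitigates but does
  not eliminate this at very small candidate counts.
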