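---
title: "Methods: LD-pruned genetic-algorithm feature selection for quantitative traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LD-pruned genetic-algorithm feature selection for quantitative traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaqtl)
```

## The model and its assumptions

`gaqtl` selects a compact subset of SNPs that predicts a quantitative
trait, under three working assumptions:

* **Biallelic, haploid-style genotypes.** Codes are −1/+1 per sample and
  locus (a 0/2 dosage dialect is remapped on read). Heterozygous or
  multi-allelic calls are rejected rather than guessed at: the intended
  designs are two-parent crosses (e.g. yeast segregant panels) where
  every marker is effectively haploid.
* **Largely additive architecture.** The fitness regressor is linear, so
  the search rewards loci with additive marginal effects. Purely
  epistatic loci with no marginal signal are invisible to both the PCC
  filter and the linear fitness (demonstrated directly on simulated
  epistatic traits in the test suite).
* **Blockwise LD.** Correlated markers are redundant for prediction;
  pruning to block representatives loses little signal while shrinking
  the search space enormously.

The pipeline: (1) split samples into train/test; (2) on the training
partition, rank SNPs by |PCC| with the trait and greedily keep a SNP iff
its r² with every already-kept SNP is ≤ α; (3) run the genetic algorithm
over binary masks of the candidates, maximizing the adjusted R² of a
Bayesian ridge fit; (4) intersect the selections of repeated runs;
(5) refit on the consensus and evaluate on the held-out partition.
Pre-processing statistics are computed on the training partition only and
then applied to both partitions, so the test set never informs selection.

### The fitness

For a mask with p set bits, the Bayesian ridge is fit on the masked
training columns and scored by

$$R^2_{adj} = 1 - (1 - R^2)\frac{n-1}{n-p-1}, \qquad R^2 = 1 - RSS/TSS.$$

The formula is evaluated as written: it can be negative for poor fits and
is not clipped. Maximizing it while the penalty term punishes p realizes
the two objectives — prediction first, compactness second; exact ties in
adjusted R² are broken toward fewer features.

The regressor is a Bayesian ridge fit by evidence maximization: weights
get a zero-mean Gaussian prior whose precision, together with the noise
precision, is re-estimated from the data (MacKay fixed-point updates with
weak Gamma hyperpriors of 10⁻⁶, convergence when the L1 change of the
coefficient vector drops below 10⁻³, at most 300 sweeps over an SVD of
the centered design). Two properties matter here: the shrinkage strength
is tuned automatically per mask with no cross-validation inside the
fitness, and the penalty is purely L2 — no coefficient is forced exactly
to zero, so a redundant feature keeps costing adjusted R² until the
search itself removes it. An L1-penalized fitness would silently zero out
redundant features and neutralize the compactness objective. The test
suite cross-checks the fit against an independent evidence-maximization
implementation to ~10⁻⁸.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `alpha` | LD r² cutoff during pruning (unitless, (0,1]) | 0.4 | Middle of the useful range: low α gives stabler, smaller candidate sets (higher I/U); high α gives denser coverage of each block. 0.4–0.5 balances the two; the keep test is boundary-inclusive so α = 1 keeps everything. |
| `K` | Max GA iterations (operator applications) | 5000 | Search stops early only on a perfect fit; K bounds runtime. |
| `S` | Parent pool size | 10 | Small steady-state pool; diversity comes from tabu-forced novelty. |
| `L` | Fitness-call budget per operator application | 10 | Each mutation/crossover proposes up to L variants and keeps the best non-tabu one. |
| `rate_floor` | Minimum probability of either operator | 0.2 | Neither operator is ever starved. |
| `window` | Improvement memory for adaptive rates | 3 | P(crossover) = clamp(c/3, 0.2, 0.8) where c counts crossover among the last 3 improvements; empty history gives 0.5. |
| `runs` | GA repetitions intersected into the consensus | 3 | Stochastic-run stability; I/U reports agreement. |
| `init_max_card` | Upper bound on initial mask size | 20 | Small initial masks keep n − p − 1 positive and let the adjusted-R² penalty act from the start. |
| `test_fraction` | Held-out share | 0.1 | 90/10 train/test split of usable samples. |

Seeds are mandatory, never defaulted: the split, each GA run
(consecutive seeds `seed`, `seed+1`, …), and the simulator all draw from
an explicitly passed seed, and each consumer restores the caller's RNG
state, so results are bit-reproducible.

## The search in detail

* **Iteration** means one operator application. The pool member to act on
  rotates round-robin; a crossover partner is drawn uniformly from the
  rest of the pool.
* **Acceptance** is steady-state replace-worst: the offspring replaces
  the pool's worst member only if strictly better (validity, then
  adjusted R², then fewer features). The pool's best therefore never
  degrades, and the best-fitness trace is non-decreasing.
* **Mutation** flips 1–3 uniformly chosen positions (count uniform);
  **crossover** inherits each gene from either parent with probability ½,
  so positions where parents agree are fixed in every child.
* **Tabu memory** stores every mask scored within a run (keyed by the bit
  pattern, unbounded — candidate spaces here are 10²–10³ bits, so the
  registry stays small). Re-proposed masks are skipped by operators
  without consuming budget; re-queried masks return the cached score
  without refitting. Model fits therefore equal the number of distinct
  non-degenerate masks ever scored, and total non-cached evaluations are
  ≤ L·K + S. On tiny candidate spaces the registry exhausts the space,
  which is why the GA provably reaches the exhaustive optimum there.
* **Degenerate masks** (p = 0, or p ≥ n − 1 where the adjusted-R²
  denominator dies) receive a sentinel worst score instead of raising, so
  operators remain total functions.

## What the simulator emulates — and what it does not

`simulate_genotypes()` builds mutually independent LD blocks; within a
block each SNP copies its left neighbour per sample with probability ρ
and is resampled uniformly from {−1,+1} otherwise. This keeps exact
±1 marginals, makes adjacent codes equal with probability (1+ρ)/2, and
gives a closed-form correlation of exactly ρ at lag 1 (ρ^d at lag d) —
chosen over multivariate-Gaussian thresholding precisely for that
assertable closed form. `simulate_phenotype()` plants k additive QTLs
(one per block where possible; equal-magnitude, alternating-sign effects
by default, avoiding sign-cancellation artifacts), optional pairwise
epistatic products, and Gaussian noise scaled so the genetic variance
share equals the target h².

Real panels differ: LD decays irregularly and leaks across block
boundaries, allele frequencies are skewed, population structure induces
long-range correlation, and effect sizes are heavy-tailed. Passing the
recovery tests here therefore shows the machinery is correct and the
search effective under clean blockwise LD — not that the same α or K are
optimal for any particular organism's panel.

## Numerical choices and degenerate inputs

* Ranking uses |PCC| by default (a strong negative effect is as
  informative as a positive one); signed ranking is available via
  `use_absolute_pcc = FALSE`. Rank ties break toward the lower column
  index, making pruning deterministic.
* Constant SNP columns get PCC 0 and r² 0 — they rank last and never
  block other SNPs; constant test-set predictions report PCC 0 with a
  warning rather than NA.
* LD is the squared Pearson correlation of the numeric codes, the
  standard biallelic r²; for ±1 haploid codes this coincides with the
  classical haplotype-frequency definition.
* Missing genotypes are imputed to the per-SNP majority code (logged);
  samples missing the trait are dropped before splitting. Sample
  alignment is by identifier join; orphans on either side are an error,
  never positional trust.
* An empty consensus (runs disagree entirely) falls back to the best
  single run's selection, flagged in the result, so evaluation never
  silently runs on zero features.

## Open design choices

Where the overall approach left details open, the package commits to:
steady-state replace-worst acceptance; uniform crossover; 1–3-bit
mutation; initial masks of cardinality uniform on [1, min(20, m)];
crossover partner uniform over the pool; P(crossover) = c/window clamped
to [0.2, 0.8] with 0.5 before the first improvement (the 2-of-3 case
gives 2/3, occasionally quoted rounded as 60/40); consecutive integer
seeds for consensus runs. When consensus sets from several cutoffs are
combined, intersection (not union) is the default, as the stricter
reading. Each choice is exercised by a dedicated test, so changing one is
a visible, tested decision rather than a silent drift.

## Problem sizes used in the tests

The suite validates the search against brute force where brute force is
exact: exhaustive enumeration of all 2⁸ masks (n = 200) for GA
optimality, full pairwise r² tables for pruning certificates and LD
concordance, and an independent quadratic pruner for the greedy filter.
Statistical properties run at n = 500–2000 with 10–100 seeded
replicates; the end-to-end recovery study uses 500 samples, 30 × 10
blocks at ρ = 0.9, five planted QTLs at h² = 0.8, α = 0.4, and K = 1000
with three intersected runs per pipeline. These sizes were chosen so each
property is measured with comfortable margins at desk scale; all defaults
scale unchanged to panels of thousands of samples and tens of thousands
of SNPs, where K = 5000 becomes the binding budget.

## Known limitations

* Marginal-signal blindness: loci acting only through interactions are
  not selectable by a linear fitness (by design; shown on simulated
  epistatic traits).
* The greedy prune is order-dependent: a kept representative is the
  highest-|PCC| member of its conflict neighbourhood, not necessarily the
  causal SNP; downstream hits should be read block-wise, which is what
  the LD-concordance report quantifies.
* Kept-set size is not exactly monotone in α per instance (only in
  expectation), a known property of greedy conflict scans.
* The I/U ratio measures stability, not correctness: three identically
  wrong runs give I/U = 1.
* No diploid/heterozygote support, no D′ or haplotype LD, no MAF
  filtering, no population-structure correction.
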