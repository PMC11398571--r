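---
title: "Evaluating Relief-based feature selection on simulated epistasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating Relief-based feature selection on simulated epistasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbapower)
```

## The problem

Epistasis — statistical interaction between genetic loci whose joint effect
on a phenotype departs from the sum of their individual effects — is one of
the hardest targets for feature selection in genetic association data. The
number of candidate k-locus interactions grows combinatorially, so
exhaustive interaction screens are intractable, and a k-way interaction
that is *pure* (no single-locus main effects) and *strict* (no informative
lower-order sub-interactions) is invisible to any univariate or
lower-order filter by construction.

Relief-based algorithms (RBAs) are nearest-neighbor feature-weighting
filters that can, in principle, detect interactions without enumerating
them: a feature is rewarded when it differs between a target instance and
its near neighbors of the opposite class, and penalized when it differs
from near neighbors of the same class. `rbapower` implements the machinery
needed to measure how far that promise extends as interaction order and
feature count grow: simulators with known ground truth, from-scratch RBA
scorers, two ranking schemes, two controls, and a power evaluation based on
the *weakest link* — the rank of the worst-ranked truly predictive
feature.

## The scoring algorithms

All scorers operate on SNP genotype matrices (values 0/1/2, additive
coding) with a binary class, using the discrete 0/1 mismatch metric per
feature; instance distances are Hamming counts over all features. Scores
of all RBAs lie in [-1, 1].

**ReliefF.** Every instance serves once as the target (a deterministic
full pass — no instance sampling). For target \(R\) with the \(NN\)
nearest hits \(H\) and nearest misses \(M\) (Hamming distance, ties broken
by ascending instance index), each feature \(A\) accumulates
\[
W[A] \mathrel{+}= \frac{\sum_{m \in M} \mathrm{diff}(A, R, m)
      - \sum_{h \in H} \mathrm{diff}(A, R, h)}{n \cdot NN}.
\]
The neighbor count `nn` is the one tunable parameter (10 and 100 are the
study settings); it is capped with a warning when a class is too small.

**MultiSURF.** Parameter-free: for each target \(i\), the near zone is
defined by the mean \(T_i\) of its distances to all other instances minus
a dead-band of half their standard deviation (\(D_i = \sigma_i / 2\));
instances with \(d < T_i - D_i\) are near. Updates are as in ReliefF but
each side (near hits, near misses) is normalized by its realized count,
targets contribute nothing for an empty side, and the sum is averaged over
targets.

**MultiSURF\*.** Adds inverse scoring of the far zone
(\(d > T_i + D_i\)): far-hit mismatches are positive updates and far-miss
mismatches negative — the mirror image of near scoring. This is what makes
the algorithm powerful on pure 2-way interactions and useless for main
effects. Near and far zones are normalized per side and contribute with
equal weight (their mean), which provably keeps scores in [-1, 1]; a
positive rescaling of this kind leaves all rankings unchanged, so the
choice of per-zone weights is cosmetic for power purposes.

The vectorized implementations are engineered to be *exactly* (bit-for-bit)
equal to naive double-loop reference implementations: mismatch counts are
integers, per-target contributions use a fixed arithmetic shape, and
accumulation order over targets is fixed. The test suite asserts exact
equality on hundreds of random datasets.

**Controls.** Mutual information (plug-in estimator on the 3-by-2
empirical contingency table, natural log) is the univariate positive
control: it detects main effects and, by purity, must fail on clean XOR
interactions. A seeded uniformly random shuffle of the features is the
negative control; for \(p\) predictive among \(n\) features its weakest
link has the closed-form law
\(P(\mathrm{wl} \le r) = \binom{r}{p} / \binom{n}{p}\), which the test
suite verifies empirically.

## Ranking and the power evaluation

*Standard* ranking sorts scores descending. *Absolute-value* ranking sorts
\(|score|\) descending, motivated by the observation that RBAs can assign
strongly *negative* scores to features involved in higher-order
interactions; ranking by magnitude recovers those without losing
positively scored main effects. Ties break by ascending feature index so
all rankings are deterministic.

Per replicate we record the weakest link; per configuration (30 replicates
in the full design) the power at rank position \(r\) is the percentage of
replicates with weakest link \(\le r\). "At or above the position" is read
inclusively, which yields monotone curves ending at 100; the strict
reading differs by a one-position shift and is available via
`power_curve(strict = TRUE)`. A configuration's heatmap matrix stacks ten
rows: the four RBAs under both schemes, mutual information (standard
ranking), and the shuffle control (native order).

## The simulated architectures

`benchmark_grid()` reproduces the 70-configuration design (2,100 datasets
at 30 replicates): clean XOR at orders 2-5 and 20-100 features; a noisy
2-way core grid (heritability 0.05-0.4, 200-1,600 instances, easy/hard
architectures); a 2-way feature sweep from 100 to 100,000 features;
two-subgroup heterogeneous 2-way epistasis (50:50 and 75:25); noisy 3-way
epistasis (heritability 0.2); and non-epistatic main-effect and additive
families. All datasets are balanced exactly 50:50 cases/controls, and all
generators are deterministic functions of a seed; per-job seeds derive
from a master seed by a stable string hash, so one integer reproduces the
entire grid.

**Clean XOR.** Each of the k predictive loci has MAF 0.5 under
Hardy-Weinberg; a genotype's parity bit (g mod 2, heterozygote = 1) is
Bernoulli(1/2), and the class is the XOR of the k bits. This is the
canonical pure, strict, fully penetrant k-way interaction: any proper
subset of the bits is independent of the class (verified to < 0.001 bits
of joint mutual information at n = 100,000), while the full set determines
it. Case/control balance is achieved by sampling genotype combinations
from their class-conditional distributions, which gives the same law as
rejection sampling at fixed quotas with deterministic cost.

**Noisy penetrance models.** Epistatic families with heritability below 1
use k-locus penetrance tables found by random search, emulating the
constraint surface of penetrance-table simulators such as GAMETES:
candidate tables are projected onto the pure-and-strict constraint set
(every proper-subset marginal penetrance flat at the prevalence K, to
within 1e-9), affinely rescaled so that
\(\sum_i f_i (p_i - K)^2 / (K(1-K))\) equals the target heritability (to
within 1e-6), and driven into \([0,1]\) by alternating projections. Note
that flat (k-1)-subset marginals imply flat marginals for all smaller
subsets, so strictness needs only the top-level constraints.

Prevalence is treated as a free parameter by default, chosen by a coarse
feasibility scan: the attainable heritability of a pure/strict table
depends sharply on K (for two MAF-0.2 loci it peaks near K = 0.3 at about
h2 = 0.42, and at K = 0.5 only about 0.30 is reachable), mirroring how
GAMETES searches architectures when no prevalence is requested. Two
feasibility facts the package surfaces as explicit errors rather than
papering over: a strict three-locus MAF-0.2 table cannot reach h2 = 0.4 at
any prevalence (the attainable maximum is about 0.22), and k = 1 is
incompatible with purity altogether.

Within the valid candidates, the *difficulty* of an architecture is
proxied by the unweighted variance of its table entries: the
frequency-weighted variance is pinned by the heritability target, so high
unweighted variance means the signal is concentrated in rare genotype
combinations — harder for neighbor-based detection. "E" (easy) picks the
minimum-variance candidate, "H" (hard) the maximum. Predictive-locus MAF
defaults to 0.2, the convention of the benchmarking datasets this design
descends from; non-predictive features draw a per-feature MAF uniformly
from (0.05, 0.5), avoiding degenerate constant columns while spanning a
realistic SNP panel.

**Heterogeneous 2-way.** Instances split into two subgroups (50:50 or
75:25); each subgroup's class follows its own independently searched
2-locus model (h2 = 0.4) while the other subgroup's pair is drawn
class-independently. Both subgroups are internally balanced. The
minority-pair signal is diluted in the pooled data, which is what makes
absolute-value ranking fragile here: minority-pair scores approach the
noise floor near zero.

**Main/additive effects.** Non-epistatic controls are additive on the
liability scale: each locus contributes a centered random effect with
liability variance proportional to its heritability share, and the
penetrance table is the logistic link of the summed liability, with the
intercept solved for exact prevalence (default 0.5) and the slope for the
exact penetrance-scale heritability. Strict additivity on the penetrance
scale was rejected as the construction because it cannot represent several
loci sharing substantial heritability — the per-locus deviation ranges add
and overflow [0,1]; four MAF-0.2 loci sharing h2 = 0.4 are infeasible at
any prevalence — while the liability link represents any heritability
below 1 and is the standard quantitative-genetics construction. The
"50:50 / 75:25" variants of the two-locus additive family are read as the
split of heritability between the loci.

## What the simulations do and do not emulate

The generators reproduce the properties the downstream power analysis
depends on: known ground truth, exact class balance, Hardy-Weinberg
genotypes, exact prevalence/heritability/purity constraints, and seeded
determinism. They do not emulate linkage disequilibrium, missing
genotypes, population structure, continuous phenotypes, or the original
EDM-based quantile model selection of GAMETES — so passing results
demonstrate algorithmic detection power under idealized sampling, not
robustness to the correlation structure of real cohorts.

## Numerical and scale choices

Unit tests run on reduced problem sizes (tens of instances); the
end-to-end checks run the 4/5-way XOR grid at its full size (1,600
instances, 20-100 features, 30 replicates) for the pooled score-magnitude
diagnostics, and 10-replicate versions of the 2-way and 4-way power
comparisons, which keeps the default suite to minutes while preserving
every qualitative contrast. The 10,000- and 100,000-feature sweep
configurations are fully supported by the generators and scorers but are
not exercised by default tests; `benchmark_grid()` exposes them and the
CLI gates them behind `--large`.

The permutation-null property (features score zero on average under label
shuffling) is asserted in the regime of balanced classes with `nn` well
below the per-class pool size. With `nn` close to the pool size, the
hit pool (which excludes the target) is one smaller than the miss pool,
and the resulting update asymmetry gives random features a small negative
expected score — a real, documented property of Relief scoring, not an
implementation artifact.

## Known limitations

- The difficulty proxy orders candidate architectures plausibly but is not
  the original EDM ease-of-detection measure; "E"/"H" contrasts are
  monotone in the proxy, not calibrated to it.
- Plug-in mutual information is biased upward by O(df/2n); at the study's
  sample sizes this floor (~0.0006 bits for a 3-by-2 table at n = 1,600)
  is far below any signal of interest but matters when interpreting
  near-zero MI values.
- The heterogeneous family assigns subgroup labels independently of the
  noise features; real heterogeneity correlates with covariates.
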