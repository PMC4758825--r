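---
title: "Measuring robustness of community assignments with bootstrap assortativity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring robustness of community assignments with bootstrap assortativity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Animal social networks are usually inferred from incomplete observation
streams: repeated sightings of groups (flocks, herds, schools) under the
gambit of the group, or dyadic association records. Community-detection
algorithms will happily partition any such network and return a modularity
score $Q$, but $Q$ says nothing about whether the *assignments* of
individuals to communities would survive resampling of the underlying
observations. Two networks with the same $Q$ can differ enormously in how
reproducible their partitions are, because confidence depends jointly on the
strength of community fidelity in the population and on how thoroughly the
dyads were sampled.

`commrobust` quantifies that confidence with a single coefficient, the
community assortativity $r_{com}$, computed by bootstrapping the observation
stream and asking how consistently pairs of individuals land in the same
community.

## The model and the statistic

Association networks are built with the simple ratio index. For individuals
$i$ and $j$,
$$\mathrm{SRI}_{ij} = \frac{x}{x + y_{ij} + y_i + y_j},$$
where $x$ counts sampling units in which the pair associated, $y_{ij}$ units
where both were observed apart, and $y_i$, $y_j$ units where only one was
observed. In group mode co-occurrence in a unit *is* association, so
$y_{ij} = 0$; in period mode (dyadic sampling) an individual counts as
observed in a period when it has at least one association there — dyadic
sampling offers no other presence signal, a convention worth bearing in mind
with very sparse data. Pairs never observed in any unit get weight 0 rather
than an undefined ratio.

Communities come from greedy agglomerative modularity optimization
(Clauset–Newman–Moore, igraph's `cluster_fast_greedy`), cut at the merge
step of maximum modularity. Any other algorithm honouring the same contract
could be substituted; the robustness machinery only consumes a labelling.
Weighted modularity is computed on the community mixing matrix,
$Q = \sum_x (e_{xx} - a_x^2)$, with each undirected edge counted once in
each direction so row and column marginals coincide.

The bootstrap resamples whole sampling units with replacement, keeping the
replicate the same size as the original — the unit, not the individual
detection, is the exchangeable observation. Across `n_boot` replicates we
accumulate $M_{ij}$ (times a pair was co-present *and* co-assigned) and
$C_{ij}$ (times co-present at all), then form the co-membership proportions
$$P_{ij} = \frac{\sum M_{ij}}{\sum C_{ij}},$$
conditioning on co-presence because individuals with few observations
routinely vanish from replicates. Finally, treating $P$ as a weighted
network, the assortativity of $P$ with respect to the *empirical* community
labels is
$$r_{com} = \frac{\sum_x e_{xx} - \sum_x a_x b_x}{1 - \sum_x a_x b_x}.$$
$r_{com} = 1$ means every replicate reproduced the empirical partition
exactly; values near zero mean replicate assignments are unrelated to the
empirical ones; negative values mean pairs from different empirical
communities are co-assigned more often than pairs from the same one.

A caution that the simulations below make concrete: in unstructured data
$r_{com}$ does not fall to 0 but floors near 0.2, because detection finds
*some* partition of the sampling noise and bootstrapping partially preserves
it. Small positive values are therefore not "near-significant" structure;
as a rule of thumb only values above roughly 0.5 indicate robust assignments,
and the permutation test below should arbitrate whether $Q$ itself exceeds
sampling artifacts.

## A worked run

```{r}
library(commrobust)

pop <- make_population(n = 30, c = 3, p_w = 0.75, p_obs = 0.8, seed = 7)
stream <- simulate_stream(pop, n_periods = 100, seed = 8)
res <- run_rcom(stream, n_boot = 100, seed = 9)
res
res$c_histogram
```

The histogram of community counts across replicates is a useful diagnostic:
when assignments are robust its mode sits at the empirical count, while
under weak structure replicates splinter into different numbers of
communities even when the bootstrap CI of $Q$ looks reassuringly tight.

## Tunable parameters

* `n_boot` (default 100): bootstrap replicates. 100 suffices for the
  simulation studies here; empirical analyses may warrant 1000 at linear
  cost.
* `min_obs` in `filter_rare_individuals()`: unit-level appearance threshold;
  field studies commonly drop individuals seen fewer than 3 times, since
  their edges rest on one or two encounters.
* `n_perm` in `permutation_test_Q()` (default 1000): length of the
  cumulative swap chain. Swaps are applied serially so the data become
  increasingly randomized; `burn_in` (default 0) discards initial steps if a
  fully mixed null is wanted. One swap per recorded step keeps successive
  null values maximally informative about the mixing trajectory.
* Simulator: `p_w` is population-level community fidelity (0.5 is exactly
  structureless since within- and between-community edge probabilities
  coincide at 0.25); `attachment_sd` (default 0.1) spreads individual
  attachment around `p_w` via a Normal(1, sd) multiplier, clamped into
  [0, 1] — the upper clamp matters at high `p_w`, the lower clamp is added
  because negative probabilities are impossible; `p_obs` thins every dyadic
  association independently, emulating detectability; streams default to
  100 sampling periods.

## What the simulator does and does not emulate

`make_population()` + `simulate_stream()` generate fission–fusion
populations with planted communities: uniform random membership over `c`
communities (empty communities can occur by chance at small `n` and are kept
as drawn), true dyadic probabilities as products of individual attachments
($p_{wi}p_{wj}$ within, $(1-p_{wi})(1-p_{wj})$ between), and independent
Bernoulli observation of each dyad in each period at rate
$p_{obs} \times e_{ij}$.

Real observation streams violate several of these assumptions: groups induce
triadic closure (our dyadic draws are independent), home-range overlap
structures who can be seen with whom, observation effort varies across
individuals and time, and membership can drift over a season. Passing the
simulation-based tests therefore demonstrates that the estimator behaves
correctly under known community structure and honest random sampling noise —
not that any particular field data set is unbiased. The data-stream
permutation test (`permutation_test_Q()`), which preserves each individual's
observation count and each group's size, is the guard against such sampling
artifacts in empirical data.

## Numerical choices and degenerate inputs

* Ties in the greedy merge sequence are resolved by taking the earliest
  step attaining the maximum modularity; with igraph's deterministic
  agglomeration this makes `detect_communities()` reproducible for a fixed
  roster order. Knife-edge networks may still legitimately partition
  differently under other implementations' tie-breaking.
* A network with zero total weight has no structure to score: $Q$ is defined
  as 0 with a warning, and every node becomes a singleton community.
* `assortativity_rcom()` returns `NaN` with a warning when $P$ is all zero
  or when all weight falls within one community (the denominator
  $1 - \sum_x a_x b_x$ vanishes); sweep summaries average over such
  replicates with `na.rm`.
* Pairs never co-present in any replicate get $P_{ij} = 0$ and are flagged
  in `never_copresent`; zero weight removes them from the assortativity
  sums without special-casing.
* Bootstrap replicates with fewer than two surviving individuals contribute
  nothing to $M$/$C$ but record $Q = 0$ and their node count, keeping the
  replicate vectors aligned with `n_boot`.
* The modularity CI is the 2.5/97.5 percentile interval of replicate $Q$ —
  the simplest defensible bootstrap interval; bias-corrected variants would
  be straightforward but are not implemented.

## Design choices where the design was open

* **Resampling unit.** Groups (or periods) are resampled, not individual
  detections; resampling the unit preserves the within-unit dependence that
  the gambit of the group creates. Duplicating a stream before
  bootstrapping leaves the expected $r_{com}$ unchanged, which the test
  suite checks.
* **Subsampling without replacement** in `subsample_curve()`: the question
  is "what would fewer observations have shown", so the largest subsample
  must converge to the empirical estimate, which with-replacement sampling
  would not.
* **Duplicate detections** in long-format files are collapsed with a
  warning rather than rejected; empirical recording systems produce them
  routinely.
* **One-sided permutation p** with the $+1$ correction,
  $p = (1 + \#\{Q_{rand} \ge Q_{emp}\})/(1 + n_{perm})$: the scientific
  question is whether the data are *more* structured than the sampling
  process alone produces.

## Problem sizes used in the shipped tests

The test suite replicates the simulation regimes at sizes chosen to give
stable means from a package test run: 20 replicate populations per grid cell
(n = 40, c = 4, 100 periods, 100 bootstrap replicates) for the
fidelity/detectability surface, 20 streams for the weak-structure
community-count diagnostic, and 8 replicate subsamples per size for the
sample-size curves. Full-scale sweeps (100 replicates per cell over the
whole grid) are a single `rcom_sweep()` call away.

## Known limitations

* Only undirected networks are handled; the assortativity formula has a
  directed generalization that is not implemented or tested here.
* `r_com` is a property of the (data, detection algorithm) pair. Swapping in
  another community-detection method changes its value; comparisons across
  studies should fix the algorithm.
* The permutation chain length needed for full mixing depends on the data;
  with the default single swap per step, early null values are close to the
  empirical stream. Use `burn_in` when a conservative, well-mixed null is
  required.
* Empirical reference statistics for published avian data sets can only be
  recomputed with those original data distributions; the package ships no
  field data.
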