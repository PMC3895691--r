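---
title: "Calling replication-timing switching domains with rtswitch"
author: "rtswitch authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling replication-timing switching domains with rtswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Replication timing (RT) is measured genome-wide as the log2 ratio of
early-S to late-S BrdU-IP signal per probe; higher values mean earlier
replication. The genome is organized into replication domains of roughly
400–800 Kb that replicate coherently, and a perturbation (a mutant, a
differentiation step, a reprogramming experiment) can switch the timing of
individual domains from early to late (EtoL) or late to early (LtoE) while
leaving most of the genome unchanged. `rtswitch` implements the analysis
half of such an experiment for a two-condition design with biological
replicates: from probe-level log2(early/late) tracks to significance-tested
200-Kb switching calls, segmented switching domains, and the comparative and
enrichment statistics usually reported alongside them. A seeded synthetic
data generator with known ground truth drives all testing.

## The statistical model

Let $x_{s,i}$ be the (normalized) value of sample $s$ at probe $i$, with
conditions $A$ (reference) and $B$ and $n_A, n_B$ replicates. Within a
fixed 200-Kb window $w$ containing $m$ usable probes, the test statistic is
the RMS-normalized Euclidean distance between the group-mean probe vectors

$$ d_w \;=\; \sqrt{\tfrac{1}{m}\textstyle\sum_{i \in w}
   (\bar a_i - \bar b_i)^2 }, $$

so windows of unequal probe counts share a common scale. Its null
distribution is estimated empirically: for every window and every unordered
within-group replicate pair, the same RMS distance is computed between the
two replicate vectors and pooled genome-wide into one null multiset. Two
calibration details matter:

* **Variance matching.** A replicate difference has per-probe variance
  $2\sigma^2$ while the difference of group means has
  $\sigma^2(1/n_A + 1/n_B)$. Each pair distance is therefore scaled by
  $\sqrt{(1/n_A + 1/n_B)/2}$ (for a 2 × 2 design, $1/\sqrt2$), which makes
  the two statistics equal in distribution under the exchangeable Gaussian
  null. Without this factor the null is stochastically larger and p-values
  pile up near 1.
* **Contrast recentring.** Per-sample median centering cannot remove a
  residual global offset between conditions when part of the genome
  genuinely switches: the switched mass drags the affected condition's own
  genome-wide median (the more so because the RT landscape is close to
  piecewise-constant, i.e. its value distribution is atomic). The package
  therefore (i) offers `align_conditions()`, which subtracts the median
  probe-level contrast between each condition's mean profile and the
  reference, and (ii) recentres every contrast vector (between-group and
  each null pair alike) by its genome-wide median inside the distance
  machinery. Both are robust as long as the switched fraction is well
  under half the genome, and both are applied identically to numerator and
  null so calibration is preserved.

P-values are right-tail add-one estimates
$p_w = (1 + \#\{d^{0} \ge d_w\})/(1 + N)$ against the pooled null of size
$N$ (ties inclusive; $p_w > 0$ always, as the q-value step requires).
Multiplicity is handled with Storey q-values: $\pi_0$ is estimated on the
grid $\lambda = 0, 0.05, \dots, 0.90$ with a cubic smoothing spline
evaluated at the largest $\lambda$, clamped conservatively to 1 whenever
the estimate leaves $(0, 1]$; then
$q_{(i)} = \min_{j \ge i} \pi_0\, m\, p_{(j)}/j$. With `pi0_method =
"fixed_1"` the result is exactly Benjamini–Hochberg, and the test suite
verifies this against an independently coded brute-force BH. A window is
called switching at $q \le 0.01$ (high confidence) or $q \le 0.05$, with
direction from the sign of its dRT (condition B mean minus condition A
mean): EtoL for negative, LtoE for positive under the log2(early/late)
convention.

A useful consequence of the empirical-null construction is a *q-value
floor*: the smallest attainable p is $1/(N+1)$ with $N = 2W$ for a 2 × 2
design over $W$ windows, so with $k$ windows at the floor the smallest q is
roughly $\pi_0 / (2k)$. Designs with only a handful of affected windows
can therefore never reach $q \le 0.01$ regardless of effect size; this is
inherent to the method, not a bug, and it shapes the sizes of the packaged
examples and tests.

### Smoothed or raw values in the test?

Profiles are loess-smoothed for display and windowed summaries: per
chromosome and sample, a tricube-weighted local *linear* fit over a fixed
±150 Kb window in bp (not a span fraction), so smoothing behaves uniformly
across chromosomes of different probe density. On a uniform grid the
interior of this smoother reduces exactly to a fixed-kernel convolution,
which is the fast path; edges and gapped tracks use the generic weighted
fit.

The significance test, however, runs on the **normalized, unsmoothed**
values by default (`use_smoothed = FALSE`). Smoothing propagates a real
domain's signal up to half a bandwidth past its edges, so windows bordering
a true switch acquire genuine leaked signal, get called, and — measured
against sharp ground truth — count as false discoveries: in the reference
simulation the false-discovery proportion at $q \le 0.01$ was ~24% with
smoothed values versus ~1% with raw values, while sensitivity was 1 in
both. Domain segmentation likewise consumes the unsmoothed per-probe
differential. The flag remains for users who prefer the smoothed variant.

## Segmentation

Switching domain extents come from a recursive binary changepoint splitter
in the spirit of circular binary segmentation: within each candidate
segment the single split maximizing the pooled-variance two-sample t
statistic is located by exhaustive scan, accepted when its within-segment
permutation p-value (default 1000 shuffles, seeded) is at most
`alpha = 0.01` and both children have at least `min_width = 5` probes, and
recursion continues until no split is accepted; adjacent segments with
means closer than `merge_tol = 0.1` are merged. This deliberately replaces
the full CBS machinery (pruning, undo-splits, hybrid p-values) with a
primitive that is exactly checkable against a brute-force scan, which the
test suite does. Segment boundaries in bp follow the midpoint rule (half
way between the boundary probes of adjacent segments, clamped to
chromosome ends), and a segment is classed EtoL/LtoE when its mean dRT
exceeds `class_threshold = 0.5` log2 units in magnitude — a documented
default; the threshold a given array platform needs is a judgement call.

## The synthetic data generator

`simulate_rt_dataset()` emulates a two-condition, two-replicate Repli-chip
experiment:

* probes on a uniform grid every 5,500 bp (typical high-density CGH array
  spacing; configurable);
* a piecewise-constant baseline RT landscape shared by both conditions:
  domains of 0.8–2 Mb with levels uniform in ±2.5 log2 units, matching the
  dynamic range such profiles span;
* injected sharp-edged switching domains of 400–800 Kb added to condition
  B only, with |effect| 1.0–1.5 log2 units and an *exact-count* direction
  mix (balanced designs keep the two conditions' genome-wide medians
  aligned, which is also why real unbalanced perturbations need
  `align_conditions()`);
* two Gaussian noise scales: one global additive offset per sample
  (sd 0.1 log2 units) plus i.i.d. probe noise (sd 0.35). Two scales are the
  minimal model giving realistic replicate-to-replicate spread for the
  within-group null; with these defaults replicate profiles correlate near
  1 after smoothing, as replicate Repli-chip arrays do. The paper-scale
  noise magnitudes are not published anywhere, so these are package
  defaults chosen once, not fitted values.

What the generator does *not* emulate: intensity-dependent dye bias (the
normalization step is correspondingly reduced to median centering plus
condition alignment), probe-specific affinity, spatially correlated noise,
copy-number artifacts, and gradual (non-sharp) domain boundaries. Passing
tests therefore demonstrate the statistical machinery under the stated
noise model, not robustness to every failure mode of real arrays.

`simulate_binding_sites()` draws per-window site counts from
$\mathrm{Poisson}(\exp(a + b\,\mathrm{RT}_w))$ with uniform positions —
the log-linear density-versus-timing relationship of a remodeler ChIP peak
set — and `simulate_expression()` places genes uniformly with log2
fold-changes independent of switch status, the null the
expression-versus-switch analysis should reproduce.

## Comparative and enrichment statistics

* `pearson_matrix()` / `drt_correlation()`: pairwise-complete Pearson
  correlations of windowed profiles and differentials.
* `overlap_permutation_test()`: the overlap of two called window sets
  against uniform random redraws of the second set over the tile frame
  (add-one right-tail p). Uniform redraw is the simplest null consistent
  with "random placement"; it ignores the clustering of real domains, so
  its p-values are if anything optimistic for strongly clustered sets.
* `developmental_alignment()`: a domain is "aligned" to a reference
  profile when none of its windows differs at $q \le 0.2$ from that
  reference, reusing the empirical-null machinery at window level with the
  reference treated as noise-free; a domain counts as aligned overall when
  at least one panel member matches. Requiring *all* windows non-significant
  is the conservative aggregation; the alternative (a majority rule) would
  be easy to swap in.
* `wilcoxon_rt_shift()`: exact enumeration over group assignments for
  $n_1 + n_2 \le 12$ (midranks for ties), normal approximation with tie
  correction above.
* `expression_vs_switch()`: Pearson R between window dRT and gene log2
  fold-change over genes in switching windows, the count of target genes
  changing more than two-fold (strictly: $|\log_2 FC| > 1$), and per-class
  (EtoL/LtoE/EtoE/LtoL, split at RT 0) fold-change summaries.

## Reproducibility and problem sizes

One top-level seed deterministically derives per-stage seeds
(`derive_seeds()`), so simulation, segmentation permutations and overlap
permutations are independently reproducible and `run_pipeline()` is
byte-deterministic given its config. The packaged evaluation
(`switch_fdr_experiment()`) uses the reference design — two 50-Mb
chromosomes, ~18,200 probes, 500 windows, 30 injected domains — which is
large enough that the q-value floor sits well below 0.01 yet small enough
that a single run takes well under a second; the acceptance script averages
the false-discovery proportion over hundreds of such simulations. The
test suite's domain-recovery checks run segmentation on a 20-Mb chromosome
with four injected domains per seed.

## Known limitations

* The empirical null assumes most of the genome is unchanged and roughly
  direction-balanced switching; switched fractions of ~20%+ in one
  direction bias even the robust recentring (an all-EtoL heavy perturbation
  is the worst case) and inflate false calls.
* P-values across windows share one pooled null, so they are dependent;
  q-value guarantees hold on average over experiments, and the realized
  FDP fluctuates more than independent tests would suggest.
* The distance test has no probe-level weighting; a window's call is
  driven by its mean contrast, not by within-window shape.
* Segmentation is single-track; replicate-aware joint segmentation is out
  of scope.
* Window-level alignment to references treats the reference profiles as
  noise-free, which overstates significance when references are themselves
  noisy.
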