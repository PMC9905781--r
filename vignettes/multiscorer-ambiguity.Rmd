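---
title: "Methods: multi-scorer staging ambiguity, consensus, and auto-scorer validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scorer staging ambiguity, consensus, and auto-scorer validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypnoagree)
```

This vignette is the package's account of its statistical machinery: the
models and conventions it implements, the defaults it chose where the
methodology admits more than one reasonable reading, and the limits of
what its synthetic data can demonstrate.

## The setting

A polysomnogram (PSG) is staged in 30-second epochs, each receiving one
of five stages: W, N1, N2, N3, R. With a panel of $n$ scorers the natural
summary is no longer a hypnogram but a *hypnodensity*: the epoch-wise
probability of each stage, estimated at epoch $e$ by the fraction of
scorers assigning each stage there. All analyses in the package are built
on two objects: aligned multi-scorer stagings (`scoring_set`) and
epoch $\times$ 5 probability matrices (`hypnodensity`), whether derived
from scorers or emitted by an automatic scorer.

The five-stage set is closed by design. Files carrying other codes (e.g.
legacy "S4", movement time) fail loudly at import unless an explicit
dialect maps them; nothing is silently coerced, and stagings of unequal
length are an error rather than a truncation, because silent alignment
would corrupt every downstream agreement statistic.

## Complete-agreement decay and the power model

For panel size $k$, the agreement statistic is the percentage of epochs
on which all $k$ scorers concur, averaged over scorer subsets. Complete
agreement is invariant to scorer order, so the average over all ordered
$k$-permutations equals the average over the $\binom{n}{k}$ unordered
subsets; the package enumerates combinations (at most
$\binom{12}{6} = 924$ per $k$ for a 12-scorer panel) and a test verifies
the permutation/combination identity exhaustively for $n \le 5$. Epochs
are pooled across PSGs by default (`pooling = "pooled_epochs"`), with a
per-PSG-then-average mode as an alternative.

The decay is summarized by the power model $y = a\,x^{b}$, with $y$ in
percent and $x$ the panel size. The fitting space is not dictated by the
model, so the package makes a choice: ordinary least squares of
$\log y$ on $\log x$, which recovers the generating parameters exactly
when the points lie on a power curve, with an optional nonlinear
least-squares refinement in the original space (`method = "nls"`).
$R^2$ is always reported in the original percent space as
$1 - SS_{res}/SS_{tot}$; for constant data reproduced exactly
($SS_{tot} = SS_{res} = 0$) the convention is $R^2 = 1$. Points with zero
agreement are a hard error (the log transform is undefined there) rather
than being dropped. Predictions $a\,x^{b}$ are clipped to $[0, 100]$.

Per-stage decay curves need a definition of "an epoch of stage $s$" that
does not privilege any scorer; the package conditions on the full-panel
consensus label (plurality with the priority tie-break below). This is a
design choice — conditioning on single-scorer labels would double-count
scorer idiosyncrasy in exactly the stages where agreement is lowest.

## From probabilities to a hypnogram: the majority rule

Collapsing a hypnodensity to one stage per epoch takes the
maximal-probability stage. Exact ties must break deterministically; the
package uses the fixed priority $N3 > N2 > N1 > R > W$ — deeper and
NREM-specific stages win — and exposes the priority as an argument. Any
fixed priority yields a valid deterministic rule; the tests pin the
default and verify that a different priority flips only tied epochs.

## Sleep report parameters from probabilities

Time in stage $s$ is the area under its probability curve,
$\sum_e p_s(e) \cdot d/60$ minutes for epoch duration $d$ seconds,
computed over the half-open lights interval
$[\text{lights\_off}, \text{lights\_on})$ (epochs are 0-based). For a
scorer-derived hypnodensity this equals the across-scorer mean stage time
*exactly* — counts divided by $n$ are rational, and summation commutes
with averaging — and the package asserts the identity to $10^{-9}$
minutes over random panels rather than merely near-equality.

Sleep onset is the first epoch with sleep probability $1 - p_W$ strictly
greater than $0.5$: an epoch at exactly $0.5$ is *not* asleep, reading
the threshold literally. Sleep latency runs from lights-off to the start
of the onset epoch; REM latency from onset to the first epoch at or
after it with $p_R > 0.5$. Either latency is absent (`NA`) when no epoch
qualifies; total sleep time is still computed. Latencies use the
epoch-start convention, so an onset at the first in-bed epoch has latency
zero. Wake-after-sleep-onset, stage shifts and cycle statistics are out
of scope.

## Consensus with reliability-weighted tie-breaking

The *unbiased consensus* for scorer $i$ is the per-epoch plurality vote
of the remaining scorers. Plurality ties are resolved by weighting: each
remaining scorer's reliability is their mean pairwise Cohen's kappa with
the other remaining scorers, computed once per scoring set over all
epochs, and the tied stage with the larger summed reliability of its
voters wins. The literature this weighting follows does not publish a
formula, so the package's definition — mean pairwise kappa as the weight,
summed per candidate stage — is its own concrete choice, documented here
and implemented behind a small surface so an alternative weighting can
replace it. A tie that survives weighting (e.g. two voters with
identical weights) falls back to the stage priority, making consensus
fully deterministic and invariant to scorer ordering.

## Cohen's kappa against three comparators

Cohen's kappa is $(p_o - p_e)/(1 - p_e)$ with $p_e$ from the marginal
label frequencies of the two sequences. When both sequences are the same
constant, $p_e = 1$ and kappa is undefined; undefined values are
excluded from aggregation and counted, never imputed. Per-stage kappa
collapses both sequences to stage-vs-rest first.

Each test scorer is evaluated against:

1. **individual** — every remaining scorer pairwise, kappas averaged;
2. **unbiased consensus** — the leave-one-out consensus above; the
   auto-scorer faces *the same* leave-one-out consensus for each scorer,
   and its kappas are averaged, so manual and auto are scored against
   identical comparators;
3. **any scorer** — agreement is credited whenever at least one
   remaining scorer matches the test label. Kappa, however, requires a
   concrete second sequence; the package realizes the counting rule by
   building a reference that carries the test label wherever some
   remaining scorer agrees and the leave-one-out consensus label
   elsewhere. This keeps the chance correction well defined and makes
   the any-scorer kappa at least the individual-comparator mean, a
   property the tests check on simulated panels.

Kappas are computed per PSG and aggregated across PSGs as mean ± SD
(manual scorers are first averaged within each PSG); a pooled-scorers
variant is available. Auto-vs-manual comparisons use two-sided
paired-samples t-tests on per-PSG values, with zero-variance differences
reported as degenerate rather than erroring.

## ICC(2,1) for probability series

Agreement between two probability series (scorer-derived vs auto-scored)
is ICC(2,1): two-way random effects, absolute agreement, single measure.
With $n$ epochs as targets and $k = 2$ raters,
$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + MS_E + \tfrac{2}{n}(MS_C - MS_E)},$$
from the two-way ANOVA mean squares (rows = epochs, columns = sources).
Absolute agreement is the point: a constant offset between sources
lowers the ICC even though their Pearson correlation is 1, and a test
pins that contrast. The 95% confidence interval uses the F-based
construction for ICC(A,1) with Satterthwaite degrees of freedom;
reliability reports in this literature rarely name their CI method, so
the implementation was cross-checked during development against an
independent ANOVA route (and one frozen reference table) to $10^{-10}$.

The overall ICC of two hypnodensities stacks the five per-stage series
into one pair of length $5n$ — one number for the whole probability
object, invariant to stage order. Averaging the five per-stage ICCs is a
different summary (it weights stages equally regardless of prevalence)
and is deliberately not the default. Stages with less than 3.5 minutes
of reference-source area are flagged `low_support`: an ICC computed on
almost none of a stage is reported but not meaningful, and flagged rows
are excluded from dataset-level summary means.

## The synthetic generator

The generator produces what the analyses need and nothing more: aligned
multi-scorer stagings with controllable ambiguity.

* **Latent architecture** — a first-order, time-homogeneous Markov chain
  over the five stages. The default transition matrix was tuned once so
  that the stationary occupancy of a ~7.5 h night matches a plausible
  clinical panel (roughly W 114, N1 67, N2 180, N3 36, R 76 minutes).
  Time-inhomogeneity (early-night N3, ultradian REM cycling) is *not*
  modeled; none of the implemented statistics are sensitive to epoch
  order, so homogeneity suffices.
* **Epoch ambiguity** — with probability `unequivocal_fraction` (default
  0.30) the truth row is one-hot on the latent stage; otherwise it is
  Dirichlet with parameter
  $\alpha = c \cdot \mathbb{1}_{latent} + A[latent,\cdot]$, where
  $c$ = `ambiguity_concentration` (default 8) and $A$ is a confusability
  mass concentrated on AASM-adjacent pairs (W–N1, N1–N2, N2–N3, N1–R),
  making N1 the most and W/R the least ambiguous stages. The default
  magnitudes were calibrated once so that the pooled 12-scorer agreement
  curve declines from ≈70% at $k=2$ to ≈28% at $k=12$ with an almost
  perfect power fit, the regime reported for real multi-scorer panels,
  and then frozen.
* **Scorers** — each scorer draws a stage from the truth row and passes
  it through a per-scorer confusion matrix; the default adds mild
  individual bias (misread probability 1–4%, leaking along the adjacency
  structure). Scorers sharing a `centers` index share a confusion
  matrix, emulating within-center alignment of scoring habits.
* **Auto-scorer** — truth probabilities perturbed by zero-mean Gaussian
  noise in log space and renormalized; `autoscorer_noise_sd` defaults to
  1.0, which puts the overall manual-vs-auto ICC near 0.91. Zero
  probabilities stay zero, and zero noise returns the truth bit for bit.

Reproducibility is strict: every sampling operation derives its stream
from the config seed via `withr::with_seed`, so identical configs give
bit-identical outputs and the caller's RNG state is never disturbed.
Dataset-level simulation derives per-PSG seeds as
$\text{seed} + 1000\,i$.

What the generator does **not** emulate: EEG/EOG/EMG signals, arousal or
respiratory events, scorer drift over a night, and systematic
stage-specific over-scoring by individual centers beyond the shared
confusion matrices. Passing tests therefore demonstrate the correctness
and internal consistency of the statistics under a controlled ambiguity
model — not that any particular clinical dataset will show the same
magnitudes.

## Lights intervals and epoch handling

How epochs outside the lights interval should enter agreement statistics
is genuinely underdetermined in practice. The package's default is to
analyze all scored epochs; the sleep-report functions take an explicit
lights interval, and restricting agreement analyses to the in-bed
interval is the caller's choice by slicing before assembly. Intervals
are half-open `[lights_off, lights_on)` with 0-based epochs, so slices
never overlap.

## Problem sizes

The default study dataset is 10 PSGs × 12 scorers × 900 epochs — a full
12-scorer panel over ~7.5 h nights. The test suite exercises smaller
panels (3–9 scorers, tens to hundreds of epochs) for exhaustive oracle
comparisons, 50-panel batches for the exact stage-time identity, and
ten-seed replicates for the stochastic ordering properties (consensus
kappa above the individual mean, any-scorer above consensus, power-law
fit quality); these sizes were chosen as the smallest at which the
checked properties are clearly expressed.

## Known limitations

* The consensus tie-break weighting is one defensible formalization of
  "weight reliable scorers heavier"; other weightings (e.g.
  consensus-anchored rather than pairwise kappa) would be equally
  defensible and can change individual tied epochs.
* The any-scorer comparator's kappa depends on the constructed reference
  sequence; its chance correction is conservative because the reference
  borrows the test label at agreeing epochs.
* ICC confidence intervals assume the two-way normal-model F
  distributions; probability series are bounded in $[0,1]$, so the
  intervals are approximate near the boundaries.
* Markov-chain homogeneity means simulated nights have no realistic
  macro-structure; any analysis sensitive to epoch ordering (none in
  this package) would need a richer generator.
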