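---
title: "Annotation-guided copy-number segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-guided copy-number segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annotseg)
```

## The problem

DNA copy-number assays (aCGH, SNP arrays) yield a noisy log-ratio
measurement at each probe position along a chromosome: around 0 where the
tumor has two copies, positive in gained or amplified regions, negative in
lost or deleted ones. The analysis task is to recover the piecewise-constant
copy-number signal — where the breakpoints are, and what state each segment
is in. Fully automatic segmenters require tuning parameters, and no single
setting is right for every profile; an expert looking at a scatterplot can
tell immediately where a model has missed an obvious breakpoint or invented
one. `annotseg` takes the supervised view: the expert draws annotated
regions, and the software computes the segmentation that is *exactly
consistent* with them.

Two region vocabularies carry the expert's judgement:

* **Breakpoint annotations** — `1breakpoint` (this region contains exactly
  one breakpoint) and `0breakpoints` (this region contains none).
* **Copy-number annotations** — `deletion`, `loss`, `normal`, `gain`,
  `amplification`, asserting the state of the segments the region overlaps.

All regions, like all files the package reads and writes, are 0-based
half-open `[start, end)` intervals, the BED/bedGraph convention. Whether a
breakpoint sitting exactly on a region boundary is inside follows the same
half-open rule; the boundary-inclusion convention is not observable from
track files, so we adopt the coordinate system's.

## Least-squares segmentation for every model size

For one chromosome let $y_1, \dots, y_d$ be the log ratios at strictly
increasing positions $p_1 < \dots < p_d$ (we take each probe's start
coordinate as its position). For every segment count $k = 1, \dots,
k_{\max}$, `fit_models()` computes the piecewise-constant model minimizing
the residual sum of squares over *all* placements of the $k-1$ changepoints
— the classical segment-neighborhood dynamic program over prefix sums,
$O(k_{\max} d^2)$ time. This is an exact minimizer: the test suite checks it
against exhaustive enumeration of every changepoint placement on small
signals. Pruned dynamic programming computes the same optima faster on very
long profiles; at the profile sizes this package targets the quadratic
program is already subsecond ($d = 5000$, $k_{\max}=20$ in about half a
second), so we keep the simpler algorithm. Prefix sums are accumulated in
extended precision and interval costs clamped at zero to absorb round-off;
ties between equal-cost placements break deterministically toward earlier
change indices.

A change between probes $j$ and $j+1$ is reported at the base pair
$\lfloor (p_j + p_{j+1})/2 \rfloor$ — halfway between the flanking probes,
floored because genome browsers need integral coordinates.

## Scoring models against annotations

The annotation error of a model is the number of annotated regions whose
predicted breakpoint count contradicts their label: a `0breakpoints` region
containing any breakpoint, or a `1breakpoint` region not containing exactly
one, each count one error (zero–one loss — a region with two breakpoints
where one was asked for is one error, not two). A model with zero error is
*consistent*. Overlapping breakpoint regions are rejected at read time:
"exactly one change in this region" is ill-posed when regions overlap. A
region spanning fewer than two probes can never contain a breakpoint, so a
`1breakpoint` label there is unsatisfiable and reported as such.

## Choosing the displayed model

When several model sizes are consistent, the package picks the one closest
to a *predicted* size $\hat k$, with ties toward fewer segments
(parsimony). $\hat k$ comes from a penalty: $k(\lambda) = \arg\min_k
\mathrm{rss}(k) + \lambda k$, a non-increasing step function of $\lambda$
computed from the lower convex hull of $\{(k, \mathrm{rss}(k))\}$. The
log-penalty is predicted by linear regression on the features $(1, \log d,
\log \hat s)$, where $\hat s$ is a robust per-chromosome noise scale: the
scaled median absolute deviation of successive differences divided by
$\sqrt 2$ (differencing removes the piecewise-constant signal except at the
few changepoints). This feature pair — signal length and noise scale — is
the standard supervised-penalty parameterization for this problem; the
regression is trained on the *other* annotated chromosomes of the profile
(leave-one-chromosome-out), so a chromosome's own annotations guide it only
through the consistency constraint.

Each annotated chromosome contributes one training example whose target is
an *interval* of acceptable log-penalties: the widest maximal interval on
the log-$\lambda$ axis whose selected model has zero annotation error
(endpoints may be infinite; when two equally wide runs exist we keep the
higher-penalty one, again parsimony). Chromosomes with no zero-error
penalty contribute nothing — they are exactly the constrained-segmentation
cases below. Training minimizes a squared-hinge interval loss with margin 1
on the log-penalty scale, by full-batch gradient descent from the zero
vector with Armijo backtracking, stopping at gradient norm $<10^{-8}$ or
$10^4$ iterations — deterministic, so refits reproduce identical weights.
With fewer than two training examples the package falls back to the
BIC-flavored default $\hat\lambda = \hat s^2 \log d$; the cold-start rule
is otherwise arbitrary and this one is scale-correct in both $d$ and noise.

## Constrained segmentation when nothing is consistent

With enough annotations (always when there are $\ge k_{\max}$ `1breakpoint`
regions, since a $k_{\max}$-segment model has only $k_{\max}-1$
breakpoints), no unconstrained model is consistent. The package then
computes the exact least-squares segmentation subject to: exactly one
changepoint whose midpoint falls inside every `1breakpoint` region, and no
changepoints anywhere else. Because changes can only occur inside
`1breakpoint` regions, every `0breakpoints` region is satisfied
automatically, and the result has annotation error zero by construction
(asserted post hoc). The optimum is a dynamic program over regions in
genomic order — state: the chosen gap in the current region; transition:
interval RSS between consecutive chosen gaps — with ties toward the
lexicographically smallest gap tuple. A `1breakpoint` region containing no
probe-gap midpoint is infeasible and raises an error naming the region;
the interactive system this models would prevent drawing one, but batch
input cannot be assumed valid.

The displayed model is therefore: the consistent unconstrained model
closest to $\hat k$ when one exists (algorithm tag `pruneddp`), else the
constrained fit (tag `segannot`). Either way its annotation error is zero —
the package's defining guarantee, which the acceptance suite verifies over
a hundred simulated chromosomes covering both branches.

## Copy-number calling

Segment states are ordered `deletion < loss < normal < gain <
amplification`. Segments overlapped (at least one shared base) by
annotations of exactly one state become training examples for that state;
overlap by two or more distinct states marks the segment `conflict` (drawn
black, to be corrected); with no copy-number annotations at all every
segment is `unlabeled` (drawn green). Between each pair of *adjacent
annotated* states a threshold on the segment mean is learned by minimizing
the number of misclassified training means; candidate thresholds are the
midpoints between consecutive distinct pooled means plus one sentinel below
the minimum and one above the maximum, which attains every achievable error
value in a single sweep of the pooled sorted means. Ties on error break
toward the candidate with the widest margin to the nearest training mean,
then the smaller threshold (the max-margin rationale). Classification is
left-closed on the upper side: a mean exactly at a threshold takes the
higher state. States that never appear in the annotations are never
predicted — with only `normal` and `gain` annotated, every segment is
called normal or gain.

Thresholds are learned independently per adjacent state pair; no joint
monotonicity is enforced. Sparse, oddly placed annotations can therefore
produce a non-monotone threshold sequence; the package warns and labels
means falling in an inverted zone `conflict` rather than silently picking a
side. Threshold learning pools training segments across all chromosomes of
a profile, which is how states generalize to chromosomes without
copy-number annotations; `call_copy_number()` on a single chromosome
without pooled thresholds learns from that chromosome alone.

## The synthetic generator

`simulate_profile()` places probes on a regular 1 kb grid and draws each
log ratio as its true segment mean plus Gaussian noise;
`annotations_from_truth()` plays the expert, producing a `1breakpoint`
region around a chosen fraction of the true midpoints (default flank: a
quarter of the smallest midpoint gap, leaving interior room), a
`0breakpoints` region in the clear interior of each true segment, and one
copy-number region per distinct true state. All generated annotations are
disjoint and feasible by construction. `simulate_cohort()` fixes the
package's reference study conditions: per chromosome, 50–2000 probes, 0–8
true changes, noise sd 0.05–0.5, jump sizes 0.3–1.0 with random sign,
annotation coverage 0.25–1. Under these conditions roughly a fifth to a
quarter of chromosomes end up in the constrained branch, so both code
paths are exercised. `add_artifacts()` reproduces the artifact types that
motivate `0breakpoints` and `normal` annotations in practice: outlier
spikes, sinusoidal waves, and a shifted baseline. Default state means are
$(-2, -0.5, 0, 0.5, 1.5)$ — arbitrary but ordered, and configurable.

What the simulator does *not* emulate: platform-specific probe densities
and spacing irregularity, heavy-tailed or autocorrelated noise, GC waves
correlated with genome sequence, and annotator disagreement. Passing tests
on synthetic data therefore demonstrate algorithmic correctness (exact
optima, the zero-training-error guarantee, threshold recovery), not
real-data breakpoint accuracy, which depends on annotation quality and
noise structure.

## Numerical and design choices

* `kmax` defaults to 20 (the track header's `maxSegments`), the usual
  interactive setting; it is the pipeline's only segmentation parameter.
* Tie rules are all deterministic and documented: earlier change indices in
  the DP, smaller $k$ in penalized selection and in the closest-to-$\hat k$
  rule, lexicographically smallest gap tuple in the constrained fit,
  widest-margin-then-smaller threshold.
* Reruns of `run_pipeline()` with identical inputs are byte-identical;
  numbers are written with 15 significant digits, so the probes track
  round-trips to the input profile within $10^{-12}$ relative error.
* The learning-curve experiment in the acceptance suite uses a
  40-chromosome cohort of 100–500-probe chromosomes and 20 resampling
  repetitions; the large-cohort consistency check uses 100-120 chromosomes
  at the full 50–2000-probe conditions. These sizes keep the whole
  validation run to a few minutes while leaving the qualitative conclusions
  stable across seeds.
* The command-line front end (`inst/cli/annotseg.R`) exposes `simulate` and
  `run`; the intermediate stages (segment / select / call / export) are the
  package's exported functions, which compose more naturally in R than as
  separate shell stages, and `run` is their composition with logging.

## Known limitations

* Squared-error loss: heavy-tailed probes are handled socially (a
  `0breakpoints` annotation around outliers), not statistically.
* The penalty regression uses three fixed features; profile-specific
  covariates (probe spacing, GC content) are out of scope.
* Copy-state thresholds are per-profile; there is no borrowing across
  profiles or platforms.
* No partial-credit output when a `1breakpoint` region is unsatisfiable —
  it is a hard error, by design.

## A worked example

```{r example}
sim <- simulate_profile(300, changes = c(100L, 200L),
                        means = c(0, 0.9, 0),
                        states = c("normal", "gain", "normal"),
                        noise_sd = 0.1, seed = 1)
pr <- sim$profile$chromosomes$chr1
anns <- annotations_from_truth(sim$truth, include_cn = TRUE, seed = 2)

fit <- fit_models(pr$logratio, kmax = 20)
dm <- select_displayed(fit, pr$start, pr$logratio, anns$breakpoint)
dm <- call_copy_number(dm, pr$start, anns$copynumber)
dm
dm$states
annotation_error(dm$model, pr$start, anns$breakpoint)
```
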