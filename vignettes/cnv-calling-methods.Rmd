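---
title: "Methods: read-depth CNV calling with target-specific HMM emissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read-depth CNV calling with target-specific HMM emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdcnv)
```

## The problem

Hybridization-capture sequencing (gene panels, exomes) measures the genome
only at sparse probe targets, so split-read and paired-end evidence for
copy number variants (CNVs) is rarely available: read depth is the signal.
Depth, however, is confounded by probe-specific capture efficiency, GC
content, library size, and correlated "batch" structure across targets.
`rdcnv` implements a train/predict caller for this setting: a panel of
background samples is used to learn (i) a normalization that strips shared
depth structure and (ii) per-target, per-copy-state emission
distributions; single query samples are then decoded with a five-state
hidden Markov model (HMM).

## Normalization

Let $D$ be the $n \times p$ matrix of non-negative read counts over $n$
targets and $p$ background samples. Training computes

$$P = \ln(D + 1),$$

centers each sample (column of $P$) about its median — absorbing
library-size scaling, which is what later lets a *single* query sample be
normalized consistently — and, writing $X$ for the centered matrix in
samples-by-targets orientation, removes the top right singular vectors:

$$T = X - X V_k^{\top} V_k.$$

$k$ is the smallest rank whose cumulative squared-singular-value fraction
reaches the variance threshold $v$ (default 0.90, always $k \ge 1$ when
any variance exists). The removed directions carry the dominant shared
structure: the per-target bias profile (identical in every centered
sample, hence rank one and usually the leading direction) and batch
effects. Targets are first split into strided partitions of approximate
size $j$ (default 1000; target $i$ goes to partition $i \bmod
\lceil n/j \rceil$) and the SVD is fitted per partition. Striding keeps
neighbouring targets in different partitions, so a CNV spanning much of
one partition cannot become a top singular vector and normalize itself
away; it also caps the projector memory at $O(j^2)$. Both an exact SVD and
a seeded randomized (Gaussian sketch, 10 oversamples, 4 power iterations)
SVD are available; for these wide matrices ($p \ll j$) the two agree to
high precision, and the exact path is the default and the test oracle.

The composite map is $f$: `transform_f()` applies it with the *stored*
basis, never refitting from a query.

## Emission distributions via pseudo-CNVs

Copy states are described by expected raw-depth multipliers
$s = \{0.01, 0.5, 1.0, 1.5, 2.0\}$ (homozygous deletion, heterozygous
deletion, diploid, heterozygous duplication, homozygous
duplication/amplification; the homozygous-deletion coefficient is kept
slightly above zero because residual mis-mapping leaves a trickle of
reads). For target $t$ and state $i$, the depths at $t$ are multiplied by
$s_i$ in every background sample, $f$ is re-applied in full (including the
median), and the sample mean and variance ($n-1$ denominator, floored at
$10^{-6}$) of the transformed values at $t$ become the Gaussian emission
parameters $(\mu_{t,i}, \sigma^2_{t,i})$. Because rescaling one target
perturbs the centered matrix by one column plus a per-sample median
shift, the transformed column has a closed form in terms of the training
residuals, $\mathrm{diag}(V_k^\top V_k)$ and its column sums; the default
"incremental" estimator uses it and is tested to $10^{-8}$ against the
naive full recomputation. Medians after a single-element replacement are
computed exactly from per-sample sorted columns.

This construction automatically encodes how informative each target is:
a deep, well-behaved target yields tight, well-separated state
distributions, while a noisy or shallow one yields overlapping
distributions and therefore weak evidence — no global signal-to-noise
parameter is assumed.

### Target resolution

As a per-target diagnostic, `target_resolution()` reports the closed-form
Gaussian Kullback–Leibler divergence from the heterozygous-deletion state
to the diploid state,
$\ln(\sigma_{dip}/\sigma_{del}) + (\sigma^2_{del} + (\mu_{del} -
\mu_{dip})^2)/(2\sigma^2_{dip}) - 1/2$. The divergence direction is a
convention (configurable in principle; the del-to-dip order is used
throughout), and the default flagging threshold of 10 is an ad-hoc rule of
thumb for "poorly resolved", not a calibrated quantity.
`resolution_bed()` emits it per target for panel-design review.

## The HMM and PMAP decoding

Prediction transforms the query with the stored basis and runs a
homogeneous five-state HMM over targets in genome order with initial
vector $\pi = (0.01, 0.01, 0.96, 0.01, 0.01)$ and the two-parameter banded
transition matrix built by `build_transition_matrix()`: $\alpha$ steps
away from diploid, $\beta$ steps back, defaults
$\alpha = \beta = 0.0025$. Smaller values favour fewer, larger calls. The
chain ignores physical inter-target distance (a deliberate simplification)
and is restarted with a fresh $\pi$ at every chromosome boundary so calls
can never span chromosomes.

Posteriors come from the scaled forward–backward recursions; emission
densities are evaluated in log space and row-shifted before
exponentiation, so chains of $10^5$ targets with $|z|$ of 40+ stay finite
(posterior rows sum to 1 within $10^{-9}$). Decoding is *pointwise maximum
a posteriori* (PMAP): each target gets its marginal-posterior argmax,
which maximizes the expected number of correctly labelled targets —
exactly the quantity that matters for small CNVs — whereas Viterbi
(provided as `viterbi_decode()` for comparison) maximizes joint path
probability and is conservative about entering short non-diploid runs.
PMAP may emit adjacencies the transition matrix forbids (e.g. homozygous
deletion directly to homozygous duplication); these are counted and
reported via the `n_inadmissible` attribute but never silently repaired,
on the view that the zeros in the transition matrix are themselves an
approximation. Ties break toward the diploid state, then the lower state
index, so output is deterministic.

Runs of identical non-diploid state within a chromosome are joined into
single calls spanning the first target's start to the last target's end.
Call quality is the mean posterior probability of the assigned state over
the segment's targets (minimum-over-targets is available via
`quality = "min"`); the default reporting threshold is 0.95. Quality is a
posterior-scale quantity in $[0, 1]$, which makes threshold optimization
against a truth set meaningful.

## What the synthetic generator emulates

`sim_config()` / `simulate_background()` stand in for real capture
backgrounds at the count level:

* **Counts, not BAMs.** The caller consumes counts, so CNV spike-ins
  multiply counts (rounding halves away from zero) rather than
  manipulating reads; for a count-driven caller the two are equivalent.
* **Depth scale.** `mean_depth` is the expected read *count* per target,
  default 450. When counts are "reads overlapping a target", a 150x mean
  read depth over ~200 bp targets with ~100 bp reads gives
  $150 \cdot (200 + 100)/100 \approx 450$ reads — the count magnitude a
  caller actually sees on such data. Interpreting 150 as the count itself
  would understate the information content of every target by a factor of
  three, which matters greatly for single-target events.
* **Target bias.** Log-normal capture efficiency with log-sd 0.5
  (severalfold spread, conservative relative to real probe sets).
* **Library size.** Log-normal per-sample factor, log-sd 0.2.
* **Residual noise.** Negative binomial with size 1000 (near-Poisson).
  The decomposition follows latent-factor count models: overdispersion
  across samples is mostly *structured* (library size, bias, batch) and is
  modelled by those explicit terms; the leftover is close to counting
  noise.
* **Batch structure.** Two rank-1 log-scale factors, loading sd 0.04 with
  standard-normal per-sample activations — a few percent run-to-run depth
  shifts, typical of a single-lab, single-instrument series. An early
  draft used 0.12, which contradicted the generator's purpose: with
  per-sample centering the bias profile dominates the spectrum, the
  $v = 0.90$ budget truncates right after it, and a 12% batch factor then
  survives normalization in every run, modelling a lab whose batch effects
  defeat the method's premise. The value was revised once, on that
  argument, and not revisited.

What a green simulation test does **not** establish: robustness to GC
waves (bias here is static per target), to overlapping or uneven probe
designs, to common polymorphic CNVs segregating in the background panel,
or to sex-chromosome ploidy (see limitations). Spike-in benchmarks share
nuisance parameters between background and query by construction, so they
bound performance from above relative to fully independent cohorts.

## Benchmark conventions

`score_calls()` implements two matching rules at a 0.5 cutoff: base-pair
reciprocal overlap (intersection over union) and a target-level Jaccard.
In both, the truth CNV is compared against the *union* of same-direction
calls overlapping it in the same sample, so a truth event fragmented into
two adjacent calls still matches; direction must agree (a deletion call
never validates a duplication). PPV counts call records after threshold
filtering; samples with zero calls report PPV as `NA`, not 0, with the
pooled figure as the fallback. `optimize_quality_threshold()` scans 10
evenly spaced thresholds across the observed quality range and returns
the F1 argmax, ties toward the stricter threshold.

## Numerical and degenerate-input choices

* Variance floor $10^{-6}$ on emission variances; zero-variance
  (constant) partitions fit an empty basis ($k = 0$, projection is the
  identity) rather than erroring.
* Partitions with fewer than two targets skip projection with a warning.
* Query target sets must match the model exactly; silent intersection
  would corrupt the stored projector and is refused.
* Prediction is single-sample by design; multi-sample input is an error,
  not an implicit loop.
* All logarithms are natural; all coordinates 0-based half-open;
  chromosome names are opaque strings compared for equality only.
* Model files are a versioned single-file container; loading checks the
  format tag and version and fails with an explicit message otherwise.

## Known limitations

* Male X/Y calling needs ploidy-aware expected coefficients; sex
  chromosomes are currently treated as autosomes.
* The homogeneous transition matrix ignores inter-target distance, so a
  CNV boundary falling in a large inter-probe gap is penalized exactly
  like one between adjacent probes.
* Single-target duplications are intrinsically the hardest class: the
  $\ln 1.5 \approx 0.405$ shift must overcome both counting noise and the
  $\approx \ln(\alpha\beta)$ transition penalty at a single position.
  Their recovery rate is the most sensitive of all benchmarks to the
  simulated depth and noise scale; the acceptance script reports the
  measured value rather than asserting it.
* PMAP paths may be transition-inadmissible (reported, not repaired);
  constrained PMAP decoding is not implemented.
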