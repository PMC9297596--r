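# rdcnv

Germline copy number variant (CNV) calling from multi-sample read-depth
matrices produced by hybridization-capture sequencing (gene panels,
exomes). In this data the only usable copy-number signal is read depth at
the capture targets, and depth is confounded by probe efficiency, library
size and batch structure. `rdcnv` is a train/predict caller for clinical
and research panels: a set of background samples yields a reusable model;
single query samples are then screened for deletions and duplications.

## Method in brief

**Training.** Counts $D$ ($n$ targets $\times$ $p$ samples) are
log-transformed, $P = \ln(D + 1)$, each sample is centered about its
median, and per strided target-partition (size $j \approx 1000$) the top
$k$ right singular vectors $V_k$ — chosen so that cumulative variance
explained reaches $v = 0.90$ — are removed:

$$T = X - X V_k^{\top} V_k .$$

This strips the shared bias profile and batch effects while leaving
sparse, sample-specific CNV signal intact. Emission distributions are then
estimated **per target and per copy state**: the raw depths at a target
are rescaled by the state coefficients
$s = \{0.01, 0.5, 1.0, 1.5, 2.0\}$ (homozygous deletion through
homozygous duplication), the normalization is re-applied, and the mean and
variance of the transformed values across background samples become that
target/state's Gaussian parameters.

**Prediction.** A query sample is normalized with the stored basis and
decoded with a homogeneous five-state HMM (initial vector
$\pi = \{0.01, 0.01, 0.96, 0.01, 0.01\}$; banded two-parameter transition
matrix with away/toward rates $\alpha = \beta = 0.0025$) using
**pointwise maximum a posteriori (PMAP)** decoding, which maximizes the
expected number of correctly labelled targets and is noticeably more
sensitive to short CNVs than Viterbi. Runs of identical non-diploid state
are joined into calls; quality is the mean posterior of the assigned
state over the segment (default reporting threshold 0.95).

The package also ships the study machinery: a count-level simulator of
capture backgrounds (target bias, library size, latent batch factors,
negative-binomial noise) with truth-tracked CNV spike-ins, scoring under
50% reciprocal-overlap or target-Jaccard rules, F1-based quality-threshold
optimization, and a per-target resolution diagnostic (Gaussian KL
divergence between the heterozygous-deletion and diploid states).

## Worked example

```r
library(rdcnv)

# a desk-scale synthetic panel: 2,000 targets, 40 background samples
cfg <- sim_config(seed = 1)
bg <- simulate_background(cfg)
bg
#> depth_matrix: 2000 targets x 40 samples on 4 chromosome(s)

model <- train_model(bg, v = 0.90, j = 1000, seed = 1)
model
#> cnv_model: 2000 targets, 40 background samples, 5 states; v = 0.9 j = 1000
#>   partitions: 2  retained ranks: 1, 1

# spike a 3-target heterozygous deletion into one background sample
query_counts <- bg$counts[, "sample_007", drop = FALSE]
query_counts[301:303, 1] <- round(query_counts[301:303, 1] * 0.5)
query <- depth_matrix(bg$targets, query_counts, "sample_007")

calls <- call_cnvs(query, model)
calls[, c("chrom", "start", "end", "state", "quality", "n_targets")]
#>   chrom  start    end   state quality n_targets
#> 1  chr1 300000 302200 HET_DEL       1         3
```

The call covers exactly the three spiked targets, labelled `HET_DEL`
(one copy lost) with posterior quality 1.00 — comfortably above the 0.95
reporting threshold. Benchmarking the whole panel:

```r
bench <- run_spikein_experiment(bg, model,
                                data.frame(span = 3, count = 100),
                                coefficient = 0.5, seed = 2)
bench$eval
#> eval_result (reciprocal rule, q >= 0.95): sensitivity 1.000 (100/100), PPV 1.000 (100 calls)

summary(target_resolution(model))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   6.254  26.325  38.301  43.490  55.328 242.290
```

All 100 spiked 3-target deletions are recovered with no false calls. The
resolution summary says most targets separate the heterozygous-deletion
and diploid states by a KL divergence well above the rule-of-thumb
flagging threshold of 10; the weakest targets (minimum 6.3) are the
shallow ones where calls deserve extra scrutiny.

## Command line

A thin CLI over the same functions is installed at
`exec/rdcnv` (`system.file("exec", "rdcnv", package = "rdcnv")`):

```sh
rdcnv simulate --out depths.bed --truth-out truth.bed --spike-span 3 --spike-count 50 --spike-coef 0.5
rdcnv train --depths depths.bed --out panel.model
rdcnv predict --model panel.model --depths query.bed --out calls.bed
rdcnv resolution --model panel.model --out resolution.bed
rdcnv evaluate --calls calls.bed --truth truth.bed --rule reciprocal --threshold 0.95
```

## Acceptance script

`scripts/acceptance.R` recomputes the headline spike-in benchmark from
scratch: it simulates the default 40-sample × 2,000-target background
panel, trains with default parameters, runs four spike-in experiments
(100 CNVs each: 3- and 10-target heterozygous deletions, 1- and 10-target
heterozygous duplications), scores per-CNV sensitivity under the 50%
reciprocal-overlap rule at quality threshold 0.95, and writes the
percentages as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
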