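---
title: "Denoising ATAC-seq coverage with dilated residual networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising ATAC-seq coverage with dilated residual networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacdenoise)
```

## The problem

ATAC-seq measures chromatin accessibility by counting Tn5 transposase
insertions along the genome. At high sequencing depth the per-base coverage
track is smooth and its peaks mark regulatory elements; at low depth (few
cells, shallow sequencing) the same track is sparse and noisy, and peak
calls degrade badly. `atacdenoise` trains a convolutional model that maps a
noisy base-pair-resolution coverage track to (i) an estimate of the clean
track and (ii) a per-base probability of lying inside a peak, and provides
the full surrounding machinery: cut-site preprocessing, genome tiling,
training, genome-wide inference, peak calling, evaluation and a
background-ensemble z-score caller for differential accessibility.

## From reads to tracks

Each read is collapsed to its Tn5 insertion point: the first aligned base,
shifted +4 bp on the plus strand and −5 bp from the rightmost aligned base
on the minus strand (the standard correction for the 9 bp duplication Tn5
creates). Cut sites are then extended ±100 bp (±5 bp for
footprinting-resolution tracks) and summed into a per-base coverage track
(`cut_sites_from_reads()`, `coverage_from_cutsites()`). Extension is
inclusive on both sides, so one interior site contributes `2*ext + 1`
bases of coverage; windows are truncated, not dropped, at chromosome ends.

Training labels are derived from the clean track alone: each base is scored
`-log10 P(X >= round(obs))` under a Poisson background whose rate defaults
to the genome-wide mean of the track (the equal-coverage control a peak
caller would use), scores are capped at 350 to keep them finite, and bases
above a cutoff of 3 are merged into labeled peaks
(`poisson_label_scores()`, `label_peaks()`). The threshold-merge-filter
segmentation used for labeling is the same code path used for peak calling
at inference (`call_segments()`), with shared defaults `min_len = 200` bp
and `max_gap = 30` bp. These two values are not dictated by the method
itself; they mirror common practice for base-pair-resolution callers and
are exposed as arguments.

## The model

`model_config()` describes a 1-D residual network operating on windows of
the genome:

* a **regression stage** of `reg_blocks` residual blocks — three dilated
  same-padding convolutions with ReLU activations plus an identity skip
  (a 1×1 projection when channel counts differ), no batch normalization —
  ending in a single-filter convolution with ReLU whose output is the
  denoised coverage (nonnegative by construction);
* a **classification stage**: the denoised signal itself (one channel) is
  passed through `cls_blocks` further residual blocks and a single-filter
  convolution with a sigmoid, read as the probability that each base lies
  in a peak. Peaks are called at probability > 0.5.

With the defaults — 15 filters, kernel 51, dilation 8, 5 regression blocks
— one output base depends on `1 + 15·(51-1)·8 = 6001` bp of input, about
6 kb of genomic context (`receptive_field()`). Dilation buys this span
without extra parameters. The number of classification blocks (default 2)
is a free choice; the probability head is deliberately a function of the
denoised signal only, taking the two-stage description literally, and it
consumes the post-ReLU output.

Windows are produced by tiling each chromosome into non-overlapping
50 kb intervals (the final partial interval is kept) padded by 5 kb of
real context on each side, so that every base of the central interval has
a full receptive field of evidence (`tiling_spec()`, `tile_genome()`,
`extract_examples()`). Within the network, convolutions use zero ("same")
padding. Extra binary input channels (e.g. strand-specific transcription
factor motif locations from `motif_channels()`) can be stacked onto the
coverage channel for cross-modality prediction.

One numerical choice deserves a note: the classification stage sees
unnormalized coverage, whose magnitude is tens of read units. With
unit-gain He initialization its sigmoid head starts saturated and learns
extremely slowly; the package therefore scales the classification stage's
initial weights by `cls_init_gain` (default 0.02) so the initial logits
are O(1). This affects only the starting point, not the architecture.

## Training

The loss for a window is a weighted sum (`loss_weights()`, default weights
1) of

* mean squared error between predicted and clean signal,
* `1 - r`, one minus the Pearson correlation of predicted and clean
  signal, with `r` defined as 0 for constant vectors (an all-zero padded
  window must not produce NaN) and an `1e-8` guard in the denominator,
* binary cross-entropy of the peak probabilities against the 0/1 labels,
  with probabilities clamped at `1e-7`.

The loss is computed over the full padded window. One interaction worth
knowing: under Adam, rescaling a loss component rescales every gradient it
produces, and Adam's per-parameter normalization cancels a uniform
rescaling; the weights therefore only shape training where a parameter
receives gradients from more than one component (the regression stage),
not for the classification stage, whose parameters see only the BCE term.
Relatedly, on short desk-scale runs the classification head becomes
well-ranked (high AUPRC) before it becomes well-calibrated — its sigmoid
outputs may all sit below 0.5 even when they order peak and background
bases almost perfectly — so peak calling on briefly trained models
warrants a lower threshold, while 0.5 suits full-length training
schedules.

Splitting is by chromosome (`split_spec()`): by convention chr20 (human) or chr11 (mouse)
validates, chr10 is held out, everything else trains. `train()` runs Adam
(learning rate 2e-4 by default, conventional `beta1 = 0.9`,
`beta2 = 0.999`, `eps = 1e-8`) for a fixed number of epochs (default 25)
in batches of 64 windows, shuffling with a seeded generator each epoch,
evaluating the validation set after every epoch, and returning the
parameters from the best-validation epoch — by lowest total validation
loss by default, with a switch to select on validation AUPRC instead. All
sources of randomness are seeded, so a rerun with the same data and
configuration is bit-identical. A non-finite loss aborts with a
diagnostic; there is no gradient clipping.

## Inference and evaluation

`denoise_genome()` applies the model tile by tile and keeps only each
window's central interval, so every base is predicted exactly once. At
inference the padded windows are clipped at chromosome ends rather than
zero-filled; together with the network's per-layer zero padding this makes
the stitched genome-wide output exactly equal to a single whole-chromosome
forward pass whenever the pad is at least half the receptive field (the
package warns when it is not).

`track_regression_metrics()` reports Pearson, Spearman (average ranks for
ties) and MSE against a clean reference, genome-wide or within/outside a
mask such as the clean-data peak set; `classification_metrics()` reports
AUROC (tie-corrected Mann-Whitney) and AUPRC (step integration over the
distinct score thresholds, no interpolation at ties — deterministic and
checkable against exhaustive enumeration). `compare_eval()` produces the
before/after comparison on identical strata.

## Differential accessibility against a background ensemble

To ask whether a particular cell subpopulation's (denoised, normalized)
track deviates from what random subsamples of the parent population
produce, the package computes per-base mean and standard deviation over an
ensemble of B background tracks within a regulatory mask (TSS positions
expanded ±100 kb and merged), z-scores the sample, selects bases with
|z| > 2, merges selections within 200 bp, converts each region's extreme
z to a two-sided normal p-value, adjusts with Benjamini-Hochberg, keeps
q < 0.05 and finally drops regions whose sample coverage never reaches a
minimum (default 1 normalized read-unit). Bases where the background is
constant (sigma 0) are assigned z = 0 and never seed regions.

Two properties of this procedure are worth understanding before use:

* **The BH step is not binding at the default settings.** A region only
  exists if some base has |z| > 2, which already implies a two-sided
  p < 0.0455; the step-up BH rule at FDR 0.05 therefore rejects every
  candidate, and the operative filters are the z cutoff and the minimum
  coverage. Genuine null control requires a stricter z cutoff (the test
  suite demonstrates control at |z| > 4.5) or a lower FDR target.
* **Selection inflates the extreme z.** The region p-value is computed
  from the maximum |z| in the region without a multiplicity correction for
  region width, so p-values are optimistic for wide regions.

Both behaviors are faithful to the procedure's description; the defaults
reproduce it, and the knobs (`z_cut`, `fdr`, `min_coverage`) let a user
calibrate. Per-sample BH (rather than pooling across samples) is used.

## The synthetic data generator

`synthetic_spec()` / `simulate_reads()` generate the fixture data every
test and example runs on: non-overlapping peaks placed by rejection
sampling (bounded retries, then an explicit error), per-peak enrichment
multipliers drawn log-uniformly from 2-20× (the long-tailed strength
distribution of real peak sets is what makes peak classification
non-trivial — a fixture whose peaks are all strong is unrealistically
easy), uniform background elsewhere, Bernoulli strands, fixed read length,
and optional cell barcodes. `thin_reads()` produces the matched noisy
data by Bernoulli thinning (pair-aware if requested, so read pairs are
never split); `sample_cells()` subsamples whole barcodes.
`simulate_footprint_tracks()` builds deterministic plateau tracks with a
configurable triangular dip at motif centers for footprinting and
cross-modality fixtures. Every generator output is a pure function of the
spec and its seed.

What the generator does **not** emulate: fragment-length structure,
sequence bias, GC effects, copy-number variation, mitochondrial
contamination, doublets, or the genome-scale sparsity of real single-cell
data. Passing tests on these fixtures therefore demonstrate that the
machinery is correct and that denoising recovers signal under controlled
Poisson-like noise — not that a desk-scale model matches results trained
on real genomes at GPU scale.

## Problem sizes used by the test suite

The recovery experiment trains on a three-chromosome ~3 Mb genome
(1.6 Mb train, 0.7 Mb validation, 0.7 Mb holdout — three chromosomes
because the chromosome-wise split requires disjoint, nonempty sets), 40
peaks per chromosome, 500,000 clean reads thinned to 10%, a model with 2
regression blocks, 6 filters, kernel 25, dilation 4, 1 classification
block, and 10 epochs at learning rate 1e-3 in batches of 4 windows of
10 kb with 600 bp pads. These sizes are the package's choice of a
configuration that trains in minutes on one CPU while leaving the
qualitative result — the denoised track correlates better with the clean
track than the noisy input does, and the probability head outperforms raw
noisy coverage as a peak score on held-out chromosomes — clearly
measurable. The learning rate is larger than the 2e-4 default because a
desk-scale run takes only a few hundred optimizer steps.

## Known limitations

* The model is trained per dataset pair; no transfer-learning utilities
  are provided.
* bigWig input/output is not built in; bedGraph (plus chrom.sizes) is the
  canonical exchange format, and external converters can bridge.
* The z-score caller's FDR semantics are nominal, as discussed above.
* Training runs single-threaded on CPU; wall time scales linearly with
  genome size, epochs, filter count squared and kernel size.
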