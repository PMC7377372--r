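---
title: "Strand-symmetric convolutional networks: model, training protocol and benchmarks"
author: "strandscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-symmetric convolutional networks: model, training protocol and benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandscan)
```

## The problem

Regulatory regions — open chromatin, transcription-factor binding sites —
are experimentally mapped by assays such as DNase-seq and ChIP-seq, whose
output is a set of *peaks* with *summits*. `strandscan` trains a
convolutional network to predict those peaks from genome sequence alone:
each chromosome is tiled into fixed windows (1 kbp by default, half-window
stride), each window is one-hot encoded, and a window is labelled positive
for a class when it contains a peak summit of that class. A trained model
can then scan any FASTA, including another species' genome.

DNA is double-stranded, and many transcription factors bind as dimers with
palindromic or near-palindromic motifs, so the signal may sit on either
strand. The package's core architectural idea — the forward- and
reverse-sequence scan (FRSS) block — lets one set of convolution kernels
read both strands.

## The strand-symmetric encoding

Bases are encoded A→(1,0,0,0), G→(0,1,0,0), C→(0,0,1,0), T→(0,0,0,1) and
N→(0,0,0,0). The channel order **A,G,C,T is load-bearing**: with A and T
(and G and C) in mirrored channel positions, rotating a window matrix by
180° (reversing both axes, `rc180()`) is exactly the encoding of the
reverse-complement sequence. Consequently, rotating a kernel stack by 180°
(`rotate_kernels()`, position and width axes index-reversed) converts a
motif detector into a detector of the motif's reverse complement:

```{r rotation}
W <- array(0, dim = c(8, 4, 1, 1))
W[, , 1, 1] <- encode_sequence("AGCTAAAG")
decode_onehot(matrix(rotate_kernels(W)[, , 1, 1], ncol = 4))  # "CTTTAGCT"
```

The identity used throughout is
`corr(rot(W), X)[i] = corr(W, rc180(X))[S - M - i]` (0-based), i.e.
scanning with rotated kernels equals scanning the other strand in reverse
order. It holds exactly for VALID cross-correlation and is fuzz-tested in
the suite.

## The FRSS block

The block runs two convolution streams over the input: the forward stream
with kernels `W0`, and a reverse stream with `rotate_kernels(W0)`. The
rotated stacks are *views*, recomputed at every forward pass — they are
never independent parameters, and their gradient is folded back into `W0`
by rotating the reverse-stream gradient. After ReLU and 2×1 stride-2 max
pooling, a second pair of convolutions (`W1`, `rot(W1)`) is applied and the
two streams are merged by element-wise summation before the second pooling:

```
X1    = pool(relu(corr(W0,      X0)))
X1rc  = pool(relu(corr(rot(W0), X0)))
X2    = pool(relu(corr(W1, X1)) + relu(corr(rot(W1), X1rc)))
```

Two wirings of the second layer are implemented. In the default **figure
mode** the rotated second-layer stream consumes the rotated first-layer
stream (`X1rc`), as drawn above. In **literal mode** both second-layer
branches consume `X1`. Only figure mode makes the block *reverse-complement
equivariant*: `frss_forward(block, rc180(X))` equals the position-reversed
`frss_forward(block, X)` whenever every pooled length is even, which
follows by applying the rotation identity layer by layer (pooling commutes
with position reversal only at even lengths; odd trailing positions are
floor-dropped and break the identity at the boundary). Literal mode is kept
for fidelity to the summation formula written with `X1` in both branches,
and the suite asserts that it *violates* the equivariance on a crafted
input, so the distinction cannot silently regress.

Convolution here means the deep-learning convention: a sliding dot product
(cross-correlation) with VALID boundary handling, so a length-`S` input and
height-`M` kernels give `S - M + 1` outputs — 992 for a 1000-bp window with
height-9 kernels.

## Architectures

`build_model()` assembles five named networks, all ending in a
fully-connected layer and an independent sigmoid per class (multi-label):

| name           | layers                                           |
|----------------|--------------------------------------------------|
| `conv4-FRSS`   | FRSS(320/320, kernels 9/8, pools 2/2) + conv(480, 8, pool 2) + conv(480, 8, pool 4) |
| `conv4-nonFRSS`| same shapes, but the reverse-stream kernels are independent trainable weights (the tying ablation) |
| `conv3-FRSS`   | FRSS(320/480) + conv(960, 8, pool 4)             |
| `conv4`        | four plain conv layers (320/320/480/480)          |
| `deepsea-type` | three plain conv layers (320/480/960, kernel 8, pools 4/4) |

The published per-layer hyperparameter table for these models is not
available to us, so map counts, pooling sizes and the 925-unit
fully-connected layer are package defaults (flagged as such in the
documentation) and every entry can be overridden at build time. The
DeepSEA-type chain uses that model's published map counts. Weights are
initialized from a truncated normal (sd 0.05, resampled beyond 2 sd),
biases at zero; the seed is a mandatory argument. Convolution layers carry
no bias terms — the rectifier nonlinearity and the fully-connected biases
absorb the offsets, and a shared conv bias would be redundant across the
two tied streams.

The loss is the mean Bernoulli cross-entropy over batch and classes with
probabilities clipped to `[1e-8, 1 - 1e-8]`, plus `λ1 Σ w²` (λ1 = 5×10⁻⁷)
over all trainable weights and `λ2 Σ|logit|` (λ2 = 1×10⁻⁸) on the
pre-sigmoid predictions; the penalties apply to the convolutional families
and can be switched off. We minimize the negated log-likelihood plus
penalties (the optimizers minimize). All gradients — including the
tied-rotation accumulation `dW0 = dW0_fwd + rot(dW0_rev)` and the max-pool
argmax routing — are hand-derived and validated against central finite
differences at 10⁻⁴ relative tolerance on small models whose biases are
nudged off the rectifier kinks (at a kink the one-sided derivatives differ
and finite differences are uninformative).

## Training protocol

`train()` implements the schedule faithfully: mini-batches of 100 windows;
each mini-batch is first *evaluated* (micro-F1 at probability 0.5 — the
monitoring threshold is our choice, the protocol does not state one) and
then used for four Adam updates, two alternating passes over its two
halves. When the mean of the last three monitoring F1 scores exceeds 0.75,
the model is tested on three withheld validation mini-batches and
checkpointed iff validation F1 improved. After training, the delivered
model is whichever of end-of-training and best checkpoint has the higher
holdout AUPRC. Negative windows (all-zero label rows) are downsampled to
25% before training; whole chromosomes are held out for evaluation, because
overlapping strides make nearby windows near-duplicates and a random window
split would leak training sequence into the test set.

Defaults the protocol leaves open, fixed here: Adam with learning rate
1e-4 (the benchmark fixture uses 1e-2, see below); micro-averaged F1 for
monitoring; validation F1 also micro-averaged over the three withheld
batches jointly.

Evaluation reports per-class AUROC (trapezoidal rule over the grouped
threshold sweep; an all-constant score gives 0.5) and AUPRC as average
precision (step-wise `Σ Δrecall × precision`, not interpolated), plus
macro means, a confusion table at 0.5, and the false-positive count at the
0.2 display threshold. Both areas are pinned to an exhaustive
threshold-sweep oracle in the tests, and AUROC additionally to `pROC`.

## Interpretability

* **Class saliency** (`saliency()`): the gradient `ω = ∂S_i/∂X⁰` of the
  *pre-sigmoid* class score with respect to the one-hot input, reported per
  position as the influential value `Σ_n |ω[s,n]|`. Windows with
  `S_i < -2` are flagged as suppressed (the display rule for irrelevant
  sequence). A first-order Taylor step predicts the effect of any
  substitution, which is why the method stands in for in silico saturation
  mutagenesis at a 4000th of the cost.
* **ISM oracle** (`ism_oracle()`): the brute-force mutagenesis matrix
  `ΔS[s,b]`, used as the agreement reference. On exactly linear models the
  gradient differences reproduce ΔS to machine precision; on trained
  fixtures the suite requires ≥80% sign agreement on the larger half of
  the effects. Untrained rectifier networks sit exactly at their kinks
  (activations near zero), where a single-base substitution crosses many
  kink and pooling-argmax boundaries; first-order agreement is a property
  of models away from that degenerate point, so the agreement checks run
  on trained fixtures.
* **Activation maximization** (`activation_maximization()`): ascends a free
  real-valued window (initialized N(0.02, 0.02) — small and slightly
  positive to escape the rectifiers' flat region) on
  `ŷ_i / Σ_{k≠i} ŷ_k − λ‖X⁰‖²` (λ = 5×10⁻³). The printed form of this
  objective is typographically ambiguous between a ratio and a product; we
  default to the ratio, which actually rewards *class-specific* sequence,
  and keep the product form behind `objective = "product"`. The common-mode
  objective is `Π_i ŷ_i − λ‖X⁰‖²`, and with a single class the empty-sum
  denominator is taken as 1. The best-objective iterate is returned;
  convergence is not guaranteed on this rugged landscape.
* **Kernel export** (`kernels_to_pwms()`, `write_meme()`): first-layer
  kernels become position probability matrices by a per-position softmax
  (temperature 1 by default; "softmax-like" is under-specified, so the
  temperature is a parameter), annotated with information content
  `2 + Σ p log₂ p` bits for logo scaling, and written in MEME minimal
  format (column order converted to A,C,G,T) for Tomtom/FIMO.

## QC: FRiP and cFRiP

`compute_frip()` removes mitochondrial peaks and peaks overlapping a
blacklist (reads are never filtered — the correction targets peak files),
counts reads overlapping any retained peak by ≥1 bp (midpoint containment
is available), and reports FRiP = reads-in-peaks / total reads. Because
FRiP inflates at low depth, the corrected score multiplies it by the
fraction of the genome covered by at least one read:
`cFRiP = FRiP × coverage ≤ FRiP`. Interval unions come from
`GenomicRanges::reduce()` and are pinned to a per-base boolean-array oracle.

## The synthetic benchmark and what it does (not) show

All stochastic properties run on a fully synthetic, ground-truthed
benchmark (`synthetic_spec()` defaults):

* two chromosomes, 300 kb (training) + 100 kb (holdout), uniform base
  composition;
* one non-palindromic 8-bp motif (consensus AGGTCATC, consensus
  probability 0.99 per position ≈ 1.9 bits — a strong, CTCF-like motif)
  planted at 5×10⁻⁴ instances per bp on uniformly random strands;
* peaks of half-width 150 bp centred on each instance (the summit *is* the
  instance centre), overlapping peaks merged keeping the first summit;
* 20,000 100-bp reads, half sampled inside peaks, for the QC module, with
  the analytic expectation FRiP ≈ p + (1−p)·(peak bases / genome bases).

The motif strength was set by a matched-filter feasibility analysis: at
substantially lower consensus probability a single mismatched instance
scores below the best chance 8-mer of a 1-kb background window, so *no*
detector — the true-PWM log-odds scan included — can separate the classes
(at 0.85 the ideal scanner's holdout AUPRC is ≈0.58; at 0.99 its ceiling
is ≈0.88–0.94). A benchmark below that ceiling would measure noise, not
learning.

The reference model (`small_frss_model()`) is a two-layer FRSS block
(16/16 maps, kernels 9/8, pool 2) with **global max pooling** over
positions, a 16-unit fully-connected layer and a sigmoid head. Global
pooling is a desk-scale design choice: with only ~300 training windows, a
flattened per-position readout memorizes the training set before the
kernels learn anything (training F1 reaches 1.0 while holdout stays at the
base rate), whereas max-over-positions forces the features to mean "was
this pattern seen anywhere", which is what motif detection is. The
full-scale architectures do not use it.

Benchmark training runs Adam at 1e-2 for 20 epochs with one validation
mini-batch (only 2–3 mini-batches exist at this scale) and **two
random-initialization restarts**, keeping the run with the higher
validation F1 — never the holdout, which is reserved for reporting. The
restarts address an honest property of desk-scale motif discovery: roughly
40% of initializations never leave the constant-prediction plateau, and
the failure follows the initialization seed, not the data seed. Under
these frozen conditions, four of five benchmark seeds reach holdout AUPRC
≈0.88–0.90 and recover the planted PWM (best-kernel alignment correlation
≥0.8); one seed plateaus in both restarts and is reported as the failure
it is. The tied-vs-untied comparison trains both variants for 8 epochs
(single start) on the same five seeds — a deliberately limited budget,
because weight tying is a data-efficiency device and its advantage is
largest before either variant saturates.

What passing these benchmarks shows: the whole pipeline — windowing,
labelling, the FRSS numerics, the training schedule, evaluation and the
kernel→motif export — works end to end, and tying measurably helps on
strand-randomized signal. What it does not show: performance on real
chromatin data. The generator plants a single strong motif in i.i.d.
background; real genomes have repeats, GC heterogeneity, nucleosome
structure, co-occurring motifs and label noise, none of which are
emulated.

## Numerical choices and degenerate inputs

* Probabilities are clipped at 1e-8 before the log; the loss gradient uses
  the unclipped sigmoid form.
* Max pooling floor-drops odd trailing positions and says so once per
  session per shape.
* `f1_score(0, 0)` is 0 by convention; classes without both a positive and
  a negative are skipped (with a warning) in evaluation.
* Windows containing N encode as all-zero rows and are kept by default
  (`max_n_fraction` filters them when asked); duplicated windows produced
  by overlapping strides are kept.
* Trailing partial windows are dropped, never padded; narrowPeak summits
  of −1 fall back to the interval midpoint; coordinates are 0-based
  half-open (BED) everywhere.
* All randomness flows through explicit integer seeds via scoped RNG, so
  every result in the test suite and the acceptance script is reproducible
  bit for bit on a given BLAS.

## Problem sizes

The suite trains the reference benchmark on ~600 windows per seed (five
seeds, two restarts), the ablation pair at 8 epochs on the same seeds, and
five 40-bp trained fixtures for the interpretability checks; the whole
test run and the acceptance script each complete comfortably on a single
CPU. These sizes are the package's reference study conditions, chosen once
and reused everywhere.

## Limitations

* Training is plain R + BLAS with a small C++ gather/scatter core — fine
  for benchmark-scale experiments, not for ENCODE-scale corpora.
* Recurrent and batch-norm architectures are out of scope.
* Kernel→PWM export uses a temperature-1 softmax; other conventions exist
  and change logo appearance, though not the alignment correlations used
  in the tests.
* The activation-maximization objective is non-convex; different seeds can
  give different motifs, and the returned iterate is only the best seen.
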