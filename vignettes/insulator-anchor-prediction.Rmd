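---
title: "Predicting insulator loop anchors from sequence: model, refinement and variant scoring"
author: "insuscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting insulator loop anchors from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

CTCF/cohesin-mediated chromatin loops organize the genome into insulated
neighbourhoods. Their anchors can be mapped by conformation assays
(ChIA-PET, Hi-C), but those assays are expensive and report fuzzy,
kilobase-scale intervals. `insuscan` addresses three tasks from DNA
sequence alone:

1. **Classification** — does a 2000 bp window contain an insulator loop
   anchor? A convolutional network maps the one-hot encoded window to
   `P(anchor) = 1 / (1 + exp(-x))`.
2. **Boundary refinement** — where inside a fuzzy window is the functional
   core? One-dimensional Grad-CAM over the final convolution block
   produces a per-base importance map whose peak defines a 40 bp refined
   anchor.
3. **Variant impact** — how much does a point variant change the anchor
   probability? The delta score is `p_wt - p_mut`, both alleles scored on
   2000 bp windows centered at the variant, so predicted insulator *loss*
   is positive.

## Data model

Labels come from peak logic, not curation. Positives are CTCF ChIP-seq
peaks that overlap a cohesin (Rad21) ChIA-PET peak. Negatives are typed:

* **type1** — CTCF peaks overlapping no anchor (hardest: they carry the
  CTCF motif and CTCF-bound chromatin context);
* **type2** — accessible (ATAC-seq) peaks off every anchor that contain a
  CTCF motif at the scan threshold `p <= 5e-5`;
* **type3** — accessible peaks without the motif (easiest).

All peaks are normalized to fixed windows centered on the peak midpoint
(floor of `(start + end) / 2`); windows running past a chromosome edge are
dropped rather than padded. The split is a uniform random 8:1:1
(largest-remainder rounding), and training-split negatives are
downsampled, stratified across types, to the positive count. Internally
every coordinate is 0-based half-open; VCF positions are converted on
ingest; overlap always means at least one shared base.

## The network and strand handling

The classifier is three convolution blocks (conv, ReLU, max-pool) followed
by three dense layers; the first-layer filters are 31 x 4 and act as
learnable position weight matrices. Fifty percent dropout on the hidden
dense layers is the architecture default. Because DNA is double stranded,
a model should score a window and its reverse complement identically;
plain CNNs do not. Four strategies are implemented:

* `standard` — forward strand only;
* `rc_augmented` — forward-only model, training data doubled with reverse
  complements;
* `trained_conjoined` — the mean of the two strand sigmoids is the
  training output, gradients flowing through both shared-weight passes;
* `posthoc_conjoined` (default) — trained exactly like `rc_augmented`,
  then converted at inference to the Siamese form: the two strand
  probabilities are averaged, which makes the prediction exactly
  reverse-complement symmetric for *any* parameters.

Training is Adam with binary cross-entropy, defaults `learning_rate =
5e-5`, 50 epochs, batch 64, weight decay `5e-4`; the checkpoint kept is
the one with minimum validation loss, evaluated at the end of each epoch.
A two-stage protocol first pretrains the same architecture to classify
motif presence (labels from the exact-p-value scanner), then fine-tunes on
anchor labels starting from all of those weights, final layer included.
One addition to the classic recipe proved necessary: a one-epoch linear
learning-rate warmup (`warmup_epochs` in `train_config()`). Adam's
bias-corrected first steps are full-sized, and without the ramp they can
destroy a pretrained initialization before the loss has any say.

## Boundary refinement

For a positive window, the gradient of the pre-sigmoid positive-class
logit is taken with respect to the final convolution block's post-ReLU
activation maps. Each channel's weight is the global average of its
gradient over positions; the importance map is the ReLU of the weighted
activation sum, linearly upsampled to input length (nearest-neighbour
optional). The refined anchor is the 40 bp interval centered on the
leftmost argmax, shifted inward at window edges; an all-zero map yields a
flagged no-signal record instead of an arbitrary interval. A
`sumwindow` mode (center the bin of maximal summed importance) and a
strand-symmetrized map (mean of the forward map and the mirrored
reverse-strand map) are available but not the defaults: the forward-strand
argmax is the plain reading of the method. Gradients are taken at the
logit, not the probability, the standard attribution convention.

## Motif scanning

The JASPAR text format is parsed into count matrices; log-odds are
`log2((counts + 0.1) / rowsum / background)` against a uniform 0-order
background (a background file is deliberately not required; the
pseudocount 0.1 avoids infinite log-odds). P-values are exact: the score
distribution of a random background k-mer is built by convolving
per-position score distributions on a 1/1000-bit lattice, and the scan
threshold for `p = 5e-5` is the smallest lattice score whose tail
probability is at or below it. Both strands are scanned; windows
containing N are skipped; every overlapping hit is reported since
downstream logic only asks whether a window contains at least one hit.

## The synthetic benchmark

Nothing in the test suite downloads data. `fixture_spec()` defines a
self-contained study: an i.i.d. background genome at human-like 41% GC
(3 chromosomes of 350 kb by default), disjoint 400 bp windows assigned to
the four classes (500 each, about 2000 windows), and motif plants drawn
from a built-in *synthetic* CTCF-like 19 bp matrix plus two 10 bp
co-factor motifs:

* positives get the primary motif near the window center (+/- 50 bp
  jitter, random strand) plus each co-motif with probability 0.8 at a
  random non-overlapping offset;
* type1 and type2 get the primary motif only — they differ solely in
  which source peak file (CTCF vs ATAC) carries them;
* type3 stays background, re-drawn until it contains no chance motif hit
  so that the labeling pipeline reconstructs every class exactly.

Planted primary instances are likewise re-drawn until detectable at the
scan threshold — the same policy for every motif-bearing class, so classes
differ only in their co-motif grammar. Variable-width source peaks
(0.7-1.0 of the window length, centered on the window) are emitted so that
peak normalization reconstructs the windows bit-for-bit. Disrupting
variants flip the highest-information motif position to its least likely
base; neutral variants flip a background base at least `neutral_buffer`
from every plant in the same window (50 bp in the 400 bp profile — the
geometry of a 400 bp window cannot hold a 200 bp buffer; the 2000 bp
profile uses 200 bp).

What the generator does *not* emulate: chromatin context, nucleosome
positioning, peak-calling noise, correlated background composition, and
the sheer scale of consortium data. Passing tests show the pipeline's
machinery is correct and that its qualitative behaviour matches the
method's claims at desk scale; they are not evidence about any particular
real genome.

## The desk-scale protocol and why its knobs differ from the defaults

The full-scale defaults above are the package's standard protocol, but a
~2000-window benchmark trained for 10 epochs on one CPU is a different
regime, and three deliberate changes define the desk-scale protocol used
by the tests and the acceptance script:

* **Learning rate 1e-3, batch 32.** At `5e-5` nothing moves in 10
  epochs; at `3e-3` and above Adam reliably collapses this small model to
  constant output. `1e-3` with the one-epoch warmup is stable.
* **Dropout 0 on the tiny profile.** With a 32/16-unit head, 50% dropout
  prevents both memorization and feature learning inside the 10-epoch
  budget; best-checkpoint selection carries the regularization burden
  instead. The architecture default stays 0.5.
* **Pool widths 2 (tiny profile) instead of 4.** The refinement module
  needs spatial resolution at the final block: with pools of 4 a 400 bp
  window leaves 16 bp per final-block position and the Grad-CAM argmax
  smears beyond the 40 bp bin; pools of 2 keep 8 bp resolution, and
  localization then recovers the planted motif in most positives on most
  training runs (attribution quality still varies with the training seed:
  fine-tuned heads that lean on memorized context rather than the motif
  produce diffuse maps). The full 2000 bp profile keeps pools of 4.

Problem sizes used by the acceptance checks: the benchmark bundle is the
default ~2000-window fixture, 10 + 10 epochs; the strategy comparison runs
4 x 250-window fixtures for 8 + 8 epochs per arm with one shared stage-1
checkpoint per seed (sharing one pretrained initialization across
strategy arms keeps the comparison about the strategies, not the
initialization); the determinism chain runs a 160-window
fixture for 2 + 2 epochs; coverage checks use 25 positive 2000 bp windows.

## Numerical and degenerate-input choices

* N bases one-hot encode as all-zero rows; an all-N window is a legal
  (all-zero) input. N-containing scan windows are skipped.
* BCE probabilities are clamped to `[1e-7, 1 - 1e-7]`.
* AUROC is the rank (Mann-Whitney) statistic with midrank ties; AUPR uses
  step interpolation over tie blocks, never trapezoids.
* Argmax ties in refinement go to the leftmost position; empty importance
  maps are flagged, not placed.
* The exact-p-value lattice is 1/1000 bit; the enumeration tests compare
  against the same lattice, so agreement is at 1e-9, not at the lattice
  error.
* All randomness flows through explicit seeds: model init, data split,
  balancing, epoch shuffling and dropout each have a documented seed or
  sub-seed, making the full pipeline byte-identical across runs.

## Known limitations

The strategy comparison (post-hoc conjoined vs trained conjoined) is
reported by the test suite and the acceptance script, but at desk scale
both arms plateau at similar overall AUPR and their median difference
sits well inside seed-to-seed noise; resolving the direction of that
comparison requires training scales this package's benchmark does not
attempt. The qualitative ordering "type3 easiest, then type2, then type1" rests on
the co-motif grammar being learnable. At 2000 windows and 10 epochs the
grammar signal is weak — the type1-vs-type2 gap sits near the noise floor
of the per-type AUPR estimates (the two classes are sequence-identical by
construction, differing only through their shared-context relation to
positives) — so that ordering should be read as directional, not as a
measured effect size. Variant delta magnitudes are likewise small on
desk-scale models; the rank separation between disrupting and neutral
variants is the robust signal. Real-data use should train the full
2000 bp profile at the full-scale defaults.

## A minimal session

```{r example}
library(insuscan)

spec <- fixture_spec(seed = 1)
fx <- plant_windows(make_background_genome(spec), spec)
manifest <- build_dataset(fx$genome, fx$peaks$ctcf, fx$peaks$chiapet,
                          fx$peaks$atac, spec$primary_motif,
                          window_length = 400, seed = 1)

model <- build_model(tiny_model_config(dropout = 0), seed = 1,
                     mode = "posthoc_conjoined")
hits <- scan_motifs(fx$genome, spec$primary_motif, 5e-5)
motif_lab <- intersect_any(genomic_intervals(manifest$windows$chrom,
                                             manifest$windows$start,
                                             manifest$windows$end), hits)
cfg <- train_config(learning_rate = 1e-3, epochs = 10, batch_size = 32,
                    seed = 2)
pre <- pretrain_motif_classifier(manifest, motif_lab, fx$genome, cfg, model)
fit <- train_anchor_classifier(manifest, fx$genome, cfg, model,
                               init_from = pre$model)

test_w <- manifest$windows[manifest$windows$split == "test", ]
evaluate_model(fit$model, test_w, fx$genome)$by_type

positives <- test_w[test_w$label == "positive", ]
refine_all(fit$model, positives, fx$genome, bin = 40)$coverage

variants <- make_variants(fx$truth, fx$genome, spec, n_each = 50)
delta_score(fit$model, variants$disrupting[1, ], fx$genome)
```
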