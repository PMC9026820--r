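# insuscan

Sequence-based prediction of CTCF/cohesin insulator loop anchors, weakly
supervised refinement of their boundaries, and single-base variant impact
scoring — as an R package with a fully synthetic, self-contained
benchmark.

Chromatin loops anchored at CTCF sites partition the genome into
insulated neighbourhoods; disrupting an anchor can rewire
enhancer–promoter contacts. Conformation assays that map anchors
(ChIA-PET, Hi-C) are costly and report fuzzy kilobase-scale intervals.
`insuscan` works from DNA sequence alone:

* **Classify.** A three-block convolutional network reads a one-hot
  encoded 2000 bp window (columns A, T, C, G) and emits
  `P(anchor) = 1/(1 + e^{-x})`. Double-strandedness is handled by a
  Siamese ("conjoined") scheme: the window and its reverse complement are
  scored by the same weights and the two sigmoids averaged, making the
  prediction exactly strand-symmetric. Four training strategies
  (`standard`, `rc_augmented`, `trained_conjoined`, `posthoc_conjoined`)
  are implemented; post-hoc conjoined — train with RC augmentation,
  convert to the Siamese form afterwards — is the default.
* **Refine.** One-dimensional Grad-CAM: channel weights
  `a_k = (1/z) Σ_i ∂y/∂A_{ki}` over the final convolution block, map
  `ReLU(Σ_k a_k A_k)` upsampled to input length, and a 40 bp window
  around the peak as the refined anchor — collapsing fuzzy annotations to
  ~2% of their original coverage.
* **Score variants.** `delta = p_WT − p_mutant` on windows centered at
  the variant; positive delta means predicted insulator loss.

Supporting machinery: FASTA/BED readers on 0-based half-open coordinates,
a JASPAR PFM parser with **exact** motif-scan p-values (dynamic
programming over the discretized score distribution, default threshold
5e-5), dataset construction from CTCF ChIP / Rad21 ChIA-PET / ATAC peak
logic with three typed negative classes, an 8:1:1 split with balanced
training negatives, two-stage training (motif pretrain → anchor
fine-tune, Adam + BCE, best-validation checkpointing),
leave-one-chromosome-out and cross-cell-line harnesses, and a seeded
synthetic planted-motif benchmark generator so everything runs without a
single download. The CNN engine (forward, backprop, Adam) is implemented
in base R matrix code within the package.

## Worked example

Train on the built-in synthetic benchmark (~2000 windows of 400 bp, a
planted CTCF-like motif plus two co-factor motifs) and inspect the three
modules:

```r
library(insuscan)

spec <- fixture_spec(seed = 1)
fx   <- plant_windows(make_background_genome(spec), spec)
mf   <- build_dataset(fx$genome, fx$peaks$ctcf, fx$peaks$chiapet,
                      fx$peaks$atac, spec$primary_motif,
                      window_length = 400, seed = 1)
print(mf)
#> dataset_manifest: 1220 windows, seed 1
#>              split
#> negative_type test train val
#>         none    41   410  49
#>         type1   51   137  51
#>         type2   56   137  48
#>         type3   52   136  52

model <- build_model(tiny_model_config(dropout = 0), seed = 1)
cfg   <- train_config(learning_rate = 1e-3, epochs = 10, batch_size = 32,
                      seed = 2)
hits  <- scan_motifs(fx$genome, spec$primary_motif, 5e-5)
lab   <- intersect_any(genomic_intervals(mf$windows$chrom, mf$windows$start,
                                         mf$windows$end), hits)
pre   <- pretrain_motif_classifier(mf, lab, fx$genome, cfg, model)
fit   <- train_anchor_classifier(mf, fx$genome, cfg, model,
                                 init_from = pre$model)

te <- mf$windows[mf$windows$split == "test", ]
evaluate_model(fit$model, te, fx$genome)$by_type
#>   negative_type     auroc      aupr
#> 1         type1 0.4868484 0.4755143
#> 2         type2 0.4668990 0.4170824
#> 3         type3 0.9643527 0.9098534
```

Anchors separate cleanly from motif-free accessible chromatin (type3,
AUROC ≈ 0.96); CTCF-motif-bearing negatives (type1/type2) are the hard
classes at this training scale, exactly the difficulty ordering the
method is built around. Refinement and variant scoring:

```r
pos <- te[te$label == "positive", ]
ra  <- refine_all(fit$model, pos, fx$genome, bin = 40)
ra$coverage
#> [1] 0.09756098   # ~40 bp kept per 400 bp window (0.02 at 2000 bp);
                   # one window had an empty importance map

vv <- make_variants(fx$truth, fx$genome, spec, n_each = 50)
delta_score(fit$model, vv$disrupting[1, ], fx$genome)
#>     id chrom  pos ref alt      p_wt     p_mut      delta
#> 1 dis1  chr1 2688   A   T 0.5348012 0.4415381 0.09326306
```

A motif-breaking substitution lowers the anchor probability (positive
delta, insulator loss); neutral background substitutions score near zero.

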