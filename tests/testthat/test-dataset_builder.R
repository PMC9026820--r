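test_that("interval overlap uses half-open semantics and matches brute force", {
  q <- genomic_intervals("chr1", 0, 10)
  expect_true(intersect_any(q, genomic_intervals("chr1", 9, 20)))
  expect_false(intersect_any(q, genomic_intervals("chr1", 10, 20)))
  expect_false(intersect_any(q, genomic_intervals("chr2", 0, 10)))
  set.seed(31)
  mk <- function(n) {
    s <- sample(0:5000, n, TRUE)
    genomic_intervals(sample(c("chr1", "chr2"), n, TRUE), s,
                      s + sample(1:300, n, TRUE))
  }
  q <- mk(200); s <- mk(200)
  got <- intersect_any(q, s)
  brute <- vapply(seq_len(200), function(i) {
    any(s$chrom == q$chrom[i] & s$start < q$end[i] & s$end > q$start[i])
  }, TRUE)
  expect_identical(got, brute)
})

test_that("window labeling types peaks per the anchor/negative rules", {
  no_hits <- genomic_intervals(character(), integer(), integer())
  # one CTCF peak overlapping one ChIA-PET peak: 1 positive, 0 negatives
  lab <- label_windows(genomic_intervals("chr1", 100, 500),
                       genomic_intervals("chr1", 300, 700),
                       no_hits[0, ], no_hits)
  expect_identical(lab$label, "positive")
  expect_identical(lab$negative_type, "none")
  # CTCF peak with no ChIA-PET overlap becomes type1
  lab <- label_windows(genomic_intervals("chr1", 100, 500),
                       genomic_intervals("chr1", 600, 700),
                       no_hits[0, ], no_hits)
  expect_identical(lab$negative_type, "type1")
  # two off-anchor ATAC peaks, one carrying a motif hit: one type2 + one type3
  atac <- genomic_intervals("chr1", c(1000, 2000), c(1400, 2400))
  hits <- genomic_intervals("chr1", 1100, 1119, strand = "+")
  lab <- label_windows(genomic_intervals("chr1", 100, 500),
                       genomic_intervals("chr1", 300, 700), atac, hits)
  expect_identical(sort(lab$negative_type), c("none", "type2", "type3"))
  expect_identical(lab$negative_type[lab$start == 1000], "type2")
  # an ATAC peak touching a positive is excluded entirely
  atac2 <- genomic_intervals("chr1", c(400, 2000), c(800, 2400))
  lab <- label_windows(genomic_intervals("chr1", 100, 500),
                       genomic_intervals("chr1", 300, 700), atac2, no_hits)
  expect_false(any(lab$start == 400))
  expect_error(label_windows(no_hits[0, ], no_hits, no_hits, no_hits),
               "no CTCF peaks")
})

test_that("every input peak lands in exactly one class or is excluded", {
  fx <- small_fixture()
  ctcf_w <- normalize_windows(fx$peaks$ctcf, fx$genome, 400L)
  atac_w <- normalize_windows(fx$peaks$atac, fx$genome, 400L)
  hits <- scan_motifs(fx$genome, fx$spec$primary_motif, 5e-5)
  lab <- label_windows(ctcf_w, fx$peaks$chiapet, atac_w, hits)
  n_excluded <- nrow(ctcf_w) + nrow(atac_w) - nrow(lab)
  expect_gte(n_excluded, 0L)
  expect_identical(anyDuplicated(paste(lab$chrom, lab$start)), 0L)
  # and the fixture's intended classes are recovered exactly
  key <- function(d) paste(d$chrom, d$start, d$end)
  want <- setNames(fx$windows$negative_type, key(fx$windows))
  got <- setNames(lab$negative_type, key(lab))
  expect_setequal(names(got), names(want))
  expect_identical(unname(got[names(want)]), unname(want))
})

test_that("window normalization centers on the floor midpoint and drops edges", {
  g <- toy_genome(random_dna(7000, seed = 2))
  out <- normalize_windows(genomic_intervals("chr1", 5000, 5400), g, 2000L)
  expect_equal(out$start, 4200L)
  expect_equal(out$end, 6200L)
  # a 1 bp peak [3000,3001) centers on base 3000 (floor midpoint)
  out <- normalize_windows(genomic_intervals("chr1", 3000, 3001), g, 2000L)
  expect_equal(out$start, 2000L)
  expect_equal(out$end, 4000L)
  out <- normalize_windows(genomic_intervals("chr1", 100, 300), g, 2000L)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_dropped"), 1L)
  expect_error(normalize_windows(genomic_intervals("chr1", 0, 10), g, 401L),
               "even")
})

test_that("8:1:1 splitting uses largest-remainder rounding deterministically", {
  mk <- function(n) data.frame(
    chrom = "chr1", start = seq_len(n) * 500L, end = seq_len(n) * 500L + 400L,
    name = ".", score = NA_real_, strand = ".", label = "negative",
    negative_type = "type3", cell_line = "x", split = NA_character_)
  m100 <- split_dataset(mk(100), seed = 4)
  expect_equal(as.integer(table(m100$windows$split)[c("train", "val", "test")]),
               c(80L, 10L, 10L))
  m101 <- split_dataset(mk(101), seed = 4)
  expect_equal(sum(m101$windows$split == "train"), 81L)
  m2 <- split_dataset(mk(101), seed = 4)
  expect_identical(m101$windows$split, m2$windows$split)
  m3 <- split_dataset(mk(101), seed = 5)
  expect_false(identical(m101$windows$split, m3$windows$split))
  expect_error(split_dataset(mk(9), seed = 1), "at least 10")
})

test_that("balancing downsamples train negatives to the positive count only", {
  mf <- small_manifest()   # already balanced by build_dataset
  w <- mf$windows
  tr <- w[w$split == "train", ]
  expect_equal(sum(tr$label == "negative"), sum(tr$label == "positive"))
  # re-balancing an already balanced manifest is the identity
  mf2 <- balance_training_negatives(mf, seed = 99)
  expect_identical(mf2$windows, mf$windows)
  # rebuild without balancing to verify val/test invariance
  fx <- small_fixture()
  ctcf_w <- normalize_windows(fx$peaks$ctcf, fx$genome, 400L)
  atac_w <- normalize_windows(fx$peaks$atac, fx$genome, 400L)
  hits <- scan_motifs(fx$genome, fx$spec$primary_motif, 5e-5)
  lab <- label_windows(ctcf_w, fx$peaks$chiapet, atac_w, hits)
  raw <- split_dataset(lab, seed = 7)
  bal <- balance_training_negatives(raw, seed = 8)
  strip <- function(d) { rownames(d) <- NULL; d }
  for (sp in c("val", "test")) {
    expect_identical(strip(bal$windows[bal$windows$split == sp, ]),
                     strip(raw$windows[raw$windows$split == sp, ]))
  }
  trb <- bal$windows[bal$windows$split == "train", ]
  expect_equal(sum(trb$label == "negative"), sum(trb$label == "positive"))
})

test_that("LOCO folds partition windows by chromosome", {
  mf <- small_manifest()
  folds <- make_loco_splits(mf)
  chroms <- sort(unique(mf$windows$chrom))
  expect_length(folds, length(chroms))
  held <- sort(vapply(folds, `[[`, "", "held_out_chrom"))
  expect_identical(held, chroms)
  for (f in folds) {
    expect_false(f$held_out_chrom %in% f$train_chroms)
    expect_setequal(c(f$held_out_chrom, f$train_chroms), chroms)
  }
  one <- mf
  one$windows <- one$windows[one$windows$chrom == chroms[1], ]
  expect_error(make_loco_splits(one), ">= 2 chromosomes")
})

test_that("manifest TSV/JSON round-trips", {
  mf <- small_manifest()
  dir <- tempfile()
  write_manifest(mf, dir)
  back <- read_manifest(dir)
  expect_equal(back$windows$start, mf$windows$start)
  expect_identical(back$windows$split, mf$windows$split)
  expect_equal(back$seed, mf$seed)
})
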