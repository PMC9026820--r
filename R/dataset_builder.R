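# Labeled training/validation/test set construction.
#
# Positives are CTCF ChIP peaks intersecting cohesin (Rad21) ChIA-PET
# peaks; negatives are typed: type1 = CTCF peaks off-anchor, type2/type3 =
# accessible (ATAC) peaks off-anchor with/without a CTCF motif. Windows
# are normalized to a fixed length centered on the source peak, split
# 8:1:1, and training negatives are balanced to the positive count.
# "Overlap" always means >= 1 shared bp under half-open semantics.

.as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = "*")
}

#' Does each query interval overlap any subject interval?
#'
#' Overlap means sharing at least 1 bp on the same chromosome under
#' half-open semantics (so `[0,10)` and `[10,20)` do not overlap).
#'
#' @param query,subject `genomic_intervals` data frames.
#' @return logical vector, one entry per query row.
#' @export
intersect_any <- function(query, subject) {
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  # suppress the benign seqlevel-mismatch warning when the two sets share
  # no chromosome at all
  suppressWarnings(
    IRanges::overlapsAny(.as_granges(query), .as_granges(subject)))
}

#' Label windows as anchors or typed negatives
#'
#' * positive: a CTCF window intersecting a ChIA-PET peak,
#' * type1: a CTCF window intersecting no positive,
#' * type2: an ATAC window off every positive that contains a motif hit,
#' * type3: an ATAC window off every positive with no motif hit.
#'
#' ATAC windows intersecting a positive are excluded entirely. Motif
#' presence is judged by >= 1 bp overlap with `motif_hits`.
#'
#' @param ctcf_peaks,chia_pet_peaks,atac_peaks `genomic_intervals` data
#'   frames (typically already normalized to fixed-width windows).
#' @param motif_hits motif hits as returned by [scan_motifs()].
#' @param cell_line tag recorded on every window.
#' @return a data.frame of labeled windows with columns
#'   chrom/start/end/name/score/strand/label/negative_type/cell_line/split.
#' @export
label_windows <- function(ctcf_peaks, chia_pet_peaks, atac_peaks, motif_hits,
                          cell_line = "synthetic") {
  if (nrow(ctcf_peaks) == 0L) stop("no CTCF peaks supplied: nothing to label")
  is_pos <- intersect_any(ctcf_peaks, chia_pet_peaks)
  positives <- ctcf_peaks[is_pos, , drop = FALSE]
  type1 <- ctcf_peaks[!is_pos, , drop = FALSE]
  if (nrow(positives) > 0L && nrow(type1) > 0L) {
    # a CTCF peak touching a positive peak is not a clean negative
    type1 <- type1[!intersect_any(type1, positives), , drop = FALSE]
  }
  keep_atac <- if (nrow(positives) > 0L)
    !intersect_any(atac_peaks, positives) else rep(TRUE, nrow(atac_peaks))
  atac <- atac_peaks[keep_atac, , drop = FALSE]
  has_motif <- if (nrow(atac)) intersect_any(atac, motif_hits) else logical(0)
  mk <- function(iv, label, ntype) {
    if (nrow(iv) == 0L) return(NULL)
    data.frame(iv[, c("chrom", "start", "end", "name", "score", "strand")],
               label = label, negative_type = ntype, cell_line = cell_line,
               split = NA_character_, stringsAsFactors = FALSE)
  }
  out <- rbind(mk(positives, "positive", "none"),
               mk(type1, "negative", "type1"),
               mk(atac[has_motif, , drop = FALSE], "negative", "type2"),
               mk(atac[!has_motif, , drop = FALSE], "negative", "type3"))
  rownames(out) <- NULL
  out
}

#' Normalize peaks to fixed-length windows centered on the peak
#'
#' Each peak becomes `[c - L/2, c + L/2)` with `c = floor((start+end)/2)`.
#' Windows that would extend past either chromosome edge are dropped (not
#' padded); the drop count is attached as an attribute.
#'
#' @param intervals `genomic_intervals` data frame.
#' @param genome a `genome` object supplying chromosome lengths.
#' @param target_length even window length (default 2000).
#' @return normalized `genomic_intervals` with attribute `n_dropped`.
#' @export
normalize_windows <- function(intervals, genome, target_length = 2000L) {
  if (target_length %% 2L != 0L) stop("target_length must be even")
  half <- target_length %/% 2L
  centers <- (intervals$start + intervals$end) %/% 2L
  start <- centers - half
  end <- centers + half
  lens <- genome_lengths(genome)[intervals$chrom]
  keep <- start >= 0L & end <= lens & !is.na(lens)
  out <- intervals[keep, , drop = FALSE]
  out$start <- start[keep]
  out$end <- end[keep]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Randomly split labeled windows into train/validation/test
#'
#' A uniform random permutation under the seed followed by contiguous
#' assignment with largest-remainder rounding of the ratios (default 8:1:1).
#'
#' @param windows labeled windows from [label_windows()].
#' @param ratios positive weights for train/val/test.
#' @param seed integer seed; the split is deterministic given it.
#' @param genome_tag free-text provenance tag recorded in the manifest.
#' @return a `dataset_manifest`: list with `windows` (split column filled),
#'   `seed`, `genome_tag` and a `counts` table.
#' @export
split_dataset <- function(windows, ratios = c(8, 1, 1), seed = 1L,
                          genome_tag = "unspecified") {
  if (any(ratios <= 0) || length(ratios) != 3L)
    stop("ratios must be three positive numbers")
  n <- nrow(windows)
  if (n < 10L) stop("need at least 10 windows to split")
  exact <- n * ratios / sum(ratios)
  sizes <- floor(exact)
  rem <- exact - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    sizes[bump] <- sizes[bump] + 1L
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  perm <- sample.int(n)
  split <- rep(c("train", "val", "test"), times = sizes)
  windows$split[perm] <- split
  manifest <- list(windows = windows, seed = seed, genome_tag = genome_tag)
  class(manifest) <- "dataset_manifest"
  manifest$counts <- manifest_counts(manifest)
  manifest
}

#' Tabulate a manifest's windows by label/type/split
#' @param manifest a `dataset_manifest`.
#' @return a table of counts.
#' @export
manifest_counts <- function(manifest) {
  with(manifest$windows, table(negative_type, split))
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat("dataset_manifest:", nrow(x$windows), "windows, seed", x$seed, "\n")
  print(manifest_counts(x))
  invisible(x)
}

#' Balance training negatives to the positive count
#'
#' Downsamples the training-split negatives uniformly without replacement
#' to the number of training positives, stratified proportionally across
#' negative types (largest-remainder allocation). Validation and test
#' splits are untouched. If negatives are already at or below the positive
#' count the manifest is returned as-is (with a warning record when below).
#'
#' @param manifest a `dataset_manifest`.
#' @param seed integer seed for the downsampling.
#' @return the balanced `dataset_manifest`.
#' @export
balance_training_negatives <- function(manifest, seed = 1L) {
  w <- manifest$windows
  tr <- which(w$split == "train")
  npos <- sum(w$label[tr] == "positive")
  if (npos < 1L) stop("training split has no positives")
  neg_idx <- tr[w$label[tr] == "negative"]
  nneg <- length(neg_idx)
  if (nneg < npos) {
    manifest$warnings <- c(manifest$warnings,
      sprintf("training negatives (%d) fewer than positives (%d); left as-is",
              nneg, npos))
    return(manifest)
  }
  if (nneg == npos) return(manifest)
  types <- w$negative_type[neg_idx]
  tab <- table(types)
  exact <- npos * as.numeric(tab) / nneg
  take <- floor(exact)
  rem <- exact - take
  short <- npos - sum(take)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    take[bump] <- pmin(take[bump] + 1L, as.numeric(tab)[bump])
  }
  # top up if rounding against a saturated type left us short
  while (sum(take) < npos) {
    room <- which(take < as.numeric(tab))
    take[room[1]] <- take[room[1]] + 1L
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  keep <- integer(0)
  for (i in seq_along(tab)) {
    pool <- neg_idx[types == names(tab)[i]]
    keep <- c(keep, if (length(pool) == 1L && take[i] == 1L) pool
              else sample(pool, take[i]))
  }
  drop <- setdiff(neg_idx, keep)
  manifest$windows <- w[-drop, , drop = FALSE]
  rownames(manifest$windows) <- NULL
  manifest$counts <- manifest_counts(manifest)
  manifest
}

#' Leave-one-chromosome-out folds
#'
#' One fold per chromosome present in the manifest: the fold's held-out
#' windows are exactly those on that chromosome, the rest train.
#'
#' @param manifest a `dataset_manifest` spanning >= 2 chromosomes.
#' @return list of folds, each `list(held_out_chrom, train_chroms)`.
#' @export
make_loco_splits <- function(manifest) {
  chroms <- sort(unique(manifest$windows$chrom))
  if (length(chroms) < 2L) stop("LOCO requires windows on >= 2 chromosomes")
  lapply(chroms, function(ch)
    list(held_out_chrom = ch, train_chroms = setdiff(chroms, ch)))
}

#' Write a manifest to disk
#'
#' Emits a TSV of windows plus a JSON sidecar with counts and the seed.
#'
#' @param manifest a `dataset_manifest`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_manifest <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(manifest$windows, file.path(dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cnt <- as.data.frame(manifest$counts)
  jsonlite::write_json(
    list(seed = manifest$seed, genome_tag = manifest$genome_tag,
         n_windows = nrow(manifest$windows), counts = cnt),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a manifest written by [write_manifest()]
#' @param dir directory containing `manifest.tsv` and `manifest.json`.
#' @return a `dataset_manifest`.
#' @export
read_manifest <- function(dir) {
  w <- read.table(file.path(dir, "manifest.tsv"), sep = "\t", header = TRUE,
                  stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"))
  manifest <- list(windows = w, seed = meta$seed, genome_tag = meta$genome_tag)
  class(manifest) <- "dataset_manifest"
  manifest$counts <- manifest_counts(manifest)
  manifest
}

#' Build a labeled dataset from peak files end-to-end
#'
#' Convenience wrapper: normalize all peaks to `window_length`, scan the
#' normalized ATAC windows for the motif, label, split and balance.
#'
#' @param genome a `genome` object.
#' @param ctcf_peaks,chia_pet_peaks,atac_peaks raw peak intervals.
#' @param pwm motif used to type ATAC negatives.
#' @param p_threshold motif scan p-value cutoff (default 5e-5).
#' @param window_length normalized window length (default 2000).
#' @param seed split/balance seed.
#' @param cell_line tag recorded on windows.
#' @return a balanced `dataset_manifest`.
#' @export
build_dataset <- function(genome, ctcf_peaks, chia_pet_peaks, atac_peaks,
                          pwm, p_threshold = 5e-5, window_length = 2000L,
                          seed = 1L, cell_line = "synthetic") {
  ctcf_w <- normalize_windows(ctcf_peaks, genome, window_length)
  atac_w <- normalize_windows(atac_peaks, genome, window_length)
  hits <- scan_motifs(genome, pwm, p_threshold)
  labeled <- label_windows(ctcf_w, chia_pet_peaks, atac_w, hits,
                           cell_line = cell_line)
  manifest <- split_dataset(labeled, seed = seed, genome_tag = cell_line)
  balance_training_negatives(manifest, seed = seed + 1L)
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
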