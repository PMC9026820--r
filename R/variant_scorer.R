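# Variant impact quantification: wild-type and mutant windows centered at
# the variant are scored with the conjoined model; the delta score is
# p_wt - p_mut, so predicted insulator LOSS is positive.

#' Read single-nucleotide variants from a minimal VCF or TSV
#'
#' Accepts a VCF-style table (CHROM POS ID REF ALT, 1-based positions;
#' `#`-prefixed lines ignored) or a 4/5-column TSV (chrom pos ref alt
#' \[id\]). Only SNVs are kept: indels are skipped and counted;
#' multi-allelic ALT fields are split into per-alt SNVs. Records whose REF
#' disagrees with the genome are rejected with a per-record report.
#'
#' @param path file path.
#' @param genome a `genome` object used to check REF.
#' @return data.frame of class `variant_calls` (chrom, pos \[1-based\],
#'   ref, alt, id) with attributes `n_indel_skipped` and `rejected`.
#' @export
read_variants <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  n_indel <- 0L
  recs <- list()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "[\t ]+")[[1]]
    if (length(f) < 4L)
      stop("variant line ", k, ": fewer than 4 fields")
    vcf_like <- length(f) >= 5L && !grepl("^[0-9]+$", f[3]) &&
      grepl("^[ACGTN,]+$", f[5])
    if (vcf_like) {
      chrom <- f[1]; pos <- f[2]; id <- f[3]; ref <- f[4]; alts <- f[5]
    } else {
      chrom <- f[1]; pos <- f[2]; ref <- f[3]; alts <- f[4]
      id <- if (length(f) >= 5L) f[5] else "."
    }
    pos <- suppressWarnings(as.integer(pos))
    if (is.na(pos)) stop("variant line ", k, ": non-integer position")
    for (alt in strsplit(alts, ",", fixed = TRUE)[[1]]) {
      if (nchar(ref) != 1L || nchar(alt) != 1L) {
        n_indel <- n_indel + 1L
        next
      }
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = chrom, pos = pos, ref = toupper(ref), alt = toupper(alt),
        id = id, stringsAsFactors = FALSE)
    }
  }
  df <- if (length(recs)) do.call(rbind, recs) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), id = character())
  rejected <- character(0)
  if (nrow(df)) {
    genome_base <- vapply(seq_len(nrow(df)), function(i) {
      s <- genome[[df$chrom[i]]]
      if (is.null(s) || df$pos[i] < 1L || df$pos[i] > nchar(s)) return(NA_character_)
      substr(s, df$pos[i], df$pos[i])
    }, "")
    ok <- !is.na(genome_base) & genome_base == df$ref
    rejected <- sprintf("%s:%d ref=%s genome=%s", df$chrom[!ok], df$pos[!ok],
                        df$ref[!ok], genome_base[!ok])
    df <- df[ok, , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("variant_calls", "data.frame")
  attr(df, "n_indel_skipped") <- n_indel
  attr(df, "rejected") <- rejected
  df
}

#' Build wild-type and mutant windows centered at a variant
#'
#' The window is `[pos0 - length/2, pos0 + length/2)` with `pos0` the
#' 0-based variant position, so the variant sits at offset `length/2`;
#' the mutant differs from the wild type at exactly that offset.
#'
#' @param variant one row of a `variant_calls` data frame.
#' @param genome a `genome` object.
#' @param length even window length (default 2000).
#' @return list `(wt_seq, mut_seq, interval)`, or `NULL` when the centered
#'   window does not fit in the chromosome.
#' @export
build_alleles <- function(variant, genome, length = 2000L) {
  if (length %% 2L != 0L) stop("window length must be even")
  pos0 <- variant$pos[1] - 1L
  half <- length %/% 2L
  s <- pos0 - half; e <- pos0 + half
  chrom <- variant$chrom[1]
  chrom_len <- nchar(genome[[chrom]])
  if (s < 0L || e > chrom_len) return(NULL)
  iv <- genomic_intervals(chrom, s, e, name = variant$id[1])
  wt <- extract_sequence(genome, iv)
  center <- half + 1L                      # 1-based offset of the variant
  stopifnot(substr(wt, center, center) == variant$ref[1])
  mut <- wt
  substr(mut, center, center) <- variant$alt[1]
  list(wt_seq = wt, mut_seq = mut, interval = iv)
}

#' Delta score of one variant
#'
#' `delta = p_wt - p_mut` with both windows scored by [predict_anchor()]
#' (strand-averaged in the conjoined modes). Positive delta means the
#' mutant is predicted to lose anchor activity (insulator disruption).
#'
#' @param model an `anchor_model` (typically `posthoc_conjoined`).
#' @param variant one row of a `variant_calls` data frame.
#' @param genome a `genome` object.
#' @return data.frame row with p_wt, p_mut, delta; `NULL` if the window
#'   does not fit.
#' @export
delta_score <- function(model, variant, genome) {
  al <- build_alleles(variant, genome, length = model$config$input_length)
  if (is.null(al)) return(NULL)
  p <- predict_anchor(model, c(al$wt_seq, al$mut_seq))$value
  data.frame(id = variant$id[1], chrom = variant$chrom[1],
             pos = variant$pos[1], ref = variant$ref[1], alt = variant$alt[1],
             p_wt = p[1], p_mut = p[2], delta = p[1] - p[2],
             stringsAsFactors = FALSE)
}

#' Score a table of variants
#'
#' When `peaks` is supplied, variants whose position falls outside every
#' peak are filtered out first (the accessible-region restriction); the
#' position is "in" a peak when it lies within `[start, end)`. Output rows
#' are sorted by `|delta|` descending.
#'
#' @param model an `anchor_model`.
#' @param variants a `variant_calls` data frame.
#' @param genome a `genome` object.
#' @param peaks optional `genomic_intervals` restricting the variants.
#' @return data.frame: id, chrom, pos, ref, alt, p_wt, p_mut, delta,
#'   in_peak; attribute `n_window_skipped` counts out-of-bounds windows.
#' @export
score_variant_table <- function(model, variants, genome, peaks = NULL) {
  in_peak <- rep(TRUE, nrow(variants))
  if (!is.null(peaks) && nrow(variants)) {
    vi <- genomic_intervals(variants$chrom, variants$pos - 1L, variants$pos)
    in_peak <- intersect_any(vi, peaks)
    variants <- variants[in_peak, , drop = FALSE]
  }
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(variants))) {
    r <- delta_score(model, variants[i, , drop = FALSE], genome)
    if (is.null(r)) skipped <- skipped + 1L else rows[[length(rows) + 1L]] <- r
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), p_wt = numeric(),
               p_mut = numeric(), delta = numeric())
  out$in_peak <- TRUE
  out <- out[order(-abs(out$delta)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_window_skipped") <- skipped
  out
}
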