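# JASPAR motif parsing and exact-p-value scanning.
#
# Internally PWM count/log-odds matrices are w x 4 with columns in A,C,G,T
# order (JASPAR row order). Log-odds are in bits (log2) against a 0-order
# background. P-values come from the exact score distribution, obtained by
# convolving per-position score distributions on a discretized lattice.

.PWM_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix object
#'
#' @param counts w x 4 non-negative matrix, columns A,C,G,T.
#' @param id,name identifiers (e.g. a JASPAR accession and TF name).
#' @param pseudocount additive smoothing applied to counts before
#'   normalization (default 0.1; avoids -Inf log-odds).
#' @param background base probabilities (A,C,G,T), summing to 1; default
#'   uniform 0.25.
#' @return a list of class `pwm` with fields `counts`, `probs`, `log_odds`
#'   (bits), `width`, `pseudocount`, `background`, `id`, `name`.
#' @export
pwm <- function(counts, id = "motif", name = id, pseudocount = 0.1,
                background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L) stop("PWM counts must have 4 columns (A,C,G,T)")
  if (any(counts < 0)) stop("negative PWM counts")
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  colnames(counts) <- .PWM_BASES
  sm <- counts + pseudocount
  probs <- sm / rowSums(sm)
  log_odds <- log2(sweep(probs, 2, background, "/"))
  structure(list(counts = counts, probs = probs, log_odds = log_odds,
                 width = nrow(counts), pseudocount = pseudocount,
                 background = background, id = id, name = name),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$id, paste0("(", x$name, ")"), "width", x$width, "\n")
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (per-position most probable base)
#' @param pwm a `pwm` object.
#' @return DNA string of length `pwm$width`.
#' @export
pwm_consensus <- function(pwm) {
  paste(.PWM_BASES[max.col(pwm$probs, ties.method = "first")], collapse = "")
}

#' Parse a JASPAR-format PFM text file
#'
#' Accepts the JASPAR 2016+ format: a `>ID NAME` header followed by four
#' rows labelled A, C, G, T with bracketed counts, e.g.
#' `A [ 87 167 281 ... ]`.
#'
#' @param path file path.
#' @param pseudocount,background passed to [pwm()].
#' @return a `pwm` object.
#' @export
parse_jaspar <- function(path, pseudocount = 0.1, background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || !startsWith(lines[1], ">"))
    stop("JASPAR format error: missing '>' header line")
  hdr <- strsplit(sub("^>", "", lines[1]), "\\s+")[[1]]
  id <- hdr[1]; name <- if (length(hdr) > 1) hdr[2] else hdr[1]
  rows <- lines[-1]
  base_of <- toupper(substr(rows, 1, 1))
  if (!setequal(base_of, .PWM_BASES) || length(rows) != 4L)
    stop("JASPAR format error: expected exactly one row per base A,C,G,T")
  vals <- lapply(rows, function(r) {
    body <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", r)
    v <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
    if (anyNA(v)) stop("JASPAR format error: non-numeric count in row: ", r)
    v
  })
  names(vals) <- base_of
  w <- unique(lengths(vals))
  if (length(w) != 1L)
    stop("JASPAR format error: base rows have unequal lengths")
  counts <- cbind(A = vals$A, C = vals$C, G = vals$G, T = vals$T)
  pwm(counts, id = id, name = name, pseudocount = pseudocount,
      background = background)
}

#' Score one k-mer against a PWM
#'
#' Sum over positions of the log-odds (bits) of the observed base.
#'
#' @param pwm a `pwm` object.
#' @param kmer DNA string of length `pwm$width`, no N.
#' @return numeric log-odds score.
#' @export
score_sequence_window <- function(pwm, kmer) {
  if (nchar(kmer) != pwm$width)
    stop("k-mer length ", nchar(kmer), " != PWM width ", pwm$width)
  idx <- match(strsplit(kmer, "", fixed = TRUE)[[1]], .PWM_BASES)
  if (anyNA(idx)) stop("k-mer contains a non-ACGT character")
  sum(pwm$log_odds[cbind(seq_len(pwm$width), idx)])
}

# Exact distribution of the PWM score of a random background k-mer on an
# integer lattice (score ~= lattice_index * granularity). Returns the
# integerized log-odds matrix, the support offset and the probability
# vector; cached on the pwm object's environment would be overkill, cheap
# enough to recompute.
pwm_score_distribution <- function(pwm, granularity = 1e-3) {
  S <- round(pwm$log_odds / granularity)     # w x 4 integer lattice scores
  # position-wise convolution
  cur <- 1; cur_lo <- 0                        # P(score==0)=1 before any pos
  for (i in seq_len(pwm$width)) {
    new_lo <- cur_lo + min(S[i, ])
    new_hi <- cur_lo + length(cur) - 1L + max(S[i, ])
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      off <- cur_lo + S[i, b] - new_lo
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + cur * pwm$background[b]
    }
    cur <- new; cur_lo <- new_lo
  }
  list(lattice = S, granularity = granularity, offset = cur_lo, prob = cur,
       scores = (cur_lo + seq_along(cur) - 1L) * granularity)
}

#' Exact p-value of a PWM score threshold
#'
#' P(score of a random background k-mer >= threshold), computed by dynamic
#' programming over a discretized score lattice (position-wise convolution
#' of the per-column score distributions).
#'
#' @param pwm a `pwm` object.
#' @param score_threshold numeric threshold (bits).
#' @param granularity lattice step in bits (default 1/1000 bit).
#' @return p-value in \[0, 1\].
#' @export
exact_score_pvalue <- function(pwm, score_threshold, granularity = 1e-3) {
  if (!is.finite(score_threshold)) stop("score threshold must be finite")
  d <- pwm_score_distribution(pwm, granularity)
  sum(d$prob[d$scores >= score_threshold - 1e-9])
}

#' Score threshold achieving a target p-value
#'
#' The smallest lattice score `s` with `exact_score_pvalue(pwm, s) <= p`.
#' For `p = 1` this is the minimal achievable score.
#'
#' @param pwm a `pwm` object.
#' @param p target p-value in (0, 1\].
#' @param granularity lattice step in bits.
#' @return numeric score threshold.
#' @export
pvalue_to_score_threshold <- function(pwm, p, granularity = 1e-3) {
  if (!is.numeric(p) || p <= 0 || p > 1) stop("p must be in (0, 1]")
  d <- pwm_score_distribution(pwm, granularity)
  tail <- rev(cumsum(rev(d$prob)))            # tail[i] = P(score >= scores[i])
  ok <- which(tail <= p + 1e-12)
  if (length(ok) == 0L) return(max(d$scores) + d$granularity)
  d$scores[ok[1]]
}

# Vectorized per-window scores of one strand of a sequence; NA where the
# window contains an N. Returns numeric(0) for sequences shorter than w.
.scan_scores <- function(seq, pwm) {
  w <- pwm$width
  n <- nchar(seq)
  if (n < w) return(numeric(0))
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]], .PWM_BASES)  # N -> NA
  nw <- n - w + 1L
  sc <- numeric(nw)
  for (i in seq_len(w)) {
    sc <- sc + pwm$log_odds[i, ][code[i:(i + nw - 1L)]]
  }
  sc
}

#' Scan a sequence or genome for motif hits
#'
#' Slides width-w windows over both strands and reports windows whose exact
#' score p-value is at or below `p_threshold`. Hit intervals are reported in
#' forward-strand coordinates with a strand flag; windows containing N are
#' skipped. Overlapping hits are all reported.
#'
#' @param x a `genome` object or a single DNA string.
#' @param pwm a `pwm` object.
#' @param p_threshold p-value cutoff (default 5e-5, the scan threshold used
#'   for typing negatives).
#' @param granularity p-value lattice step in bits.
#' @param chrom chromosome name used when `x` is a bare string.
#' @return a `genomic_intervals` data frame with `score` = -log10(p-value)
#'   and an extra `logodds` column; strand is `+` or `-`.
#' @export
scan_motifs <- function(x, pwm, p_threshold = 5e-5, granularity = 1e-3,
                        chrom = "seq") {
  if (p_threshold <= 0 || p_threshold > 1) stop("p_threshold must be in (0, 1]")
  d <- pwm_score_distribution(pwm, granularity)
  tail <- rev(cumsum(rev(d$prob)))
  pval_of <- function(sc) {                    # map scores to exact tail p
    idx <- pmin(pmax(round(sc / d$granularity) - d$offset + 1L, 1L),
                length(tail))
    ifelse(round(sc / d$granularity) > d$offset + length(tail) - 1L, 0, tail[idx])
  }
  thr <- pvalue_to_score_threshold(pwm, p_threshold, granularity)
  seqs <- if (inherits(x, "genome")) x else setNames(list(x), chrom)
  out <- list()
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    n <- nchar(s)
    w <- pwm$width
    fwd <- .scan_scores(s, pwm)
    if (length(fwd)) {
      hit <- which(!is.na(fwd) & fwd >= thr - 1e-9)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          chrom = nm, start = hit - 1L, end = hit - 1L + w, strand = "+",
          logodds = fwd[hit], stringsAsFactors = FALSE)
    }
    rev_scores <- .scan_scores(reverse_complement(s), pwm)
    if (length(rev_scores)) {
      hit <- which(!is.na(rev_scores) & rev_scores >= thr - 1e-9)
      if (length(hit)) {
        # window starting at i (1-based) on the RC maps to forward
        # coordinates [n - i + 1 - w, n - i + 1)
        st <- n - hit + 1L - w
        out[[length(out) + 1L]] <- data.frame(
          chrom = nm, start = st, end = st + w, strand = "-",
          logodds = rev_scores[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    res <- genomic_intervals(character(), integer(), integer())
    res$logodds <- numeric(0)
    res$pvalue <- numeric(0)
    return(res)
  }
  df <- do.call(rbind, out)
  pv <- pval_of(df$logodds)
  res <- genomic_intervals(df$chrom, df$start, df$end,
                           name = pwm$id, score = -log10(pmax(pv, 1e-300)),
                           strand = df$strand)
  res$logodds <- df$logodds
  res$pvalue <- pv
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
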