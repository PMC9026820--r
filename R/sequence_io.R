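#' @importFrom stats approx median quantile rbinom runif sd setNames wilcox.test
#' @importFrom utils read.table write.table head tail
NULL

# Internal coordinate convention: 0-based half-open [start, end) everywhere
# (BED). VCF positions are converted on ingest in read_variants().

#' Construct a genomic interval table
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`
#' (0-based half-open), `name`, `score`, `strand`. This is the common
#' currency for peaks, anchors, windows and motif hits across the package.
#'
#' @param chrom character vector of chromosome identifiers.
#' @param start,end integer vectors, 0-based half-open; `start < end`.
#' @param name optional names (default `"."`).
#' @param score optional numeric scores (default `NA`).
#' @param strand one of `"+"`, `"-"`, `"."` per interval (default `"."`).
#' @return a data.frame of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, name = ".", score = NA_real_,
                              strand = ".") {
  n <- length(chrom)
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-integer interval coordinates")
  if (any(start < 0L)) stop("negative interval start")
  if (any(start >= end)) stop("empty or inverted interval (start >= end)")
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Width of intervals
#' @param x a `genomic_intervals` data frame.
#' @return integer vector of widths `end - start`.
#' @export
interval_width <- function(x) x$end - x$start

#' Read a multi-record FASTA file
#'
#' Sequences are uppercased on load (soft-masking is ignored). Duplicate
#' headers and non-IUPAC DNA characters are rejected.
#'
#' @param path FASTA file path.
#' @return a named list of class `genome`: uppercase DNA strings keyed by
#'   chromosome, record order preserved, with a `lengths` attribute.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">"))
    stop("malformed FASTA header at line 1 of ", path)
  dss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nm))
    stop("duplicate FASTA header: ", nm[duplicated(nm)][1])
  seqs <- toupper(as.character(dss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    # locate the offending line for the error message
    lines <- readLines(path)
    hit <- grep("[^ACGTNacgtn]", lines[!startsWith(lines, ">")])
    stop("non-ACGTN character in FASTA record ", nm[bad][1],
         if (length(hit)) paste0(" (sequence line ", hit[1], ")") else "")
  }
  names(seqs) <- nm
  structure(as.list(seqs), lengths = setNames(nchar(seqs), nm),
            class = "genome")
}

#' Write a genome to FASTA
#' @param genome a `genome` object.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Chromosome lengths of a genome
#' @param genome a `genome` object.
#' @return named integer vector.
#' @export
genome_lengths <- function(genome) {
  attr(genome, "lengths")
}

#' Read a BED3+ file
#'
#' Coordinates are kept verbatim (0-based half-open). Optional columns 4-6
#' map to name/score/strand; a missing strand becomes `"."`.
#'
#' @param path BED file path.
#' @return a `genomic_intervals` data frame.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(genomic_intervals(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED line ", which(nf < 3L)[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("BED line ", which(is.na(start) | is.na(end))[1],
         ": non-integer coordinate")
  bad <- start >= end
  if (any(bad))
    stop("BED line ", which(bad)[1], ": start >= end (empty interval)")
  grab <- function(i, default) {
    ifelse(nf >= i, vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, ""), default)
  }
  name <- grab(4L, ".")
  score <- suppressWarnings(as.numeric(grab(5L, NA)))
  strand <- grab(6L, ".")
  strand[!strand %in% c("+", "-")] <- "."
  genomic_intervals(chrom, start, end, name, score, strand)
}

#' Write intervals as BED
#'
#' Round-trips with [read_bed()] on chrom/start/end/name/score/strand.
#' Scores are formatted with `format(..., scientific = FALSE)` (no locale
#' separators); `NA` scores are written as 0.
#'
#' @param intervals a `genomic_intervals` data frame.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  sc <- ifelse(is.na(intervals$score), "0",
               format(intervals$score, scientific = FALSE, trim = TRUE,
                      digits = 15))
  out <- paste(intervals$chrom, intervals$start, intervals$end,
               intervals$name, sc, intervals$strand, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Extract the DNA of an interval
#'
#' Returns the genome substring over `[start, end)`; minus-strand intervals
#' are reverse-complemented, matching how strand-aware tools interpret BED
#' column 6.
#'
#' @param genome a `genome` object.
#' @param interval a single-row `genomic_intervals` data frame (or a row
#'   index into a larger one via `i`).
#' @param i row to extract when `interval` has several.
#' @return DNA string.
#' @export
extract_sequence <- function(genome, interval, i = 1L) {
  chrom <- interval$chrom[i]
  if (is.null(genome[[chrom]])) stop("unknown chromosome: ", chrom)
  len <- nchar(genome[[chrom]])
  s <- interval$start[i]; e <- interval$end[i]
  if (s < 0L || e > len)
    stop("interval ", chrom, ":[", s, ",", e, ") out of bounds (chrom length ",
         len, ")")
  seq <- substr(genome[[chrom]], s + 1L, e)
  if (identical(interval$strand[i], "-")) seq <- reverse_complement(seq)
  seq
}

#' Extract DNA for every row of an interval table
#' @inheritParams extract_sequence
#' @return character vector of sequences.
#' @export
extract_sequences <- function(genome, interval) {
  vapply(seq_len(nrow(interval)), function(i) extract_sequence(genome, interval, i), "")
}

#' Reverse complement of a DNA string
#'
#' Involution over the alphabet \{A,C,G,T,N\}; N maps to N.
#'
#' @param seq DNA string.
#' @return reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  if (grepl("[^ACGTN]", seq)) stop("invalid character in DNA sequence")
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

.BASE_COLS <- c(A = 1L, T = 2L, C = 3L, G = 4L)  # fixed one-hot column order

#' One-hot encode a DNA string
#'
#' Returns an L x 4 0/1 matrix with column order A, T, C, G. Ambiguous N
#' bases encode as all-zero rows, so column sums equal base counts and row
#' sums are 1 (unambiguous) or 0 (N).
#'
#' @param seq DNA string over \{A,C,G,T,N\}.
#' @return L x 4 matrix with colnames A,T,C,G.
#' @export
onehot_encode <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- !chars %in% c("A", "C", "G", "T", "N")
  if (any(bad)) stop("invalid character in DNA sequence: ", chars[bad][1])
  L <- length(chars)
  m <- matrix(0, nrow = L, ncol = 4L, dimnames = list(NULL, names(.BASE_COLS)))
  idx <- .BASE_COLS[chars]            # NA for N
  keep <- !is.na(idx)
  m[cbind(which(keep), idx[keep])] <- 1
  m
}

#' Decode a one-hot matrix back to a DNA string
#' @param x L x 4 one-hot matrix (column order A,T,C,G).
#' @return DNA string; all-zero rows decode to N.
#' @export
onehot_decode <- function(x) {
  bases <- names(.BASE_COLS)[max.col(x, ties.method = "first")]
  bases[rowSums(x) == 0] <- "N"
  paste(bases, collapse = "")
}

#' Reverse complement in one-hot space
#'
#' Equals `onehot_encode(reverse_complement(decode(x)))`, implemented as a
#' row-order reversal plus the column swap A<->T, C<->G. All-zero (N) rows
#' stay all-zero.
#'
#' @param x L x 4 one-hot matrix.
#' @return the reverse-complemented one-hot matrix.
#' @export
onehot_reverse_complement <- function(x) {
  out <- x[rev(seq_len(nrow(x))), c(2L, 1L, 4L, 3L), drop = FALSE]
  colnames(out) <- names(.BASE_COLS)
  out
}
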