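# Synthetic planted-motif benchmark generator.
#
# Emulates the four sample classes the classifier is trained on, in a
# small random genome, with no external downloads:
#   positive - primary (CTCF-like) motif near the window center plus a
#              co-motif grammar (each co-motif planted with probability
#              co_motif_prob at a random offset),
#   type1    - primary motif planted, no co-motifs (off-anchor CTCF site),
#   type2    - primary motif alone in accessible background (type1 and
#              type2 differ only in which source peak file carries them),
#   type3    - untouched background (re-drawn until it carries no chance
#              primary-motif hit, so labels reconstruct exactly).
# All randomness flows from the single spec seed.

#' Built-in CTCF-like primary motif (synthetic)
#'
#' A 19-wide high-information PFM shipped as a JASPAR-format text fixture.
#' It is a synthetic stand-in shaped like the canonical CTCF motif, not
#' the JASPAR MA0139.1 matrix itself.
#'
#' @param pseudocount,background passed to [parse_jaspar()].
#' @return a `pwm`.
#' @export
ctcf_like_pwm <- function(pseudocount = 0.1, background = rep(0.25, 4)) {
  parse_jaspar(system.file("extdata", "ctcf_like_synthetic.jaspar",
                           package = "insuscan", mustWork = TRUE),
               pseudocount = pseudocount, background = background)
}

.co_motif_counts <- function(consensus, dominant = 88, other = 4) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  counts <- matrix(other, length(chars), 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[cbind(seq_along(chars), match(chars, c("A", "C", "G", "T")))] <- dominant
  counts
}

#' Built-in synthetic co-motifs
#'
#' Two moderate-information 10-bp secondary motifs forming the positive
#' class's grammar alongside the primary motif.
#'
#' @return list of two `pwm`s.
#' @export
builtin_co_motifs <- function() {
  list(pwm(.co_motif_counts("ACGGAAGTCA"), id = "SYNCO1", name = "cofactor_a"),
       pwm(.co_motif_counts("TTGACCTTGG"), id = "SYNCO2", name = "cofactor_b"))
}

#' Fixture specification
#'
#' Defaults are the desk-scale profile: 3 chromosomes of 350 kb, 400 bp
#' windows, 500 windows per class (~2000 total), primary motif planted
#' near the window center with +/- 50 bp jitter, and co-motifs planted in
#' positives only (probability 0.8 each). The full 2000 bp profile is
#' `fixture_spec(window_length = 2000, chrom_length = ...)`.
#'
#' @param seed single seed for every source of randomness.
#' @param n_chroms,chrom_length genome shape.
#' @param gc_content background GC fraction (default 0.41, human-like).
#' @param window_length window width in bp.
#' @param n_positive,n_type1,n_type2,n_type3 windows per class.
#' @param co_motif_prob per-co-motif planting probability in positives.
#' @param motif_placement_jitter max |offset| of the primary motif from
#'   the window center, in bp.
#' @param neutral_buffer min distance (bp) of a neutral variant from every
#'   planted motif in its window.
#' @param p_threshold scan p-value used for planting checks.
#' @param primary_motif,co_motifs `pwm`s (defaults: built-ins).
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_chroms = 3L, chrom_length = 350000L,
                         gc_content = 0.41, window_length = 400L,
                         n_positive = 500L, n_type1 = 500L, n_type2 = 500L,
                         n_type3 = 500L, co_motif_prob = 0.8,
                         motif_placement_jitter = 50L, neutral_buffer = 50L,
                         p_threshold = 5e-5,
                         primary_motif = NULL, co_motifs = NULL) {
  if (is.null(primary_motif)) primary_motif <- ctcf_like_pwm()
  if (is.null(co_motifs)) co_motifs <- builtin_co_motifs()
  if (any(c(n_positive, n_type1, n_type2, n_type3) < 0)) stop("negative counts")
  spec <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
               chrom_length = as.integer(chrom_length),
               gc_content = gc_content, window_length = as.integer(window_length),
               n_positive = as.integer(n_positive), n_type1 = as.integer(n_type1),
               n_type2 = as.integer(n_type2), n_type3 = as.integer(n_type3),
               co_motif_prob = co_motif_prob,
               motif_placement_jitter = as.integer(motif_placement_jitter),
               neutral_buffer = as.integer(neutral_buffer),
               p_threshold = p_threshold,
               primary_motif = primary_motif, co_motifs = co_motifs)
  class(spec) <- "fixture_spec"
  spec
}

#' Generate an i.i.d. background genome
#'
#' Bases drawn independently at the specified GC content; deterministic
#' under the spec seed.
#'
#' @param spec a `fixture_spec`.
#' @return a `genome` with chromosomes `chr1..chrN`.
#' @export
make_background_genome <- function(spec) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  p <- c(A = (1 - spec$gc_content) / 2, C = spec$gc_content / 2,
         G = spec$gc_content / 2, T = (1 - spec$gc_content) / 2)
  seqs <- vapply(seq_len(spec$n_chroms), function(i)
    paste(sample(names(p), spec$chrom_length, replace = TRUE, prob = p),
          collapse = ""), "")
  names(seqs) <- paste0("chr", seq_len(spec$n_chroms))
  structure(as.list(seqs), lengths = setNames(nchar(seqs), names(seqs)),
            class = "genome")
}

.sample_pwm_instance <- function(pwm) {
  paste(vapply(seq_len(pwm$width), function(i)
    sample(c("A", "C", "G", "T"), 1L, prob = pwm$probs[i, ]), ""),
    collapse = "")
}

.random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.splice <- function(s, start0, repl) {
  # replace bases [start0, start0 + nchar(repl)) (0-based) of string s
  substr(s, start0 + 1L, start0 + nchar(repl)) <- repl
  s
}

# does sequence region contain a primary-motif hit at the spec threshold?
.has_primary_hit <- function(seq, spec, thr) {
  f <- .scan_scores(seq, spec$primary_motif)
  r <- .scan_scores(reverse_complement(seq), spec$primary_motif)
  any(c(f, r) >= thr - 1e-9, na.rm = TRUE)
}

#' Plant motifs and define windows, peaks and ground truth
#'
#' Lays the requested class counts out as disjoint windows (shuffled
#' across chromosomes), plants motif instances sampled from the PWMs
#' (primary motif on a random strand near the window center), and derives
#' the source peak files: variable-width CTCF peaks (positives + type1),
#' ChIA-PET peaks inside positives only, and ATAC peaks (type2 + type3).
#' Every peak is centered on its window so normalization reconstructs the
#' window exactly.
#'
#' @param genome background genome from [make_background_genome()].
#' @param spec a `fixture_spec`.
#' @return list: `genome` (mutated), `windows` (labeled, split `NA`),
#'   `truth` (one row per planted motif, plus window class rows), `peaks`
#'   (list of ctcf/chiapet/atac `genomic_intervals`).
#' @export
plant_windows <- function(genome, spec) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed + 1L)
  W <- spec$window_length
  classes <- rep(c("positive", "type1", "type2", "type3"),
                 c(spec$n_positive, spec$n_type1, spec$n_type2, spec$n_type3))
  n <- length(classes)
  classes <- classes[sample.int(n)]
  per_chrom <- rep(n %/% spec$n_chroms, spec$n_chroms)
  extra <- n - sum(per_chrom)
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  starts <- integer(0); chroms <- character(0)
  for (ci in seq_len(spec$n_chroms)) {
    m <- per_chrom[ci]
    if (m == 0L) next
    slack <- spec$chrom_length - m * W
    if (slack < m) stop("layout error: windows do not fit disjointly; ",
                        "increase chrom_length or reduce counts")
    offs <- sort(sample.int(slack + 1L, m) - 1L)
    starts <- c(starts, offs + (seq_len(m) - 1L) * W)
    chroms <- c(chroms, rep(paste0("chr", ci), m))
  }
  pm <- spec$primary_motif
  w <- pm$width
  thr <- pvalue_to_score_threshold(pm, spec$p_threshold)
  center_off <- W %/% 2L - w %/% 2L
  jit <- spec$motif_placement_jitter
  truth <- list()
  for (i in seq_len(n)) {
    cl <- classes[i]
    ch <- chroms[i]; ws <- starts[i]
    if (cl == "type3") {
      # re-draw until the window carries no chance primary hit (check an
      # extended region so boundary-straddling hits are caught too)
      for (try in 1:50) {
        ext_s <- max(0L, ws - w + 1L)
        ext_e <- min(nchar(genome[[ch]]), ws + W + w - 1L)
        region <- substr(genome[[ch]], ext_s + 1L, ext_e)
        if (!.has_primary_hit(region, spec, thr)) break
        genome[[ch]] <- .splice(genome[[ch]], ws, .random_dna(W, spec$gc_content))
      }
      next
    }
    # primary motif instance, random strand, near the window center; the
    # planted instance must be detectable at the scan threshold (same
    # redraw policy for every class that carries the motif, so classes
    # differ only in their co-motif content)
    strand <- sample(c("+", "-"), 1L)
    moff <- center_off + sample((-jit):jit, 1L)
    for (try in 1:20) {
      inst <- .sample_pwm_instance(pm)
      planted <- if (strand == "-") reverse_complement(inst) else inst
      genome[[ch]] <- .splice(genome[[ch]], ws + moff, planted)
      win <- substr(genome[[ch]], ws + 1L, ws + W)
      if (.has_primary_hit(win, spec, thr)) break
    }
    occupied <- list(c(moff, moff + w))
    truth[[length(truth) + 1L]] <- data.frame(
      window_id = i, chrom = ch, window_start = ws, window_end = ws + W,
      class = cl, motif_id = pm$id, motif_start = ws + moff,
      motif_end = ws + moff + w, strand = strand, stringsAsFactors = FALSE)
    cp <- if (cl == "positive") spec$co_motif_prob else 0
    if (cp > 0) for (cm in spec$co_motifs) {
      if (runif(1) > cp) next
      cw <- cm$width
      for (try in 1:50) {
        off <- sample.int(W - cw + 1L, 1L) - 1L
        clash <- any(vapply(occupied, function(iv)
          off < iv[2] && off + cw > iv[1], TRUE))
        if (!clash) break
      }
      if (clash) next   # overcrowded window: skip this co-motif
      ci_inst <- .sample_pwm_instance(cm)
      cstrand <- sample(c("+", "-"), 1L)
      genome[[ch]] <- .splice(genome[[ch]], ws + off,
                              if (cstrand == "-") reverse_complement(ci_inst)
                              else ci_inst)
      occupied[[length(occupied) + 1L]] <- c(off, off + cw)
      truth[[length(truth) + 1L]] <- data.frame(
        window_id = i, chrom = ch, window_start = ws, window_end = ws + W,
        class = cl, motif_id = cm$id, motif_start = ws + off,
        motif_end = ws + off + cw, strand = cstrand, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(window_id = integer(), chrom = character(),
               window_start = integer(), window_end = integer(),
               class = character(), motif_id = character(),
               motif_start = integer(), motif_end = integer(),
               strand = character())
  windows <- data.frame(
    chrom = chroms, start = starts, end = starts + W,
    name = paste0("win", seq_len(n)), score = NA_real_, strand = ".",
    label = ifelse(classes == "positive", "positive", "negative"),
    negative_type = ifelse(classes == "positive", "none", classes),
    cell_line = "synthetic", split = NA_character_,
    stringsAsFactors = FALSE)
  # source peaks: variable widths in [0.7 W, W], centered on the window
  halfw <- function(k) sample(ceiling(0.35 * W):(W %/% 2L), k, replace = TRUE)
  centers <- starts + W %/% 2L
  mk_peaks <- function(sel, prefix) {
    k <- sum(sel)
    h <- halfw(k)
    genomic_intervals(chroms[sel], centers[sel] - h, centers[sel] + h,
                      name = paste0(prefix, seq_len(k)))
  }
  is_pos <- classes == "positive"
  ctcf <- mk_peaks(is_pos | classes == "type1", "ctcf")
  hc <- W %/% 8L
  chiapet <- genomic_intervals(chroms[is_pos], centers[is_pos] - hc,
                               centers[is_pos] + hc,
                               name = paste0("loop", seq_len(sum(is_pos))))
  atac <- mk_peaks(classes %in% c("type2", "type3"), "atac")
  list(genome = genome, windows = windows, truth = truth,
       peaks = list(ctcf = ctcf, chiapet = chiapet, atac = atac))
}

#' Generate motif-disrupting and neutral point variants
#'
#' Disrupting variants flip the highest-information position of a planted
#' primary motif to its least-probable base (complemented for minus-strand
#' plants); neutral variants flip a background base at least
#' `neutral_buffer` bp from every planted motif in the same window. Both
#' sets live in positive windows whose variant-centered scoring window
#' fits the chromosome.
#'
#' @param truth truth table from [plant_windows()].
#' @param genome the planted genome.
#' @param spec a `fixture_spec`.
#' @param n_each number of variants per set (default 50).
#' @return list of two `variant_calls` data frames: `disrupting`,
#'   `neutral`.
#' @export
make_variants <- function(truth, genome, spec, n_each = 50L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed + 2L)
  pm <- spec$primary_motif
  ic <- 2 + rowSums(pm$probs * log2(pm$probs))
  jstar <- which.max(ic)
  bases <- c("A", "C", "G", "T")
  prim <- truth[truth$class == "positive" & truth$motif_id == pm$id, ,
                drop = FALSE]
  if (nrow(prim) == 0L) stop("no positive windows in truth")
  half <- spec$window_length %/% 2L
  dis <- list(); neu <- list()
  for (i in seq_len(nrow(prim))) {
    if (length(dis) >= n_each) break
    r <- prim[i, ]
    w <- pm$width
    gpos0 <- if (r$strand == "+") r$motif_start + jstar - 1L
             else r$motif_start + (w - jstar)
    chrom_len <- nchar(genome[[r$chrom]])
    if (gpos0 - half < 0L || gpos0 + half > chrom_len) next
    ref <- substr(genome[[r$chrom]], gpos0 + 1L, gpos0 + 1L)
    worst <- bases[order(pm$probs[jstar, ])]
    if (r$strand == "-") worst <- chartr("ACGT", "TGCA", worst)
    alt <- worst[worst != ref][1]
    # neutral site in the same window, buffered away from every plant
    win_truth <- truth[truth$window_id == r$window_id, , drop = FALSE]
    offs <- setdiff(seq_len(spec$window_length) - 1L, unlist(lapply(
      seq_len(nrow(win_truth)), function(k)
        max(0L, win_truth$motif_start[k] - r$window_start - spec$neutral_buffer):
        min(spec$window_length - 1L,
            win_truth$motif_end[k] - r$window_start + spec$neutral_buffer - 1L))))
    npos0 <- NA_integer_
    for (cand in offs[sample.int(length(offs))]) {
      g <- r$window_start + cand
      if (g - half >= 0L && g + half <= chrom_len) { npos0 <- g; break }
    }
    if (is.na(npos0)) next
    nref <- substr(genome[[r$chrom]], npos0 + 1L, npos0 + 1L)
    nalt <- sample(setdiff(bases, nref), 1L)
    dis[[length(dis) + 1L]] <- data.frame(
      chrom = r$chrom, pos = gpos0 + 1L, ref = ref, alt = alt,
      id = sprintf("dis%d", length(dis) + 1L), stringsAsFactors = FALSE)
    neu[[length(neu) + 1L]] <- data.frame(
      chrom = r$chrom, pos = npos0 + 1L, ref = nref, alt = nalt,
      id = sprintf("neu%d", length(neu) + 1L), stringsAsFactors = FALSE)
  }
  as_vc <- function(x) {
    df <- do.call(rbind, x)
    class(df) <- c("variant_calls", "data.frame")
    df
  }
  list(disrupting = as_vc(dis), neutral = as_vc(neu))
}

#' Write a complete benchmark directory
#'
#' Generates the genome, windows, peaks and variants and writes: genome
#' FASTA, ctcf/chiapet/atac peak BEDs (laid out so the labeling pipeline
#' reconstructs the intended classes), a minimal variants VCF, the truth
#' TSV and a spec-echo JSON.
#'
#' @param spec a `fixture_spec`.
#' @param out_dir output directory (created).
#' @param n_variants variants per set.
#' @return the fixture list from [plant_windows()] with `variants` added,
#'   invisibly.
#' @export
make_benchmark <- function(spec, out_dir, n_variants = 50L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fx <- plant_windows(make_background_genome(spec), spec)
  fx$variants <- make_variants(fx$truth, fx$genome, spec, n_variants)
  write_fasta(fx$genome, file.path(out_dir, "genome.fa"))
  write_bed(fx$peaks$ctcf, file.path(out_dir, "ctcf_peaks.bed"))
  write_bed(fx$peaks$chiapet, file.path(out_dir, "chiapet_peaks.bed"))
  write_bed(fx$peaks$atac, file.path(out_dir, "atac_peaks.bed"))
  vcf <- rbind(fx$variants$disrupting, fx$variants$neutral)
  con <- file(file.path(out_dir, "variants.vcf"), "w")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT"), con)
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s", vcf$chrom, vcf$pos, vcf$id,
                     vcf$ref, vcf$alt), con)
  close(con)
  write.table(fx$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  echo <- spec[setdiff(names(spec), c("primary_motif", "co_motifs"))]
  echo$primary_motif_id <- spec$primary_motif$id
  echo$co_motif_ids <- vapply(spec$co_motifs, function(p) p$id, "")
  jsonlite::write_json(echo, file.path(out_dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fx)
}
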