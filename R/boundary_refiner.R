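# Weakly supervised boundary refinement via 1D Grad-CAM.
#
# Channel weights are the global average of the positive-class logit's
# gradient over the final convolution block's post-ReLU activation maps;
# the ReLU of the weighted activation sum is upsampled to input length and
# a fixed-width (default 40 bp) window is placed around its argmax.

#' Capture final-block activations and their gradients
#'
#' Runs an inference-mode forward pass (dropout off) on one input and
#' records the final convolution block's post-ReLU activation maps
#' together with the gradient of the pre-sigmoid forward-strand logit with
#' respect to them.
#'
#' @param model an `anchor_model`.
#' @param x a single L x 4 one-hot matrix.
#' @return an `activation_stack`: list with `A` (K x M activations), `grad`
#'   (K x M), `y_C` (the logit) and `z` (spatial size M).
#' @export
capture_final_block <- function(model, x) {
  cfg <- model$config
  if (length(cfg$blocks) == 0L) stop("model has no convolution blocks")
  fw <- nn_forward(model$params, cfg, x, 1L, train = FALSE, keep_cache = TRUE)
  bw <- nn_backward(model$params, cfg, fw$cache, 1)
  nb <- length(cfg$blocks)
  A <- t(fw$cache$blocks[[nb]]$A)        # K x M
  grad <- t(bw$d_final_act)
  structure(list(A = A, grad = grad, y_C = fw$logits, z = ncol(A)),
            class = "activation_stack")
}

#' Grad-CAM channel weights
#'
#' `a_k = (1/z) * sum_i grad[k, i]`: 1D global average pooling of the
#' class gradient over positions.
#'
#' @param stack an `activation_stack`.
#' @return numeric vector of K channel weights.
#' @export
channel_weights <- function(stack) {
  rowMeans(stack$grad)
}

#' Combine activation maps into a Grad-CAM importance map
#'
#' Position-wise `ReLU(sum_k a_k * A[k, ])`.
#'
#' @param stack an `activation_stack`.
#' @param weights length-K channel weights.
#' @return length-M non-negative vector.
#' @export
gradcam_map <- function(stack, weights) {
  if (length(weights) != nrow(stack$A))
    stop("weights length ", length(weights), " != channel count ",
         nrow(stack$A))
  pmax(as.numeric(crossprod(stack$A, weights)), 0)
}

#' Upsample an importance map to input length
#'
#' Linear interpolation onto L uniformly spaced positions with endpoints
#' mapped to endpoints; non-negativity is preserved. Nearest-neighbour
#' interpolation is available via `method = "nearest"`.
#'
#' @param map length-M non-negative vector.
#' @param target_length L >= M.
#' @param method `"linear"` (default) or `"nearest"`.
#' @return an `importance_map`: list with `scores` (length L),
#'   `source_length` and `method_tag`.
#' @export
upsample_map <- function(map, target_length, method = c("linear", "nearest")) {
  method <- match.arg(method)
  M <- length(map)
  if (M > target_length) stop("cannot upsample: source longer than target")
  scores <- if (M == target_length) as.numeric(map)
  else if (M == 1L) rep(as.numeric(map), target_length)
  else approx(seq(0, 1, length.out = M), map,
              xout = seq(0, 1, length.out = target_length),
              method = if (method == "linear") "linear" else "constant",
              f = 0.5)$y
  structure(list(scores = pmax(scores, 0), source_length = M,
                 method_tag = "gradcam-final-block"),
            class = "importance_map")
}

#' Place the refined anchor window around the importance peak
#'
#' Finds the leftmost argmax of the map and returns the `bin`-wide genomic
#' interval centered there, shifted inward at window edges to preserve
#' width. An all-zero map yields a flagged no-signal result instead of an
#' arbitrary window. `mode = "sumwindow"` centers instead on the bin of
#' maximal summed importance.
#'
#' @param map an `importance_map` whose length equals the parent width.
#' @param parent single-row `genomic_intervals` (the 2000 bp window).
#' @param bin refined width in bp (default 40).
#' @param mode `"argmax"` (default) or `"sumwindow"`.
#' @return a `refined_anchor`: list with `interval`, `peak_position`
#'   (0-based offset in the parent), `peak_score`, `no_signal`.
#' @export
refine_window <- function(map, parent, bin = 40L, mode = c("argmax", "sumwindow")) {
  mode <- match.arg(mode)
  sc <- map$scores
  L <- length(sc)
  if (L != parent$end[1] - parent$start[1])
    stop("importance map length != parent window width")
  if (all(sc == 0)) {
    return(structure(list(interval = NULL, peak_position = NA_integer_,
                          peak_score = 0, no_signal = TRUE),
                     class = "refined_anchor"))
  }
  if (mode == "argmax") {
    p <- which.max(sc)                   # leftmost on ties
  } else {
    wsum <- stats::filter(sc, rep(1, bin), sides = 1)  # sum ending at i
    wsum <- wsum[bin:L]
    p <- which.max(wsum) - 1L + bin %/% 2L + 1L        # center of best bin
  }
  offset <- p - 1L
  s <- parent$start[1] + offset - bin %/% 2L
  e <- s + bin
  if (s < parent$start[1]) { s <- parent$start[1]; e <- s + bin }
  if (e > parent$end[1]) { e <- parent$end[1]; s <- max(parent$start[1], e - bin) }
  structure(list(
    interval = genomic_intervals(parent$chrom[1], s, e,
                                 name = parent$name[1], score = max(sc),
                                 strand = "."),
    peak_position = offset, peak_score = max(sc), no_signal = FALSE),
    class = "refined_anchor")
}

#' Grad-CAM importance map for one window sequence
#'
#' Convenience composition of [capture_final_block()], [channel_weights()],
#' [gradcam_map()] and [upsample_map()]. By default the map comes from the
#' forward-strand pass's positive-class logit; `strand_symmetric = TRUE`
#' averages it with the coordinate-mirrored reverse-strand map.
#'
#' @param model an `anchor_model`.
#' @param seq window sequence of the configured input length.
#' @param strand_symmetric average forward and mirrored-reverse maps.
#' @param method interpolation method for [upsample_map()].
#' @return an `importance_map` of input length.
#' @export
importance_map <- function(model, seq, strand_symmetric = FALSE,
                           method = "linear") {
  L <- model$config$input_length
  x <- onehot_encode(seq)
  stack <- capture_final_block(model, x)
  m <- upsample_map(gradcam_map(stack, channel_weights(stack)), L, method)
  if (strand_symmetric) {
    stack_rc <- capture_final_block(model, onehot_reverse_complement(x))
    m_rc <- upsample_map(gradcam_map(stack_rc, channel_weights(stack_rc)),
                         L, method)
    m$scores <- (m$scores + rev(m_rc$scores)) / 2
  }
  m
}

#' Refine all positive windows and report coverage
#'
#' Applies Grad-CAM refinement to positive-labeled windows only (the true
#' insulator samples). Windows with an all-zero map are excluded and
#' counted. The coverage ratio is the summed refined width divided by the
#' summed original width; pass `original` (e.g. the raw, variable-width
#' peaks) to use pre-normalization widths as the denominator.
#'
#' @param model an `anchor_model`.
#' @param positives `genomic_intervals`/labeled windows of the model's
#'   input length (positive windows).
#' @param genome a `genome` object.
#' @param bin refined width (default 40).
#' @param original optional intervals whose widths form the coverage
#'   denominator (defaults to `positives`).
#' @param strand_symmetric see [importance_map()].
#' @return list with `refined` (`genomic_intervals`), `n_no_signal`, and
#'   `coverage` (`NA` when there are no refined windows).
#' @export
refine_all <- function(model, positives, genome, bin = 40L, original = NULL,
                       strand_symmetric = FALSE) {
  n <- nrow(positives)
  out <- vector("list", n)
  n_no_signal <- 0L
  for (i in seq_len(n)) {
    seq <- extract_sequence(genome, positives, i)
    m <- importance_map(model, seq, strand_symmetric = strand_symmetric)
    r <- refine_window(m, positives[i, , drop = FALSE], bin = bin)
    if (r$no_signal) n_no_signal <- n_no_signal + 1L else out[[i]] <- r$interval
  }
  refined <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  denom <- if (is.null(original)) positives else original
  coverage <- if (is.null(refined) || nrow(refined) == 0L) NA_real_
  else sum(interval_width(refined)) / sum(interval_width(denom))
  list(refined = refined, n_no_signal = n_no_signal, coverage = coverage)
}
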