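# Anchor model: a three-conv-block / three-dense-layer CNN mapping a one-hot
# DNA window to a single logit, with four strategies for handling the
# reverse-complement strand:
#   standard          - forward strand only,
#   rc_augmented      - forward only, but training data is RC-augmented,
#   trained_conjoined - mean of the two strand sigmoids inside training,
#   posthoc_conjoined - trained like rc_augmented, converted to
#                       strand-averaged (Siamese) inference after training.
# The two strand passes always share all parameters.

#' Model architecture configuration
#'
#' The first convolution filters span all 4 channels with width 31 (a PWM
#' reader); each of the three blocks is conv -> ReLU -> max-pool. Dropout
#' applies only to the hidden dense layers.
#'
#' @param input_length window length in bp (default 2000).
#' @param blocks list of 3 specs `list(filters, kernel, pool)`.
#' @param dense sizes of the three dense layers; the last must be 1.
#' @param dropout dropout rate on hidden dense layers (default 0.5).
#' @return a `model_config` list (includes the derived flattened size).
#' @export
model_config <- function(input_length = 2000L,
                         blocks = list(list(filters = 64L, kernel = 31L, pool = 4L),
                                       list(filters = 128L, kernel = 11L, pool = 4L),
                                       list(filters = 128L, kernel = 7L, pool = 4L)),
                         dense = c(256L, 64L, 1L),
                         dropout = 0.5) {
  if (length(blocks) != 3L)
    stop("config error: exactly 3 convolution blocks are required, got ",
         length(blocks))
  if (blocks[[1]]$kernel != 31L)
    stop("config error: first block kernel width must be 31")
  if (length(dense) != 3L || dense[length(dense)] != 1L)
    stop("config error: need 3 dense layers ending in a single output unit")
  L <- as.integer(input_length)
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    if (L < blk$kernel)
      stop("config error: block ", b, " input length ", L,
           " shorter than kernel ", blk$kernel)
    if (L < blk$pool)
      stop("config error: block ", b, " input length ", L,
           " shorter than pool width ", blk$pool)
    L <- L %/% blk$pool
  }
  cfg <- list(input_length = as.integer(input_length), blocks = blocks,
              dense = as.integer(dense), dropout = dropout,
              final_length = L,
              flat_size = L * blocks[[length(blocks)]]$filters)
  class(cfg) <- "model_config"
  cfg
}

#' Small architecture profile for desk-scale experiments
#'
#' Same three-block topology with 8/16/16 filters, 400 bp windows and
#' 32/16/1 dense sizes; every field overridable. Pool widths are 2 rather
#' than the full profile's 4 so the final convolution block keeps 8 bp
#' spatial resolution, which the 40 bp Grad-CAM refinement needs at this
#' window length.
#'
#' @param input_length window length (default 400).
#' @param ... overrides passed to [model_config()].
#' @return a `model_config`.
#' @export
tiny_model_config <- function(input_length = 400L, ...) {
  model_config(input_length = input_length,
               blocks = list(list(filters = 8L, kernel = 31L, pool = 2L),
                             list(filters = 16L, kernel = 11L, pool = 2L),
                             list(filters = 16L, kernel = 7L, pool = 2L)),
               dense = c(32L, 16L, 1L), ...)
}

#' Number of trainable parameters implied by a config
#' @param config a `model_config`.
#' @return integer parameter count.
#' @export
n_parameters <- function(config) {
  n <- 0L; Cin <- 4L
  for (blk in config$blocks) {
    n <- n + blk$kernel * Cin * blk$filters + blk$filters
    Cin <- blk$filters
  }
  Din <- config$flat_size
  for (Dout in config$dense) {
    n <- n + Din * Dout + Dout
    Din <- Dout
  }
  n
}

#' Build an anchor model with deterministic initialization
#'
#' @param config a `model_config`.
#' @param seed integer seed: two builds with the same seed have identical
#'   initial parameters.
#' @param mode one of `"standard"`, `"rc_augmented"`, `"trained_conjoined"`,
#'   `"posthoc_conjoined"` (default).
#' @return an `anchor_model`.
#' @export
build_model <- function(config, seed = 1L, mode = "posthoc_conjoined") {
  mode <- match.arg(mode, c("standard", "rc_augmented", "trained_conjoined",
                            "posthoc_conjoined"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  model <- list(config = config, params = nn_init_params(config),
                mode = mode, seed = as.integer(seed))
  class(model) <- "anchor_model"
  model
}

#' @export
print.anchor_model <- function(x, ...) {
  cat("anchor_model:", x$mode, "mode,", x$config$input_length,
      "bp input,", n_parameters(x$config), "parameters\n")
  invisible(x)
}

# one-hot encode a character vector of equal-length sequences into the
# (B*L) x 4 batch layout
onehot_batch <- function(seqs) {
  do.call(rbind, lapply(seqs, onehot_encode))
}

#' Pre-sigmoid logit(s) of one-hot input
#'
#' Inference-mode forward pass (dropout off) on the strand given. Accepts a
#' single L x 4 matrix or a (B*L) x 4 stacked batch with `B` set.
#'
#' @param model an `anchor_model`.
#' @param x one-hot matrix.
#' @param B batch size (default 1).
#' @return numeric vector of B logits.
#' @export
forward_logit <- function(model, x, B = 1L) {
  L <- model$config$input_length
  if (nrow(x) != B * L)
    stop("input has ", nrow(x), " rows; expected B*L = ", B * L)
  nn_forward(model$params, model$config, x, B, train = FALSE)$logits
}

#' Predict anchor probabilities for DNA sequences
#'
#' In the conjoined modes both strands are scored with the shared-weight
#' network and the two sigmoids averaged; in `standard`/`rc_augmented`
#' modes the forward-strand probability is the value (the reverse strand is
#' still recorded).
#'
#' @param model an `anchor_model`.
#' @param seqs character vector of sequences of the configured length.
#' @return data.frame with `forward`, `reverse`, `value` columns.
#' @export
predict_anchor <- function(model, seqs) {
  B <- length(seqs)
  L <- model$config$input_length
  if (any(nchar(seqs) != L))
    stop("sequence length must equal the configured input length ", L)
  Xf <- onehot_batch(seqs)
  Xr <- do.call(rbind, lapply(seqs, function(s)
    onehot_reverse_complement(onehot_encode(s))))
  pf <- sigmoid(forward_logit(model, Xf, B))
  pr <- sigmoid(forward_logit(model, Xr, B))
  value <- if (model$mode %in% c("posthoc_conjoined", "trained_conjoined"))
    (pf + pr) / 2 else pf
  data.frame(forward = pf, reverse = pr, value = value)
}

#' Training-time scalar for one one-hot sample
#'
#' The number the loss consumes: the forward-strand sigmoid for
#' `standard`/`rc_augmented`/`posthoc_conjoined` (the latter two differ
#' only in the data loader, which also emits the RC strand as an
#' independent sample), or the mean of the two strand sigmoids for
#' `trained_conjoined` (gradients flow through both passes).
#'
#' @param model an `anchor_model`.
#' @param x a single L x 4 one-hot matrix.
#' @return scalar in (0, 1).
#' @export
training_output <- function(model, x) {
  pf <- sigmoid(forward_logit(model, x))
  if (model$mode == "trained_conjoined") {
    pr <- sigmoid(forward_logit(model, onehot_reverse_complement(x)))
    (pf + pr) / 2
  } else pf
}

#' Save a model checkpoint
#'
#' A versioned container recording config, parameters, mode and seed so
#' predictions are exactly reproducible.
#'
#' @param model an `anchor_model`.
#' @param path output file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "insuscan-checkpoint-v1",
               config = model$config, params = model$params,
               mode = model$mode, seed = model$seed), path)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param path checkpoint file.
#' @return an `anchor_model`.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "insuscan-checkpoint-v1"))
    stop("not an insuscan checkpoint: ", path)
  model <- list(config = x$config, params = x$params, mode = x$mode,
                seed = x$seed)
  class(model) <- "anchor_model"
  model
}

#' Switch the reverse-complement handling mode of a trained model
#'
#' Converting an `rc_augmented` model to `posthoc_conjoined` is the
#' post-hoc Siamese conversion: parameters are untouched, only inference
#' changes to strand averaging.
#'
#' @param model an `anchor_model`.
#' @param mode new mode.
#' @return the model with `mode` replaced.
#' @export
set_mode <- function(model, mode) {
  model$mode <- match.arg(mode, c("standard", "rc_augmented",
                                  "trained_conjoined", "posthoc_conjoined"))
  model
}
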