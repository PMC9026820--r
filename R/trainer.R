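# Two-stage training protocol: stage 1 pretrains a motif-presence
# classifier, stage 2 fine-tunes on anchor labels starting from those
# weights (all layers transferred, including dense). Checkpoint selection
# is by minimum validation loss, evaluated at the end of every epoch.

#' Training configuration
#'
#' Defaults are the protocol's values: Adam, learning rate 5e-5, 50
#' epochs, batch size 64, weight decay 5e-4, binary cross-entropy loss.
#'
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param weight_decay L2 weight decay folded into the Adam gradient.
#' @param seed seed for the training stream (shuffling + dropout); model
#'   initialization is seeded separately in [build_model()].
#' @param warmup_epochs linear learning-rate warmup over this many initial
#'   epochs (default 1). Adam's bias-corrected first steps are full-sized
#'   and can wreck a pretrained initialization; the warmup ramps them in.
#' @param stage `"motif_pretrain"` or `"anchor_finetune"` (bookkeeping tag).
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-5, epochs = 50L, batch_size = 64L,
                         weight_decay = 5e-4, seed = 1L, warmup_epochs = 1L,
                         stage = "anchor_finetune") {
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, loss = "bce",
                 seed = as.integer(seed), warmup_epochs = as.integer(warmup_epochs),
                 stage = stage),
            class = "train_config")
}

#' Binary cross-entropy loss
#'
#' `-(y log p + (1-y) log(1-p))`, with `p` clamped to
#' `[1e-7, 1 - 1e-7]`; for vectors the batch value is the mean.
#'
#' @param p predicted probabilities.
#' @param y labels in \{0, 1\}.
#' @return mean loss.
#' @export
bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney formulation; ties contribute 1/2 via midranks.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("AUROC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve (step interpolation)
#'
#' Walks the ranked list, emitting one PR point per distinct score (so tied
#' scores enter as a block), and integrates precision over recall steps
#' without linear interpolation (avoids the optimistic bias of trapezoids).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(scores, labels) {
  npos <- sum(labels == 1)
  if (npos == 0 || sum(labels == 0) == 0) stop("AUPR needs both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y == 1); n_seen <- seq_along(y)
  boundary <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  prec <- tp[boundary] / n_seen[boundary]
  rec <- tp[boundary] / npos
  sum(diff(c(0, rec)) * prec)
}

# ---- core minibatch loop -------------------------------------------------

# Encode equal-length sequences as one stacked batch matrix (B*L) x 4 and
# remember B/L.
.encode_set <- function(seqs) {
  list(X = onehot_batch(seqs), B = length(seqs), L = nchar(seqs[1]))
}

.batch_rows <- function(idx, L) rep((idx - 1L) * L, each = L) + seq_len(L)

# Eval-mode probabilities for a stacked set, using the mode's validation
# semantics (mean of strands only for trained_conjoined; the posthoc
# conversion happens after training).
.val_probs <- function(params, config, enc, enc_rc, mode, batch = 256L) {
  B <- enc$B; L <- enc$L
  out <- numeric(B)
  for (st in seq(1L, B, by = batch)) {
    idx <- st:min(st + batch - 1L, B)
    rows <- .batch_rows(idx, L)
    p <- sigmoid(nn_forward(params, config, enc$X[rows, , drop = FALSE],
                            length(idx))$logits)
    if (mode == "trained_conjoined") {
      pr <- sigmoid(nn_forward(params, config, enc_rc$X[rows, , drop = FALSE],
                               length(idx))$logits)
      p <- (p + pr) / 2
    }
    out[idx] <- p
  }
  out
}

# Train on (train_seqs, y) validating on (val_seqs, yv). Returns the
# best-validation-loss model plus the per-epoch log. All randomness flows
# from model$seed (init, done by the caller) and config$seed (shuffle +
# dropout).
.train_core <- function(model, train_seqs, y, val_seqs, yv, config,
                        verbose = FALSE) {
  cfg <- model$config
  mode <- model$mode
  if (mode %in% c("rc_augmented", "posthoc_conjoined")) {
    # the loader emits both strands as independent samples
    train_seqs <- c(train_seqs, vapply(train_seqs, reverse_complement, ""))
    y <- c(y, y)
  }
  enc <- .encode_set(train_seqs)
  enc_rc <- NULL
  if (mode == "trained_conjoined") {
    enc_rc <- .encode_set(vapply(train_seqs, reverse_complement, ""))
  }
  venc <- .encode_set(val_seqs)
  venc_rc <- if (mode == "trained_conjoined")
    .encode_set(vapply(val_seqs, reverse_complement, "")) else NULL
  L <- cfg$input_length
  n <- enc$B
  params <- model$params
  opt <- adam_init(params)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  log <- vector("list", config$epochs)
  best <- list(loss = Inf, params = params)
  warmup <- if (is.null(config$warmup_epochs)) 0L else config$warmup_epochs
  steps_per_epoch <- ceiling(n / config$batch_size)
  warmup_steps <- warmup * steps_per_epoch
  global_step <- 0L
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    tot_loss <- 0; nb <- 0L
    for (st in seq(1L, n, by = config$batch_size)) {
      idx <- perm[st:min(st + config$batch_size - 1L, n)]
      B <- length(idx)
      rows <- .batch_rows(idx, L)
      yb <- y[idx]
      if (mode == "trained_conjoined") {
        fw <- nn_forward(params, cfg, enc$X[rows, , drop = FALSE], B,
                         train = TRUE, keep_cache = TRUE)
        rv <- nn_forward(params, cfg, enc_rc$X[rows, , drop = FALSE], B,
                         train = TRUE, keep_cache = TRUE)
        pf <- sigmoid(fw$logits); pr <- sigmoid(rv$logits)
        p <- pmin(pmax((pf + pr) / 2, 1e-7), 1 - 1e-7)
        dLdp <- (p - yb) / (p * (1 - p)) / B
        gf <- nn_backward(params, cfg, fw$cache,
                          dLdp * 0.5 * pf * (1 - pf))$grads
        gr <- nn_backward(params, cfg, rv$cache,
                          dLdp * 0.5 * pr * (1 - pr))$grads
        grads <- grad_axpy(1, gf, 1, gr)
      } else {
        fw <- nn_forward(params, cfg, enc$X[rows, , drop = FALSE], B,
                         train = TRUE, keep_cache = TRUE)
        p <- sigmoid(fw$logits)
        grads <- nn_backward(params, cfg, fw$cache, (p - yb) / B)$grads
      }
      tot_loss <- tot_loss + bce_loss(p, yb)
      nb <- nb + 1L
      global_step <- global_step + 1L
      lr_eff <- if (global_step <= warmup_steps)
        config$learning_rate * global_step / warmup_steps
      else config$learning_rate
      stp <- adam_step(params, grads, opt, lr_eff, config$weight_decay)
      params <- stp$params; opt <- stp$state
    }
    vp <- .val_probs(params, cfg, venc, venc_rc, mode)
    vl <- bce_loss(vp, yv)
    saved <- vl < best$loss
    if (saved) best <- list(loss = vl, params = params)
    log[[epoch]] <- data.frame(
      epoch = epoch, train_loss = tot_loss / nb, val_loss = vl,
      val_auroc = auroc(vp, yv), val_aupr = aupr(vp, yv),
      checkpoint_saved = saved)
    if (verbose)
      message(sprintf("epoch %d train %.4f val %.4f auroc %.3f",
                      epoch, tot_loss / nb, vl, log[[epoch]]$val_auroc))
  }
  model$params <- best$params
  list(model = model, log = do.call(rbind, log))
}

.split_seqs <- function(manifest, genome, split) {
  w <- manifest$windows[manifest$windows$split == split, , drop = FALSE]
  list(seqs = extract_sequences(genome, w), windows = w)
}

#' Stage 1: pretrain a motif-presence classifier
#'
#' Trains the same architecture to classify windows by whether they carry
#' a motif (labels typically derived from [scan_motifs()] on the windows),
#' not by anchor status. The best-validation checkpoint is returned for
#' stage-2 initialization.
#'
#' @param manifest a `dataset_manifest` with train/val splits.
#' @param motif_labels logical/0-1 vector aligned with `manifest$windows`.
#' @param genome a `genome` object.
#' @param config a `train_config`.
#' @param model an `anchor_model` to start from (its mode governs the
#'   strand handling); built fresh by the caller.
#' @return list with `model` (best checkpoint) and `log`.
#' @export
pretrain_motif_classifier <- function(manifest, motif_labels, genome, config,
                                      model) {
  y_all <- as.integer(motif_labels)
  if (length(unique(y_all)) < 2L)
    stop("motif labels are all one class; nothing to pretrain on")
  tr <- manifest$windows$split == "train"
  va <- manifest$windows$split == "val"
  if (!any(va)) stop("manifest lacks a validation split")
  seqs <- extract_sequences(genome, manifest$windows)
  config$stage <- "motif_pretrain"
  .train_core(model, seqs[tr], y_all[tr], seqs[va], y_all[va], config)
}

#' Stage 2: train the anchor classifier
#'
#' Anchor-label training under the model's reverse-complement mode,
#' optionally initialized from a stage-1 checkpoint (all weights copied,
#' the final layer included). Returns the checkpoint with minimal
#' validation loss and the full per-epoch log.
#'
#' @param manifest a balanced `dataset_manifest`.
#' @param genome a `genome` object.
#' @param config a `train_config`.
#' @param model an `anchor_model`; when `init_from` is given its
#'   parameters are replaced by the stage-1 weights before training.
#' @param init_from optional stage-1 `anchor_model`.
#' @return list with `model` and `log`.
#' @export
train_anchor_classifier <- function(manifest, genome, config, model,
                                    init_from = NULL) {
  if (!any(manifest$windows$split == "val"))
    stop("manifest lacks a validation split")
  if (!is.null(init_from)) model$params <- init_from$params
  tr <- .split_seqs(manifest, genome, "train")
  va <- .split_seqs(manifest, genome, "val")
  config$stage <- "anchor_finetune"
  .train_core(model,
              tr$seqs, as.integer(tr$windows$label == "positive"),
              va$seqs, as.integer(va$windows$label == "positive"),
              config)
}

#' Evaluate a model on labeled windows
#'
#' AUROC by the rank statistic and AUPR by step interpolation, overall and
#' per negative type (positives vs type1 only, vs type2 only, vs type3
#' only), mirroring evaluation against the three negative test sets.
#'
#' @param model an `anchor_model`.
#' @param windows labeled windows (both classes present).
#' @param genome a `genome` object.
#' @return list with `auroc`, `aupr`, `by_type` (data.frame) and `scores`.
#' @export
evaluate_model <- function(model, windows, genome) {
  y <- as.integer(windows$label == "positive")
  if (length(unique(y)) < 2L) stop("evaluation needs both classes")
  seqs <- extract_sequences(genome, windows)
  p <- predict_anchor(model, seqs)$value
  types <- c("type1", "type2", "type3")
  by_type <- do.call(rbind, lapply(types, function(tt) {
    sel <- y == 1 | windows$negative_type == tt
    if (sum(y[sel] == 0) == 0) return(NULL)
    data.frame(negative_type = tt,
               auroc = auroc(p[sel], y[sel]),
               aupr = aupr(p[sel], y[sel]))
  }))
  list(auroc = auroc(p, y), aupr = aupr(p, y), by_type = by_type,
       scores = data.frame(windows[, c("chrom", "start", "end",
                                       "label", "negative_type")],
                           score = p))
}

#' Leave-one-chromosome-out validation
#'
#' Trains one model per chromosome fold ([make_loco_splits()]); the
#' held-out chromosome serves as validation for checkpoint selection and
#' as the reported test set.
#'
#' @param manifest a `dataset_manifest`.
#' @param genome a `genome` object.
#' @param config a `train_config`.
#' @param model_cfg a `model_config` for the per-fold models.
#' @param mode reverse-complement mode.
#' @param init_from optional stage-1 checkpoint shared across folds.
#' @return data.frame: one row per held-out chromosome plus a `mean` row.
#' @export
run_loco <- function(manifest, genome, config, model_cfg,
                     mode = "posthoc_conjoined", init_from = NULL) {
  folds <- make_loco_splits(manifest)
  rows <- lapply(folds, function(fold) {
    w <- manifest$windows
    trw <- w[w$chrom %in% fold$train_chroms, , drop = FALSE]
    how <- w[w$chrom == fold$held_out_chrom, , drop = FALSE]
    model <- build_model(model_cfg, seed = config$seed, mode = mode)
    if (!is.null(init_from)) model$params <- init_from$params
    fit <- .train_core(model,
                       extract_sequences(genome, trw),
                       as.integer(trw$label == "positive"),
                       extract_sequences(genome, how),
                       as.integer(how$label == "positive"),
                       config)
    ev <- evaluate_model(fit$model, how, genome)
    data.frame(held_out = fold$held_out_chrom, auroc = ev$auroc,
               aupr = ev$aupr)
  })
  tab <- do.call(rbind, rows)
  rbind(tab, data.frame(held_out = "mean", auroc = mean(tab$auroc),
                        aupr = mean(tab$aupr)))
}

#' Cross-group (cross-cell-line) validation
#'
#' Trains one model per group on its train/val splits and evaluates every
#' model on every group's test split.
#'
#' @param manifests_by_group named list of `dataset_manifest`s.
#' @param genomes_by_group named list of matching `genome`s (or one genome
#'   recycled for all).
#' @param config a `train_config`.
#' @param model_cfg a `model_config`.
#' @param mode reverse-complement mode.
#' @return list of two group x group matrices, `auroc` and `aupr`.
#' @export
run_cross_group <- function(manifests_by_group, genomes_by_group, config,
                            model_cfg, mode = "posthoc_conjoined") {
  groups <- names(manifests_by_group)
  if (length(groups) < 2L) stop("cross-group validation needs >= 2 groups")
  if (inherits(genomes_by_group, "genome"))
    genomes_by_group <- setNames(rep(list(genomes_by_group), length(groups)),
                                 groups)
  for (g in groups) {
    if (!any(manifests_by_group[[g]]$windows$split == "test"))
      stop("group ", g, " has no test split")
  }
  models <- lapply(groups, function(g) {
    model <- build_model(model_cfg, seed = config$seed, mode = mode)
    train_anchor_classifier(manifests_by_group[[g]], genomes_by_group[[g]],
                            config, model)$model
  })
  names(models) <- groups
  au <- matrix(NA_real_, length(groups), length(groups),
               dimnames = list(train = groups, test = groups))
  ap <- au
  for (g in groups) for (h in groups) {
    w <- manifests_by_group[[h]]$windows
    te <- w[w$split == "test", , drop = FALSE]
    ev <- evaluate_model(models[[g]], te, genomes_by_group[[h]])
    au[g, h] <- ev$auroc; ap[g, h] <- ev$aupr
  }
  list(auroc = au, aupr = ap)
}
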