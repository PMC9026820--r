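# Brute-force metric oracles kept independent of the package's
# implementations.
pair_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
step_aupr <- function(scores, labels) {
  npos <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / npos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

test_that("binary cross-entropy matches closed forms and is a batch mean", {
  expect_equal(bce_loss(0.5, 1), log(2))
  expect_equal(bce_loss(0.5, 0), log(2))
  expect_lt(bce_loss(1, 1), 1e-6)
  expect_lt(bce_loss(0, 0), 1e-6)
  set.seed(41)
  p <- runif(20); y <- rbinom(20, 1, 0.5)
  expect_equal(bce_loss(p, y),
               mean(vapply(1:20, function(i) bce_loss(p[i], y[i]), 0)))
})

test_that("AUROC equals the concordant-pair statistic with midrank ties", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  labels <- c(1, 1, 0, 1, 0, 0)
  expect_equal(auroc(scores, labels), pair_auroc(scores, labels))
  expect_equal(auroc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  set.seed(42)
  for (i in 1:10) {
    s <- round(runif(30), 1)  # heavy ties
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auroc(s, y), pair_auroc(s, y))
  }
  # random scores hover around chance
  set.seed(43)
  null_au <- replicate(50, auroc(runif(100), rep(c(0, 1), 50)))
  expect_lt(abs(mean(null_au) - 0.5), 0.05)
})

test_that("AUROC agrees with pROC on random data", {
  set.seed(44)
  s <- runif(200); y <- rbinom(200, 1, 0.4)
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1)))),
               tolerance = 1e-12)
})

test_that("AUPR uses step interpolation over tie blocks", {
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(45)
  for (i in 1:10) {
    s <- round(runif(40), 1)
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(aupr(s, y), step_aupr(s, y), tolerance = 1e-12)
  }
})

test_that("a short run logs per epoch, selects the best checkpoint, and repeats", {
  ns <- asNamespace("insuscan")
  cfg <- micro_config(dropout = 0.5)
  cons <- pwm_consensus(ctcf_like_pwm())
  set.seed(46)
  n <- 48
  seqs <- replicate(n, random_dna(cfg$input_length))
  y <- rep(c(1, 0), n / 2)
  for (i in which(y == 1)) substr(seqs[i], 20, 38) <- cons
  model <- build_model(cfg, seed = 47, mode = "standard")
  tc <- train_config(learning_rate = 1e-3, epochs = 4, batch_size = 16, seed = 48)
  fit <- ns$.train_core(model, seqs[1:32], y[1:32], seqs[33:48], y[33:48], tc)
  expect_equal(nrow(fit$log), 4L)
  expect_equal(fit$log$epoch, 1:4)
  # checkpoint_saved marks exactly the running minima of val_loss
  expect_identical(fit$log$checkpoint_saved,
                   fit$log$val_loss == cummin(fit$log$val_loss))
  # the returned model reproduces the minimum validation loss
  vp <- sigmoid(vapply(seqs[33:48], function(s)
    forward_logit(fit$model, onehot_encode(s)), 0))
  expect_equal(bce_loss(unname(vp), y[33:48]), min(fit$log$val_loss),
               tolerance = 1e-12)
  # epoch-1 loss starts near chance level on balanced data
  expect_lt(abs(fit$log$train_loss[1] - log(2)), 0.15)
  # identical rerun
  model2 <- build_model(cfg, seed = 47, mode = "standard")
  fit2 <- ns$.train_core(model2, seqs[1:32], y[1:32], seqs[33:48], y[33:48], tc)
  expect_identical(fit$log, fit2$log)
  expect_identical(fit$model$params, fit2$model$params)
})

test_that("stage contracts reject degenerate inputs", {
  fx <- small_fixture()
  mf <- small_manifest()
  model <- build_model(tiny_model_config(), seed = 1)
  expect_error(pretrain_motif_classifier(mf, rep(1, nrow(mf$windows)),
                                         fx$genome, train_config(), model),
               "one class")
  mf_noval <- mf
  mf_noval$windows$split[mf_noval$windows$split == "val"] <- "train"
  expect_error(train_anchor_classifier(mf_noval, fx$genome, train_config(),
                                       model),
               "validation split")
  expect_error(evaluate_model(model,
                              mf$windows[mf$windows$label == "positive", ],
                              fx$genome),
               "both classes")
})

test_that("evaluation reports overall and per-negative-type metrics", {
  fx <- small_fixture()
  mf <- small_manifest()
  model <- build_model(tiny_model_config(), seed = 2)
  te <- mf$windows[mf$windows$split == "test", ]
  ev <- evaluate_model(model, te, fx$genome)
  expect_true(all(c("auroc", "aupr", "by_type", "scores") %in% names(ev)))
  expect_setequal(ev$by_type$negative_type, c("type1", "type2", "type3"))
  expect_true(all(ev$by_type$aupr >= 0 & ev$by_type$aupr <= 1))
  expect_equal(nrow(ev$scores), nrow(te))
})

test_that("LOCO folds never leak held-out windows and report a mean row", {
  fx <- small_fixture()
  mf <- small_manifest()
  tc <- train_config(learning_rate = 1e-3, epochs = 1, batch_size = 32, seed = 9)
  tab <- run_loco(mf, fx$genome, tc, tiny_model_config(dropout = 0))
  chroms <- sort(unique(mf$windows$chrom))
  expect_equal(nrow(tab), length(chroms) + 1L)
  expect_identical(tab$held_out, c(chroms, "mean"))
  k <- length(chroms)
  expect_equal(tab$auroc[k + 1], mean(tab$auroc[1:k]))
  expect_equal(tab$aupr[k + 1], mean(tab$aupr[1:k]))
})

test_that("cross-group validation fills a square matrix consistently", {
  fx <- small_fixture()
  mf <- small_manifest()
  w <- mf$windows
  g1 <- mf; g1$windows <- w[w$chrom == "chr1", ]
  g2 <- mf; g2$windows <- w[w$chrom == "chr2", ]
  tc <- train_config(learning_rate = 1e-3, epochs = 1, batch_size = 32, seed = 10)
  out <- run_cross_group(list(a = g1, b = g2), fx$genome, tc,
                         tiny_model_config(dropout = 0))
  expect_equal(dim(out$auroc), c(2L, 2L))
  expect_equal(dim(out$aupr), c(2L, 2L))
  expect_false(anyNA(out$auroc))
  g_broken <- g2
  g_broken$windows$split[g_broken$windows$split == "test"] <- "train"
  expect_error(run_cross_group(list(a = g1, b = g_broken), fx$genome, tc,
                               tiny_model_config(dropout = 0)),
               "no test split")
})
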