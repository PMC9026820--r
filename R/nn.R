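# Minimal 1D CNN engine: batched forward/backward passes written with base
# R matrix algebra (BLAS does the heavy lifting).
#
# Batch layout: a batch of B sequences of length L with C channels is one
# (B*L) x C matrix, rows sample-major (sample 1 positions 1..L, then
# sample 2, ...). Convolutions use 'same' zero padding and stride 1,
# implemented as a sum over kernel offsets of shifted-row matrix products;
# max pooling uses stride == pool width with any trailing remainder
# dropped.

.pad_rows <- function(B, L, p) {
  # rows of the padded (B*(L+2p)) x C matrix holding real data
  Lp <- L + 2L * p
  rep((0:(B - 1L)) * Lp, each = L) + p + seq_len(L)
}

.out_base <- function(B, L, p) {
  # padded row index of the window start for each output row (B*L rows)
  Lp <- L + 2L * p
  rep((0:(B - 1L)) * Lp, each = L) + seq_len(L)
}

conv1d_forward <- function(X, W, b, B, L) {
  # X: (B*L) x Cin; W: k x Cin x Cout array; returns Z (B*L) x Cout
  k <- dim(W)[1]; Cin <- dim(W)[2]; Cout <- dim(W)[3]
  p <- (k - 1L) %/% 2L
  Lp <- L + 2L * p
  Xp <- matrix(0, B * Lp, Cin)
  Xp[.pad_rows(B, L, p), ] <- X
  base <- .out_base(B, L, p)
  Z <- matrix(rep(b, each = B * L), B * L, Cout)
  for (j in seq_len(k)) {
    Z <- Z + Xp[base + (j - 1L), , drop = FALSE] %*% matrix(W[j, , ], Cin, Cout)
  }
  list(Z = Z, Xp = Xp, base = base)
}

conv1d_backward <- function(dZ, cache, W, B, L, need_dx = TRUE) {
  k <- dim(W)[1]; Cin <- dim(W)[2]; Cout <- dim(W)[3]
  p <- (k - 1L) %/% 2L
  dW <- array(0, dim(W))
  db <- colSums(dZ)
  dXp <- if (need_dx) matrix(0, nrow(cache$Xp), Cin) else NULL
  base <- cache$base
  for (j in seq_len(k)) {
    rows <- base + (j - 1L)
    dW[j, , ] <- crossprod(cache$Xp[rows, , drop = FALSE], dZ)
    if (need_dx) {
      dXp[rows, ] <- dXp[rows, ] + dZ %*% t(matrix(W[j, , ], Cin, Cout))
    }
  }
  dX <- if (need_dx) dXp[.pad_rows(B, L, p), , drop = FALSE] else NULL
  list(dW = dW, db = db, dX = dX)
}

maxpool_forward <- function(A, pw, B, L) {
  # A: (B*L) x C; returns pooled (B*Lo) x C plus argmax bookkeeping
  Lo <- L %/% pw
  C <- ncol(A)
  base <- rep((0:(B - 1L)) * L, each = Lo) + rep(seq(1L, Lo * pw, by = pw), B)
  out <- A[base, , drop = FALSE]
  amax <- matrix(1L, nrow(out), C)
  if (pw > 1L) for (j in 2:pw) {
    cand <- A[base + (j - 1L), , drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    amax[upd] <- j
  }
  list(P = out, amax = amax, base = base, Lo = Lo)
}

maxpool_backward <- function(dP, cache, pw, B, L, C) {
  dA <- matrix(0, B * L, C)
  for (j in seq_len(pw)) {
    sel <- cache$amax == j
    if (!any(sel)) next
    block <- matrix(0, nrow(dP), C)
    block[sel] <- dP[sel]
    rows <- cache$base + (j - 1L)
    dA[rows, ] <- dA[rows, ] + block
  }
  dA
}

flatten_forward <- function(P, B, M, K) {
  # (B*M) x K sample-major -> B x (M*K), row b = vec(sample b's M x K block)
  arr <- array(P, dim = c(M, B, K))
  arr <- aperm(arr, c(1, 3, 2))      # M x K x B
  dim(arr) <- c(M * K, B)
  t(arr)
}

flatten_backward <- function(dF, B, M, K) {
  arr <- array(t(dF), dim = c(M, K, B))
  arr <- aperm(arr, c(1, 3, 2))      # M x B x K
  dim(arr) <- c(M * B, K)
  arr
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Logistic sigmoid
#'
#' `1 / (1 + exp(-x))`, the map from the network's output logit to the
#' anchor probability.
#'
#' @param x numeric vector.
#' @return values in (0, 1).
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

# He-uniform for ReLU conv layers, Glorot-uniform for dense layers; the
# final layer is scaled down so initial logits sit near zero (chance-level
# starting loss ~ ln 2 on balanced data).
.init_mat <- function(nr, nc, fan_in, fan_out = NULL) {
  lim <- if (is.null(fan_out)) sqrt(6 / fan_in)
  else sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

nn_init_params <- function(config) {
  params <- list(conv = list(), dense = list())
  Cin <- 4L
  for (b in seq_along(config$blocks)) {
    blk <- config$blocks[[b]]
    k <- blk$kernel
    W <- array(.init_mat(k * Cin, blk$filters, fan_in = k * Cin),
               dim = c(k, Cin, blk$filters))
    params$conv[[b]] <- list(W = W, b = numeric(blk$filters))
    Cin <- blk$filters
  }
  Din <- config$flat_size
  nd <- length(config$dense)
  for (d in seq_len(nd)) {
    Dout <- config$dense[d]
    W <- .init_mat(Din, Dout, fan_in = Din, fan_out = Dout)
    if (d == nd) W <- W * 0.1
    params$dense[[d]] <- list(W = W, b = numeric(Dout))
    Din <- Dout
  }
  params
}

# Full forward pass. X: (B*L) x 4. Returns logits (length B) and, when
# keep_cache, everything backward needs. Dropout (train mode only) uses the
# current RNG stream.
nn_forward <- function(params, config, X, B, train = FALSE,
                       keep_cache = FALSE) {
  L <- config$input_length
  cache <- list(B = B, L = L)
  cur <- X; curL <- L
  for (b in seq_along(config$blocks)) {
    blk <- config$blocks[[b]]
    cv <- conv1d_forward(cur, params$conv[[b]]$W, params$conv[[b]]$b, B, curL)
    A <- relu(cv$Z)
    pl <- maxpool_forward(A, blk$pool, B, curL)
    if (keep_cache) {
      cache$blocks[[b]] <- list(conv = cv[c("Xp", "base")],
                                mask = cv$Z > 0, pool = pl[c("amax", "base")],
                                Lin = curL, A = if (b == length(config$blocks)) A else NULL)
    }
    cur <- pl$P
    curL <- pl$Lo
  }
  M <- curL; K <- config$blocks[[length(config$blocks)]]$filters
  Fl <- flatten_forward(cur, B, M, K)
  cache$M <- M; cache$K <- K
  h <- Fl
  nd <- length(config$dense)
  for (d in seq_len(nd)) {
    Z <- h %*% params$dense[[d]]$W +
      matrix(params$dense[[d]]$b, B, config$dense[d], byrow = TRUE)
    if (d < nd) {
      Hd <- relu(Z)
      mask <- NULL
      if (train && config$dropout > 0) {
        keep <- 1 - config$dropout
        mask <- matrix((runif(length(Hd)) < keep) / keep, nrow(Hd), ncol(Hd))
        Hd <- Hd * mask
      }
      if (keep_cache) cache$dense[[d]] <- list(input = h, Z = Z, mask = mask)
      h <- Hd
    } else {
      if (keep_cache) cache$dense[[d]] <- list(input = h)
      h <- Z
    }
  }
  list(logits = as.numeric(h), cache = if (keep_cache) cache else NULL)
}

# Backward pass from d(logit) (length B). Returns gradients shaped like
# params, plus d(final-block post-ReLU activations) for Grad-CAM.
nn_backward <- function(params, config, cache, dlogit) {
  B <- cache$B
  nd <- length(config$dense)
  grads <- list(conv = vector("list", length(config$blocks)),
                dense = vector("list", nd))
  dh <- matrix(dlogit, B, 1L)
  for (d in rev(seq_len(nd))) {
    cc <- cache$dense[[d]]
    grads$dense[[d]] <- list(W = crossprod(cc$input, dh), b = colSums(dh))
    dh <- dh %*% t(params$dense[[d]]$W)
    if (d > 1L) {
      prev <- cache$dense[[d - 1L]]
      if (!is.null(prev$mask)) dh <- dh * prev$mask
      dh <- dh * (prev$Z > 0)
    }
  }
  dP <- flatten_backward(dh, B, cache$M, cache$K)
  d_final_act <- NULL
  nb <- length(config$blocks)
  for (b in rev(seq_len(nb))) {
    bc <- cache$blocks[[b]]
    blk <- config$blocks[[b]]
    dA <- maxpool_backward(dP, bc$pool, blk$pool, B, bc$Lin, blk$filters)
    if (b == nb) d_final_act <- dA
    dZ <- dA * bc$mask
    cv <- conv1d_backward(dZ, bc$conv, params$conv[[b]]$W, B, bc$Lin,
                          need_dx = b > 1L)
    grads$conv[[b]] <- cv[c("dW", "db")]
    dP <- cv$dX
  }
  list(grads = grads, d_final_act = d_final_act)
}

# Adam with L2 weight decay folded into the gradient (the convention of
# the classic Adam-with-weight-decay setup).
adam_init <- function(params) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    g <- g + weight_decay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (b in seq_along(params$conv)) {
    for (f in c("W", "b")) {
      r <- upd(params$conv[[b]][[f]], grads$conv[[b]][[if (f == "W") "dW" else "db"]],
               state$m$conv[[b]][[f]], state$v$conv[[b]][[f]])
      params$conv[[b]][[f]] <- r$p
      state$m$conv[[b]][[f]] <- r$m
      state$v$conv[[b]][[f]] <- r$v
    }
  }
  for (d in seq_along(params$dense)) {
    for (f in c("W", "b")) {
      r <- upd(params$dense[[d]][[f]], grads$dense[[d]][[f]],
               state$m$dense[[d]][[f]], state$v$dense[[d]][[f]])
      params$dense[[d]][[f]] <- r$p
      state$m$dense[[d]][[f]] <- r$m
      state$v$dense[[d]][[f]] <- r$v
    }
  }
  list(params = params, state = state)
}

# elementwise a*x + b*y over two gradient trees
grad_axpy <- function(a, gx, b, gy) {
  for (i in seq_along(gx$conv)) {
    gx$conv[[i]]$dW <- a * gx$conv[[i]]$dW + b * gy$conv[[i]]$dW
    gx$conv[[i]]$db <- a * gx$conv[[i]]$db + b * gy$conv[[i]]$db
  }
  for (i in seq_along(gx$dense)) {
    gx$dense[[i]]$W <- a * gx$dense[[i]]$W + b * gy$dense[[i]]$W
    gx$dense[[i]]$b <- a * gx$dense[[i]]$b + b * gy$dense[[i]]$b
  }
  gx
}
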