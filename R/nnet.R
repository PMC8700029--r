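# Forward and backward pass of the branch-fusion CNN, vectorised over the
# batch with im2col matrix products. Layout conventions:
#   input batch X: N x n_injectors x n_sensors x n_timesteps
#   im2col matrix per branch: (conv_len * N) x (kernel * sensors),
#     position fastest along rows, column = (offset - 1) * sensors + channel
#   conv weight W: (kernel * sensors) x filters, rows in the same order.

# Gather indices mapping the branch slice (N x sensors x timesteps, viewed
# as N x (sensors * timesteps)) to im2col columns, grouped by position.
im2col_index <- function(spec) {
  C <- spec$n_sensors; k <- spec$kernel_size
  P <- spec$n_timesteps - k + 1L
  idx <- integer(P * k * C)
  pos <- 1L
  for (p in seq_len(P)) {
    for (j in seq_len(k)) {
      t <- p + j - 1L
      idx[pos:(pos + C - 1L)] <- (t - 1L) * C + seq_len(C)
      pos <- pos + C
    }
  }
  idx
}

im2col <- function(Xb, spec, idx) {
  # Xb: N x C x T
  N <- dim(Xb)[1L]
  C <- spec$n_sensors; k <- spec$kernel_size
  P <- spec$n_timesteps - k + 1L
  Xmat <- Xb
  dim(Xmat) <- c(N, C * spec$n_timesteps)
  big <- Xmat[, idx, drop = FALSE]          # N x (kC * P), grouped by p
  dim(big) <- c(N, k * C, P)
  Xc <- aperm(big, c(3L, 1L, 2L))           # P x N x kC
  dim(Xc) <- c(P * N, k * C)
  Xc
}

# Full forward pass. `training` enables dropout (draws from the current RNG
# stream). Returns class probabilities plus the caches backward() needs.
nn_forward <- function(params, spec, X, training = FALSE,
                       keep_cache = FALSE) {
  N <- dim(X)[1L]
  d <- spec_dims(spec)
  P <- d$conv_len; Pp <- d$pool_len
  FLT <- spec$conv_filters
  keep <- 1 - spec$dropout_rate
  idx <- im2col_index(spec)

  H0 <- matrix(0, N, d$concat)
  caches <- if (keep_cache) vector("list", spec$n_injectors)
  for (b in seq_len(spec$n_injectors)) {
    Xb <- X[, b, , , drop = FALSE]
    dim(Xb) <- dim(X)[-2L]
    Xc <- im2col(Xb, spec, idx)                       # (P*N) x kC
    Z <- Xc %*% params$conv[[b]]$W
    Z <- sweep(Z, 2L, params$conv[[b]]$b, `+`)        # (P*N) x F
    relu_mask <- Z > 0
    A <- Z * relu_mask
    if (training && spec$dropout_rate > 0) {
      drop_mask <- matrix(
        (runif(length(A)) < keep) / keep, nrow(A), ncol(A))
      A <- A * drop_mask
    } else {
      drop_mask <- NULL
    }
    arr <- A
    dim(arr) <- c(P, N, FLT)
    # max-pooling over non-overlapping windows of pool_size positions
    pooled <- arr[seq(1L, by = spec$pool_size, length.out = Pp), , ,
                  drop = FALSE]
    argmax <- array(1L, dim(pooled))
    if (spec$pool_size > 1L) {
      for (o in 2:spec$pool_size) {
        cand <- arr[seq(o, by = spec$pool_size, length.out = Pp), , ,
                    drop = FALSE]
        better <- cand > pooled
        pooled[better] <- cand[better]
        argmax[better] <- o
      }
    }
    flat <- aperm(pooled, c(2L, 1L, 3L))              # N x Pp x F
    dim(flat) <- c(N, d$branch_flat)
    H0[, (b - 1L) * d$branch_flat + seq_len(d$branch_flat)] <- flat
    if (keep_cache) {
      caches[[b]] <- list(Xc = Xc, relu_mask = relu_mask,
                          drop_mask = drop_mask, argmax = argmax)
    }
  }
  Z1 <- sweep(H0 %*% params$W1, 2L, params$b1, `+`)
  A1 <- Z1 * (Z1 > 0)
  logits <- sweep(A1 %*% params$W2, 2L, params$b2, `+`)
  probs <- softmax(logits)
  list(probs = probs,
       cache = if (keep_cache) list(branches = caches, H0 = H0, Z1 = Z1,
                                    A1 = A1, N = N))
}

# Gradient of the mean sparse categorical cross-entropy w.r.t. all
# parameters. `fw` is the output of nn_forward(..., keep_cache = TRUE).
nn_backward <- function(params, spec, X, labels, fw) {
  d <- spec_dims(spec)
  N <- fw$cache$N
  P <- d$conv_len; Pp <- d$pool_len
  FLT <- spec$conv_filters

  Y <- matrix(0, N, spec$n_classes)
  Y[cbind(seq_len(N), labels + 1L)] <- 1
  dlogits <- (fw$probs - Y) / N

  A1 <- fw$cache$A1
  grads <- list(conv = vector("list", spec$n_injectors))
  grads$W2 <- crossprod(A1, dlogits)
  grads$b2 <- colSums(dlogits)
  dA1 <- tcrossprod(dlogits, params$W2)
  dZ1 <- dA1 * (fw$cache$Z1 > 0)
  grads$W1 <- crossprod(fw$cache$H0, dZ1)
  grads$b1 <- colSums(dZ1)
  dH0 <- tcrossprod(dZ1, params$W1)

  for (b in seq_len(spec$n_injectors)) {
    cb <- fw$cache$branches[[b]]
    dflat <- dH0[, (b - 1L) * d$branch_flat + seq_len(d$branch_flat),
                 drop = FALSE]
    dim(dflat) <- c(N, Pp, FLT)
    dpool <- aperm(dflat, c(2L, 1L, 3L))              # Pp x N x F
    dA <- array(0, c(P, N, FLT))
    base <- seq(0L, by = spec$pool_size, length.out = Pp)
    for (o in seq_len(spec$pool_size)) {
      sel <- cb$argmax == o
      rows <- base + o
      tmp <- array(0, c(Pp, N, FLT))
      tmp[sel] <- dpool[sel]
      dA[rows, , ] <- dA[rows, , , drop = FALSE] + tmp
    }
    dim(dA) <- c(P * N, FLT)
    if (!is.null(cb$drop_mask)) dA <- dA * cb$drop_mask
    dZ <- dA * cb$relu_mask
    grads$conv[[b]] <- list(W = crossprod(cb$Xc, dZ), b = colSums(dZ))
  }
  grads
}

# Mean loss and accuracy of a model on a tensor + labels, dropout off.
nn_eval <- function(params, spec, X, labels, chunk = 1024L) {
  N <- dim(X)[1L]
  loss_sum <- 0
  correct <- 0L
  for (start in seq(1L, N, by = chunk)) {
    ix <- start:min(start + chunk - 1L, N)
    Xc <- X[ix, , , , drop = FALSE]
    probs <- nn_forward(params, spec, Xc)$probs
    loss_sum <- loss_sum +
      categorical_cross_entropy(labels[ix], probs, reduction = "sum")
    pred <- predicted_class(probs)
    correct <- correct + sum(pred == labels[ix])
  }
  list(loss = loss_sum / N, accuracy = correct / N)
}

# Argmax with ties broken toward class 0: class k wins only if its
# probability strictly exceeds all earlier classes'.
predicted_class <- function(probs) {
  max.col(probs, ties.method = "first") - 1L
}
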