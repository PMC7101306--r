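# A small convolutional network trained from scratch.
#
# Architecture: 3x3 valid convolution (F filters) -> ReLU -> 2x2 max pool
# -> dense softmax over 2 classes. Implemented as vectorized base R: the
# convolution is an im2col gather followed by one matrix multiply per
# batch, so a full five-trial protocol on ~1500 block-colour images runs
# in minutes on one CPU. All randomness (init, shuffling) comes from R's
# RNG, so seeded runs are bit-reproducible.

# patch-gather index matrix: P[p, e] is the linear index into a
# res x res x 3 image of patch element e at output position p
cnn_im2col_indices <- function(res, k = 3L) {
  out <- res - k + 1L
  P <- matrix(0L, out * out, 3L * k * k)
  e <- 0L
  for (d in 1:3) {
    for (dj in 0:(k - 1L)) {
      for (di in 0:(k - 1L)) {
        e <- e + 1L
        oi <- rep(seq_len(out), out)
        oj <- rep(seq_len(out), each = out)
        P[, e] <- (oi + di) + (oj + dj - 1L) * res + (d - 1L) * res * res
      }
    }
  }
  P
}

# pool-group index matrix: G[q, s] is the conv-output position of slot s
# (of 4) in pool cell q, for an out x out grid pooled 2x2
cnn_pool_indices <- function(out) {
  po <- out %/% 2L
  G <- matrix(0L, po * po, 4L)
  q <- 0L
  for (pj in seq_len(po)) {
    for (pi in seq_len(po)) {
      q <- q + 1L
      i <- 2L * pi - 1L; j <- 2L * pj - 1L
      G[q, ] <- c(i + (j - 1L) * out, i + 1L + (j - 1L) * out,
                  i + j * out, i + 1L + j * out)
    }
  }
  G
}

cnn_init <- function(res, n_filters) {
  out <- res - 2L
  po <- out %/% 2L
  d_dense <- po * po * n_filters
  list(W1 = matrix(stats::rnorm(27 * n_filters, 0, sqrt(2 / 27)),
                   27, n_filters),
       b1 = numeric(n_filters),
       W2 = matrix(stats::rnorm(d_dense * 2, 0, sqrt(2 / d_dense)),
                   d_dense, 2),
       b2 = numeric(2),
       res = res, out = out, po = po, n_filters = n_filters)
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# forward pass; returns softmax probabilities and, if keep = TRUE, the
# intermediates needed for the backward pass
cnn_forward <- function(net, x, P, G, keep = FALSE) {
  B <- nrow(x)
  out2 <- net$out^2
  M <- (x - 0.5)[, as.vector(P), drop = FALSE]
  dim(M) <- c(B * out2, 27L)
  Z <- add_bias(M %*% net$W1, net$b1)
  Zr <- Z * (Z > 0)
  H <- matrix(0, B, net$po^2 * net$n_filters)
  masks <- if (keep) vector("list", net$n_filters) else NULL
  for (f in seq_len(net$n_filters)) {
    Zf <- Zr[, f]
    dim(Zf) <- c(B, out2)
    z1 <- Zf[, G[, 1], drop = FALSE]; z2 <- Zf[, G[, 2], drop = FALSE]
    z3 <- Zf[, G[, 3], drop = FALSE]; z4 <- Zf[, G[, 4], drop = FALSE]
    pooled <- pmax(z1, z2, z3, z4)
    H[, (f - 1) * net$po^2 + seq_len(net$po^2)] <- pooled
    if (keep) {
      m1 <- z1 == pooled
      m2 <- (z2 == pooled) & !m1
      m3 <- (z3 == pooled) & !m1 & !m2
      m4 <- (z4 == pooled) & !m1 & !m2 & !m3
      masks[[f]] <- list(m1, m2, m3, m4)
    }
  }
  logits <- add_bias(H %*% net$W2, net$b2)
  mx <- pmax(logits[, 1], logits[, 2])
  ez <- exp(logits - mx)
  probs <- ez / rowSums(ez)
  if (!keep) return(list(probs = probs))
  list(probs = probs, M = M, Z = Z, H = H, masks = masks, B = B)
}

cnn_backward <- function(net, fwd, yidx, G) {
  B <- fwd$B
  out2 <- net$out^2
  Y <- matrix(0, B, 2)
  Y[cbind(seq_len(B), yidx)] <- 1
  dlog <- (fwd$probs - Y) / B
  dW2 <- crossprod(fwd$H, dlog)
  db2 <- colSums(dlog)
  dH <- tcrossprod(dlog, net$W2)
  dZ <- matrix(0, B * out2, net$n_filters)
  for (f in seq_len(net$n_filters)) {
    dPf <- dH[, (f - 1) * net$po^2 + seq_len(net$po^2), drop = FALSE]
    dZf <- matrix(0, B, out2)
    mk <- fwd$masks[[f]]
    for (s in 1:4) dZf[, G[, s]] <- dPf * mk[[s]]
    dZ[, f] <- as.vector(dZf)
  }
  dZ <- dZ * (fwd$Z > 0)
  dW1 <- crossprod(fwd$M, dZ)
  db1 <- colSums(dZ)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

adam_state <- function(net) {
  params <- c("W1", "b1", "W2", "b2")
  list(m = lapply(params, function(p) net[[p]] * 0),
       v = lapply(params, function(p) net[[p]] * 0),
       t = 0)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  params <- c("W1", "b1", "W2", "b2")
  state$t <- state$t + 1
  for (i in seq_along(params)) {
    p <- params[i]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[p]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[p]]^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    net[[p]] <- net[[p]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(net = net, state = state)
}

cnn_loss <- function(probs, yidx) {
  -mean(log(pmax(probs[cbind(seq_along(yidx), yidx)], 1e-12)))
}

# train the small CNN; x: n x (res^2*3) in [0,1], yidx: 1 = first level
cnn_train <- function(x, yidx, x_val, yidx_val, res, n_filters, lr, epochs,
                      batch_size, seed) {
  with_seed(seed, {
    net <- cnn_init(res, n_filters)
    P <- cnn_im2col_indices(res)
    G <- cnn_pool_indices(net$out)
    state <- adam_state(net)
    n <- nrow(x)
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_accuracy = numeric(0))
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        fwd <- cnn_forward(net, x[idx, , drop = FALSE], P, G, keep = TRUE)
        losses <- c(losses, cnn_loss(fwd$probs, yidx[idx]))
        grads <- cnn_backward(net, fwd, yidx[idx], G)
        upd <- adam_step(net, grads, state, lr)
        net <- upd$net; state <- upd$state
      }
      val_acc <- if (is.null(x_val) || nrow(x_val) == 0) NA_real_ else {
        pv <- cnn_predict_probs(net, x_val, P, G)
        mean((pv[, 1] >= 0.5) == (yidx_val == 1))
      }
      log <- rbind(log, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_accuracy = val_acc))
    }
    list(net = net, log = log)
  })
}

cnn_predict_probs <- function(net, x, P = NULL, G = NULL, chunk = 64L) {
  if (is.null(P)) P <- cnn_im2col_indices(net$res)
  if (is.null(G)) G <- cnn_pool_indices(net$out)
  n <- nrow(x)
  probs <- matrix(0, n, 2)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    probs[idx, ] <- cnn_forward(net, x[idx, , drop = FALSE], P, G)$probs
  }
  probs
}

# linear softmax head over precomputed features (the transfer-learning
# final-layer-replacement recipe)
head_train <- function(feats, yidx, lr, epochs, batch_size, seed) {
  with_seed(seed, {
    d <- ncol(feats)
    net <- list(W = matrix(stats::rnorm(d * 2, 0, sqrt(1 / d)), d, 2),
                b = numeric(2))
    m <- list(W = net$W * 0, b = net$b * 0)
    v <- m; tstep <- 0
    n <- nrow(feats)
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_accuracy = numeric(0))
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        Fb <- feats[idx, , drop = FALSE]
        logits <- add_bias(Fb %*% net$W, net$b)
        mx <- pmax(logits[, 1], logits[, 2])
        ez <- exp(logits - mx)
        probs <- ez / rowSums(ez)
        losses <- c(losses, cnn_loss(probs, yidx[idx]))
        Y <- matrix(0, length(idx), 2)
        Y[cbind(seq_along(idx), yidx[idx])] <- 1
        dlog <- (probs - Y) / length(idx)
        g <- list(W = crossprod(Fb, dlog), b = colSums(dlog))
        tstep <- tstep + 1
        for (p in c("W", "b")) {
          m[[p]] <- 0.9 * m[[p]] + 0.1 * g[[p]]
          v[[p]] <- 0.999 * v[[p]] + 0.001 * g[[p]]^2
          net[[p]] <- net[[p]] - lr * (m[[p]] / (1 - 0.9^tstep)) /
            (sqrt(v[[p]] / (1 - 0.999^tstep)) + 1e-8)
        }
      }
      log <- rbind(log, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_accuracy = NA_real_))
    }
    list(net = net, log = log)
  })
}

head_predict_probs <- function(net, feats) {
  logits <- add_bias(feats %*% net$W, net$b)
  mx <- pmax(logits[, 1], logits[, 2])
  ez <- exp(logits - mx)
  ez / rowSums(ez)
}
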