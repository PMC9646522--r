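# Small convolutional network over the window axis of per-bin feature
# matrices, implemented directly with matrix operations (im2col convolutions,
# full-batch Adam on mean squared error). Architecture: two convolution
# blocks (ReLU) -> global average pooling -> optional concatenation of extra
# scalar inputs (flanking counts) -> dense layer to the embedding -> linear
# head to the predicted count. The embedding (not the head output) is what
# the Gaussian process consumes downstream.

# input array C x W x N, kernel width k -> matrix (C*k) x (Wout*N),
# column index (n-1)*Wout + w
.im2col <- function(X, k) {
  C <- dim(X)[1]; W <- dim(X)[2]; N <- dim(X)[3]
  Wout <- W - k + 1L
  stopifnot(Wout >= 1L)
  out <- matrix(0, nrow = C * k, ncol = Wout * N)
  for (o in seq_len(k)) {
    sl <- X[, o:(o + Wout - 1L), , drop = FALSE]
    dim(sl) <- c(C, Wout * N)
    out[((o - 1L) * C + 1L):(o * C), ] <- sl
  }
  out
}

# gradient counterpart of .im2col: (C*k) x (Wout*N) -> C x W x N accumulation
.col2im <- function(G, C, k, W, N) {
  Wout <- W - k + 1L
  out <- array(0, dim = c(C, W, N))
  for (o in seq_len(k)) {
    sl <- G[((o - 1L) * C + 1L):(o * C), , drop = FALSE]
    dim(sl) <- c(C, Wout, N)
    out[, o:(o + Wout - 1L), ] <- out[, o:(o + Wout - 1L), ] + sl
  }
  out
}

.nnInit <- function(Tn, W, nExtra, config) {
  f <- config$convFilters; k <- config$kernelWidths; E <- config$embeddingDim
  he <- function(nr, nc, fanin) matrix(stats::rnorm(nr * nc, 0,
                                                    sqrt(2 / fanin)), nr, nc)
  list(W1 = he(f[1], Tn * k[1], Tn * k[1]), b1 = numeric(f[1]),
       W2 = he(f[2], f[1] * k[2], f[1] * k[2]), b2 = numeric(f[2]),
       We = he(E, f[2] + nExtra, f[2] + nExtra), be = numeric(E),
       wh = he(1, E, E), bh = 0)
}

# forward pass; returns intermediates when grad = TRUE
.nnForward <- function(par, X, extra, k1, k2, grad = FALSE) {
  Tn <- dim(X)[1]; W <- dim(X)[2]; N <- dim(X)[3]
  A1 <- .im2col(X, k1)
  Z1 <- par$W1 %*% A1 + par$b1
  H1 <- pmax(Z1, 0)
  F1 <- nrow(par$W1); W1w <- W - k1 + 1L
  H1a <- array(H1, dim = c(F1, W1w, N))
  A2 <- .im2col(H1a, k2)
  Z2 <- par$W2 %*% A2 + par$b2
  H2 <- pmax(Z2, 0)
  F2 <- nrow(par$W2); W2w <- W1w - k2 + 1L
  H2a <- array(H2, dim = c(F2, W2w, N))
  P <- colMeans(aperm(H2a, c(2, 1, 3)))       # F2 x N
  if (!is.matrix(P)) P <- matrix(P, nrow = F2, ncol = N)
  Pe <- if (is.null(extra)) P else rbind(P, extra)
  Emb <- par$We %*% Pe + par$be
  yhat <- as.vector(par$wh %*% Emb) + par$bh
  if (!grad) return(list(yhat = yhat, emb = Emb))
  list(yhat = yhat, emb = Emb, A1 = A1, Z1 = Z1, A2 = A2, Z2 = Z2,
       Pe = Pe, W1w = W1w, W2w = W2w, F1 = F1, F2 = F2, N = N)
}

.nnGrad <- function(par, fw, y, nExtra, k2) {
  N <- fw$N
  dyhat <- matrix(2 * (fw$yhat - y) / N, nrow = 1)
  g <- list()
  g$wh <- dyhat %*% t(fw$emb)
  g$bh <- sum(dyhat)
  dEmb <- t(par$wh) %*% dyhat
  g$We <- dEmb %*% t(fw$Pe)
  g$be <- rowSums(dEmb)
  dPe <- t(par$We) %*% dEmb
  dP <- dPe[seq_len(fw$F2), , drop = FALSE]
  dH2 <- dP[, rep(seq_len(N), each = fw$W2w), drop = FALSE] / fw$W2w
  dZ2 <- dH2 * (fw$Z2 > 0)
  g$W2 <- dZ2 %*% t(fw$A2)
  g$b2 <- rowSums(dZ2)
  dA2 <- t(par$W2) %*% dZ2
  dH1a <- .col2im(dA2, fw$F1, k2, fw$W1w, N)
  dH1 <- dH1a; dim(dH1) <- c(fw$F1, fw$W1w * N)
  dZ1 <- dH1 * (fw$Z1 > 0)
  g$W1 <- dZ1 %*% t(fw$A1)
  g$b1 <- rowSums(dZ1)
  g
}

.adamStep <- function(par, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(g)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(par = par, state = state)
}

# trains on (Xtr, ytr) with early stopping on (Xva, yva); y already scaled
.nnTrain <- function(Xtr, extraTr, ytr, Xva, extraVa, yva, config) {
  k1 <- config$kernelWidths[1]; k2 <- config$kernelWidths[2]
  if (config$epochs < 1L) stop("at least one training epoch is required")
  nExtra <- if (is.null(extraTr)) 0L else nrow(extraTr)
  par <- .nnInit(dim(Xtr)[1], dim(Xtr)[2], nExtra, config)
  state <- list(m = lapply(par, function(p) p * 0),
                v = lapply(par, function(p) p * 0))
  best <- list(par = par, val = Inf, epoch = 0L)
  wait <- 0L
  for (ep in seq_len(config$epochs)) {
    fw <- .nnForward(par, Xtr, extraTr, k1, k2, grad = TRUE)
    if (!all(is.finite(fw$yhat))) stop("non-finite loss during training")
    g <- .nnGrad(par, fw, ytr, nExtra, k2)
    st <- .adamStep(par, g, state, config$lr, ep)
    par <- st$par; state <- st$state
    fv <- .nnForward(par, Xva, extraVa, k1, k2)
    val <- mean((fv$yhat - yva)^2)
    if (!is.finite(val)) stop("non-finite validation loss")
    if (val < best$val - 1e-10) {
      best <- list(par = par, val = val, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  best
}
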