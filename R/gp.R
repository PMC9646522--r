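# Exact Gaussian-process regression with an isotropic RBF kernel and learned
# observation noise, used as the predictive head over the network embeddings.
# Hyperparameters (signal variance, lengthscale, noise variance) maximise the
# log marginal likelihood via L-BFGS-B on their logs with analytic gradients.
# Beyond .gpMaxExact training points a seeded random subset is used.

.gpSqDist <- function(A, B = A) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  pmax(d2, 0)
}

.gpMaxExact <- 2000L

.gpNll <- function(logp, D2, y, jitter = 1e-8) {
  s2 <- exp(logp[1]); ell2 <- exp(2 * logp[2]); noise <- exp(logp[3])
  n <- length(y)
  K0 <- exp(-0.5 * D2 / ell2)
  K <- s2 * K0 + diag(noise + jitter, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(list(nll = 1e10, grad = c(0, 0, 0)))
  alpha <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(ch)
  A <- Kinv - tcrossprod(alpha)          # K^-1 - alpha alpha^T
  gs2 <- 0.5 * sum(A * (s2 * K0))
  gell <- 0.5 * sum(A * (s2 * K0 * (D2 / ell2)))
  gnoise <- 0.5 * sum(diag(A)) * noise
  list(nll = nll, grad = c(gs2, gell, gnoise))
}

# X: n x d embeddings; y: observed (scaled) counts
.gpFit <- function(X, y, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n > .gpMaxExact) {
    keep <- withr::with_seed(seed, sample.int(n, .gpMaxExact))
    X <- X[keep, , drop = FALSE]; y <- y[keep]
    n <- .gpMaxExact
  }
  D2 <- .gpSqDist(X)
  med <- stats::median(sqrt(D2[upper.tri(D2)]))
  if (!is.finite(med) || med <= 0) med <- 1
  vy <- stats::var(y); if (!is.finite(vy) || vy <= 0) vy <- 1
  init <- log(c(vy, med, 0.1 * vy))
  env <- new.env()
  fn <- function(p) { r <- .gpNll(p, D2, y); env$g <- r$grad; r$nll }
  gr <- function(p) env$g
  opt <- stats::optim(init, fn, gr, method = "L-BFGS-B",
                      lower = log(c(1e-6 * vy, 1e-3 * med, 1e-6 * vy)),
                      upper = log(c(1e3 * vy, 1e3 * med, 1e2 * vy)),
                      control = list(maxit = 200))
  s2 <- exp(opt$par[1]); ell <- exp(opt$par[2]); noise <- exp(opt$par[3])
  K <- s2 * exp(-0.5 * D2 / ell^2) + diag(noise + 1e-8, n)
  ch <- chol(K)
  alpha <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  list(X = X, alpha = alpha, chol = ch, s2 = s2, ell = ell, noise = noise)
}

# predictive mean and variance; var includes the observation-noise term,
# varEpi is the epistemic (kernel) part only
.gpPredict <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  D2 <- .gpSqDist(Xnew, fit$X)
  Ks <- fit$s2 * exp(-0.5 * D2 / fit$ell^2)
  mu <- as.vector(Ks %*% fit$alpha)
  V <- backsolve(fit$chol, t(Ks), transpose = TRUE)   # solves L v = k*
  varEpi <- pmax(fit$s2 - colSums(V^2), 0)
  list(mu = mu, var = pmax(varEpi + fit$noise, 1e-10),
       varEpi = pmax(varEpi, 1e-10))
}
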