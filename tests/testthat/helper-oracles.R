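## Independent oracles used by the test suite. These deliberately avoid the
## package's own computational paths: normal equations via solve(), brute
## force pair enumeration, projected (proximal) gradient descent, and
## batch-means Monte-Carlo standard errors.

## OLS by explicit normal equations; returns coefficients, SEs and
## two-sided t-test p-values.
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  bhat <- solve(XtX, crossprod(X, y))
  r <- y - X %*% bhat
  df <- nrow(X) - ncol(X)
  s2 <- sum(r^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  tval <- bhat / se
  list(beta = as.vector(bhat), se = as.vector(se),
       p = as.vector(2 * pt(-abs(tval), df)), df = df)
}

## Ridge closed form at penalty lambda (no intercept; X, y as given).
ridge_oracle <- function(X, y, lambda) {
  solve(crossprod(X) + diag(lambda, ncol(X)), crossprod(X, y))[, 1]
}

## AUC by O(n^2) enumeration over all case-control pairs.
auc_bruteforce <- function(labels, s) {
  lab <- as.logical(labels)
  cs <- s[lab]
  ct <- s[!lab]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

## PR-AUC by explicit threshold-by-threshold enumeration (descending
## unique scores; average-precision step rule, no (0,1) interpolation).
prauc_enumeration <- function(labels, s) {
  lab <- as.logical(labels)
  ths <- sort(unique(s), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  for (th in ths) {
    sel <- s >= th
    tp <- sum(lab & sel)
    prec <- tp / sum(sel)
    rec <- tp / sum(lab)
    area <- area + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  area
}

## Proximal-gradient (ISTA) solver for the elastic net
##   (1/2n)||y - b0 - X b||^2 + lambda (alpha |b|_1 + (1-alpha)/2 |b|_2^2)
## run to tight convergence; independent of glmnet's coordinate descent.
enet_prox_oracle <- function(X, y, lambda, alpha, max_iter = 200000,
                             tol = 1e-12) {
  n <- nrow(X)
  p <- ncol(X)
  b <- rep(0, p)
  b0 <- mean(y)
  L <- (max(svd(X, nu = 0, nv = 0)$d)^2) / n + lambda * (1 - alpha)
  step <- 1 / L
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    r <- y - b0 - as.vector(X %*% b)
    grad <- -as.vector(crossprod(X, r)) / n + lambda * (1 - alpha) * b
    b <- soft(b - step * grad, step * lambda * alpha)
    b0 <- mean(y - as.vector(X %*% b))
    if (it %% 50 == 0) {
      obj <- sum((y - b0 - as.vector(X %*% b))^2) / (2 * n) +
        lambda * (alpha * sum(abs(b)) + (1 - alpha) / 2 * sum(b^2))
      if (abs(obj_prev - obj) < tol * max(1, abs(obj))) break
      obj_prev <- obj
    }
  }
  list(intercept = b0, beta = b)
}

## Batch-means Monte-Carlo standard error of a chain's mean (robust to
## autocorrelation).
mcse_batch <- function(x, n_batches = 50) {
  n <- length(x)
  bs <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches), function(b)
    mean(x[((b - 1) * bs + 1):(b * bs)]), numeric(1))
  sd(means) / sqrt(n_batches)
}

## Standardize columns to population variance 1 (test-local copy).
std_cols <- function(X) {
  Xc <- sweep(X, 2, colMeans(X), "-")
  sweep(Xc, 2, sqrt(colMeans(Xc^2)), "/")
}

std_vec <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
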