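## Internal helpers shared across modules.

#' Derive a per-operation RNG seed from a master seed
#'
#' Each stochastic operation draws from its own stream so that adding a new
#' simulation never shifts the draws of an existing one. The rule is a single
#' multiplicative-congruential step (Lehmer multiplier 48271 modulo 2^31 - 1)
#' keyed by a small integer stream id; the result is a valid 32-bit R seed.
#'
#' @param seed master seed (integer).
#' @param stream stream id (small non-negative integer, one per operation).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream = 0L) {
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(seed) %% m) + 1
  out <- (s * 48271 + as.numeric(stream) * 104729) %% m
  as.integer(out + 1)
}

## Population (1/n) variance: the package-wide convention so that
## "scaled to variance 1" holds exactly at any n.
popvar <- function(x) {
  mean((x - mean(x))^2)
}

## Standardize to mean 0, population variance 1.
standardize <- function(x) {
  v <- popvar(x)
  if (v <= 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / sqrt(v)
}

## Column-wise standardization of a matrix; returns NULL-variance columns'
## indices via attribute "dropped" after removing them.
standardize_cols <- function(X, tol = 1e-12) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  v <- colMeans(Xc^2)
  keep <- v > tol
  Xs <- sweep(Xc[, keep, drop = FALSE], 2L, sqrt(v[keep]), "/")
  attr(Xs, "dropped") <- which(!keep)
  Xs
}

## Convert methylation fractions (beta values) to M-values and back.

#' Logit (M-value) transform of methylation beta values
#'
#' Beta values are clamped away from 0 and 1 by `eps` before the logit, the
#' standard guard used when array or count-derived fractions hit the
#' boundary.
#'
#' @param beta matrix or vector of methylation fractions in `[0, 1]`.
#' @param eps boundary clamp.
#' @return M-values, `log(beta / (1 - beta))`.
#' @export
beta_to_mvalue <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  qlogis(b)
}

#' Inverse logit, mapping M-values back to methylation fractions
#' @param m M-value matrix or vector.
#' @return beta values in `(0, 1)`.
#' @export
mvalue_to_beta <- function(m) {
  plogis(m)
}

## Residualize columns of Y on a covariate design (with intercept) via QR.
## Returns the residual matrix.
residualize_on <- function(Y, design) {
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) stop("covariate matrix is rank deficient")
  Y - design %*% qr.coef(qr_d, Y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
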