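std_instance <- function(n, p, seed, h2 = 0.3, n_causal = 1) {
  set.seed(seed)
  X <- std_cols(matrix(rnorm(n * p), n, p))
  colnames(X) <- sprintf("cg%04d", seq_len(p))
  b <- rep(0, p)
  if (n_causal > 0) b[seq_len(n_causal)] <- sqrt(h2 / n_causal)
  g <- as.vector(X %*% b)
  y <- std_vec(g + rnorm(n, 0, sqrt(max(1 - h2, 1e-12))))
  list(X = X, y = y)
}

test_that("retained-sample count and determinism are exact", {
  d <- std_instance(60, 20, seed = 1)
  ch <- chain_config(burn_in = 50, post_burn_iterations = 212, thin = 5,
                     seed = 99)
  a <- run_gibbs(d$X, d$y, chain = ch)
  expect_equal(a$n_retained, floor(212 / 5))
  expect_equal(length(a$vexp), 42)
  b <- run_gibbs(d$X, d$y, chain = ch)
  expect_identical(a$pip, b$pip)
  expect_identical(a$vexp, b$vexp)
})

test_that("non-standardized inputs are rejected", {
  d <- std_instance(40, 5, seed = 2)
  expect_error(run_gibbs(d$X + 1, d$y), "standardized")
  expect_error(run_gibbs(d$X, d$y * 3), "standardized")
  bad <- d$X
  bad[1, 1] <- NA
  expect_error(run_gibbs(bad, d$y), "missing")
})

test_that("incremental residual equals y - X beta throughout the chain", {
  d <- std_instance(50, 30, seed = 3)
  out <- run_gibbs(d$X, d$y,
                   chain = chain_config(burn_in = 20,
                                        post_burn_iterations = 100,
                                        thin = 5, seed = 4),
                   check_residual = TRUE)
  expect_lt(out$max_residual_drift, 1e-8)
  expect_equal(out$residual_last,
               d$y - as.vector(d$X %*% out$beta_last), tolerance = 1e-10)
})

test_that("single-predictor conjugate posterior matches the closed form", {
  set.seed(7)
  n <- 200
  x <- std_vec(rnorm(n))
  y <- std_vec(0.5 * x + rnorm(n, 0, 0.9))
  s2e <- 0.8
  s2b <- 0.5
  prior <- mixture_prior(spike = FALSE,
                         slab_active = c(FALSE, FALSE, FALSE, TRUE),
                         fixed_pi = 1,
                         fixed_sigma2_beta = s2b, fixed_sigma2_e = s2e)
  out <- run_gibbs(cbind(cg1 = x), y, prior = prior,
                   chain = chain_config(burn_in = 200,
                                        post_burn_iterations = 5000,
                                        thin = 1, seed = 5))
  xtx <- sum(x^2)
  closed <- sum(x * y) / (xtx + s2e / s2b)
  draws_mean <- out$post_mean[1]
  ## single predictor: full-conditional draws are iid, so the MCSE of the
  ## chain mean is post_sd / sqrt(S)
  post_sd <- sqrt(s2e / (xtx + s2e / s2b))
  expect_lt(abs(draws_mean - closed), 3 * post_sd / sqrt(5000))
})

test_that("spike-free single-slab fixed-variance chain attains the ridge limit", {
  set.seed(11)
  n <- 300
  p <- 5
  X <- std_cols(matrix(rnorm(n * p), n, p))
  colnames(X) <- paste0("cg", 1:p)
  y <- std_vec(as.vector(X %*% c(0.4, -0.3, 0.2, 0, 0)) + rnorm(n, 0, 0.8))
  s2e <- 0.7
  s2b <- 0.3
  prior <- mixture_prior(spike = FALSE,
                         slab_active = c(FALSE, FALSE, FALSE, TRUE),
                         fixed_pi = 1,
                         fixed_sigma2_beta = s2b, fixed_sigma2_e = s2e)
  out <- run_gibbs(X, y, prior = prior,
                   chain = chain_config(burn_in = 500,
                                        post_burn_iterations = 8000,
                                        thin = 1, seed = 13))
  ridge <- ridge_oracle(X, y, lambda = s2e / s2b)
  ## posterior sd per coordinate bounds the MC error of the chain mean
  post_sd <- sqrt(s2e / (colSums(X^2) + s2e / s2b))
  expect_true(all(abs(out$post_mean - ridge) <
                    4 * post_sd / sqrt(8000 / 10)))
})

test_that("null data keep PIPs near the prior floor and vexp small", {
  d <- std_instance(300, 400, seed = 17, h2 = 0, n_causal = 0)
  out <- run_gibbs(d$X, d$y,
                   chain = chain_config(burn_in = 300,
                                        post_burn_iterations = 600,
                                        thin = 5, seed = 19))
  expect_lt(mean(out$pip), 0.8 + 0.02) # prior inclusion mass 4/5
  expect_lt(mean(out$vexp), 0.25)
})

test_that("a strong causal CpG is recovered with high PIP", {
  d <- std_instance(500, 300, seed = 23, h2 = 0.3, n_causal = 1)
  out <- run_gibbs(d$X, d$y,
                   chain = chain_config(burn_in = 300,
                                        post_burn_iterations = 1000,
                                        thin = 5, seed = 29))
  expect_gt(out$pip[1], 0.95)
  expect_equal(which.max(abs(out$post_mean)), 1L)
})

test_that("variance_explained summarises the chain correctly", {
  fake <- structure(list(vexp = c(0.40, 0.45, 0.50, 0.55, 0.60)),
                    class = "posterior_summary")
  ve <- variance_explained(fake)
  expect_equal(ve[["mean"]], 0.5)
  expect_error(variance_explained(structure(list(vexp = 0.1),
                                            class = "posterior_summary")),
               "at least 2")

  ## an all-spike chain gives identically zero variance explained
  d <- std_instance(40, 6, seed = 31)
  prior <- mixture_prior(fixed_pi = c(1, 0, 0, 0, 0))
  out <- run_gibbs(d$X, d$y, prior = prior,
                   chain = chain_config(burn_in = 10,
                                        post_burn_iterations = 50,
                                        thin = 5, seed = 3))
  expect_equal(unname(variance_explained(out)), c(0, 0, 0))
})

test_that("tiered PIP calling uses strict thresholds", {
  pips <- c(a = 0.99, b = 0.85, c = 0.50)
  tiers <- call_significant(pips)
  expect_equal(tiers$pip_gt_0.95, "a")
  expect_equal(tiers$pip_gt_0.8, c("a", "b"))
  expect_equal(call_significant(c(x = 0.95))$pip_gt_0.95, character(0))
  expect_equal(call_significant(numeric(0))$pip_gt_0.8, character(0))
  ## 0.95 tier is always a subset of the 0.80 tier
  set.seed(1)
  pp <- runif(200)
  tt <- call_significant(pp)
  expect_true(all(tt$pip_gt_0.95 %in% tt$pip_gt_0.8))
})
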