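test_that("prefilter restricts to the allowed list", {
  M <- matrix(rnorm(50), 5, 10,
              dimnames = list(NULL, sprintf("cg%02d", 1:10)))
  expect_identical(suppressMessages(prefilter_sites(M, colnames(M))), M)
  expect_error(prefilter_sites(M, c("x", "y")), "no overlap")
  out <- suppressMessages(prefilter_sites(M, c("cg01", "cg05", "cg07",
                                               "zz")))
  expect_equal(colnames(out), c("cg01", "cg05", "cg07"))
})

test_that("penalty limits: lambda beyond lambda_max zeroes all weights; lambda ~ 0 recovers OLS", {
  set.seed(71)
  n <- 50
  ## near-orthonormal design via QR
  Q <- qr.Q(qr(matrix(rnorm(n * 8), n, 8))) * sqrt(n)
  colnames(Q) <- paste0("cg", 1:8)
  b <- c(1, -2, 0.5, rep(0, 5))
  y <- as.vector(Q %*% b) + rnorm(n, 0, 0.3)

  huge <- train_elastic_net(Q, y, lambda_fixed = 1e4, standardize = FALSE)
  expect_equal(length(huge$weights), 0)
  expect_equal(huge$intercept, mean(y), tolerance = 1e-8)

  tiny <- train_elastic_net(Q, y, lambda_fixed = 1e-10,
                            standardize = FALSE)
  ols <- ols_oracle(cbind(1, Q), y)
  w <- setNames(rep(0, 8), colnames(Q))
  w[names(tiny$weights)] <- tiny$weights
  expect_equal(unname(w), ols$beta[-1], tolerance = 1e-6)
})

test_that("solutions satisfy elastic-net KKT and beat the prox oracle objective", {
  set.seed(73)
  n <- 80
  p <- 200
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("cg%03d", 1:p)))
  b <- c(rnorm(10), rep(0, p - 10))
  ## unit-variance target: the scaling under which the KKT contract holds
  y <- std_vec(as.vector(X %*% b) + rnorm(n))
  lam <- 0.05
  fit <- train_elastic_net(X, y, alpha = 0.5, lambda_fixed = lam,
                           standardize = FALSE)
  beta <- setNames(rep(0, p), colnames(X))
  beta[names(fit$weights)] <- fit$weights
  expect_lt(enet_kkt_residual(X, y, fit$intercept, beta, lam, 0.5), 1e-6)
  orc <- enet_prox_oracle(X, y, lam, 0.5)
  expect_lte(enet_objective(X, y, fit$intercept, beta, lam, 0.5),
             enet_objective(X, y, orc$intercept, orc$beta, lam, 0.5) +
               1e-6)
})

test_that("cross-validation is seed-reproducible and the path is monotone in sparsity", {
  set.seed(79)
  n <- 120
  p <- 60
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("cg%03d", 1:p)))
  y <- as.vector(X[, 1:5] %*% rep(0.5, 5)) + rnorm(n)
  m1 <- train_elastic_net(X, y, seed = 5)
  m2 <- train_elastic_net(X, y, seed = 5)
  expect_identical(m1$lambda_selected, m2$lambda_selected)
  expect_identical(m1$weights, m2$weights)
  m3 <- train_elastic_net(X, y, seed = 6)
  expect_true(is.numeric(m3$lambda_selected))

  ## sparsity non-increasing as lambda grows along the path (orthonormal
  ## design, where the path is monotone by construction)
  Q <- qr.Q(qr(matrix(rnorm(n * 20), n, 20))) * sqrt(n)
  yq <- std_vec(as.vector(Q[, 1:4] %*% c(2, -1, 0.5, 0.25)) + rnorm(n))
  fitq <- glmnet::glmnet(Q, yq, alpha = 0.5, standardize = FALSE)
  nz <- colSums(as.matrix(fitq$beta) != 0)
  expect_true(all(diff(nz[order(fitq$lambda)]) <= 0))
})

test_that("scoring applies weights with training-mean imputation", {
  model <- structure(list(intercept = 1,
                          weights = c(cg1 = 2),
                          training_means = c(cg1 = 0.25),
                          alpha = 0.5, lambda_selected = 0.1,
                          n = 10L, n_features_prefilter = 1L,
                          standardize = TRUE),
                     class = "biomarker_model")
  M <- matrix(0.5, 1, 1, dimnames = list("s1", "cg1"))
  expect_equal(score(model, M), 2.0)
  M2 <- matrix(0.9, 1, 1, dimnames = list("s1", "cgX"))
  expect_equal(suppressWarnings(suppressMessages(score(model, M2))), 1.5)
  expect_error(suppressMessages(score(model, M2, strict = TRUE)),
               "absent")
  ## all-zero weights: score is the intercept everywhere
  m0 <- model
  m0$weights <- m0$weights[0]
  m0$training_means <- m0$training_means[0]
  expect_equal(score(m0, matrix(rnorm(6), 3, 2,
                                dimnames = list(NULL, c("a", "b")))),
               rep(1, 3))
})

test_that("single-site model is exact least squares", {
  m <- c(0.2, 0.4, 0.5, 0.7, 0.9)
  expect_equal(unname(train_single_site(m, 3 * m)$weights), 3,
               tolerance = 1e-12)
  expect_equal(train_single_site(m, 3 * m)$intercept, 0,
               tolerance = 1e-12)
  ## 5-point hand dataset: slope = Sxy/Sxx
  y <- c(1.1, 0.8, 1.6, 2.1, 2.4)
  sl <- sum((m - mean(m)) * (y - mean(y))) / sum((m - mean(m))^2)
  expect_equal(unname(train_single_site(m, y)$weights), sl)
  expect_error(train_single_site(rep(0.5, 5), y), "constant")
  ## orthogonal target: slope within 2 SE of zero
  set.seed(83)
  mm <- rnorm(500, 0.5, 0.1)
  yy <- rnorm(500)
  fit <- train_single_site(mm, yy)
  se <- sqrt(sum((yy - mean(yy))^2) / 498 / sum((mm - mean(mm))^2))
  expect_lt(abs(unname(fit$weights)), 3 * se)
})

test_that("weights TSV round trip preserves the model", {
  set.seed(89)
  X <- matrix(rnorm(300), 30, 10,
              dimnames = list(NULL, sprintf("cg%02d", 1:10)))
  y <- X[, 1] + rnorm(30)
  m <- train_elastic_net(X, y, n_folds = 5, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_biomarker_tsv(m, f)
  back <- read_biomarker_tsv(f)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$weights, m$weights)
  expect_equal(back$training_means, m$training_means)
  ## projected scores agree
  expect_equal(score(back, X), score(m, X))
})

test_that("score transfer: multi-site beats the single-site comparator", {
  cfg <- sim_config(n_individuals = 700, n_cpgs = 300, target_h2 = 0.6,
                    spike_fraction = 0.9,
                    slab_proportions = c(0.06, 0.03, 0.008, 0.002),
                    never_smoker_fraction = 0, seed = 97)
  train <- simulate_methylation_cohort(cfg)
  test <- simulate_methylation_cohort(
    sim_config(n_individuals = 700, n_cpgs = 300, target_h2 = 0.6,
               never_smoker_fraction = 0, seed = 101),
    architecture = train$truth$architecture)
  ph <- train$phenotype
  y <- transform_phenotype(ph$pack_years, ph$age, ph$sex)
  Xtr <- beta_to_mvalue(train$methylation)
  model <- train_elastic_net(Xtr, y, seed = 1)
  top_site <- which.max(abs(train$truth$beta))
  single <- train_single_site(Xtr[, top_site], y,
                              site_id = colnames(Xtr)[top_site])
  Xte <- beta_to_mvalue(test$methylation)
  s_multi <- score(model, Xte)
  s_single <- score(single, Xte)
  expect_gt(cor(s_multi, test$truth$true_score),
            cor(s_single, test$truth$true_score))
})
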