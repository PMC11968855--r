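## biomarker module: the elastic-net methylation score of pack years and a
## single-site comparator, with cross-cohort projection. The penalised fit
## is delegated to glmnet (coordinate descent; alpha fixed at 0.5 and the
## cross-validated lambda minimising mean squared prediction error), with
## fold assignment, the KKT check and the weight container owned here.

#' Restrict a methylation matrix to an allowed site list
#'
#' @param M samples x sites matrix.
#' @param allowed character vector of permitted site ids (e.g. a previous
#'   meta-analysis FDR < 0.05 list).
#' @return `M` restricted to the intersection; errors if empty.
#' @export
prefilter_sites <- function(M, allowed) {
  stopifnot(length(allowed) > 0)
  shared <- intersect(colnames(M), allowed)
  if (length(shared) == 0L) stop("no overlap between matrix sites and the allowed list")
  message("prefilter_sites: ", length(shared), " of ", ncol(M),
          " site(s) retained")
  M[, shared, drop = FALSE]
}

#' Train the elastic-net methylation biomarker
#'
#' Squared-error elastic net (`lambda * [alpha*|b|_1 + (1-alpha)/2*|b|_2^2]`)
#' over a 100-knot log-spaced lambda path spanning four decades below
#' `lambda_max`; lambda is chosen by `n_folds`-fold cross-validation
#' minimising mean squared prediction error, with folds assigned by a
#' seeded permutation, and the final model refit on all data at the
#' selected lambda. Predictors are standardized internally by default and
#' coefficients stored on the raw beta-value scale so the model projects
#' onto new cohorts directly.
#'
#' The fitted solution coincides with the minimiser of the stated
#' objective exactly when the target has unit population variance — the
#' package's phenotype convention ([transform_phenotype()] output); for
#' other scalings the backend's internal response standardization rescales
#' the ridge component of the penalty.
#'
#' @param X samples x sites matrix of methylation values.
#' @param y training target (transformed pack years by convention).
#' @param alpha elastic-net mixing parameter (0.5 by default).
#' @param n_folds cross-validation folds.
#' @param seed fold-assignment seed.
#' @param standardize standardize predictors for the penalty?
#' @param lambda_fixed optional penalty value: skip cross-validation and
#'   fit at this lambda (used for limit checks and sensitivity analyses).
#' @return object of class `biomarker_model`: `intercept`, sparse
#'   `weights`, `training_means` for every weighted site, `alpha`,
#'   `lambda_selected`, and training metadata.
#' @export
train_elastic_net <- function(X, y, alpha = 0.5, n_folds = 10L, seed = 1L,
                              standardize = TRUE, lambda_fixed = NULL) {
  stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) >= n_folds)
  if (popvar(y) <= 0) stop("training target is constant")
  if (any(!is.finite(X))) stop("non-finite methylation values")
  if (is.null(colnames(X))) colnames(X) <- sprintf("site%d", seq_len(ncol(X)))
  if (is.null(lambda_fixed)) {
    set.seed(derive_seed(seed, 10L))
    foldid <- sample(rep(seq_len(n_folds), length.out = nrow(X)))
    cv <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                            family = "gaussian", standardize = standardize,
                            nlambda = 100, lambda.min.ratio = 1e-4,
                            type.measure = "mse")
    lam_sel <- cv$lambda.min
    lam_path <- cv$lambda
    cvm <- cv$cvm
    fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = lam_path,
                          family = "gaussian", standardize = standardize)
  } else {
    lam_sel <- lambda_fixed
    lam_path <- NULL
    cvm <- NULL
    ## descend a short path onto the target lambda for a warm-started,
    ## tightly converged solution
    lam_seq <- sort(unique(c(exp(seq(log(max(lambda_fixed, 1e-3) * 100),
                                     log(max(lambda_fixed, 1e-10)),
                                     length.out = 20)), lambda_fixed)),
                    decreasing = TRUE)
    fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = lam_seq,
                          family = "gaussian", standardize = standardize,
                          thresh = 1e-14)
  }
  co <- if (is.null(lambda_fixed)) {
    as.matrix(coef(fit, s = lam_sel))[, 1]
  } else { # exact path knot, no interpolation
    as.matrix(coef(fit))[, which.min(abs(fit$lambda - lam_sel))]
  }
  w <- co[-1][co[-1] != 0]
  tm <- colMeans(X)[names(w)]
  structure(list(intercept = unname(co[1]), weights = w,
                 training_means = tm, alpha = alpha,
                 lambda_selected = lam_sel,
                 lambda_path = lam_path, cv_mse = cvm,
                 n = nrow(X), n_features_prefilter = ncol(X),
                 standardize = standardize),
            class = "biomarker_model")
}

#' @export
print.biomarker_model <- function(x, ...) {
  cat("biomarker_model:", length(x$weights), "non-zero CpGs of",
      x$n_features_prefilter, "| alpha =", x$alpha,
      "| lambda =", signif(x$lambda_selected, 5), "\n")
  invisible(x)
}

#' Project a biomarker model onto a new cohort
#'
#' score = intercept + sum_j w_j m_ij; sites absent from the new matrix
#' are imputed at their training mean (the count imputed is logged). Under
#' strict mode, more than 50% absent weighted sites is an error instead of
#' a warning.
#'
#' @param model a `biomarker_model`.
#' @param M_new samples x sites matrix.
#' @param strict escalate heavy missingness to an error.
#' @return numeric vector of per-sample scores.
#' @export
score <- function(model, M_new, strict = FALSE) {
  stopifnot(inherits(model, "biomarker_model"), is.matrix(M_new))
  w <- model$weights
  present <- names(w) %in% colnames(M_new)
  n_missing <- sum(!present)
  if (n_missing > 0) {
    message("score: imputing ", n_missing, " of ", length(w),
            " weighted site(s) at training means")
    if (n_missing > 0.5 * length(w)) {
      msg <- paste0(n_missing, "/", length(w),
                    " weighted sites absent from the new cohort")
      if (strict) stop(msg) else warning(msg)
    }
  }
  out <- rep(model$intercept, nrow(M_new))
  if (any(present)) {
    out <- out + as.vector(M_new[, names(w)[present], drop = FALSE] %*%
                             w[present])
  }
  if (n_missing > 0) {
    out <- out + sum(w[!present] * model$training_means[!present])
  }
  out
}

#' Train the single-site comparator biomarker
#'
#' Simple least-squares regression of the target on one CpG (the published
#' analogue uses AHRR cg05575921), packaged in the shared model structure.
#'
#' @param m numeric vector: one CpG column.
#' @param y training target.
#' @param site_id name of the site.
#' @return a `biomarker_model` with a single weight.
#' @export
train_single_site <- function(m, y, site_id = "cg05575921") {
  if (popvar(m) <= 0) stop("site is constant")
  b <- sum((m - mean(m)) * (y - mean(y))) / sum((m - mean(m))^2)
  a <- mean(y) - b * mean(m)
  structure(list(intercept = a, weights = setNames(b, site_id),
                 training_means = setNames(mean(m), site_id),
                 alpha = NA_real_, lambda_selected = 0,
                 n = length(y), n_features_prefilter = 1L,
                 standardize = FALSE),
            class = "biomarker_model")
}

#' Elastic-net KKT residual
#'
#' Maximum violation of the stationarity conditions of
#' `(1/2n)||y - b0 - X b||^2 + lambda (alpha |b|_1 + (1-alpha)/2 |b|_2^2)`
#' at a candidate solution: for active coordinates the subgradient must
#' vanish, for inactive ones the gradient must lie inside the l1 tube, and
#' the intercept must zero the mean residual.
#'
#' @param X,y data on the scale of the fit (no internal standardization).
#' @param intercept,beta candidate solution.
#' @param lambda,alpha penalty.
#' @return scalar: largest KKT violation.
#' @export
enet_kkt_residual <- function(X, y, intercept, beta, lambda, alpha) {
  n <- nrow(X)
  r <- y - intercept - as.vector(X %*% beta)
  g <- as.vector(crossprod(X, r)) / n
  active <- beta != 0
  viol <- abs(mean(r))
  if (any(active)) {
    viol <- max(viol, abs(g[active] - lambda * (1 - alpha) * beta[active] -
                            lambda * alpha * sign(beta[active])))
  }
  if (any(!active)) {
    viol <- max(viol, max(0, abs(g[!active]) - lambda * alpha))
  }
  viol
}

#' Elastic-net objective value
#' @inheritParams enet_kkt_residual
#' @return scalar objective.
#' @export
enet_objective <- function(X, y, intercept, beta, lambda, alpha) {
  n <- nrow(X)
  r <- y - intercept - as.vector(X %*% beta)
  sum(r^2) / (2 * n) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

#' Write / read biomarker weights as TSV
#'
#' Header row then (site_id, weight, training_mean); the intercept is a
#' special `(Intercept)` row with an NA training mean.
#'
#' @param model a `biomarker_model`.
#' @param path TSV path.
#' @return `path` (write) or a `biomarker_model` (read).
#' @export
write_biomarker_tsv <- function(model, path) {
  df <- data.frame(site_id = c("(Intercept)", names(model$weights)),
                   weight = c(model$intercept, unname(model$weights)),
                   training_mean = c(NA_real_,
                                     unname(model$training_means)))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_biomarker_tsv
#' @export
read_biomarker_tsv <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  int <- df$weight[df$site_id == "(Intercept)"]
  df <- df[df$site_id != "(Intercept)", , drop = FALSE]
  structure(list(intercept = int,
                 weights = setNames(df$weight, df$site_id),
                 training_means = setNames(df$training_mean, df$site_id),
                 alpha = NA_real_, lambda_selected = NA_real_,
                 n = NA_integer_, n_features_prefilter = NA_integer_,
                 standardize = NA),
            class = "biomarker_model")
}
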