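## bayes_ewas module: spike-at-origin + four-Gaussian-slab penalised
## regression sampled by Gibbs; posterior inclusion probabilities and
## posterior variance explained.

#' Mixture prior for the Bayesian EWAS
#'
#' Four Gaussian slabs with variances that are fixed fractions (by default
#' 0.001, 0.01, 0.1 and 1, i.e. 0.1%, 1%, 10% and 100%) of a common sampled
#' effect-scale parameter `sigma2_beta`, plus a discrete spike at the
#' origin for CpGs with no effect. A symmetric Dirichlet prior is placed on
#' the five component probabilities and weakly informative scaled
#' inverse-chi-square priors on the two variance parameters.
#'
#' For oracle checks, individual components can be disabled and the
#' variances or mixture probabilities held fixed.
#'
#' @param slab_variance_fractions strictly increasing positive fractions.
#' @param dirichlet_concentration concentration of the symmetric Dirichlet
#'   prior on component probabilities (informational; the sampler uses 1).
#' @param nu_beta,s2_beta degrees of freedom and scale of the prior on the
#'   effect-scale variance.
#' @param nu_e,s2_e same for the residual variance.
#' @param spike keep the point mass at zero?
#' @param slab_active logical(4), which slabs participate.
#' @param fixed_pi optional fixed component probabilities (length = number
#'   of active components, spike first when present).
#' @param fixed_sigma2_beta,fixed_sigma2_e optional fixed variances
#'   (`NA` = sample them).
#' @return object of class `mixture_prior`.
#' @export
mixture_prior <- function(slab_variance_fractions = c(0.001, 0.01, 0.1, 1),
                          dirichlet_concentration = 1,
                          nu_beta = 4, s2_beta = 0.01,
                          nu_e = 4, s2_e = 1,
                          spike = TRUE,
                          slab_active = rep(TRUE, 4),
                          fixed_pi = NULL,
                          fixed_sigma2_beta = NA_real_,
                          fixed_sigma2_e = NA_real_) {
  fr <- slab_variance_fractions
  if (any(fr <= 0) || any(diff(fr) <= 0)) {
    stop("slab variance fractions must be strictly increasing and positive")
  }
  stopifnot(length(slab_active) == length(fr), any(slab_active) || spike)
  if (!is.null(fixed_pi)) {
    n_comp <- sum(slab_active) + spike
    if (length(fixed_pi) != n_comp || any(fixed_pi < 0)) {
      stop("fixed_pi must be ", n_comp, " non-negative probabilities")
    }
    fixed_pi <- fixed_pi / sum(fixed_pi)
  }
  structure(list(slab_variance_fractions = fr,
                 dirichlet_concentration = dirichlet_concentration,
                 nu_beta = nu_beta, s2_beta = s2_beta,
                 nu_e = nu_e, s2_e = s2_e,
                 spike = spike, slab_active = slab_active,
                 fixed_pi = fixed_pi,
                 fixed_sigma2_beta = fixed_sigma2_beta,
                 fixed_sigma2_e = fixed_sigma2_e),
            class = "mixture_prior")
}

#' Chain configuration for the Gibbs sampler
#'
#' Defaults follow the analysis protocol: a burn-in of 5000 samples, after
#' which every fifth sample is retained across 10,000 post-burn-in
#' iterations (2000 retained samples).
#'
#' @param burn_in burn-in iterations.
#' @param post_burn_iterations iterations after burn-in.
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param seed RNG seed.
#' @param random_scan randomize the CpG update order each sweep? Default
#'   keeps input order for reproducibility.
#' @return object of class `chain_config`.
#' @export
chain_config <- function(burn_in = 5000L, post_burn_iterations = 10000L,
                         thin = 5L, seed = 1L, random_scan = FALSE) {
  stopifnot(burn_in >= 0, post_burn_iterations >= thin, thin >= 1)
  structure(list(burn_in = as.integer(burn_in),
                 post_burn_iterations = as.integer(post_burn_iterations),
                 thin = as.integer(thin), seed = as.integer(seed),
                 random_scan = isTRUE(random_scan)),
            class = "chain_config")
}

#' Run the spike-and-slab Gibbs sampler
#'
#' Per sweep: for each CpG the five-way component indicator is sampled from
#' its full conditional with the effect marginalized analytically per
#' component (log weights with max subtraction), then the effect given the
#' indicator; mixture proportions are sampled from their Dirichlet full
#' conditional and both variances from scaled inverse-chi-square full
#' conditionals. The residual vector is updated incrementally per CpG.
#'
#' @param X residualized, standardized samples x CpGs matrix (each column
#'   mean 0, population variance 1).
#' @param y standardized phenotype vector.
#' @param prior a [mixture_prior()].
#' @param chain a [chain_config()].
#' @param check_residual recompute the residual sufficient statistic from
#'   scratch every iteration and track the maximum drift of the
#'   incrementally updated state (slow; for small-instance invariant
#'   checks).
#' @param cache_max_p cache `X'X` (fast sufficient-statistic updates) when
#'   `p` is at most this value; beyond it the sampler streams over the
#'   columns of `X`. The cache costs `8 p^2` bytes.
#' @return object of class `posterior_summary` with per-CpG `pip`,
#'   `post_mean`, `comp_prob` (5 columns: spike then the four slabs),
#'   retained-sample traces of the mixture proportions, both variances and
#'   the variance explained `var(X beta)/var(y)`.
#' @export
run_gibbs <- function(X, y, prior = mixture_prior(),
                      chain = chain_config(), check_residual = FALSE,
                      cache_max_p = 6000L) {
  stopifnot(is.matrix(X), nrow(X) == length(y),
            inherits(prior, "mixture_prior"), inherits(chain, "chain_config"))
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  n <- nrow(X)
  cm <- colMeans(X)
  cv <- colMeans(X^2) - cm^2
  tol <- 1e-4
  if (any(abs(cm) > tol) || any(abs(cv - 1) > tol)) {
    stop("columns of X must be standardized (mean 0, population variance 1)")
  }
  if (abs(mean(y)) > tol || abs(popvar(y) - 1) > tol) {
    stop("y must be standardized (mean 0, population variance 1)")
  }

  act <- which(prior$slab_active)
  fr <- prior$slab_variance_fractions[act]
  set.seed(chain$seed)
  res <- .gibbs_cpp(X, y, fr, as.integer(act), prior$spike,
                    chain$burn_in, chain$post_burn_iterations, chain$thin,
                    prior$nu_beta, prior$s2_beta, prior$nu_e, prior$s2_e,
                    if (is.null(prior$fixed_pi)) NULL else
                      as.numeric(prior$fixed_pi),
                    if (is.na(prior$fixed_sigma2_beta)) -1 else
                      prior$fixed_sigma2_beta,
                    if (is.na(prior$fixed_sigma2_e)) -1 else
                      prior$fixed_sigma2_e,
                    chain$random_scan, isTRUE(check_residual),
                    as.integer(cache_max_p))
  ids <- colnames(X) %||% sprintf("cpg%d", seq_len(ncol(X)))
  out <- list(cpg_id = ids,
              pip = as.vector(res$pip),
              post_mean = as.vector(res$post_mean),
              comp_prob = res$comp_prob,
              pi_samples = res$pi_samples,
              sigma2_beta = as.vector(res$sigma2_beta),
              sigma2_e = as.vector(res$sigma2_e),
              vexp = as.vector(res$vexp),
              n_retained = res$n_retained,
              beta_last = as.vector(res$beta_last),
              residual_last = as.vector(res$residual_last),
              max_residual_drift = res$max_residual_drift,
              prior = prior, chain = chain, n = n, p = ncol(X))
  colnames(out$comp_prob) <- colnames(out$pi_samples) <-
    c("spike", paste0("slab", 1:4))
  class(out) <- "posterior_summary"
  out
}

#' @export
print.posterior_summary <- function(x, ...) {
  ve <- variance_explained(x)
  cat("posterior_summary:", x$p, "CpGs,", x$n, "samples,",
      x$n_retained, "retained draws\n")
  cat(sprintf("  variance explained: %.3f (95%% CrI %.3f - %.3f)\n",
              ve[["mean"]], ve[["lower"]], ve[["upper"]]))
  cat("  CpGs at PIP > 0.95:", sum(x$pip > 0.95),
      " | PIP > 0.80:", sum(x$pip > 0.80), "\n")
  invisible(x)
}

#' Posterior variance explained with an equal-tailed credible interval
#'
#' @param summary a `posterior_summary`.
#' @param level credible level (default 0.95).
#' @return named numeric `(mean, lower, upper)`.
#' @export
variance_explained <- function(summary, level = 0.95) {
  v <- summary$vexp
  if (length(v) < 2L) stop("need at least 2 retained samples")
  qs <- quantile(v, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  c(mean = mean(v), lower = qs[1], upper = qs[2])
}

#' Tiered significant-CpG calling from posterior inclusion probabilities
#'
#' Strict inequality at each threshold; a CpG with PIP exactly at a
#' threshold is excluded from that tier. The default tiers are PIP > 0.80
#' (reported associations) and PIP > 0.95 (epigenome-wide significant).
#'
#' @param pips numeric vector in `[0, 1]`, optionally named.
#' @param thresholds numeric thresholds.
#' @return named list of CpG id (or index) vectors, one per threshold.
#' @export
call_significant <- function(pips, thresholds = c(0.80, 0.95)) {
  stopifnot(all(pips >= 0 & pips <= 1))
  ids <- names(pips) %||% as.character(seq_along(pips))
  out <- lapply(thresholds, function(th) ids[pips > th])
  names(out) <- sprintf("pip_gt_%g", thresholds)
  out
}

#' Write per-CpG posterior results as TSV
#' @param summary a `posterior_summary`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_posterior_tsv <- function(summary, path) {
  df <- data.frame(cpg_id = summary$cpg_id, pip = summary$pip,
                   post_mean_beta = summary$post_mean,
                   summary$comp_prob, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
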