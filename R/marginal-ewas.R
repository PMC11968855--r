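## marginal_ewas module: per-CpG linear-model EWAS with methylation as the
## outcome, genomic inflation, threshold tiers, and cross-platform overlap.

#' Per-site linear-model EWAS
#'
#' For each site, ordinary least squares of methylation (outcome) on the
#' smoking phenotype plus covariates (age, sex); two-sided p-values from
#' the t reference at the exact residual degrees of freedom. The phenotype
#' may be binary (current vs never), ordinal (0/1/2) or continuous. Sites
#' are fitted by the Frisch-Waugh projection, which reproduces full-design
#' OLS exactly; sites with missing methylation fall back to per-site
#' complete-case fits.
#'
#' @param M samples x sites methylation matrix (fractions), NA allowed.
#' @param phenotype numeric vector (binary 0/1, ordinal 0/1/2 or
#'   continuous).
#' @param covariates data.frame or matrix of covariates (e.g. age, sex01);
#'   may be `NULL`.
#' @param site_info optional data.frame (`chrom`, `start`, `end`) aligned
#'   with columns of `M`.
#' @param genome genome build label attached to the result.
#' @return data.frame of class `ewas_result`: site_id, beta, se, p, n.
#' @export
ewas_lm <- function(M, phenotype, covariates = NULL, site_info = NULL,
                    genome = "GRCh38") {
  stopifnot(is.matrix(M), nrow(M) == length(phenotype))
  if (popvar(phenotype) <= 0) stop("phenotype does not vary")
  Z <- cbind(`(Intercept)` = rep(1, nrow(M)))
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    keep <- apply(cv, 2L, popvar) > 0
    Z <- cbind(Z, cv[, keep, drop = FALSE])
  }
  k <- ncol(Z) + 1L # covariates + intercept + phenotype
  if (nrow(M) <= k + 1L) stop("too few samples for the covariate set")
  ids <- colnames(M) %||% sprintf("site%d", seq_len(ncol(M)))

  fit_one <- function(m) {
    ok <- !is.na(m)
    n_ok <- sum(ok)
    if (n_ok <= k + 1L || popvar(m[ok]) == 0 ||
        popvar(phenotype[ok]) == 0) {
      return(c(NA_real_, NA_real_, NA_real_, n_ok))
    }
    Zo <- Z[ok, , drop = FALSE]
    xt <- as.vector(residualize_on(cbind(phenotype[ok]), Zo))
    mt <- as.vector(residualize_on(cbind(m[ok]), Zo))
    sxx <- sum(xt^2)
    b <- sum(xt * mt) / sxx
    df <- n_ok - ncol(Zo) - 1L
    rss <- sum(mt^2) - b^2 * sxx
    se <- sqrt(max(rss, 0) / df / sxx)
    tval <- b / se
    c(b, se, 2 * pt(-abs(tval), df), n_ok)
  }

  if (!anyNA(M)) {
    xt <- as.vector(residualize_on(cbind(phenotype), Z))
    Mt <- residualize_on(M, Z)
    sxx <- sum(xt^2)
    b <- as.vector(crossprod(Mt, xt)) / sxx
    df <- nrow(M) - ncol(Z) - 1L
    rss <- colSums(Mt^2) - b^2 * sxx
    const <- apply(M, 2L, popvar) == 0
    se <- sqrt(pmax(rss, 0) / df / sxx)
    p <- 2 * pt(-abs(b / se), df)
    b[const] <- se[const] <- p[const] <- NA_real_
    if (any(const)) {
      message("ewas_lm: ", sum(const), " constant site(s) skipped")
    }
    res <- data.frame(site_id = ids, beta = b, se = se, p = p,
                      n = nrow(M), stringsAsFactors = FALSE)
  } else {
    est <- t(vapply(seq_len(ncol(M)), function(j) fit_one(M[, j]),
                    numeric(4)))
    if (anyNA(est[, 1])) {
      message("ewas_lm: ", sum(is.na(est[, 1])),
              " site(s) skipped (constant or too few complete cases)")
    }
    res <- data.frame(site_id = ids, beta = est[, 1], se = est[, 2],
                      p = est[, 3], n = as.integer(est[, 4]),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(site_info)) res <- cbind(res, site_info)
  attr(res, "genome") <- genome
  class(res) <- c("ewas_result", class(res))
  res
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)`; about 1
#' under a well-calibrated null.
#'
#' @param pvalues numeric p-values in `(0, 1]` (NA dropped).
#' @return scalar lambda.
#' @export
genomic_inflation <- function(pvalues) {
  p <- pvalues[is.finite(pvalues)]
  if (length(p) == 0L) stop("no finite p-values")
  stopifnot(all(p >= 0 & p <= 1))
  ## p values that underflowed to 0 map to an infinite chi-square; the
  ## median is robust to them
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

#' Significance tiers for EWAS / GWAS results
#' @param genome_wide_p genome-wide threshold (EWAS default 3.6e-8).
#' @param suggestive_p suggestive threshold (default 1e-5).
#' @return list of class `significance_tiers`.
#' @export
significance_tiers <- function(genome_wide_p = 3.6e-8,
                               suggestive_p = 1e-5) {
  stopifnot(genome_wide_p < suggestive_p)
  structure(list(genome_wide_p = genome_wide_p,
                 suggestive_p = suggestive_p),
            class = "significance_tiers")
}

#' Tiered hit calling with strict thresholds
#'
#' Genome-wide hits are `p < genome_wide_p`, suggestive hits
#' `p < suggestive_p` (strict inequalities, so a p-value exactly at a
#' threshold is excluded). For the brain analyses, use a single tier by
#' setting both thresholds to 1e-5.
#'
#' @param result an `ewas_result` (or any data.frame with `site_id`, `p`).
#' @param tiers a [significance_tiers()].
#' @return list with `genome_wide` and `suggestive` site-id vectors.
#' @export
tier_hits <- function(result, tiers = significance_tiers()) {
  p <- result$p
  list(genome_wide = result$site_id[!is.na(p) & p < tiers$genome_wide_p],
       suggestive = result$site_id[!is.na(p) & p < tiers$suggestive_p])
}

#' Cross-platform overlap of tiered hits
#'
#' Intersects the tiered hits of two EWAS result sets matched by exact
#' site id (same half-open interval convention), and reports counts plus
#' effect-sign concordance among shared hits.
#'
#' @param resultsA,resultsB `ewas_result` data.frames carrying a `genome`
#'   attribute.
#' @param tiers a [significance_tiers()].
#' @param tier which tier to intersect.
#' @return list with per-platform counts, `shared` ids, and
#'   `sign_concordance` among shared hits.
#' @export
cross_platform_overlap <- function(resultsA, resultsB,
                                   tiers = significance_tiers(),
                                   tier = c("genome_wide", "suggestive")) {
  tier <- match.arg(tier)
  ga <- attr(resultsA, "genome") %||% "GRCh38"
  gb <- attr(resultsB, "genome") %||% "GRCh38"
  if (!identical(ga, gb)) {
    stop("mixed genome builds: ", ga, " vs ", gb)
  }
  hitsA <- tier_hits(resultsA, tiers)[[tier]]
  hitsB <- tier_hits(resultsB, tiers)[[tier]]
  shared <- intersect(hitsA, hitsB)
  conc <- NA_real_
  if (length(shared) > 0L) {
    sa <- sign(resultsA$beta[match(shared, resultsA$site_id)])
    sb <- sign(resultsB$beta[match(shared, resultsB$site_id)])
    conc <- mean(sa == sb)
  }
  list(n_A = length(hitsA), n_B = length(hitsB),
       n_shared = length(shared), shared = shared,
       sign_concordance = conc)
}
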