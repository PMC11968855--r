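## gwas_lite module: unrelated-samples association scan with PC covariates,
## genomic inflation, and Haseman-Elston heritability. This is a desk-scale
## stand-in for a GRM-based mixed-model GWAS: the relatedness correction is
## deliberately replaced by OLS on (simulated) unrelated samples, while the
## comparison structure — two phenotypes, shared covariates, lambda,
## overlap of hits — is preserved.

.impute_standardize_dosages <- function(G) {
  G <- apply(G, 2L, function(g) {
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  standardize_cols(G)
}

#' Top principal components of the genotype matrix
#'
#' PCs of the column-standardized (mean-imputed) dosage matrix via
#' singular value decomposition. The sign convention makes the
#' largest-magnitude loading of each component positive, so repeated runs
#' return identical scores.
#'
#' @param G samples x SNPs dosage matrix (0/1/2, NA allowed).
#' @param k number of components.
#' @return n x k matrix of PC scores.
#' @export
compute_pcs <- function(G, k = 20L) {
  Z <- .impute_standardize_dosages(G)
  if (k > min(nrow(Z) - 1L, ncol(Z))) {
    stop("k must be smaller than the matrix rank bound min(n - 1, p)")
  }
  sv <- svd(Z, nu = k, nv = k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(sv$v[, j]))
    if (sv$v[i_max, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Per-SNP association scan
#'
#' Least-squares regression of the phenotype on each SNP dosage plus
#' covariates (age, sex, PCs), two-sided t-test p-values at the exact
#' residual degrees of freedom, scan-level genomic inflation, and tier
#' calls at p < 5e-8 (genome-wide) and p < 1e-5 (suggestive).
#'
#' @param G samples x SNPs dosage matrix.
#' @param y phenotype vector.
#' @param covariates matrix/data.frame of covariates or `NULL`.
#' @param snp_info optional data.frame aligned with SNP columns.
#' @return list of class `gwas_result`: per-SNP table, `lambda`, tiers.
#' @export
gwas_scan <- function(G, y, covariates = NULL, snp_info = NULL) {
  stopifnot(is.matrix(G), nrow(G) == length(y))
  Z <- cbind(`(Intercept)` = rep(1, nrow(G)))
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    keep <- apply(cv, 2L, popvar) > 0
    Z <- cbind(Z, cv[, keep, drop = FALSE])
  }
  if (nrow(G) <= ncol(Z) + 2L) stop("too few samples for the covariate set")
  Gi <- apply(G, 2L, function(g) {
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  yt <- as.vector(residualize_on(cbind(y), Z))
  Gt <- residualize_on(Gi, Z)
  sgg <- colSums(Gt^2)
  mono <- apply(Gi, 2L, popvar) == 0 | sgg <= 1e-12
  b <- as.vector(crossprod(Gt, yt)) / sgg
  df <- nrow(G) - ncol(Z) - 1L
  rss <- sum(yt^2) - b^2 * sgg
  se <- sqrt(pmax(rss, 0) / df / sgg)
  p <- 2 * pt(-abs(b / se), df)
  b[mono] <- se[mono] <- p[mono] <- NA_real_
  if (any(mono)) message("gwas_scan: ", sum(mono), " monomorphic SNP(s)")
  ids <- colnames(G) %||% sprintf("snp%d", seq_len(ncol(G)))
  tab <- data.frame(site_id = ids, beta = b, se = se, p = p, n = nrow(G),
                    stringsAsFactors = FALSE)
  if (!is.null(snp_info)) tab <- cbind(tab, snp_info)
  tiers <- significance_tiers(genome_wide_p = 5e-8, suggestive_p = 1e-5)
  structure(list(table = tab,
                 lambda = genomic_inflation(p[!is.na(p)]),
                 tiers = tier_hits(tab, tiers)),
            class = "gwas_result")
}

#' Haseman-Elston regression heritability
#'
#' Regresses off-diagonal phenotype cross-products `y_i y_j` on the
#' corresponding genomic-relationship entries (standardized dosages,
#' `A = Z Z' / p`); the slope estimates the SNP heritability. The standard
#' error is a delete-one-sample jackknife. The phenotype is standardized
#' internally (population variance).
#'
#' @param G samples x SNPs dosage matrix.
#' @param y phenotype vector.
#' @return named numeric `(h2, se)`.
#' @export
he_regression <- function(G, y) {
  n <- length(y)
  if (n < 50L) stop("need at least 50 samples for HE regression")
  Z <- .impute_standardize_dosages(G)
  p <- ncol(Z)
  A <- tcrossprod(Z) / p
  ys <- standardize(y)
  P <- tcrossprod(ys) # y_i y_j
  diag(A) <- diag(P) <- 0
  m <- n * (n - 1)
  sA <- sum(A); sA2 <- sum(A^2); sAP <- sum(A * P); sP <- sum(P)
  slope_from <- function(sA, sA2, sAP, sP, m) {
    (sAP - sA * sP / m) / (sA2 - sA^2 / m)
  }
  h2 <- slope_from(sA, sA2, sAP, sP, m)

  ## delete-one jackknife via row sums (each pair counted twice in sums)
  rA <- rowSums(A); rA2 <- rowSums(A^2); rAP <- rowSums(A * P)
  rP <- rowSums(P)
  mk <- (n - 1) * (n - 2)
  jk <- vapply(seq_len(n), function(k) {
    slope_from(sA - 2 * rA[k], sA2 - 2 * rA2[k], sAP - 2 * rAP[k],
               sP - 2 * rP[k], mk)
  }, numeric(1))
  se <- sqrt((n - 1) / n * sum((jk - mean(jk))^2))
  c(h2 = h2, se = se)
}

#' Compare two association scans
#'
#' Per-tier overlap counts and effect-sign concordance among shared
#' genome-wide hits; used to contrast self-report and epigenetic-score
#' phenotypes on the same genotypes.
#'
#' @param resultA,resultB `gwas_result` objects.
#' @return list with per-tier counts, shared ids and sign concordance.
#' @export
compare_phenotype_scans <- function(resultA, resultB) {
  shared_all <- intersect(resultA$table$site_id, resultB$table$site_id)
  if (length(shared_all) == 0L) stop("no shared SNPs between scans")
  out <- lapply(c("genome_wide", "suggestive"), function(tr) {
    sa <- resultA$tiers[[tr]]
    sb <- resultB$tiers[[tr]]
    sh <- intersect(sa, sb)
    conc <- NA_real_
    if (length(sh) > 0L) {
      ba <- resultA$table$beta[match(sh, resultA$table$site_id)]
      bb <- resultB$table$beta[match(sh, resultB$table$site_id)]
      conc <- mean(sign(ba) == sign(bb))
    }
    list(n_A = length(sa), n_B = length(sb), n_shared = length(sh),
         shared = sh, sign_concordance = conc)
  })
  names(out) <- c("genome_wide", "suggestive")
  out$n_shared_snps <- length(shared_all)
  out
}
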