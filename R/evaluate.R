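## evaluate module: benchmarking scores against self-report — incremental
## R-squared, correlations, ROC-AUC and PR-AUC over pairwise smoking
## category contrasts (current vs never, current vs former, former vs
## never).

#' Incremental R-squared of a score over age and sex
#'
#' Difference between the variance explained by the full model
#' `y ~ age + sex + score` and the null model `y ~ age + sex`, both by
#' least squares. Non-negative by construction (nested models).
#'
#' @param y outcome (transformed pack years by convention).
#' @param scr score vector.
#' @param age,sex covariates.
#' @return scalar incremental R-squared.
#' @export
incremental_r2 <- function(y, scr, age, sex) {
  stopifnot(length(y) > 4)
  sex01 <- if (is.character(sex) || is.factor(sex)) {
    as.numeric(as.character(sex) == "M")
  } else as.numeric(sex)
  Znull <- cbind(1, age, sex01)
  if (qr(Znull)$rank < ncol(Znull)) stop("collinear covariates")
  r2 <- function(design) {
    r <- as.vector(residualize_on(cbind(y), design))
    1 - sum(r^2) / sum((y - mean(y))^2)
  }
  full <- if (popvar(scr) > 0) cbind(Znull, scr) else Znull
  max(r2(full) - r2(Znull), 0)
}

#' ROC area under the curve by the rank statistic
#'
#' AUC = P(score_case > score_control) + 0.5 P(tie), computed from average
#' ranks (equivalent to the trapezoidal area under the ROC curve).
#'
#' @param labels binary vector (1/TRUE = positive class).
#' @param scr score vector.
#' @return scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scr) {
  lab <- as.logical(labels)
  n1 <- sum(lab)
  n0 <- sum(!lab)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scr, ties.method = "average")
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation over thresholds at the observed scores
#' (descending, ties grouped): `sum_k (R_k - R_{k-1}) P_k`, anchoring the
#' precision at recall 0 to the highest-score threshold rather than
#' interpolating to (0, 1). Under a non-informative score the expected
#' value is the positive-class prevalence.
#'
#' @param labels binary vector (1/TRUE = positive class).
#' @param scr score vector.
#' @return scalar PR-AUC in `[0, 1]`.
#' @export
pr_auc <- function(labels, scr) {
  lab <- as.logical(labels)
  if (sum(lab) == 0L) stop("no positive cases")
  ord <- order(scr, decreasing = TRUE)
  lab <- lab[ord]
  s <- scr[ord]
  grp_end <- cumsum(rle(s)$lengths) # group tied scores as one threshold
  tp <- cumsum(lab)[grp_end]
  fp <- cumsum(!lab)[grp_end]
  recall <- tp / sum(lab)
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Pearson and Spearman correlations
#'
#' Spearman uses average ranks for ties.
#'
#' @param y,scr numeric vectors (both must vary; n >= 3).
#' @return named numeric `(pearson_r, spearman_r)`.
#' @export
correlations <- function(y, scr) {
  stopifnot(length(y) >= 3)
  if (popvar(y) == 0 || popvar(scr) == 0) stop("zero variance input")
  c(pearson_r = cor(y, scr, method = "pearson"),
    spearman_r = cor(y, scr, method = "spearman"))
}

#' Full evaluation report across smoking-category contrasts
#'
#' @param pack_years_t transformed pack years (outcome for incremental
#'   R-squared and correlations).
#' @param scr score vector.
#' @param status smoking status ("never"/"former"/"current").
#' @param age,sex covariates.
#' @return list of class `evaluation_report` with incremental R-squared,
#'   correlations, and per-contrast AUC/PR-AUC and sample sizes.
#' @export
evaluation_report <- function(pack_years_t, scr, status, age, sex) {
  contrasts <- list(current_vs_never = c("current", "never"),
                    current_vs_former = c("current", "former"),
                    former_vs_never = c("former", "never"))
  per <- lapply(contrasts, function(cs) {
    sel <- status %in% cs
    if (!all(cs %in% status)) {
      return(list(auc = NA_real_, prauc = NA_real_, n = sum(sel)))
    }
    lab <- status[sel] == cs[1]
    list(auc = roc_auc(lab, scr[sel]), prauc = pr_auc(lab, scr[sel]),
         n = sum(sel))
  })
  structure(list(incremental_r2 = incremental_r2(pack_years_t, scr, age,
                                                 sex),
                 correlations = correlations(pack_years_t, scr),
                 contrasts = per),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("incremental R2 = %.3f | r = %.3f | spearman = %.3f\n",
              x$incremental_r2, x$correlations[["pearson_r"]],
              x$correlations[["spearman_r"]]))
  for (nm in names(x$contrasts)) {
    ct <- x$contrasts[[nm]]
    cat(sprintf("  %-18s AUC = %.3f  PRAUC = %.3f  (n = %d)\n",
                nm, ct$auc, ct$prauc, ct$n))
  }
  invisible(x)
}
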