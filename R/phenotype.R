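## phenotype module: pack-years construction, questionnaire consistency
## checks, phenotype transformation and methylation residualization --
## exactly the preprocessing fed to the EWAS and biomarker stages.

#' Compute smoking pack years from questionnaire fields
#'
#' Pack years = years of smoking x cigarettes per day / 20 (cigarettes in a
#' pack). Years smoked is `age_stopped - age_started` for former smokers
#' and `current_age - age_started` for current smokers; never smokers are
#' assigned zero. Records with a negative smoking duration are returned as
#' `NA` (a record error picked up by [flag_inconsistent_records()]), never
#' silently clipped.
#'
#' @param table data.frame with columns `smoking_status`, `cigs_per_day`,
#'   `age_started`, `age_stopped`, `current_age`.
#' @return numeric vector of pack years (NA for invalid records).
#' @export
compute_pack_years <- function(table) {
  status <- table$smoking_status
  stopifnot(all(status %in% c("never", "former", "current")))
  years <- rep(NA_real_, nrow(table))
  fo <- status == "former"
  cu <- status == "current"
  years[fo] <- table$age_stopped[fo] - table$age_started[fo]
  years[cu] <- table$current_age[cu] - table$age_started[cu]
  py <- years * table$cigs_per_day / 20
  py[status == "never"] <- 0
  bad <- !is.na(years) & years < 0
  if (any(bad)) {
    message(sum(bad), " record(s) with negative smoking duration set to NA")
    py[bad] <- NA_real_
  }
  py
}

#' Flag internally inconsistent smoking questionnaire records
#'
#' Cross-references reported smoking status with the other questionnaire
#' variables and flags conflicting records for exclusion:
#' (a) never smokers reporting nonzero cigarettes/day or any start/stop
#' age; (b) stop age at or before start age; (c) start age after current
#' age; (d) current smokers reporting a stop age.
#'
#' @param table phenotype data.frame (see [compute_pack_years()]).
#' @return data.frame with logical `flagged` and a `reason` string
#'   (semicolon-separated codes among "a","b","c","d"; "" if clean).
#' @export
flag_inconsistent_records <- function(table) {
  n <- nrow(table)
  status <- table$smoking_status
  has_start <- !is.na(table$age_started)
  has_stop <- !is.na(table$age_stopped)
  a <- status == "never" &
    (table$cigs_per_day > 0 | has_start | has_stop)
  b <- has_start & has_stop & table$age_stopped <= table$age_started
  c_ <- has_start & table$age_started > table$current_age
  d <- status == "current" & has_stop
  reasons <- character(n)
  m <- cbind(a = a, b = b, c = c_, d = d)
  for (i in seq_len(n)) {
    reasons[i] <- paste(colnames(m)[m[i, ]], collapse = ";")
  }
  flagged <- a | b | c_ | d
  message("flag_inconsistent_records: ", sum(flagged), " of ", n,
          " record(s) flagged")
  data.frame(sample_id = table$sample_id, flagged = flagged,
             reason = reasons, stringsAsFactors = FALSE)
}

#' Transform pack years into the analysis phenotype
#'
#' Natural log(pack years + 1), adjusted for age and sex by linear
#' regression (residuals saved), then scaled to mean 0 and variance 1
#' (population variance, so the unit-variance contract holds exactly at
#' any n).
#'
#' @param pack_years non-negative numeric vector.
#' @param age,sex covariates (`sex` coded "F"/"M" or 0/1).
#' @return numeric vector of residualized standardized values.
#' @export
transform_phenotype <- function(pack_years, age, sex) {
  stopifnot(length(pack_years) >= 3, all(!is.na(pack_years)),
            all(pack_years >= 0))
  y <- log1p(pack_years)
  sex01 <- if (is.character(sex) || is.factor(sex)) {
    as.numeric(as.character(sex) == "M")
  } else as.numeric(sex)
  design <- cbind(1, age, sex01)
  ## drop constant covariate columns (degenerate designs still legal)
  keep <- c(TRUE, popvar(age) > 0, popvar(sex01) > 0)
  r <- as.vector(residualize_on(cbind(y), design[, keep, drop = FALSE]))
  if (popvar(r) <= .Machine$double.eps * 100) {
    stop("phenotype is constant after transformation; nothing to analyze")
  }
  standardize(r)
}

#' Residualize a methylation matrix on age, sex and batch
#'
#' Each CpG column is corrected for age, sex and batch by linear regression
#' (batch entered as dummy indicators) and replaced by its standardized
#' residuals. Columns with zero residual variance are dropped with a
#' warning.
#'
#' @param M samples x CpGs methylation matrix (beta or M-values).
#' @param age,sex,batch per-sample covariates; `batch` may be `NULL`.
#' @return residualized, standardized matrix (possibly fewer columns).
#' @export
residualize_methylation <- function(M, age, sex, batch = NULL) {
  stopifnot(is.matrix(M), nrow(M) == length(age))
  sex01 <- if (is.character(sex) || is.factor(sex)) {
    as.numeric(as.character(sex) == "M")
  } else as.numeric(sex)
  parts <- list(`(Intercept)` = rep(1, nrow(M)))
  if (popvar(age) > 0) parts$age <- age
  if (popvar(sex01) > 0) parts$sex <- sex01
  if (!is.null(batch) && length(unique(batch)) > 1L) {
    lev <- sort(unique(as.character(batch)))
    for (l in lev[-1]) parts[[paste0("batch", l)]] <-
      as.numeric(batch == l)
  }
  design <- do.call(cbind, parts)
  R <- residualize_on(M, design)
  v <- colMeans(sweep(R, 2L, colMeans(R), "-")^2)
  drop <- v <= 1e-12
  if (any(drop)) {
    warning(sum(drop), " CpG(s) with zero residual variance dropped: ",
            paste(head(colnames(M)[drop], 5L), collapse = ", "))
    R <- R[, !drop, drop = FALSE]
    v <- v[!drop]
  }
  sweep(sweep(R, 2L, colMeans(R), "-"), 2L, sqrt(v), "/")
}

#' Encode smoking status on the ordinal 0/1/2 scale
#'
#' never = 0, former = 1, current = 2, the coding used when smoking
#' category is treated as a continuous predictor in small-sample EWAS.
#'
#' @param status character vector of statuses.
#' @return integer vector in `{0, 1, 2}`.
#' @export
encode_smoking_ordinal <- function(status) {
  map <- c(never = 0L, former = 1L, current = 2L)
  out <- map[as.character(status)]
  if (any(is.na(out))) {
    stop("unknown smoking status label(s): ",
         paste(unique(status[is.na(out)]), collapse = ", "))
  }
  unname(out)
}
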