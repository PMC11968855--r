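## matching module: heavy-smoker case selection and age/sex-matched
## never-smoker controls under the published pairing constraint (sex
## identical, age difference strictly under 12 months).

#' Select heavy-smoker cases
#'
#' Top `n_per_sex` current smokers by pack years within each sex;
#' deterministic tie-break by sample id (lexicographically smaller id
#' wins).
#'
#' @param phenotypes data.frame with `sample_id`, `smoking_status`, `sex`,
#'   `pack_years`.
#' @param n_per_sex cases per sex.
#' @return character vector of case sample ids.
#' @export
select_cases <- function(phenotypes, n_per_sex = 12L) {
  cur <- phenotypes[phenotypes$smoking_status == "current", , drop = FALSE]
  out <- character(0)
  for (sx in sort(unique(phenotypes$sex))) {
    cand <- cur[cur$sex == sx, , drop = FALSE]
    if (nrow(cand) < n_per_sex) {
      stop("insufficient current-smoker candidates for sex ", sx, ": need ",
           n_per_sex, ", have ", nrow(cand),
           " (shortfall ", n_per_sex - nrow(cand), ")")
    }
    cand <- cand[order(-cand$pack_years, cand$sample_id), , drop = FALSE]
    out <- c(out, cand$sample_id[seq_len(n_per_sex)])
  }
  out
}

#' Match never-smoker controls to cases by age and sex
#'
#' Greedy nearest-age matching within sex. Cases are processed in order of
#' fewest eligible controls first (scarcity-first), with sample id as the
#' deterministic tie-break; each control is used at most once. A case with
#' no control inside the age window is reported unmatched, not an error.
#'
#' @param cases data.frame with `sample_id`, `sex`, `age_days` (age in
#'   days; whole years x 365.25 is acceptable).
#' @param pool data.frame of candidate controls with the same columns.
#' @param max_age_diff_days window; pairs require a strictly smaller gap.
#' @return list with `pairs` (case_id, control_id, age_difference, sex)
#'   and `unmatched` case ids.
#' @export
match_controls <- function(cases, pool, max_age_diff_days = 365) {
  stopifnot(nrow(pool) > 0)
  eligible <- lapply(seq_len(nrow(cases)), function(i) {
    which(pool$sex == cases$sex[i] &
            abs(pool$age_days - cases$age_days[i]) < max_age_diff_days)
  })
  ord <- order(lengths(eligible), cases$sample_id)
  used <- rep(FALSE, nrow(pool))
  pairs <- list()
  unmatched <- character(0)
  for (i in ord) {
    el <- eligible[[i]]
    el <- el[!used[el]]
    if (length(el) == 0L) {
      unmatched <- c(unmatched, cases$sample_id[i])
      next
    }
    d <- abs(pool$age_days[el] - cases$age_days[i])
    el <- el[order(d, pool$sample_id[el])]
    pick <- el[1L]
    used[pick] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      case_id = cases$sample_id[i], control_id = pool$sample_id[pick],
      age_difference = abs(pool$age_days[pick] - cases$age_days[i]),
      sex = cases$sex[i], stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(case_id = character(0), control_id = character(0),
               age_difference = numeric(0), sex = character(0))
  pairs <- pairs[order(pairs$case_id), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, unmatched = sort(unmatched))
}

#' Validate matched pairs against the pairing contract
#'
#' Flags any pair whose age difference reaches 365 days (i.e. 12 months or
#' more); flagged pairs are excluded from the returned clean set, and the
#' exclusion is logged.
#'
#' @param pairs data.frame as returned by [match_controls()].
#' @param max_age_diff_days the contract window.
#' @return list with `pass` (logical), `violations` (offending rows) and
#'   `pairs` (the surviving pairs).
#' @export
validate_pairs <- function(pairs, max_age_diff_days = 365) {
  stopifnot(all(c("case_id", "control_id", "age_difference") %in%
                  names(pairs)))
  if (anyNA(pairs$age_difference)) stop("unresolvable ages in pairs")
  bad <- pairs$age_difference >= max_age_diff_days
  if (any(bad)) {
    message("validate_pairs: excluding ", sum(bad),
            " pair(s) with age gap >= ", max_age_diff_days, " days")
  }
  list(pass = !any(bad), violations = pairs[bad, , drop = FALSE],
       pairs = pairs[!bad, , drop = FALSE])
}
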