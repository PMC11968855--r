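## cli_orchestrator module: end-to-end pipeline driver over the synthetic
## generators and all analysis stages, with a deterministic manifest.

#' Pipeline configuration
#'
#' Stage toggles and per-stage parameter blocks. Defaults reproduce the
#' published parameterization (burn-in 5000, thin 5, alpha 0.5, 10 folds,
#' thresholds 3.6e-8 / 1e-5 / 5e-8, minimal coverage 2, 0.99 quantile, 40
#' samples at 10/5 reads, 12-month matching window); the `demo` preset
#' scales sizes down to run end-to-end on one CPU in minutes.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param stages character vector of enabled stages among
#'   `c("cohort", "bayes", "marginal", "seq", "matching", "biomarker",
#'   "evaluate", "gwas")`.
#' @param cohort,bayes,seq,matching,biomarker,gwas per-stage parameter
#'   lists; see the function body for defaults.
#' @param demo use the reduced demonstration scale.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("cohort", "bayes", "marginal",
                                       "seq", "matching", "biomarker",
                                       "evaluate", "gwas"),
                            cohort = list(), bayes = list(), seq = list(),
                            matching = list(), biomarker = list(),
                            gwas = list(), demo = TRUE) {
  defaults <- list(
    cohort = list(n = if (demo) 400L else 2000L,
                  p = if (demo) 600L else 2000L,
                  target_h2 = 0.5, never_fraction = 0.5),
    bayes = list(burn_in = if (demo) 500L else 5000L,
                 iters = if (demo) 1000L else 10000L, thin = 5L),
    marginal = list(genome_wide_p = 3.6e-8, suggestive_p = 1e-5),
    seq = list(n_samples = 46L, n_sites = if (demo) 400L else 5000L,
               mean_depth = 30, min_doc = 2L, quantile = 0.99,
               min_samples = 40L, n_effect_sites = 5L),
    matching = list(n_per_sex = if (demo) 6L else 12L,
                    max_age_diff_days = 365),
    biomarker = list(alpha = 0.5, n_folds = 10L),
    gwas = list(n = if (demo) 500L else 2000L,
                p = if (demo) 800L else 5000L, h2_snp = 0.4,
                n_pcs = if (demo) 5L else 20L))
  cfg <- defaults
  for (nm in setdiff(names(defaults), "marginal")) {
    cfg[[nm]] <- utils::modifyList(defaults[[nm]], get(nm, inherits = FALSE))
  }
  structure(c(list(seed = as.integer(seed), stages = stages, demo = demo),
              cfg), class = "pipeline_config")
}

.fwrite_num <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in dependency order (simulate -> phenotype
#' -> Bayesian and marginal EWAS -> sequencing filters -> matching ->
#' biomarker -> evaluation -> genotype scan), writing every artifact as
#' TSV/JSON under `out_dir` plus a `manifest.json` recording the package
#' version, the full configuration, per-stage record counts and the md5
#' digest of every output. Outputs are byte-identical across repeated runs
#' with the same configuration.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created; must be empty or absent).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "smokemark",
                   version = as.character(utils::packageVersion("smokemark")),
                   seed = config$seed,
                   config = unclass(config),
                   counts = list(), files = list())
  stage_on <- function(s) s %in% config$stages
  need <- function(obj, stage, dep) {
    if (is.null(obj)) {
      stop("stage '", stage, "' requires upstream stage '", dep,
           "' which is disabled")
    }
    obj
  }
  log_count <- function(stage, ...) {
    manifest$counts[[stage]] <<- list(...)
    message("[", stage, "] ", paste(names(list(...)), unlist(list(...)),
                                    sep = "=", collapse = " "))
  }

  cohort <- NULL
  yproc <- NULL
  Xres <- NULL

  if (stage_on("cohort")) {
    cc <- config$cohort
    cohort <- simulate_methylation_cohort(sim_config(
      n_individuals = cc$n, n_cpgs = cc$p, target_h2 = cc$target_h2,
      never_smoker_fraction = cc$never_fraction, seed = config$seed))
    .fwrite_num(cohort$phenotype, file.path(out_dir, "phenotype.tsv"))
    .fwrite_num(data.frame(cpg_id = cohort$truth$cpg_id,
                           beta = cohort$truth$beta,
                           component = cohort$truth$component),
                file.path(out_dir, "truth_cpgs.tsv"))
    ph <- cohort$phenotype
    yproc <- transform_phenotype(ph$pack_years, ph$age, ph$sex)
    Xres <- residualize_methylation(beta_to_mvalue(cohort$methylation),
                                    ph$age, ph$sex, ph$batch)
    log_count("cohort", n = nrow(ph), p = ncol(cohort$methylation),
              realized_vexp = signif(cohort$truth$realized_vexp, 4))
  }

  if (stage_on("bayes")) {
    need(cohort, "bayes", "cohort")
    bc <- config$bayes
    post <- run_gibbs(Xres, yproc,
                      chain = chain_config(burn_in = bc$burn_in,
                                           post_burn_iterations = bc$iters,
                                           thin = bc$thin,
                                           seed = derive_seed(config$seed,
                                                              20L)))
    write_posterior_tsv(post, file.path(out_dir, "bayes_ewas.tsv"))
    ve <- variance_explained(post)
    .fwrite_num(data.frame(vexp = post$vexp, sigma2_e = post$sigma2_e,
                           sigma2_beta = post$sigma2_beta),
                file.path(out_dir, "bayes_chain.tsv"))
    log_count("bayes", retained = post$n_retained,
              vexp_mean = signif(ve[["mean"]], 4),
              pip_gt_95 = sum(post$pip > 0.95))
  }

  if (stage_on("marginal")) {
    need(cohort, "marginal", "cohort")
    ph <- cohort$phenotype
    res <- ewas_lm(cohort$methylation,
                   as.numeric(ph$smoking_status == "current"),
                   covariates = data.frame(age = ph$age,
                                           sex01 = as.numeric(ph$sex ==
                                                                "M")))
    .fwrite_num(as.data.frame(res), file.path(out_dir,
                                              "marginal_ewas.tsv"))
    hits <- tier_hits(res)
    log_count("marginal", lambda = signif(genomic_inflation(res$p), 4),
              genome_wide = length(hits$genome_wide),
              suggestive = length(hits$suggestive))
  }

  if (stage_on("seq")) {
    sc <- config$seq
    sim <- simulate_coverage(sc$n_samples, sc$n_sites,
                             platform = "short_read_panel",
                             mean_depth = sc$mean_depth,
                             n_effect_sites = sc$n_effect_sites,
                             seed = derive_seed(config$seed, 30L))
    flt <- apply_filters(sim$coverage,
                         filter_policy(min_doc = sc$min_doc,
                                       high_coverage_quantile = sc$quantile,
                                       min_samples = sc$min_samples))
    .fwrite_num(flt$audit, file.path(out_dir, "seq_filter_audit.tsv"))
    frac <- methylation_fraction(flt$coverage)
    seq_res <- ewas_lm(frac,
                       as.numeric(sim$truth$group == "case"))
    .fwrite_num(as.data.frame(seq_res),
                file.path(out_dir, "seq_ewas.tsv"))
    log_count("seq", sites_in = sc$n_sites,
              sites_out = nrow(flt$coverage$sites))
  }

  matched <- NULL
  if (stage_on("matching")) {
    qn <- simulate_smoking_phenotype(if (config$demo) 400L else 2000L,
                                     seed = derive_seed(config$seed, 40L))
    flags <- flag_inconsistent_records(qn)
    qn <- qn[!flags$flagged, , drop = FALSE]
    qn$age_days <- qn$current_age * 365.25
    cases <- select_cases(qn, n_per_sex = config$matching$n_per_sex)
    case_df <- qn[match(cases, qn$sample_id), ]
    pool <- qn[qn$smoking_status == "never", ]
    matched <- match_controls(case_df, pool,
                              config$matching$max_age_diff_days)
    val <- validate_pairs(matched$pairs,
                          config$matching$max_age_diff_days)
    .fwrite_num(val$pairs, file.path(out_dir, "matched_pairs.tsv"))
    log_count("matching", pairs = nrow(val$pairs),
              unmatched = length(matched$unmatched))
  }

  model <- NULL
  if (stage_on("biomarker")) {
    need(cohort, "biomarker", "cohort")
    model <- train_elastic_net(cohort$methylation, yproc,
                               alpha = config$biomarker$alpha,
                               n_folds = config$biomarker$n_folds,
                               seed = derive_seed(config$seed, 50L))
    write_biomarker_tsv(model, file.path(out_dir,
                                         "biomarker_weights.tsv"))
    log_count("biomarker", nonzero = length(model$weights),
              lambda = signif(model$lambda_selected, 5))
  }

  if (stage_on("evaluate")) {
    need(model, "evaluate", "biomarker")
    test <- simulate_methylation_cohort(sim_config(
      n_individuals = config$cohort$n, n_cpgs = config$cohort$p,
      target_h2 = config$cohort$target_h2,
      never_smoker_fraction = config$cohort$never_fraction,
      seed = derive_seed(config$seed, 60L)),
      architecture = cohort$truth$architecture)
    ph <- test$phenotype
    scr <- score(model, test$methylation)
    yt <- transform_phenotype(ph$pack_years, ph$age, ph$sex)
    rep <- evaluation_report(yt, scr, ph$smoking_status, ph$age, ph$sex)
    out <- c(list(incremental_r2 = rep$incremental_r2),
             as.list(rep$correlations),
             setNames(lapply(rep$contrasts, function(ct)
               ct[c("auc", "prauc", "n")]), names(rep$contrasts)))
    jsonlite::write_json(out, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_count("evaluate", inc_r2 = signif(rep$incremental_r2, 4),
              auc_cn = signif(rep$contrasts$current_vs_never$auc, 4))
  }

  if (stage_on("gwas")) {
    gc_ <- config$gwas
    gsim <- simulate_genotypes(gc_$n, gc_$p, h2_snp = gc_$h2_snp,
                               n_causal = max(10L, gc_$p %/% 100L),
                               seed = derive_seed(config$seed, 70L))
    pcs <- compute_pcs(gsim$genotypes, k = gc_$n_pcs)
    covs <- cbind(age = gsim$phenotype$age,
                  sex01 = as.numeric(gsim$phenotype$sex == "M"), pcs)
    scan <- gwas_scan(gsim$genotypes, gsim$phenotype$y, covs)
    .fwrite_num(scan$table, file.path(out_dir, "gwas_scan.tsv"))
    h2 <- he_regression(gsim$genotypes, gsim$phenotype$y)
    .fwrite_num(data.frame(h2 = h2[["h2"]], se = h2[["se"]],
                           lambda = scan$lambda),
                file.path(out_dir, "gwas_h2.tsv"))
    log_count("gwas", lambda = signif(scan$lambda, 4),
              h2 = signif(h2[["h2"]], 4))
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest$files <- lapply(setNames(files, files), function(f)
    unname(tools::md5sum(file.path(out_dir, f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
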