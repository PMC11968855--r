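test_that("cohort generator is seed-deterministic and respects invariants", {
  cfg <- sim_config(n_individuals = 120, n_cpgs = 150, seed = 3)
  a <- simulate_methylation_cohort(cfg)
  b <- simulate_methylation_cohort(cfg)
  expect_identical(a, b)

  expect_true(all(a$methylation >= 0 & a$methylation <= 1))
  expect_true(all(a$phenotype$pack_years >= 0))
  ## spike label iff zero effect
  expect_identical(a$truth$component == 0L, a$truth$beta == 0)
  ## bookkeeping: realized vexp recomputable exactly from emitted truth
  g <- a$truth$true_score
  e <- a$truth$noise
  pv <- function(x) mean((x - mean(x))^2)
  expect_equal(a$truth$realized_vexp, pv(g) / pv(g + e))
  ## never-smoker point mass matches the configured fraction
  expect_equal(mean(a$phenotype$pack_years == 0), 0.5, tolerance = 0.05)
})

test_that("architecture reuse yields a new cohort from the same world", {
  cfg <- sim_config(n_individuals = 80, n_cpgs = 60, seed = 5)
  a <- simulate_methylation_cohort(cfg)
  b <- simulate_methylation_cohort(sim_config(n_individuals = 80,
                                              n_cpgs = 60, seed = 6),
                                   architecture = a$truth$architecture)
  expect_identical(a$truth$beta, b$truth$beta)
  expect_false(identical(a$methylation, b$methylation))
})

test_that("realized variance explained tracks the target at n = 2000", {
  sim <- simulate_methylation_cohort(
    sim_config(n_individuals = 2000, n_cpgs = 300, target_h2 = 0.5,
               seed = 7))
  expect_gt(sim$truth$realized_vexp, 0.45)
  expect_lt(sim$truth$realized_vexp, 0.55)
})

test_that("null cohorts (h2 = 0) give a calibrated marginal EWAS", {
  lambdas <- vapply(1:5, function(s) {
    sim <- simulate_methylation_cohort(
      sim_config(n_individuals = 200, n_cpgs = 500, target_h2 = 0,
                 never_smoker_fraction = 0, seed = s))
    ph <- sim$phenotype
    y <- transform_phenotype(ph$pack_years, ph$age, ph$sex)
    res <- ewas_lm(sim$methylation, y,
                   covariates = data.frame(age = ph$age,
                                           sex01 = as.numeric(ph$sex == "M")))
    genomic_inflation(res$p)
  }, numeric(1))
  expect_lt(abs(mean(lambdas) - 1), 0.1)
})

test_that("config validation rejects bad worlds", {
  expect_error(sim_config(spike_fraction = 0.5,
                          slab_proportions = c(0.1, 0.1, 0.1, 0.1)),
               "sum to 1")
  expect_error(sim_config(target_h2 = 1), "target_h2")
  expect_error(sim_config(slab_variances = c(1, 0.1, 0.01, 0.001)),
               "increasing")
})

test_that("questionnaire generator: categories, zero inflation, corruption", {
  all_never <- simulate_smoking_phenotype(200, never_fraction = 1, seed = 2)
  expect_true(all(all_never$pack_years == 0))

  clean <- simulate_smoking_phenotype(500, corruption_rate = 0, seed = 4)
  flags <- flag_inconsistent_records(clean)
  expect_equal(sum(flags$flagged), 0)
  ## clean structural rules
  nev <- clean$smoking_status == "never"
  cur <- clean$smoking_status == "current"
  fo <- clean$smoking_status == "former"
  expect_true(all(clean$pack_years[nev] == 0))
  expect_true(all(is.na(clean$age_stopped[cur])))
  expect_true(all(clean$age_started[cur] < clean$current_age[cur]))
  expect_true(all(clean$age_stopped[fo] > clean$age_started[fo]))
  expect_true(all(clean$age_stopped[fo] <= clean$current_age[fo]))

  ## corruption: flagged count ~ Binomial(1000, 0.1) within 3 SD
  cor10 <- simulate_smoking_phenotype(1000, corruption_rate = 0.1, seed = 9)
  flagged <- sum(flag_inconsistent_records(cor10)$flagged)
  expect_gt(flagged, 100 - 3 * sqrt(1000 * 0.1 * 0.9))
  expect_lt(flagged, 100 + 3 * sqrt(1000 * 0.1 * 0.9))
})

test_that("coverage generator: count laws and retention behaviour", {
  sim <- simulate_coverage(46, 300, mean_depth = 30, seed = 11)
  ct <- sim$coverage
  expect_true(all(ct$meth <= ct$total, na.rm = TRUE))
  expect_true(all(ct$meth >= 0, na.rm = TRUE))
  expect_true(all(ct$sites$end - ct$sites$start == 2))
  expect_equal(mean(ct$total), 30, tolerance = 0.1 * 30)

  ## at mean depth 0.5 virtually no site survives the retention filter
  lo <- simulate_coverage(46, 200, mean_depth = 0.5, seed = 12)
  flt <- apply_filters(lo$coverage,
                       filter_policy(min_samples = 40,
                                     min_reads_platform = 10))
  expect_lt(nrow(flt$coverage$sites), 5)
})

test_that("designated coverage effect sites are detectable (power)", {
  hits <- vapply(1:5, function(s) {
    sim <- simulate_coverage(46, 100, mean_depth = 30, n_effect_sites = 1,
                             effect_size = 0.3, seed = s)
    frac <- methylation_fraction(sim$coverage)
    res <- ewas_lm(frac, as.numeric(sim$truth$group == "case"))
    res$p[match(sim$truth$effect_sites, res$site_id)] < 1e-5
  }, logical(1))
  expect_gte(sum(hits), 3) # majority of seeds
})

test_that("genotype generator: HWE dosages and causal-SNP power", {
  g <- simulate_genotypes(400, 50, maf_range = c(0.5, 0.5), h2_snp = 0,
                          seed = 3)
  expect_true(all(g$genotypes %in% 0:2))
  af <- colMeans(g$genotypes) / 2
  expect_lt(max(abs(af - 0.5)), 0.1)
  expect_equal(g$truth$realized_h2, 0)

  expect_error(simulate_genotypes(100, 50, n_causal = 60), "n_causal")

  ## single strong causal SNP attains the smallest p in a majority of seeds
  top <- vapply(1:5, function(s) {
    sim <- simulate_genotypes(2000, 50, h2_snp = 0.2, n_causal = 1,
                              seed = s)
    scan <- gwas_scan(sim$genotypes, sim$phenotype$y)
    scan$table$site_id[which.min(scan$table$p)] == sim$truth$causal
  }, logical(1))
  expect_gte(sum(top), 3)
})
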