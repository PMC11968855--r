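## synthetic_data module: generators that emulate the statistical structure
## of the restricted-access cohort data every downstream stage assumes.
## Each generator draws from its own RNG stream (see derive_seed) so adding
## a new simulation never shifts existing draws. Streams: 1 = methylation
## cohort, 2 = smoking questionnaire, 3 = sequencing coverage, 4 = genotypes.

#' Configuration for the synthetic methylation cohort generator
#'
#' The generative model mirrors the analysis prior: a per-CpG effect is zero
#' with probability `spike_fraction`, otherwise drawn from one of four
#' Gaussian components whose variances are `slab_variances` (fractions
#' 0.001, 0.01, 0.1, 1 of a common scale). Effects act on the M-value
#' (logit) scale; the stored matrix holds beta values in `[0, 1]`.
#'
#' @param n_individuals number of samples.
#' @param n_cpgs number of CpG sites.
#' @param spike_fraction prior probability of a null CpG.
#' @param slab_variances four increasing positive variance fractions.
#' @param slab_proportions four proportions; together with `spike_fraction`
#'   they must sum to 1.
#' @param target_h2 proportion of (covariate-adjusted) phenotype variance
#'   contributed by methylation, in `[0, 1)`.
#' @param covariate_effects list with `age` and `sex` effect sizes on the
#'   latent phenotype (standardized-covariate scale).
#' @param cpg_covariate_sd list with `age`, `sex`, `batch` SDs of per-CpG
#'   covariate loadings on the M-value scale.
#' @param never_smoker_fraction proportion of individuals with pack years
#'   fixed at zero (the lowest-latent-exposure tail).
#' @param n_batches number of processing batches.
#' @param ar1_rho optional AR(1) correlation between adjacent CpGs' noise
#'   (0 = independent; no attempt at realistic long-range structure).
#' @param pack_years_scale log-scale slope mapping the latent trait to pack
#'   years for smokers.
#' @param seed RNG seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 1000L,
                       n_cpgs = 2000L,
                       spike_fraction = 0.99,
                       slab_variances = c(0.001, 0.01, 0.1, 1.0),
                       slab_proportions = c(0.006, 0.003, 0.0008, 0.0002),
                       target_h2 = 0.5,
                       covariate_effects = list(age = 0.2, sex = 0.1),
                       cpg_covariate_sd = list(age = 0.1, sex = 0.1,
                                               batch = 0.2),
                       never_smoker_fraction = 0.5,
                       n_batches = 4L,
                       ar1_rho = 0,
                       pack_years_scale = 1.25,
                       seed = 1L) {
  stopifnot(n_individuals >= 1, n_cpgs >= 1)
  if (length(slab_variances) != 4L || any(slab_variances <= 0) ||
      any(diff(slab_variances) <= 0)) {
    stop("slab_variances must be 4 strictly increasing positive values")
  }
  if (length(slab_proportions) != 4L || any(slab_proportions < 0)) {
    stop("slab_proportions must be 4 non-negative proportions")
  }
  tot <- spike_fraction + sum(slab_proportions)
  if (abs(tot - 1) > 1e-8) {
    stop("spike_fraction + slab_proportions must sum to 1 (got ", tot, ")")
  }
  if (target_h2 < 0 || target_h2 >= 1) stop("target_h2 must be in [0, 1)")
  if (never_smoker_fraction < 0 || never_smoker_fraction > 1) {
    stop("never_smoker_fraction must be in [0, 1]")
  }
  if (abs(ar1_rho) >= 1) stop("ar1_rho must be in (-1, 1)")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_cpgs = as.integer(n_cpgs),
                 spike_fraction = spike_fraction,
                 slab_variances = slab_variances,
                 slab_proportions = slab_proportions,
                 target_h2 = target_h2,
                 covariate_effects = covariate_effects,
                 cpg_covariate_sd = cpg_covariate_sd,
                 never_smoker_fraction = never_smoker_fraction,
                 n_batches = as.integer(n_batches),
                 ar1_rho = ar1_rho,
                 pack_years_scale = pack_years_scale,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a methylation cohort with a sparse mixture-architecture phenotype
#'
#' Generates beta-value methylation (effects on the M-value scale, squashed
#' through the inverse logit), a zero-inflated pack-years phenotype driven
#' by a latent trait `covariates + methylation part + noise`, and a truth
#' record for parameter-recovery tests. The methylation part `g` is built
#' from the covariate-free component of methylation, so its variance share
#' is defined net of covariates: `realized_vexp = var(g) / var(g + e)`,
#' matching an analysis in which both phenotype and CpGs are
#' covariate-adjusted.
#'
#' @param config a [sim_config()].
#' @param architecture optional `truth$architecture` from a previous run:
#'   reuses that cohort's per-CpG baselines, covariate loadings, noise
#'   scales and true effects so a new draw represents new individuals from
#'   the same population (needed for cross-cohort score transfer).
#' @return list with `methylation` (n x p beta values), `phenotype`
#'   (data.frame), and `truth` (effects, component labels, per-individual
#'   true score, realized variance explained, and the reusable
#'   `architecture`).
#' @export
simulate_methylation_cohort <- function(config, architecture = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  p <- config$n_cpgs
  set.seed(derive_seed(config$seed, 1L))

  sample_id <- sprintf("S%05d", seq_len(n))
  cpg_id <- sprintf("cg%07d", seq_len(p))

  ## Covariates: GS-like age structure, majority-female sample, batches.
  age <- pmin(pmax(round(rnorm(n, 47.6, 14.9)), 18), 99)
  sex <- ifelse(runif(n) < 0.591, "F", "M")
  batch <- paste0("B", sample.int(config$n_batches, n, replace = TRUE))
  age_s <- if (popvar(age) > 0) standardize(age) else rep(0, n)
  sex01 <- as.numeric(sex == "M")
  sex_c <- sex01 - mean(sex01)

  ## Latent M-value methylation: baseline + covariate loadings + noise.
  ## The per-CpG architecture (baselines, loadings, noise scales, effects)
  ## defines the population; reuse it to draw an independent cohort from
  ## the same world.
  batch_lv <- paste0("B", seq_len(config$n_batches))
  if (is.null(architecture)) {
    arch <- list(
      b0 = qlogis(runif(p, 0.1, 0.9)),
      l_age = rnorm(p, 0, config$cpg_covariate_sd$age),
      l_sex = rnorm(p, 0, config$cpg_covariate_sd$sex),
      l_batch = matrix(rnorm(p * length(batch_lv), 0,
                             config$cpg_covariate_sd$batch),
                       nrow = length(batch_lv)),
      sigma_j = runif(p, 0.4, 1.2),
      beta = NULL, component = NULL)
  } else {
    arch <- architecture
    stopifnot(length(arch$b0) == p)
  }
  b0 <- arch$b0
  l_age <- arch$l_age
  l_sex <- arch$l_sex
  l_batch <- arch$l_batch
  sigma_j <- arch$sigma_j
  eps <- matrix(rnorm(n * p), n, p)
  if (config$ar1_rho != 0) {
    rho <- config$ar1_rho
    for (j in 2:p) eps[, j] <- rho * eps[, j - 1] + sqrt(1 - rho^2) * eps[, j]
  }
  eps <- sweep(eps, 2L, sigma_j, "*")

  M <- sweep(eps, 2L, b0, "+") +
    outer(age_s, l_age) + outer(sex_c, l_sex) +
    l_batch[match(batch, batch_lv), , drop = FALSE]

  ## Sparse effects on the standardized covariate-free noise component.
  if (is.null(arch$beta)) {
    comp <- rep(0L, p)
    beta <- rep(0, p)
    if (config$target_h2 > 0) {
      probs <- c(config$spike_fraction, config$slab_proportions)
      comp <- sample(0:4, p, replace = TRUE, prob = probs)
      nz <- comp > 0L
      if (!any(nz)) { # guarantee at least one causal CpG when h2 > 0
        comp[sample.int(p, 1L)] <- 4L
        nz <- comp > 0L
      }
      beta[nz] <- rnorm(sum(nz), 0,
                        sqrt(config$slab_variances[comp[nz]]))
      beta <- beta * sqrt(config$target_h2 / sum(beta^2))
    }
    arch$beta <- beta
    arch$component <- comp
  } else {
    beta <- arch$beta
    comp <- arch$component
  }
  eps_std <- standardize_cols(eps)
  g <- as.vector(eps_std %*% beta)

  vg <- popvar(g)
  if (config$target_h2 > 0) {
    var_e <- vg * (1 - config$target_h2) / config$target_h2
  } else {
    var_e <- 1
  }
  e <- rnorm(n, 0, sqrt(var_e))
  realized <- if (vg > 0) vg / popvar(g + e) else 0

  latent <- config$covariate_effects$age * age_s +
    config$covariate_effects$sex * sex_c + g + e

  ## Zero-inflated pack years: the lowest-exposure tail never smoked.
  t_std <- (latent - mean(latent)) / sqrt(popvar(latent))
  cut <- quantile(t_std, config$never_smoker_fraction, type = 7)
  pack_years <- ifelse(t_std <= cut, 0,
                       expm1((t_std - cut) * config$pack_years_scale))
  status <- ifelse(pack_years == 0, "never", "current")

  methylation <- mvalue_to_beta(M)
  dimnames(methylation) <- list(sample_id, cpg_id)

  phenotype <- data.frame(sample_id = sample_id, age = age, sex = sex,
                          batch = batch, pack_years = pack_years,
                          smoking_status = status,
                          stringsAsFactors = FALSE)
  truth <- list(cpg_id = cpg_id, beta = beta, component = comp,
                true_score = g, noise = e, latent = latent,
                realized_vexp = realized, architecture = arch)
  list(methylation = methylation, phenotype = phenotype, truth = truth)
}

#' Simulate smoking questionnaire records
#'
#' Emulates the questionnaire fields from which pack years are derived:
#' smoking status, cigarettes per day, start age, stop age (former smokers
#' only) and current age. Clean records satisfy all the consistency rules
#' checked by [flag_inconsistent_records()]; an optional corruption rate
#' injects one inconsistency per corrupted record for testing the flags.
#'
#' @param n number of records.
#' @param never_fraction proportion of never smokers.
#' @param corruption_rate per-record probability of injecting an
#'   inconsistency.
#' @param seed RNG seed.
#' @return data.frame with questionnaire fields and derived `pack_years`.
#' @export
simulate_smoking_phenotype <- function(n, never_fraction = 0.5,
                                       corruption_rate = 0, seed = 1L) {
  stopifnot(n >= 1, never_fraction >= 0, never_fraction <= 1,
            corruption_rate >= 0, corruption_rate <= 1)
  set.seed(derive_seed(seed, 2L))
  sample_id <- sprintf("Q%05d", seq_len(n))
  current_age <- pmin(pmax(round(rnorm(n, 47.6, 14.9)), 25), 99)
  sex <- ifelse(runif(n) < 0.591, "F", "M")
  batch <- paste0("B", sample.int(4L, n, replace = TRUE))
  status <- ifelse(runif(n) < never_fraction, "never",
                   ifelse(runif(n) < 0.5, "former", "current"))

  age_started <- rep(NA_real_, n)
  age_stopped <- rep(NA_real_, n)
  cigs_per_day <- rep(0, n)
  ever <- status != "never"
  age_started[ever] <- pmin(pmax(round(rnorm(sum(ever), 17, 3)), 10),
                            current_age[ever] - 1)
  cigs_per_day[ever] <- pmin(pmax(round(rlnorm(sum(ever), log(15), 0.5)),
                                  1), 80)
  fo <- status == "former"
  if (any(fo)) {
    span <- current_age[fo] - age_started[fo]
    age_stopped[fo] <- age_started[fo] + 1 +
      floor(runif(sum(fo)) * pmax(span - 1, 1))
    age_stopped[fo] <- pmin(age_stopped[fo], current_age[fo])
  }

  corrupted <- runif(n) < corruption_rate
  for (i in which(corrupted)) {
    if (status[i] == "never") {
      if (runif(1) < 0.5) cigs_per_day[i] <- 10 else age_started[i] <- 16
    } else if (status[i] == "former") {
      if (runif(1) < 0.5) {
        age_stopped[i] <- age_started[i] - sample.int(5L, 1L)
      } else {
        age_started[i] <- current_age[i] + sample.int(10L, 1L)
      }
    } else {
      if (runif(1) < 0.5) {
        age_stopped[i] <- age_started[i] + 1 # current smoker with stop age
      } else {
        age_started[i] <- current_age[i] + sample.int(10L, 1L)
      }
    }
  }

  tab <- data.frame(sample_id = sample_id, smoking_status = status,
                    cigs_per_day = cigs_per_day,
                    age_started = age_started, age_stopped = age_stopped,
                    current_age = current_age, sex = sex, batch = batch,
                    stringsAsFactors = FALSE)
  tab$pack_years <- compute_pack_years(tab)
  attr(tab, "corrupted") <- corrupted
  tab
}

#' Simulate per-site sequencing methylation coverage
#'
#' Read totals follow a negative binomial (overdispersed) distribution and
#' methylated counts a binomial given a per-site true methylation fraction;
#' designated effect sites carry a case-control shift in that fraction.
#'
#' @param n_samples total samples; the first `ceiling(n/2)` are cases.
#' @param n_sites number of CpG dinucleotide sites.
#' @param platform `"short_read_panel"` (bedGraph dialect) or
#'   `"long_read"` (bedMethyl dialect).
#' @param mean_depth mean read depth per site and sample.
#' @param dispersion negative-binomial size parameter.
#' @param n_effect_sites number of leading sites given a group shift.
#' @param effect_size shift of the case methylation fraction.
#' @param seed RNG seed.
#' @return list with a `CoverageTable` and a truth record (true fractions,
#'   group labels, effect-site ids).
#' @export
simulate_coverage <- function(n_samples, n_sites,
                              platform = c("short_read_panel", "long_read"),
                              mean_depth = 30, dispersion = 3,
                              n_effect_sites = 0L, effect_size = 0.3,
                              seed = 1L) {
  platform <- match.arg(platform)
  stopifnot(mean_depth > 0, n_samples >= 1, n_sites >= 1,
            n_effect_sites <= n_sites)
  set.seed(derive_seed(seed, 3L))
  samples <- sprintf("%s%03d", ifelse(seq_len(n_samples) <=
                                        ceiling(n_samples / 2), "CA", "CO"),
                     seq_len(n_samples))
  group <- rep(c("case", "control"),
               c(ceiling(n_samples / 2), floor(n_samples / 2)))

  start <- cumsum(sample(10:500, n_sites, replace = TRUE)) + 10000L
  sites <- data.frame(chrom = "chr1", start = start, end = start + 2L,
                      stringsAsFactors = FALSE)

  ## Bimodal methylome: most sites near-fully methylated, a CpG-island-like
  ## minority near zero.
  island <- runif(n_sites) < 0.3
  frac <- ifelse(island, rbeta(n_sites, 2, 8), rbeta(n_sites, 8, 2))
  frac <- pmin(pmax(frac, 0.02), 0.98)

  frac_mat <- matrix(frac, n_sites, n_samples)
  eff <- seq_len(n_effect_sites)
  if (n_effect_sites > 0L) {
    frac_mat[eff, group == "case"] <-
      pmin(pmax(frac_mat[eff, group == "case"] - effect_size, 0.02), 0.98)
  }

  total <- matrix(rnbinom(n_sites * n_samples, mu = mean_depth,
                          size = dispersion), n_sites, n_samples)
  meth <- matrix(rbinom(n_sites * n_samples, as.vector(total),
                        as.vector(frac_mat)), n_sites, n_samples)
  dimnames(total) <- dimnames(meth) <- list(NULL, samples)

  tab <- coverage_table(sites, meth, total, samples, platform = platform)
  truth <- list(true_fraction = frac, group = group,
                effect_sites = if (n_effect_sites > 0L)
                  site_ids(tab)[eff] else character(0))
  list(coverage = tab, truth = truth)
}

#' Simulate genotype dosages with a polygenic phenotype
#'
#' Dosages are drawn under Hardy-Weinberg equilibrium at allele frequencies
#' uniform on `maf_range`; the phenotype is a standardized polygenic part
#' (variance `h2_snp` of the non-covariate phenotype) plus Gaussian noise
#' and small age/sex effects.
#'
#' @param n_individuals,n_snps dimensions.
#' @param maf_range length-2 range within `(0, 0.5]`.
#' @param h2_snp SNP heritability in `[0, 1)`.
#' @param n_causal number of causal SNPs.
#' @param seed RNG seed.
#' @return list with `genotypes` (n x p dosage matrix), `snps` (data.frame),
#'   `phenotype` (data.frame with `y`, `age`, `sex`) and `truth`.
#' @export
simulate_genotypes <- function(n_individuals, n_snps,
                               maf_range = c(0.05, 0.5), h2_snp = 0.4,
                               n_causal = 50L, seed = 1L) {
  stopifnot(length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (h2_snp < 0 || h2_snp >= 1) stop("h2_snp must be in [0, 1)")
  if (n_causal > n_snps) stop("n_causal exceeds n_snps")
  set.seed(derive_seed(seed, 4L))
  n <- as.integer(n_individuals)
  p <- as.integer(n_snps)
  f <- runif(p, maf_range[1], maf_range[2])
  G <- matrix(rbinom(n * p, 2L, rep(f, each = n)), n, p)
  snp_id <- sprintf("rs%06d", seq_len(p))
  dimnames(G) <- list(sprintf("G%05d", seq_len(n)), snp_id)
  snps <- data.frame(snp_id = snp_id, chrom = "chr1",
                     pos = seq_len(p) * 1000L, a1 = "A", a2 = "G",
                     maf = f, stringsAsFactors = FALSE)

  beta <- rep(0, p)
  g <- rep(0, n)
  causal <- integer(0)
  if (h2_snp > 0 && n_causal > 0L) {
    causal <- sort(sample.int(p, n_causal))
    Zc <- standardize_cols(G[, causal, drop = FALSE])
    kept <- setdiff(seq_along(causal), attr(Zc, "dropped"))
    u <- rnorm(length(kept))
    g_raw <- as.vector(Zc %*% u)
    sc <- sqrt(h2_snp / popvar(g_raw))
    g <- g_raw * sc
    beta[causal[kept]] <- u * sc
  }
  var_e <- if (h2_snp > 0) popvar(g) * (1 - h2_snp) / h2_snp else 1
  e <- rnorm(n, 0, sqrt(var_e))
  age <- pmin(pmax(round(rnorm(n, 47.6, 14.9)), 18), 99)
  sex <- ifelse(runif(n) < 0.591, "F", "M")
  y <- 0.1 * standardize(age) + 0.05 * (sex == "M") + g + e

  phenotype <- data.frame(sample_id = rownames(G), y = y, age = age,
                          sex = sex, stringsAsFactors = FALSE)
  truth <- list(beta = beta, causal = snp_id[causal], polygenic = g,
                realized_h2 = if (h2_snp > 0) popvar(g) / popvar(g + e)
                else 0)
  list(genotypes = G, snps = snps, phenotype = phenotype, truth = truth)
}
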