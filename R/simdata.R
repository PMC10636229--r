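#' Simulation configuration for a synthetic case-control consortium
#'
#' Collects the generative parameters for a multi-study case-control
#' consortium with known genetic architecture. All simulator distributions are
#' synthetic stand-ins for an observational consortium: there is no public
#' generative model for the real data, so the generator exists to give every
#' analysis stage a ground-truth test bed, not to mimic any specific cohort.
#'
#' @param n_studies number of studies.
#' @param n_cases,n_controls per-study case and control counts (recycled to
#'   `n_studies`).
#' @param variant_spec data.frame with columns `maf` (minor allele frequency
#'   in (0, 0.5]) and `tag` (`"causal"` or `"null"`).
#' @param baseline_logit log-odds of disease at reference covariate values.
#' @param beta_g log-OR per allele copy for each causal variant.
#' @param beta_e log-OR for the exposure.
#' @param beta_gxe interaction log-OR (allele copy x exposure).
#' @param ge_dependence_theta log-OR of exposure per allele copy of the first
#'   causal variant in the source population (0 = gene-environment
#'   independence).
#' @param exposure_prevalence marginal prevalence of the binary exposure.
#' @param study_sd between-study SD of `beta_e` (meta-analysis heterogeneity).
#' @param n_source size of the simulated source population per study from
#'   which cases and controls are drawn retrospectively.
#' @param gamma named covariate log-OR vector for `age` (per year, centered at
#'   60), `sex` (male vs female) and `energy` (per kcal/d, centered at 2000).
#' @param dosage_sd SD of additive dosage noise; 0 gives hard genotype calls.
#' @param seed integer seed; identical seed + config gives identical output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_studies = 1L,
                       n_cases = 1000L,
                       n_controls = 1000L,
                       variant_spec = data.frame(maf = 0.3, tag = "causal"),
                       baseline_logit = stats::qlogis(0.15),
                       beta_g = 0,
                       beta_e = 0,
                       beta_gxe = 0,
                       ge_dependence_theta = 0,
                       exposure_prevalence = 0.4,
                       study_sd = 0,
                       n_source = NULL,
                       gamma = c(age = 0.01, sex = 0.2, energy = 0),
                       dosage_sd = 0,
                       seed = 1L) {
  variant_spec <- as.data.frame(variant_spec)
  stopifnot(all(c("maf", "tag") %in% names(variant_spec)))
  if (any(variant_spec$maf <= 0 | variant_spec$maf > 0.5)) {
    bad <- which(variant_spec$maf <= 0 | variant_spec$maf > 0.5)
    stop("MAF outside (0, 0.5] for variant(s): ", paste(bad, collapse = ", "))
  }
  if (!all(variant_spec$tag %in% c("causal", "null"))) {
    stop("variant tags must be 'causal' or 'null'")
  }
  n_cases <- rep_len(as.integer(n_cases), n_studies)
  n_controls <- rep_len(as.integer(n_controls), n_studies)
  if (any(n_cases <= 0L) || any(n_controls <= 0L)) stop("case/control counts must be positive")
  if (exposure_prevalence <= 0 || exposure_prevalence >= 1) stop("exposure_prevalence must be in (0,1)")
  if (study_sd < 0) stop("study_sd must be >= 0")
  n_causal <- sum(variant_spec$tag == "causal")
  beta_g <- rep_len(beta_g, max(n_causal, 1L))
  if (is.null(n_source)) n_source <- max(20000L, 5L * (max(n_cases) + max(n_controls)))
  structure(list(
    n_studies = as.integer(n_studies), n_cases = n_cases,
    n_controls = n_controls, variant_spec = variant_spec,
    baseline_logit = baseline_logit, beta_g = beta_g, beta_e = beta_e,
    beta_gxe = beta_gxe, ge_dependence_theta = ge_dependence_theta,
    exposure_prevalence = exposure_prevalence, study_sd = study_sd,
    n_source = as.integer(n_source), gamma = gamma, dosage_sd = dosage_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate Hardy-Weinberg genotypes, optionally with dosage noise
#'
#' Genotypes are drawn independently per variant as Binomial(2, maf), i.e.
#' under Hardy-Weinberg equilibrium without linkage disequilibrium. With
#' `dosage_sd > 0` the hard calls are perturbed by additive Gaussian noise and
#' clamped to `[0, 2]`, emulating expected allele-count dosages from
#' imputation.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param variant_spec data.frame with `maf` (in (0, 0.5]) and optionally
#'   `tag`; variants are named `rs1 ... rsM` on `chr1` at positions
#'   `1e6 * index` unless `chr`/`pos`/`rsid` columns are supplied.
#' @param seed optional integer seed.
#' @param dosage_sd SD of additive dosage noise (default 0: hard calls).
#' @return a [genotype_matrix()]; `info$maf` records the realized (sample)
#'   allele frequency, `info$maf_spec` the generating one.
#' @export
simulate_genotypes <- function(n_subjects, variant_spec, seed = NULL, dosage_sd = 0) {
  variant_spec <- as.data.frame(variant_spec)
  if (any(variant_spec$maf <= 0 | variant_spec$maf > 0.5)) {
    bad <- which(variant_spec$maf <= 0 | variant_spec$maf > 0.5)
    stop("MAF outside (0, 0.5] for variant(s): ", paste(bad, collapse = ", "))
  }
  stopifnot(n_subjects >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- nrow(variant_spec)
  g <- vapply(variant_spec$maf, function(p) stats::rbinom(n_subjects, 2L, p),
              numeric(n_subjects))
  g <- matrix(as.numeric(g), nrow = n_subjects, ncol = m)
  if (dosage_sd > 0) {
    g <- pmin(pmax(g + stats::rnorm(length(g), 0, dosage_sd), 0), 2)
  }
  info <- data.frame(
    chr = variant_spec$chr %||% rep("chr1", m),
    pos = variant_spec$pos %||% (1e6 * seq_len(m)),
    rsid = variant_spec$rsid %||% paste0("rs", seq_len(m)),
    a1 = "A", a2 = "T",
    maf = colMeans(g) / 2,
    maf_spec = variant_spec$maf,
    r2 = 1,
    tag = if ("tag" %in% names(variant_spec)) variant_spec$tag else "null",
    stringsAsFactors = FALSE
  )
  rownames(g) <- paste0("S", seq_len(n_subjects))
  genotype_matrix(g, info)
}

#' Simulate a binary exposure with controlled gene-environment dependence
#'
#' Draws exposure E with `logit P(E=1 | g) = a + theta * g`, where the
#' intercept `a` is solved numerically so the marginal prevalence matches the
#' target in the given genotype sample. `theta = 0` gives exact
#' gene-environment independence, the assumption under which the case-only
#' interaction test is valid.
#'
#' @param genotypes a [genotype_matrix()] or numeric dosage vector.
#' @param variant_id variant (column index or rsid) driving the dependence
#'   when a matrix is supplied.
#' @param theta log-OR of exposure per allele copy.
#' @param prevalence target marginal prevalence in (0, 1).
#' @param seed optional integer seed.
#' @return integer 0/1 exposure vector.
#' @export
simulate_exposure <- function(genotypes, variant_id = 1L, theta = 0,
                              prevalence, seed = NULL) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  g <- if (inherits(genotypes, "genotype_matrix")) {
    if (is.character(variant_id)) variant_id <- match(variant_id, genotypes$info$rsid)
    genotypes$dosage[, variant_id]
  } else {
    as.numeric(genotypes)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  f <- function(a) mean(stats::plogis(a + theta * g)) - prevalence
  lo <- -45; hi <- 45
  if (f(lo) > 0 || f(hi) < 0) {
    stop("no intercept achieves prevalence ", prevalence,
         " with theta = ", theta, " (degenerate configuration)")
  }
  a <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  stats::rbinom(length(g), 1L, stats::plogis(a + theta * g))
}

#' Simulate baseline covariates
#'
#' Age ~ Normal(60, 8), sex ~ Bernoulli(0.5) (1 = male), total energy ~
#' Normal(2000, 500) truncated positive. Arbitrary but documented defaults for
#' a nutritional-epidemiology test bed.
#'
#' @param n number of subjects.
#' @param seed optional integer seed.
#' @return data.frame with `age`, `sex`, `energy`.
#' @export
simulate_covariates <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  energy <- stats::rnorm(n, 2000, 500)
  while (any(energy <= 0)) {
    energy[energy <= 0] <- stats::rnorm(sum(energy <= 0), 2000, 500)
  }
  data.frame(age = stats::rnorm(n, 60, 8),
             sex = stats::rbinom(n, 1L, 0.5),
             energy = energy)
}

#' Simulate disease outcomes and draw a retrospective case-control sample
#'
#' Disease is generated from the logistic model
#' `logit P(D=1) = baseline_logit + beta_g * g + beta_e * e + beta_gxe * g * e
#' + gamma * covariates` in a source population, after which the requested
#' numbers of cases and controls are sampled without replacement — mirroring a
#' retrospective case-control design so marginal odds ratios stay
#' interpretable.
#'
#' @param genotypes a [genotype_matrix()] for the source population.
#' @param exposure 0/1 exposure vector.
#' @param covariates data.frame from [simulate_covariates()] (or NULL).
#' @param config a [sim_config()]; `beta_g`/`beta_gxe` act on the causal
#'   variants (interaction on the first causal variant).
#' @param n_cases,n_controls target sample sizes; NULL keeps the full source
#'   population (cohort mode).
#' @param seed optional integer seed.
#' @return list with `idx` (selected rows), `outcome` (0/1 for selected rows),
#'   `outcome_source` (full source outcome), `p_disease`.
#' @export
simulate_outcome <- function(genotypes, exposure, covariates, config,
                             n_cases = NULL, n_controls = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(is.finite(c(config$baseline_logit, config$beta_g, config$beta_e,
                       config$beta_gxe)))) stop("model coefficients must be finite")
  g <- genotypes$dosage
  causal <- which(genotypes$info$tag == "causal")
  eta <- rep(config$baseline_logit, nrow(g))
  if (length(causal)) {
    bg <- rep_len(config$beta_g, length(causal))
    eta <- eta + drop(g[, causal, drop = FALSE] %*% bg)
    eta <- eta + config$beta_gxe * g[, causal[1L]] * exposure
  }
  eta <- eta + config$beta_e * exposure
  if (!is.null(covariates)) {
    gam <- config$gamma
    eta <- eta + gam[["age"]] * (covariates$age - 60) +
      gam[["sex"]] * covariates$sex +
      gam[["energy"]] * (covariates$energy - 2000)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- stats::plogis(eta)
  d <- stats::rbinom(length(p), 1L, p)
  if (is.null(n_cases)) {
    return(list(idx = seq_along(d), outcome = d, outcome_source = d, p_disease = p))
  }
  cases <- which(d == 1L)
  controls <- which(d == 0L)
  if (length(cases) < n_cases) {
    stop("source population produced ", length(cases), " cases but ", n_cases,
         " were requested; increase n_source or baseline_logit")
  }
  if (length(controls) < n_controls) {
    stop("source population produced ", length(controls), " controls but ",
         n_controls, " were requested; increase n_source")
  }
  idx <- c(sample(cases, n_cases), sample(controls, n_controls))
  list(idx = idx, outcome = d[idx], outcome_source = d, p_disease = p)
}

#' Simulate a multi-study case-control consortium
#'
#' Generates `n_studies` independent studies sharing one variant panel. Each
#' study's exposure log-OR is drawn Normal(`beta_e`, `study_sd`^2) to induce
#' controllable between-study heterogeneity for the meta-analysis stage. One
#' global seed deterministically spawns independent per-study substreams.
#'
#' @param config a [sim_config()].
#' @return list of studies; each has `genotypes` (a [genotype_matrix()]),
#'   `phenotypes` (data.frame: subject_id, outcome, study, exposure, age, sex,
#'   energy) and `truth` (generating parameters, incl. the realized per-study
#'   `beta_e`).
#' @export
simulate_consortium <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- spawn_seeds(config$seed, config$n_studies + 1L)
  set.seed(seeds[config$n_studies + 1L])
  beta_e_study <- stats::rnorm(config$n_studies, config$beta_e, config$study_sd)
  lapply(seq_len(config$n_studies), function(s) {
    set.seed(seeds[s])
    geno_src <- simulate_genotypes(config$n_source, config$variant_spec,
                                   dosage_sd = 0)
    causal <- which(geno_src$info$tag == "causal")
    gdep <- if (length(causal)) causal[1L] else 1L
    expo <- simulate_exposure(geno_src, gdep, config$ge_dependence_theta,
                              config$exposure_prevalence)
    covs <- simulate_covariates(config$n_source)
    cfg_s <- config
    cfg_s$beta_e <- beta_e_study[s]
    out <- simulate_outcome(geno_src, expo, covs, cfg_s,
                            n_cases = config$n_cases[s],
                            n_controls = config$n_controls[s])
    idx <- out$idx
    dos <- geno_src$dosage[idx, , drop = FALSE]
    if (config$dosage_sd > 0) {
      dos <- pmin(pmax(dos + stats::rnorm(length(dos), 0, config$dosage_sd), 0), 2)
    }
    ids <- sprintf("study%d_%05d", s, seq_along(idx))
    rownames(dos) <- ids
    info <- geno_src$info
    info$maf <- colMeans(dos) / 2
    pheno <- data.frame(
      subject_id = ids,
      outcome = out$outcome,
      study = paste0("study", s),
      exposure = expo[idx],
      age = covs$age[idx],
      sex = covs$sex[idx],
      energy = covs$energy[idx],
      stringsAsFactors = FALSE
    )
    list(
      genotypes = genotype_matrix(dos, info),
      phenotypes = pheno,
      truth = list(beta_g = config$beta_g, beta_e = beta_e_study[s],
                   beta_gxe = config$beta_gxe,
                   theta = config$ge_dependence_theta,
                   baseline_logit = config$baseline_logit,
                   seed = seeds[s], study = paste0("study", s))
    )
  })
}

#' Stack the studies of a consortium into one pooled analysis set
#'
#' @param studies output of [simulate_consortium()].
#' @return list with pooled `genotypes` and `phenotypes` (study kept as a
#'   column for fixed-effect adjustment).
#' @export
pool_consortium <- function(studies) {
  dos <- do.call(rbind, lapply(studies, function(s) s$genotypes$dosage))
  pheno <- do.call(rbind, lapply(studies, function(s) s$phenotypes))
  rownames(pheno) <- NULL
  info <- studies[[1L]]$genotypes$info
  info$maf <- colMeans(dos) / 2
  list(genotypes = genotype_matrix(dos, info), phenotypes = pheno)
}
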