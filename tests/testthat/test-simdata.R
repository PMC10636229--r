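test_that("genotypes follow Hardy-Weinberg proportions", {
  spec <- data.frame(maf = c(0.1, 0.25, 0.5), tag = "null")
  g <- simulate_genotypes(50000, spec, seed = 42)
  for (j in 1:3) {
    p <- spec$maf[j]
    obs <- tabulate(g$dosage[, j] + 1L, 3)
    expected <- 50000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    chi2 <- sum((obs - expected)^2 / expected)
    expect_lt(chi2, qchisq(0.999, df = 2))
  }
  # mean dosage at maf = 0.5 is 1 within 3 SE
  se <- sqrt(2 * 0.5 * 0.5 / 50000)
  expect_lt(abs(mean(g$dosage[, 3]) - 1), 3 * se)
})

test_that("genotype simulation is deterministic and rejects bad MAF", {
  spec <- data.frame(maf = 0.2, tag = "null")
  g1 <- simulate_genotypes(3, spec, seed = 9)
  g2 <- simulate_genotypes(3, spec, seed = 9)
  expect_identical(g1$dosage, g2$dosage)
  expect_error(simulate_genotypes(10, data.frame(maf = 0.7, tag = "null")),
               "variant")
  expect_error(simulate_genotypes(10, data.frame(maf = 0, tag = "null")),
               "MAF")
})

test_that("dosage noise keeps values in [0, 2] with the right mean", {
  spec <- data.frame(maf = 0.3, tag = "null")
  g <- simulate_genotypes(20000, spec, seed = 5, dosage_sd = 0.2)
  expect_true(all(g$dosage >= 0 & g$dosage <= 2))
  # clamping at the boundaries biases the mean slightly upward at this maf
  expect_lt(abs(mean(g$dosage) - 0.6), 0.05)
  expect_false(all(g$dosage %in% 0:2))
})

test_that("exposure simulation hits the target prevalence and dependence", {
  spec <- data.frame(maf = 0.3, tag = "null")
  g <- simulate_genotypes(10000, spec, seed = 1)
  e0 <- simulate_exposure(g, 1, theta = 0, prevalence = 0.4, seed = 2)
  se <- sqrt(0.4 * 0.6 / 10000)
  expect_lt(abs(mean(e0) - 0.4), 3 * se)
  # independence: logistic slope CI covers 0
  f0 <- glm(e0 ~ g$dosage[, 1], family = binomial())
  ci <- coef(f0)[2] + c(-1, 1) * qnorm(0.975) * sqrt(diag(vcov(f0)))[2]
  expect_true(ci[1] < 0 && ci[2] > 0)

  g2 <- simulate_genotypes(50000, spec, seed = 3)
  e1 <- simulate_exposure(g2, 1, theta = log(1.5), prevalence = 0.4, seed = 4)
  f1 <- glm(e1 ~ g2$dosage[, 1], family = binomial())
  ci1 <- coef(f1)[2] + c(-1, 1) * qnorm(0.975) * sqrt(diag(vcov(f1)))[2]
  expect_true(ci1[1] < log(1.5) && ci1[2] > log(1.5))
})

test_that("degenerate exposure prevalence is rejected", {
  g <- simulate_genotypes(100, data.frame(maf = 0.3, tag = "null"), seed = 1)
  expect_error(simulate_exposure(g, 1, theta = 0, prevalence = 1.2), "prevalence")
  expect_error(simulate_exposure(g, 1, theta = 200, prevalence = 1e-12),
               "prevalence|degenerate")
})

test_that("the null disease model reproduces the baseline prevalence", {
  cfg <- sim_config(baseline_logit = qlogis(0.3), beta_g = 0, beta_e = 0,
                    beta_gxe = 0, gamma = c(age = 0, sex = 0, energy = 0),
                    seed = 1)
  g <- simulate_genotypes(20000, cfg$variant_spec, seed = 2)
  e <- simulate_exposure(g, 1, 0, 0.4, seed = 3)
  cov <- simulate_covariates(20000, seed = 4)
  out <- simulate_outcome(g, e, cov, cfg, seed = 5)
  se <- sqrt(0.3 * 0.7 / 20000)
  expect_lt(abs(mean(out$outcome) - 0.3), 3 * se)
})

test_that("impossible case-control targets raise the advisory error", {
  cfg <- sim_config(baseline_logit = -50, beta_g = 0, beta_e = 0, beta_gxe = 0,
                    seed = 1)
  g <- simulate_genotypes(500, cfg$variant_spec, seed = 2)
  e <- simulate_exposure(g, 1, 0, 0.4, seed = 3)
  expect_error(simulate_outcome(g, e, NULL, cfg, n_cases = 10, n_controls = 10,
                                seed = 4),
               "increase n_source|cases")
})

test_that("interaction fits on retrospective samples recover beta_gxe", {
  # moderate replicate count; coverage is re-checked at scale in acceptance
  covered <- logical(40)
  bias <- numeric(40)
  for (r in 1:40) {
    cfg <- sim_config(n_cases = 1500, n_controls = 1500,
                      variant_spec = data.frame(maf = 0.3, tag = "causal"),
                      beta_g = 0, beta_e = 0, beta_gxe = log(2),
                      exposure_prevalence = 0.4, n_source = 18000,
                      seed = 100 + r)
    st <- simulate_consortium(cfg)[[1]]
    ph <- st$phenotypes
    t1 <- test_gxe(st$genotypes$dosage[, 1], ph$exposure, ph$outcome)
    covered[r] <- abs(t1$beta_gxe - log(2)) < qnorm(0.975) * t1$se_gxe
    bias[r] <- t1$beta_gxe - log(2)
  }
  expect_gt(mean(covered), 0.85)
  expect_lt(abs(mean(bias)), 0.08)
})

test_that("consortium generation is deterministic with aligned subjects", {
  cfg <- sim_config(n_studies = 3, n_cases = 100, n_controls = 100,
                    variant_spec = data.frame(maf = c(0.2, 0.4),
                                              tag = c("causal", "null")),
                    n_source = 3000, seed = 11)
  c1 <- simulate_consortium(cfg)
  c2 <- simulate_consortium(cfg)
  expect_identical(c1[[2]]$genotypes$dosage, c2[[2]]$genotypes$dosage)
  expect_identical(c1[[3]]$phenotypes, c2[[3]]$phenotypes)
  for (s in c1) {
    expect_identical(rownames(s$genotypes$dosage), s$phenotypes$subject_id)
    expect_equal(sum(s$phenotypes$outcome), 100)
    expect_equal(sum(1 - s$phenotypes$outcome), 100)
    expect_true(all(s$genotypes$dosage >= 0 & s$genotypes$dosage <= 2))
  }
  # single-study consortium degenerates cleanly
  cfg1 <- sim_config(n_studies = 1, n_cases = 50, n_controls = 50,
                     n_source = 2000, seed = 3)
  expect_length(simulate_consortium(cfg1), 1L)
})

test_that("homogeneous consortia show only sampling-error heterogeneity", {
  cfg <- sim_config(n_studies = 5, n_cases = 800, n_controls = 800,
                    beta_e = log(0.9), study_sd = 0, n_source = 10000,
                    baseline_logit = qlogis(0.2), seed = 21)
  studies <- simulate_consortium(cfg)
  ests <- lapply(studies, function(s)
    study_estimate(s$phenotypes, "exposure", "binary"))
  m <- pool_random_effects(ests)
  # Q ~ chi2 with k-1 df under homogeneity
  expect_lt(m$Q, qchisq(0.995, df = 4))
  expect_lt(m$tau2, 0.05)
})

test_that("between-study variance is detected when simulated", {
  pos <- logical(25)
  for (r in 1:25) {
    cfg <- sim_config(n_studies = 8, n_cases = 400, n_controls = 400,
                      beta_e = log(0.9), study_sd = 0.35, n_source = 6000,
                      baseline_logit = qlogis(0.2), seed = 300 + r)
    studies <- simulate_consortium(cfg)
    ests <- lapply(studies, function(s)
      study_estimate(s$phenotypes, "exposure", "binary"))
    pos[r] <- pool_random_effects(ests)$tau2 > 0
  }
  expect_gt(mean(pos), 0.5)
})
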