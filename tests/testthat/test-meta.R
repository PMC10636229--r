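test_that("identical studies pool to themselves with zero heterogeneity", {
  est <- data.frame(study_id = paste0("s", 1:4), log_or = rep(-0.1, 4),
                    se = rep(0.05, 4))
  m <- pool_random_effects(est)
  expect_equal(m$pooled_log_or, -0.1)
  expect_equal(m$tau2, 0)
  expect_equal(m$Q, 0)
  expect_equal(m$i2, 0)
})

test_that("two equal-precision studies pool to the midpoint", {
  est <- data.frame(log_or = c(0.1, 0.3), se = c(0.1, 0.1))
  m <- pool_random_effects(est)
  expect_equal(m$pooled_log_or, 0.2, tolerance = 1e-12)
})

test_that("k = 1 degenerates to the study estimate", {
  est <- data.frame(log_or = 0.25, se = 0.1)
  m <- pool_random_effects(est)
  expect_true(m$degenerate)
  expect_equal(m$pooled_log_or, 0.25)
  expect_equal(m$ci_high - m$ci_low, 2 * qnorm(0.975) * 0.1, tolerance = 1e-10)
})

test_that("non-positive standard errors are rejected by name", {
  est <- data.frame(study_id = c("good", "bad"), log_or = c(0.1, 0.2),
                    se = c(0.1, 0))
  expect_error(pool_random_effects(est), "bad")
})

test_that("DL and REML tau2 match metafor and a grid-search oracle", {
  skip_if_not_installed("metafor")
  set.seed(20)
  y <- rnorm(6, 0.2, 0.25)
  se <- runif(6, 0.08, 0.2)
  est <- data.frame(log_or = y, se = se)

  m_dl <- pool_random_effects(est, tau2_method = "DL", hk = TRUE)
  ref_dl <- metafor::rma(yi = y, sei = se, method = "DL", test = "knha")
  expect_equal(m_dl$tau2, unname(ref_dl$tau2), tolerance = 1e-8)
  expect_equal(m_dl$pooled_log_or, unname(ref_dl$beta[1]), tolerance = 1e-8)
  expect_equal(m_dl$ci_low, unname(ref_dl$ci.lb), tolerance = 1e-6)
  expect_equal(m_dl$ci_high, unname(ref_dl$ci.ub), tolerance = 1e-6)
  expect_equal(m_dl$p, unname(ref_dl$pval), tolerance = 1e-6)

  m_reml <- pool_random_effects(est, tau2_method = "REML")
  ref_reml <- metafor::rma(yi = y, sei = se, method = "REML")
  expect_equal(m_reml$tau2, unname(ref_reml$tau2), tolerance = 1e-4)

  # independent grid-search oracle for the REML criterion
  grid <- seq(0, 0.5, by = 1e-4)
  crit <- vapply(grid, function(t2) {
    w <- 1 / (se^2 + t2)
    mu <- sum(w * y) / sum(w)
    0.5 * (sum(log(se^2 + t2)) + log(sum(w)) + sum(w * (y - mu)^2))
  }, numeric(1))
  expect_lt(abs(m_reml$tau2 - grid[which.min(crit)]), 2e-4)  # grid step 1e-4
})

test_that("HK interval is wider than the normal interval when Q > df", {
  set.seed(21)
  y <- c(-0.4, 0.1, 0.5, -0.2, 0.6)
  se <- rep(0.08, 5)
  m_hk <- pool_random_effects(data.frame(log_or = y, se = se), hk = TRUE)
  m_n <- pool_random_effects(data.frame(log_or = y, se = se), hk = FALSE)
  expect_gt(m_hk$Q, m_hk$df)
  expect_gt(m_hk$ci_high - m_hk$ci_low, m_n$ci_high - m_n$ci_low)
  # modified-HK truncation can only widen the plain HK interval
  m_tr <- pool_random_effects(data.frame(log_or = y, se = se), hk = TRUE,
                              hk_truncate = TRUE)
  expect_gte(m_tr$ci_high - m_tr$ci_low, m_hk$ci_high - m_hk$ci_low)
})

test_that("with many homogeneous studies HK approaches the normal CI", {
  set.seed(22)
  y <- rnorm(50, 0.1, 0.2)  # spread matches the within-study SE: homogeneity
  se <- rep(0.2, 50)
  m_hk <- pool_random_effects(data.frame(log_or = y, se = se), hk = TRUE)
  m_n <- pool_random_effects(data.frame(log_or = y, se = se), hk = FALSE)
  w_hk <- m_hk$ci_high - m_hk$ci_low
  w_n <- m_n$ci_high - m_n$ci_low
  expect_lt(abs(w_hk - w_n) / w_n, 0.1)
})

test_that("the pooled estimate lies within the study range, order-invariantly", {
  set.seed(23)
  for (i in 1:20) {
    k <- sample(2:10, 1)
    est <- data.frame(log_or = rnorm(k, 0, 0.4), se = runif(k, 0.05, 0.4))
    m <- pool_random_effects(est)
    expect_gte(m$pooled_log_or, min(est$log_or))
    expect_lte(m$pooled_log_or, max(est$log_or))
    m2 <- pool_random_effects(est[sample(k), ])
    expect_equal(m$pooled_log_or, m2$pooled_log_or, tolerance = 1e-12)
    expect_equal(m$tau2, m2$tau2, tolerance = 1e-12)
  }
})

test_that("I2 follows its closed form with a floor at zero", {
  expect_equal(heterogeneity_i2(10, 5), 50)
  expect_equal(heterogeneity_i2(3, 5), 0)
  expect_equal(heterogeneity_i2(5, 5), 0)
  expect_error(heterogeneity_i2(-1, 5))
})

test_that("two-subgroup heterogeneity equals the z-test on the difference", {
  m1 <- pool_random_effects(data.frame(log_or = c(0.1, 0.2), se = c(0.1, 0.1)))
  m2 <- pool_random_effects(data.frame(log_or = c(-0.2, -0.1), se = c(0.12, 0.12)))
  het <- subgroup_heterogeneity(list(m1, m2))
  z <- (m1$pooled_log_or - m2$pooled_log_or) / sqrt(m1$se^2 + m2$se^2)
  expect_equal(het$p, 2 * pnorm(-abs(z)), tolerance = 1e-10)
  # identical subgroups: p = 1
  het0 <- subgroup_heterogeneity(list(m1, m1))
  expect_equal(het0$p, 1)
  expect_error(subgroup_heterogeneity(list(m1)), "2 subgroups")
})

test_that("subgroup heterogeneity p-values are uniform under equal truth", {
  set.seed(24)
  ps <- replicate(500, {
    # single-study subgroups make the subgroup SEs exact, so the null
    # distribution of Q_between is exactly chi-square
    e1 <- data.frame(log_or = rnorm(1, 0.1, 0.1), se = 0.1)
    e2 <- data.frame(log_or = rnorm(1, 0.1, 0.12), se = 0.12)
    subgroup_heterogeneity(list(pool_random_effects(e1),
                                pool_random_effects(e2)))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("funnel export sorts by SE and flags planted outliers", {
  est <- data.frame(study_id = paste0("s", 1:6),
                    log_or = c(0.1, 0.12, 0.09, 0.11, 0.1, 1.1),
                    se = c(0.05, 0.2, 0.08, 0.1, 0.06, 0.2))
  fd <- funnel_data(est)
  expect_true(all(diff(fd$se) >= 0))
  expect_true(fd$outlier[fd$study_id == "s6"])
  expect_false(any(fd$outlier[fd$study_id != "s6"]))
  one <- funnel_data(est[1, ])
  expect_equal(nrow(one), 1L)
  expect_false(one$outlier)
})

test_that("study_estimate recovers a simulated per-quartile trend", {
  set.seed(25)
  n <- 4000
  q <- sample(0:3, n, replace = TRUE)
  age <- rnorm(n, 60, 8); sex <- rbinom(n, 1, 0.5); energy <- rnorm(n, 2000, 500)
  d <- rbinom(n, 1, plogis(-0.5 + log(0.9) * q + 0.01 * (age - 60)))
  ph <- data.frame(subject_id = seq_len(n), outcome = d, study = "s1",
                   folate_q = q, age = age, sex = sex, energy = energy)
  est <- study_estimate(ph, "folate_q", "quartile")
  expect_lt(abs(est$log_or - log(0.9)), qnorm(0.975) * est$se)
  expect_error(study_estimate(transform(ph, outcome = 0), "folate_q"),
               "case and one control")
  # sensitivity covariate set widens the design by two columns
  ph$bmi_scaled <- rnorm(n, 5.4, 0.9)
  ph$smoking <- sample(c("never", "ever"), n, replace = TRUE)
  est2 <- study_estimate(ph, "folate_q", "quartile",
                         covariates = c("age", "sex", "energy", "bmi_scaled",
                                        "smoking"))
  expect_true(is.finite(est2$log_or))
})
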