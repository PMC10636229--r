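#' Study-level exposure association estimate
#'
#' Fits the study-specific logistic model of disease on the exposure —
#' per-quartile linear trend for an ordinal exposure, user-vs-nonuser for a
#' binary one — adjusted by default for age at the referent time, sex and
#' total energy; the sensitivity covariate set additionally adjusts for BMI
#' (per 5 kg/m^2) and never/ever smoking.
#'
#' @param pheno one study's phenotype data.frame with `outcome` and the
#'   exposure and covariate columns.
#' @param exposure_name exposure column name.
#' @param exposure_type `"binary"` or `"quartile"` (ordinal trend).
#' @param covariates adjustment covariates (default `c("age", "sex",
#'   "energy")`); use `c("age", "sex", "energy", "bmi_scaled", "smoking")`
#'   for the sensitivity set.
#' @return list of class `study_estimate`: `study_id`, `log_or`, `se`,
#'   `n_cases`, `n_controls`, `separation_flag`, `converged`.
#' @export
study_estimate <- function(pheno, exposure_name,
                           exposure_type = c("binary", "quartile"),
                           covariates = c("age", "sex", "energy")) {
  exposure_type <- match.arg(exposure_type)
  e <- pheno[[exposure_name]]
  if (is.null(e)) stop("exposure column '", exposure_name, "' not found")
  d <- pheno$outcome
  cc <- !is.na(e) & !is.na(d)
  covmat <- covariate_matrix(pheno, covariates)
  if (!is.null(covmat)) cc <- cc & stats::complete.cases(covmat)
  e <- e[cc]; d <- d[cc]
  cm <- if (!is.null(covmat)) covmat[cc, , drop = FALSE]
  if (sum(d == 1L) < 1L || sum(d == 0L) < 1L) {
    stop("study needs at least one case and one control")
  }
  if (stats::var(e) == 0) stop("exposure is constant in this study")
  x <- cbind(`(Intercept)` = 1, exposure = e, cm)
  fit <- fit_logistic(x, d)
  structure(list(
    study_id = as.character(pheno$study[1] %||% "study"),
    log_or = unname(fit$coefficients["exposure"]),
    se = sqrt(fit$covariance["exposure", "exposure"]),
    n_cases = sum(d == 1L), n_controls = sum(d == 0L),
    separation_flag = fit$separation_flag, converged = fit$converged
  ), class = "study_estimate")
}

#' Random-effects meta-analysis with the Hartung-Knapp adjustment
#'
#' Pools study-level log odds ratios. The between-study variance tau^2 is
#' estimated by DerSimonian-Laird (`max(0, (Q - df) / C)`) or REML; weights
#' are `1 / (se^2 + tau^2)`. With `hk = TRUE` (default) the pooled variance
#' is the Hartung-Knapp estimator `q / sum(w)` with
#' `q = sum(w (y - pooled)^2) / (k - 1)` and the confidence interval uses the
#' t distribution with `k - 1` df. The plain (untruncated) HK variance is the
#' default; `hk_truncate = TRUE` applies the modified-HK floor `q >= 1` so
#' the CI is never narrower than the normal-approximation CI.
#'
#' @param estimates list of [study_estimate()] objects, or a data.frame with
#'   `study_id`, `log_or`, `se`.
#' @param tau2_method `"DL"` (default) or `"REML"`.
#' @param hk use the Hartung-Knapp CI (default TRUE).
#' @param hk_truncate apply the modified-HK variance floor (default FALSE).
#' @param conf_level confidence level (default 0.95).
#' @return list of class `meta_result`: `pooled_log_or`, `ci_low`, `ci_high`,
#'   `se`, `tau2`, `Q`, `df`, `i2`, `p`, `method`, `weights` (normalized),
#'   `k`, `degenerate` (TRUE when k = 1).
#' @export
pool_random_effects <- function(estimates, tau2_method = c("DL", "REML"),
                                hk = TRUE, hk_truncate = FALSE,
                                conf_level = 0.95) {
  tau2_method <- match.arg(tau2_method)
  est <- as_estimate_df(estimates)
  if (any(est$se <= 0)) {
    stop("non-positive standard error for study: ",
         paste(est$study_id[est$se <= 0], collapse = ", "))
  }
  k <- nrow(est)
  y <- est$log_or; v <- est$se^2
  if (k == 1L) {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    return(structure(list(
      pooled_log_or = y, ci_low = y - z * est$se, ci_high = y + z * est$se,
      se = est$se, tau2 = 0, Q = 0, df = 0, i2 = 0,
      p = 2 * stats::pnorm(-abs(y / est$se)),
      method = "single-study", weights = 1, k = 1L, degenerate = TRUE
    ), class = "meta_result"))
  }
  wf <- 1 / v
  yf <- sum(wf * y) / sum(wf)
  Q <- sum(wf * (y - yf)^2)
  df <- k - 1L
  C <- sum(wf) - sum(wf^2) / sum(wf)
  tau2 <- if (tau2_method == "DL") max(0, (Q - df) / C) else reml_tau2(y, v)
  w <- 1 / (v + tau2)
  pooled <- sum(w * y) / sum(w)
  var_fe <- 1 / sum(w)
  if (hk) {
    q <- sum(w * (y - pooled)^2) / df
    if (hk_truncate) q <- max(q, 1)
    se_p <- sqrt(q * var_fe)
    crit <- stats::qt(1 - (1 - conf_level) / 2, df)
    p <- 2 * stats::pt(-abs(pooled / se_p), df)
  } else {
    se_p <- sqrt(var_fe)
    crit <- stats::qnorm(1 - (1 - conf_level) / 2)
    p <- 2 * stats::pnorm(-abs(pooled / se_p))
  }
  structure(list(
    pooled_log_or = pooled, ci_low = pooled - crit * se_p,
    ci_high = pooled + crit * se_p, se = se_p, tau2 = tau2, Q = Q, df = df,
    i2 = heterogeneity_i2(Q, df), p = p,
    method = paste0(tau2_method, if (hk) "+HK" else ""),
    weights = w / sum(w), k = k, degenerate = FALSE
  ), class = "meta_result")
}

# profile REML estimate of tau^2 by 1-d optimization
reml_tau2 <- function(y, v, upper = NULL) {
  if (is.null(upper)) upper <- max(10 * stats::var(y), 1e-3)
  nll <- function(t2) {
    w <- 1 / (v + t2)
    mu <- sum(w * y) / sum(w)
    0.5 * (sum(log(v + t2)) + log(sum(w)) + sum(w * (y - mu)^2))
  }
  opt <- stats::optimize(nll, c(0, upper), tol = 1e-10)
  # guard against an interior optimum reported at the boundary
  if (nll(0) <= opt$objective) 0 else opt$minimum
}

#' Inconsistency index I-squared
#'
#' Percentage of between-study variability attributable to heterogeneity
#' rather than sampling error: `I2 = max(0, (Q - df) / Q) * 100`.
#'
#' @param Q Cochran's Q statistic (>= 0).
#' @param df its degrees of freedom (number of studies minus 1).
#' @return percentage in `[0, 100]`.
#' @export
heterogeneity_i2 <- function(Q, df) {
  stopifnot(Q >= 0, df >= 1)
  max(0, (Q - df) / Q) * 100
}

#' Between-subgroup heterogeneity test
#'
#' Compares pooled estimates across subgroups (e.g. males vs females) with
#' the fixed-effect between-group Q statistic: `Q_between = sum(w_j *
#' (y_j - ybar)^2)` with `w_j = 1 / se(y_j)^2`, referred to chi-square with
#' `J - 1` df. For two subgroups this is identical to the two-sided z-test
#' on the difference of pooled estimates.
#'
#' @param pooled list of [pool_random_effects()] results (>= 2 subgroups).
#' @return list: `Q_between`, `df`, `p`.
#' @export
subgroup_heterogeneity <- function(pooled) {
  if (length(pooled) < 2L) stop("need at least 2 subgroups")
  y <- vapply(pooled, function(m) m$pooled_log_or, numeric(1))
  se <- vapply(pooled, function(m) m$se, numeric(1))
  if (!all(is.finite(y)) || !all(is.finite(se))) stop("non-finite subgroup estimates")
  w <- 1 / se^2
  ybar <- sum(w * y) / sum(w)
  Qb <- sum(w * (y - ybar)^2)
  df <- length(y) - 1L
  list(Q_between = Qb, df = df, p = stats::pchisq(Qb, df, lower.tail = FALSE))
}

#' Funnel-plot data with outlier flags
#'
#' Exports (log OR, SE) pairs sorted by SE, flagging studies whose
#' standardized deviation from the pooled estimate exceeds 1.96 — the studies
#' a funnel plot would show outside the 95% band.
#'
#' @param estimates as in [pool_random_effects()].
#' @param pooled optional pooled log OR; computed by fixed-effect pooling
#'   when absent.
#' @return data.frame: `study_id`, `log_or`, `se`, `z`, `outlier`.
#' @export
funnel_data <- function(estimates, pooled = NULL) {
  est <- as_estimate_df(estimates)
  if (is.null(pooled)) {
    w <- 1 / est$se^2
    pooled <- sum(w * est$log_or) / sum(w)
  }
  z <- (est$log_or - pooled) / est$se
  out <- data.frame(study_id = est$study_id, log_or = est$log_or, se = est$se,
                    z = z, outlier = abs(z) > 1.96, stringsAsFactors = FALSE)
  if (nrow(out) == 1L) out$outlier <- FALSE
  out[order(out$se), , drop = FALSE]
}

as_estimate_df <- function(estimates) {
  if (is.data.frame(estimates)) {
    stopifnot(all(c("log_or", "se") %in% names(estimates)))
    if (is.null(estimates$study_id)) estimates$study_id <- paste0("study", seq_len(nrow(estimates)))
    return(estimates)
  }
  if (inherits(estimates, "study_estimate")) estimates <- list(estimates)
  data.frame(
    study_id = vapply(estimates, function(s) s$study_id, character(1)),
    log_or = vapply(estimates, function(s) s$log_or, numeric(1)),
    se = vapply(estimates, function(s) s$se, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "<meta_result> k = %d (%s)\n  OR = %.3f [%.3f, %.3f], p = %.3g\n  tau2 = %.4g, Q = %.3f (df %d), I2 = %.1f%%\n",
    x$k, x$method, exp(x$pooled_log_or), exp(x$ci_low), exp(x$ci_high), x$p,
    x$tau2, x$Q, x$df, x$i2))
  invisible(x)
}
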