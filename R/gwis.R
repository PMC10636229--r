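#' Configuration for the genome-wide interaction scan
#'
#' @param exposure_name phenotype column holding the exposure.
#' @param exposure_type `"binary"` (0/1, e.g. supplement use) or
#'   `"quartile"` (ordinal score 0-3 entered as a linear trend).
#' @param covariates phenotype columns entered as adjustment covariates;
#'   character/factor columns (e.g. `study`, `platform`) become fixed-effect
#'   indicator sets.
#' @param maf_min strict minor-allele-frequency filter (default 0.01).
#' @param r2_min strict imputation-accuracy filter (default 0.8).
#' @param alpha_primary genome-wide significance threshold (default 2e-8,
#'   accounting for the use of three testing procedures).
#' @param alpha_suggestive suggestive threshold (default 5e-8).
#' @param min_n minimum complete-case sample size per variant (default 50).
#' @return list of class `scan_config`.
#' @export
scan_config <- function(exposure_name = "exposure",
                        exposure_type = c("binary", "quartile"),
                        covariates = c("age", "sex", "study"),
                        maf_min = 0.01, r2_min = 0.8,
                        alpha_primary = 2e-8, alpha_suggestive = 5e-8,
                        min_n = 50L) {
  exposure_type <- match.arg(exposure_type)
  stopifnot(maf_min > 0, maf_min < 0.5,
            alpha_primary > 0, alpha_primary < 1,
            alpha_suggestive > 0, alpha_suggestive < 1)
  structure(list(exposure_name = exposure_name, exposure_type = exposure_type,
                 covariates = covariates, maf_min = maf_min, r2_min = r2_min,
                 alpha_primary = alpha_primary,
                 alpha_suggestive = alpha_suggestive,
                 min_n = as.integer(min_n)),
            class = "scan_config")
}

# expand phenotype covariate columns into a numeric matrix (no intercept)
covariate_matrix <- function(pheno, covariates) {
  if (!length(covariates)) return(NULL)
  miss <- setdiff(covariates, names(pheno))
  if (length(miss)) stop("phenotype table lacks covariates: ",
                         paste(miss, collapse = ", "))
  df <- pheno[, covariates, drop = FALSE]
  for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  mm <- stats::model.matrix(~ ., data = df, na.action = stats::na.pass)
  mm[, -1L, drop = FALSE]
}

#' Standard gene-environment interaction test
#'
#' Fits `logit P(D=1) = b0 + bG g + bE e + bGxE (g x e) + covariates` with the
#' variant entered log-additively as its allele dosage, and reports the Wald
#' test of the interaction coefficient plus the joint 2-df Wald test of
#' `(bG, bGxE)` from the same model.
#'
#' @param dosage numeric dosage vector in `[0, 2]`.
#' @param exposure exposure vector (binary 0/1 or ordinal quartile score).
#' @param outcome binary 0/1 disease status.
#' @param covmat numeric covariate matrix without intercept (or NULL).
#' @return list: `beta_gxe`, `se_gxe`, `p_gxe`, `beta_g_main`, `chi2_2df`,
#'   `p_2df`, `fit`.
#' @export
test_gxe <- function(dosage, exposure, outcome, covmat = NULL) {
  x <- cbind(`(Intercept)` = 1, g = dosage, e = exposure, gxe = dosage * exposure,
             covmat)
  fit <- fit_logistic(x, outcome)
  if (!fit$converged || !all(c("g", "gxe") %in% names(fit$coefficients))) {
    return(list(beta_gxe = NA_real_, se_gxe = NA_real_, p_gxe = NA_real_,
                beta_g_main = NA_real_, chi2_2df = NA_real_, p_2df = NA_real_,
                fit = fit))
  }
  w1 <- wald_test(fit, "gxe")
  w2 <- wald_test(fit, c("g", "gxe"))
  list(beta_gxe = unname(fit$coefficients["gxe"]),
       se_gxe = sqrt(fit$covariance["gxe", "gxe"]),
       p_gxe = w1$p,
       beta_g_main = unname(fit$coefficients["g"]),
       chi2_2df = w2$chi2, p_2df = w2$p, fit = fit)
}

#' Marginal genetic association test (D|G)
#'
#' Fits `logit P(D=1) = b0 + bG g + covariates` — the interaction structure is
#' absent — and reports the Wald test of the dosage coefficient.
#'
#' @inheritParams test_gxe
#' @return list: `beta_dg`, `se_dg`, `p_dg`, `chi2_dg`, `fit`.
#' @export
test_marginal_g <- function(dosage, outcome, covmat = NULL) {
  x <- cbind(`(Intercept)` = 1, g = dosage, covmat)
  fit <- fit_logistic(x, outcome)
  if (!fit$converged || !("g" %in% names(fit$coefficients))) {
    return(list(beta_dg = NA_real_, se_dg = NA_real_, p_dg = NA_real_,
                chi2_dg = NA_real_, fit = fit))
  }
  w <- wald_test(fit, "g")
  list(beta_dg = unname(fit$coefficients["g"]),
       se_dg = sqrt(fit$covariance["g", "g"]),
       p_dg = w$p, chi2_dg = w$chi2, fit = fit)
}

#' Gene-environment correlation test (G|E), combined sample or cases only
#'
#' Regresses the exposure on the allele dosage (plus covariates): logistic
#' regression for a binary exposure, linear regression of the ordinal
#' quartile score otherwise. `subset = "cases_only"` restricts to cases,
#' giving the case-only interaction test, which is powerful but biased when
#' gene and environment are dependent in the source population.
#'
#' @inheritParams test_gxe
#' @param subset `"all"` (combined case-control set) or `"cases_only"`.
#' @param exposure_type `"binary"` or `"quartile"`.
#' @return list: `delta_ge`, `se_ge`, `p_ge`, `chi2_ge`, `fit`.
#' @export
test_ge <- function(dosage, exposure, outcome = NULL, covmat = NULL,
                    subset = c("all", "cases_only"),
                    exposure_type = c("binary", "quartile")) {
  subset <- match.arg(subset)
  exposure_type <- match.arg(exposure_type)
  if (subset == "cases_only") {
    if (is.null(outcome)) stop("cases_only subset requires the outcome")
    keep <- outcome == 1L
    if (!any(keep)) stop("case subset is empty")
    dosage <- dosage[keep]
    exposure <- exposure[keep]
    covmat <- if (!is.null(covmat)) covmat[keep, , drop = FALSE]
  }
  x <- cbind(`(Intercept)` = 1, g = dosage, covmat)
  fit <- if (exposure_type == "binary") fit_logistic(x, exposure)
         else fit_linear(x, exposure)
  if (!fit$converged || !("g" %in% names(fit$coefficients))) {
    return(list(delta_ge = NA_real_, se_ge = NA_real_, p_ge = NA_real_,
                chi2_ge = NA_real_, fit = fit))
  }
  w <- wald_test(fit, "g")
  list(delta_ge = unname(fit$coefficients["g"]),
       se_ge = sqrt(fit$covariance["g", "g"]),
       p_ge = w$p, chi2_ge = w$chi2, fit = fit)
}

#' Combine independent chi-square components into a joint test
#'
#' Sums the component statistics and refers the total to a chi-square with
#' the summed degrees of freedom — the construction behind the 3-df joint
#' test (2-df case-control component plus the combined-sample G|E component).
#'
#' @param components list of `c(chi2, df)` pairs (or a 2-column matrix).
#' @return list: `chi2`, `df`, `p`.
#' @export
joint_chi2 <- function(components) {
  if (is.matrix(components)) {
    components <- lapply(seq_len(nrow(components)), function(i) components[i, ])
  }
  if (!length(components)) stop("no chi-square components supplied")
  chi2s <- vapply(components, `[`, numeric(1), 1L)
  dfs <- vapply(components, `[`, numeric(1), 2L)
  if (any(chi2s < 0)) stop("chi-square components must be non-negative")
  chi2 <- sum(chi2s)
  df <- sum(dfs)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Genome-wide gene-environment interaction scan
#'
#' For every variant surviving the MAF and imputation-accuracy filters, fits
#' the interaction, marginal and gene-environment-correlation models and
#' assembles all five statistics: the standard GxE Wald test, the marginal
#' D|G test, the combined-sample and case-only G|E tests, the 2-df joint Wald
#' test of `(bG, bGxE)`, and the 3-df joint test (2-df statistic + G|E
#' statistic on 3 df). Models are complete-case per variant; study and other
#' categorical covariates enter as fixed-effect indicators. Variants with a
#' constant dosage, too few complete cases, separation or non-convergence are
#' flagged and their statistics set missing.
#'
#' @param geno a [genotype_matrix()].
#' @param pheno phenotype data.frame with `outcome`, the exposure column and
#'   the covariates named in `config`.
#' @param config a [scan_config()].
#' @return data.frame, one row per retained variant, sorted by (chr, pos),
#'   with the per-test coefficients, standard errors, chi-squares and
#'   p-values, `n_used` and a `flag` column.
#' @export
gxe_scan <- function(geno, pheno, config = scan_config()) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(config, "scan_config"))
  if (nrow(geno$dosage) != nrow(pheno)) {
    stop("genotypes and phenotypes have different numbers of subjects; align first")
  }
  info <- geno$info
  af <- colMeans(geno$dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf > config$maf_min & info$r2 > config$r2_min
  gxewas_log("scan", sum(!keep), " of ", length(keep),
             " variants excluded by MAF/R2 filters")
  if (!any(keep)) stop("no variants survive the MAF/R2 filters")
  info <- info[keep, , drop = FALSE]
  info$maf <- maf[keep]
  dos <- geno$dosage[, keep, drop = FALSE]

  e <- pheno[[config$exposure_name]]
  if (is.null(e)) stop("exposure column '", config$exposure_name, "' not found")
  d <- pheno$outcome
  covmat <- covariate_matrix(pheno, config$covariates)
  base_cc <- !is.na(e) & !is.na(d)
  if (!is.null(covmat)) base_cc <- base_cc & stats::complete.cases(covmat)

  res <- lapply(seq_len(ncol(dos)), function(j) {
    scan_one(dos[, j], e, d, covmat, base_cc, config)
  })
  out <- cbind(info[, c("chr", "pos", "rsid", "a1", "a2", "maf", "r2")],
               do.call(rbind, lapply(res, as.data.frame)))
  out <- out[order(out$chr, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

scan_one <- function(g, e, d, covmat, base_cc, config) {
  empty <- list(n_used = NA_integer_, beta_g_main = NA_real_,
                beta_gxe = NA_real_, se_gxe = NA_real_, p_gxe = NA_real_,
                beta_dg = NA_real_, se_dg = NA_real_, p_dg = NA_real_,
                chi2_dg = NA_real_,
                delta_ge = NA_real_, se_ge = NA_real_, p_ge = NA_real_,
                chi2_ge = NA_real_,
                delta_ge_caseonly = NA_real_, p_caseonly = NA_real_,
                chi2_2df = NA_real_, p_2df = NA_real_,
                chi2_3df = NA_real_, p_3df = NA_real_, flag = "")
  cc <- base_cc & !is.na(g)
  n <- sum(cc)
  empty$n_used <- n
  if (n < config$min_n) { empty$flag <- "small_n"; return(empty) }
  gv <- g[cc]; ev <- e[cc]; dv <- d[cc]
  cm <- if (!is.null(covmat)) covmat[cc, , drop = FALSE]
  if (stats::var(gv) == 0) { empty$flag <- "constant_dosage"; return(empty) }

  t1 <- test_gxe(gv, ev, dv, cm)
  t2 <- test_marginal_g(gv, dv, cm)
  t3 <- test_ge(gv, ev, covmat = cm, subset = "all",
                exposure_type = config$exposure_type)
  t4 <- tryCatch(test_ge(gv, ev, outcome = dv, covmat = cm,
                         subset = "cases_only",
                         exposure_type = config$exposure_type),
                 error = function(err) list(delta_ge = NA_real_, p_ge = NA_real_,
                                            fit = NULL))
  flags <- character(0)
  for (f in list(t1$fit, t2$fit, t3$fit)) {
    if (is.null(f)) next
    if (!f$converged) flags <- c(flags, "nonconvergence")
    if (isTRUE(f$separation_flag)) flags <- c(flags, "separation")
  }
  out <- empty
  out$flag <- paste(unique(flags), collapse = ";")
  out$beta_g_main <- t1$beta_g_main
  out$beta_gxe <- t1$beta_gxe; out$se_gxe <- t1$se_gxe; out$p_gxe <- t1$p_gxe
  out$chi2_2df <- t1$chi2_2df; out$p_2df <- t1$p_2df
  out$beta_dg <- t2$beta_dg; out$se_dg <- t2$se_dg; out$p_dg <- t2$p_dg
  out$chi2_dg <- t2$chi2_dg
  out$delta_ge <- t3$delta_ge; out$se_ge <- t3$se_ge; out$p_ge <- t3$p_ge
  out$chi2_ge <- t3$chi2_ge
  out$delta_ge_caseonly <- t4$delta_ge
  out$p_caseonly <- t4$p_ge
  if (!is.na(out$chi2_2df) && !is.na(out$chi2_ge)) {
    j <- joint_chi2(list(c(out$chi2_2df, 2), c(out$chi2_ge, 1)))
    out$chi2_3df <- j$chi2
    out$p_3df <- j$p
  }
  out
}
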