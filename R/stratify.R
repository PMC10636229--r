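#' Genotype-stratified odds ratios in both parameterizations
#'
#' Reproduces the two complementary readings of a genotype-by-exposure table:
#' the exposure effect within each genotype stratum (E-parameterization:
#' logistic of disease on exposure among carriers of 0, 1 or 2 copies), and
#' the genotype effect within each exposure level (G-parameterization:
#' logistic of disease on genotype indicators vs the common homozygote,
#' separately among unexposed and exposed). Strata are formed from best-guess
#' genotypes (dosage rounded to the nearest copy number); expected fractional
#' cell counts come from per-subject genotype probabilities via
#' [expected_counts()]. Strata with zero cases and zero controls are omitted
#' with a flag; separation (e.g. a zero cell) is flagged and the extremely
#' wide interval reported as-is.
#'
#' @param dosage dosage vector in `[0, 2]`.
#' @param exposure binary 0/1 exposure.
#' @param outcome binary 0/1 disease status.
#' @param covmat numeric covariate matrix without intercept, or NULL for the
#'   crude (unadjusted) table.
#' @param conf_level confidence level (default 0.95).
#' @param geno_probs optional n x 3 matrix of per-subject genotype class
#'   probabilities; derived from the dosage by [dosage_to_probs()] when
#'   absent.
#' @return list of class `stratified_result` with `e_by_g` (per genotype
#'   stratum: OR, CI, p, counts, flags), `g_by_e` (per exposure level: OR per
#'   genotype vs reference), `expected` (fractional counts from
#'   [expected_counts()]) and `n`.
#' @export
stratified_effects <- function(dosage, exposure, outcome, covmat = NULL,
                               conf_level = 0.95, geno_probs = NULL) {
  stopifnot(all(exposure %in% c(0, 1)), all(outcome %in% c(0, 1)))
  g_best <- pmin(pmax(round(dosage), 0), 2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  e_by_g <- lapply(0:2, function(gg) {
    ix <- which(g_best == gg)
    row <- list(genotype = gg, n_cases = sum(outcome[ix] == 1),
                n_controls = sum(outcome[ix] == 0),
                or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p = NA_real_, flag = "")
    if (row$n_cases == 0 && row$n_controls == 0) {
      row$flag <- "empty_stratum"
      return(row)
    }
    if (length(unique(exposure[ix])) < 2L || length(unique(outcome[ix])) < 2L) {
      row$flag <- "uninformative"
      return(row)
    }
    x <- cbind(`(Intercept)` = 1, e = exposure[ix],
               if (!is.null(covmat)) covmat[ix, , drop = FALSE])
    fit <- fit_logistic(x, outcome[ix])
    if (!("e" %in% names(fit$coefficients))) {
      row$flag <- "uninformative"
      return(row)
    }
    b <- fit$coefficients["e"]
    se <- sqrt(fit$covariance["e", "e"])
    row$or <- exp(unname(b))
    row$ci_low <- exp(unname(b) - z * se)
    row$ci_high <- exp(unname(b) + z * se)
    row$p <- wald_test(fit, "e")$p
    if (fit$separation_flag) row$flag <- "separation"
    if (!fit$converged) row$flag <- paste0(row$flag, ";nonconvergence")
    row
  })
  e_by_g <- do.call(rbind, lapply(e_by_g, as.data.frame))

  g_by_e <- lapply(c(0, 1), function(ee) {
    ix <- which(exposure == ee)
    base <- data.frame(exposure = ee, genotype = 1:2, or = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                       flag = "", stringsAsFactors = FALSE)
    if (length(unique(outcome[ix])) < 2L) {
      base$flag <- "uninformative"
      return(base)
    }
    x <- cbind(`(Intercept)` = 1,
               g1 = as.numeric(g_best[ix] == 1),
               g2 = as.numeric(g_best[ix] == 2),
               if (!is.null(covmat)) covmat[ix, , drop = FALSE])
    fit <- fit_logistic(x, outcome[ix])
    for (k in 1:2) {
      nm <- paste0("g", k)
      if (!(nm %in% names(fit$coefficients))) {
        base$flag[k] <- "dropped"
        next
      }
      b <- fit$coefficients[nm]
      se <- sqrt(fit$covariance[nm, nm])
      base$or[k] <- exp(unname(b))
      base$ci_low[k] <- exp(unname(b) - z * se)
      base$ci_high[k] <- exp(unname(b) + z * se)
      base$p[k] <- wald_test(fit, nm)$p
      if (fit$separation_flag) base$flag[k] <- "separation"
    }
    base
  })
  g_by_e <- do.call(rbind, g_by_e)

  probs <- geno_probs %||% dosage_to_probs(dosage)
  expected <- expected_counts(probs, exposure, outcome)

  structure(list(e_by_g = e_by_g, g_by_e = g_by_e, expected = expected,
                 n = length(outcome)), class = "stratified_result")
}

#' Decompose a dosage into genotype class probabilities
#'
#' A dosage alone under-determines the three genotype probabilities; the
#' deterministic, total-dosage-preserving convention used here puts all mass
#' on the two adjacent copy-number classes: `p2 = max(0, d - 1)`,
#' `p1 = d - 2 * p2`, `p0 = 1 - p1 - p2`. Exact per-class probabilities
#' (e.g. a VCF GP field) should be passed through instead when available.
#'
#' @param dosage numeric vector in `[0, 2]`.
#' @return n x 3 matrix of probabilities for 0, 1, 2 copies; rows sum to 1.
#' @export
dosage_to_probs <- function(dosage) {
  stopifnot(all(dosage >= 0 & dosage <= 2))
  p2 <- pmax(0, dosage - 1)
  p1 <- dosage - 2 * p2
  p0 <- 1 - p1 - p2
  cbind(p0 = p0, p1 = p1, p2 = p2)
}

#' Expected fractional counts per genotype-by-exposure-by-outcome cell
#'
#' Cell counts "calculated by genotype probabilities": each subject
#' contributes its class probability to every genotype cell of its
#' (exposure, outcome) margin, so hard genotypes reproduce the integer
#' crosstabulation and imputed dosages yield fractional counts whose totals
#' equal the number of analyzed subjects exactly.
#'
#' @param probs n x 3 genotype probability matrix (rows sum to 1 within 1e-6).
#' @param exposure binary 0/1 exposure.
#' @param outcome binary 0/1 outcome.
#' @return data.frame: `exposure`, `outcome`, `g0`, `g1`, `g2`.
#' @export
expected_counts <- function(probs, exposure, outcome) {
  probs <- as.matrix(probs)
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("genotype probabilities must sum to 1 (tolerance 1e-6)")
  }
  grid <- expand.grid(exposure = sort(unique(exposure)),
                      outcome = c(0, 1))
  cells <- t(apply(grid, 1L, function(r) {
    ix <- exposure == r[["exposure"]] & outcome == r[["outcome"]]
    colSums(probs[ix, , drop = FALSE])
  }))
  out <- cbind(grid, cells)
  names(out) <- c("exposure", "outcome", "g0", "g1", "g2")
  rownames(out) <- NULL
  out
}

#' Route scan results into known-loci and novel-locus streams
#'
#' Interaction signals that merely tag previously established susceptibility
#' loci are analyzed separately under a Bonferroni threshold of
#' `alpha / n_loci`, while the remaining variants form the novel-locus
#' stream under the genome-wide threshold. A variant belongs to the
#' known-loci stream when it lies within `window_bp` of a known locus on the
#' same chromosome (closed interval, so a variant exactly at the boundary is
#' included); distance-window routing is a proxy for "driven by" a known
#' locus, since the linkage structure behind the established loci is not
#' modeled here. Duplicate loci (same chr, pos) are collapsed with a
#' warning.
#'
#' @param scan output of [gxe_scan()].
#' @param loci data.frame with `chr`, `pos` (and optionally `rsid`).
#' @param window_bp half-width of the routing window (default 500000).
#' @param alpha total alpha for the known-loci stream (default 0.05).
#' @return list: `threshold` (= alpha / n_loci), `n_loci`, `known` and
#'   `novel` (disjoint subsets of `scan`, the former with a
#'   `known_significant` column).
#' @export
known_loci_filter <- function(scan, loci, window_bp = 5e5, alpha = 0.05) {
  loci <- as.data.frame(loci)
  if (!nrow(loci)) stop("known-loci list is empty")
  key <- paste(loci$chr, loci$pos)
  if (anyDuplicated(key)) {
    warning("duplicate known loci collapsed: ",
            paste(unique(key[duplicated(key)]), collapse = ", "))
    loci <- loci[!duplicated(key), , drop = FALSE]
  }
  n_loci <- nrow(loci)
  threshold <- alpha / n_loci
  scan <- as.data.frame(scan)
  is_known <- vapply(seq_len(nrow(scan)), function(i) {
    any(loci$chr == scan$chr[i] & abs(loci$pos - scan$pos[i]) <= window_bp)
  }, logical(1))
  known <- scan[is_known, , drop = FALSE]
  if (nrow(known)) known$known_significant <- known$p_gxe < threshold
  gxewas_log("known_loci", nrow(known), " variant(s) routed to the known-loci stream (threshold ",
             format(threshold, digits = 5), ")")
  list(threshold = threshold, n_loci = n_loci,
       known = known, novel = scan[!is_known, , drop = FALSE])
}

#' Flag a qualitative interaction across genotype strata
#'
#' TRUE when the exposure effect points in opposite directions in different
#' genotype strata with confidence intervals excluding the null on both
#' sides: some stratum's OR interval lies entirely above 1 while another's
#' lies entirely below 1. Strata with missing or null-spanning intervals
#' never trigger the flag.
#'
#' @param stratified a [stratified_effects()] result, or a data.frame with
#'   `or`, `ci_low`, `ci_high` per stratum.
#' @return logical.
#' @export
qualitative_interaction_flag <- function(stratified) {
  tab <- if (inherits(stratified, "stratified_result")) stratified$e_by_g
         else as.data.frame(stratified)
  ok <- !is.na(tab$ci_low) & !is.na(tab$ci_high)
  if (sum(ok) < 2L) return(FALSE)
  any(tab$ci_low[ok] > 1) && any(tab$ci_high[ok] < 1)
}

#' @export
print.stratified_result <- function(x, ...) {
  cat("<stratified_result> exposure effect by genotype stratum:\n")
  print(x$e_by_g, row.names = FALSE)
  invisible(x)
}
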