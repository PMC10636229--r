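#' Total folate intake in dietary folate equivalents (DFE)
#'
#' Synthetic folic acid is more bioavailable than natural food folate, so
#' total intake is expressed as dietary folate equivalents:
#' `total DFE (ug/d) = dietary folate + 1.7 x supplemental folic acid`.
#' When the supplemental dose is unknown but the subject reports supplement
#' use, a standard multivitamin dose of 400 ug/d is assumed; non-users
#' contribute no supplemental folic acid. A missing dietary value propagates
#' to a missing total.
#'
#' @param dietary dietary folate, ug/d (>= 0 or NA).
#' @param supplemental supplemental folic acid dose, ug/d (>= 0 or NA).
#' @param supplement_use logical supplement use, used only when the dose is
#'   missing; NA with a missing dose gives a missing total.
#' @return total DFE, ug/d. Vectorized; monotone non-decreasing in both
#'   intake arguments.
#' @examples
#' compute_dfe(200, 400)               # 880
#' compute_dfe(200, NA, supplement_use = TRUE)  # 880 via the 400 ug/d rule
#' @export
compute_dfe <- function(dietary, supplemental = NA_real_, supplement_use = NA) {
  n <- max(length(dietary), length(supplemental), length(supplement_use))
  dietary <- rep_len(as.numeric(dietary), n)
  supplemental <- rep_len(as.numeric(supplemental), n)
  supplement_use <- rep_len(as.logical(supplement_use), n)
  if (any(dietary < 0, na.rm = TRUE) || any(supplemental < 0, na.rm = TRUE)) {
    stop("folate intakes must be non-negative")
  }
  dose <- ifelse(!is.na(supplemental), supplemental,
                 ifelse(is.na(supplement_use), NA_real_,
                        ifelse(supplement_use, 400, 0)))
  dietary + 1.7 * dose
}

#' Sex- and study-specific quartile coding
#'
#' Exposure variables are coded as quartiles within each stratum (typically
#' sex x study) before modeling, so that between-study differences in diet
#' instruments do not leak into the pooled coefficient. Cut points are the
#' 25/50/75 linear-interpolation percentiles of the stratum's non-missing
#' values (cases and controls combined — exposure coding never uses the
#' outcome); values equal to a cut point fall in the lower quartile. Strata
#' with fewer than 4 non-missing values are set entirely missing with a
#' warning.
#'
#' @param values numeric vector.
#' @param strata stratum labels (vector or list of vectors, e.g.
#'   `list(sex, study)`), recycled against `values`.
#' @return integer codes 0..3; NA where the value is missing or the stratum
#'   is too small. Codes are invariant to strictly increasing transforms of
#'   `values`.
#' @export
quartile_code <- function(values, strata = NULL) {
  n <- length(values)
  strat <- if (is.null(strata)) rep(1L, n) else interaction(strata, drop = TRUE)
  strat <- rep_len(strat, n)
  out <- rep(NA_integer_, n)
  for (s in levels(factor(strat))) {
    ix <- which(strat == s)
    v <- values[ix]
    ok <- !is.na(v)
    if (sum(ok) < 4L) {
      warning("stratum '", s, "' has fewer than 4 non-missing values; codes set missing")
      next
    }
    cuts <- stats::quantile(v[ok], c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    # left-open / right-closed: values equal to a cut point go to the lower quartile
    code <- rowSums(outer(v, cuts, ">"))
    out[ix] <- as.integer(code)
  }
  out
}

#' Harmonize raw lifestyle covariates into analysis variables
#'
#' Deterministic recoding of the raw fields into the forms the models use:
#' alcohol intake (g/d) dichotomized at 1 g/d into nondrinker (<= 1) and
#' drinker (> 1); BMI (kg/m^2) rescaled so one unit is a 5 kg/m^2 increment;
#' smoking history collapsed to never/ever (any non-never history is ever).
#' The raw columns are retained, so applying the harmonization to its own
#' output is the identity.
#'
#' @param raw data.frame; recognized raw columns are `alcohol` (g/d), `bmi`
#'   (kg/m^2) and `smoking` (one of `never`, `former`, `current`, `ever`).
#' @return `raw` with `alcohol_group`, `bmi_scaled` and `smoking` (recoded)
#'   columns added or refreshed.
#' @export
harmonize_covariates <- function(raw) {
  raw <- as.data.frame(raw)
  if ("alcohol" %in% names(raw)) {
    raw$alcohol_group <- ifelse(is.na(raw$alcohol), NA_character_,
                                ifelse(raw$alcohol <= 1, "nondrinker", "drinker"))
  }
  if ("bmi" %in% names(raw)) {
    raw$bmi_scaled <- raw$bmi / 5
  }
  if ("smoking" %in% names(raw)) {
    known <- c("never", "former", "current", "ever")
    bad <- setdiff(unique(raw$smoking[!is.na(raw$smoking)]), known)
    if (length(bad)) {
      stop("unknown smoking labels: ", paste(bad, collapse = ", "))
    }
    raw$smoking <- ifelse(is.na(raw$smoking), NA_character_,
                          ifelse(raw$smoking == "never", "never", "ever"))
  }
  model_cov <- intersect(c("age", "sex", "energy"), names(raw))
  if (length(model_cov)) {
    raw$complete_covariates <- stats::complete.cases(raw[, model_cov, drop = FALSE])
  }
  raw
}

#' Build the full exposure record for each subject
#'
#' Convenience wrapper combining [compute_dfe()] and [quartile_code()]:
#' computes total DFE, codes dietary and total folate as sex- and
#' study-specific quartiles, and derives the binary supplement-use indicator
#' (a reported dose > 0 implies use when the use flag is missing).
#'
#' @param pheno data.frame with `dietary_folate`, and optionally
#'   `supplemental_folate`, `supplement_use`, `sex`, `study`.
#' @return `pheno` with `total_dfe`, `dietary_quartile`, `total_quartile`,
#'   `supplement_binary` added.
#' @export
harmonize_exposures <- function(pheno) {
  pheno <- as.data.frame(pheno)
  supp <- pheno$supplemental_folate %||% rep(NA_real_, nrow(pheno))
  use <- pheno$supplement_use %||% rep(NA, nrow(pheno))
  use <- as.logical(use)
  use[is.na(use) & !is.na(supp) & supp > 0] <- TRUE
  use[is.na(use) & !is.na(supp) & supp == 0] <- FALSE
  pheno$total_dfe <- compute_dfe(pheno$dietary_folate, supp, use)
  strat <- list(pheno$sex %||% rep(1L, nrow(pheno)),
                pheno$study %||% rep(1L, nrow(pheno)))
  pheno$dietary_quartile <- quartile_code(pheno$dietary_folate, strat)
  pheno$total_quartile <- quartile_code(pheno$total_dfe, strat)
  pheno$supplement_binary <- as.integer(use)
  pheno
}
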