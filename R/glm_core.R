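#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression with Wald (inverse observed
#' information) covariance, written as a small self-contained engine so that
#' every downstream interaction statistic shares one numerical substrate with
#' explicit convergence and separation diagnostics.
#'
#' Collinear columns of the design matrix are dropped by a pivoted QR
#' decomposition in input order and reported in `dropped`. Step-halving (up to
#' 10 halvings) guarantees the log-likelihood never decreases across
#' iterations. Convergence is declared when the maximum absolute score falls
#' below `tol` or the relative log-likelihood change falls below `tol`.
#' Quasi-complete separation — a fitted probability within 1e-8 of 0 or 1
#' together with a diverging coefficient — sets `separation_flag`; the fit is
#' reported as-is (wide confidence intervals), not penalized.
#'
#' @param x design matrix including an intercept column; rows with missing
#'   values must be removed by the caller.
#' @param y binary 0/1 outcome vector, `length(y) == nrow(x)`.
#' @param max_iter maximum IRLS iterations (default 50).
#' @param tol convergence tolerance on the score norm and relative
#'   log-likelihood change (default 1e-8).
#' @param firth logical; use Firth's penalized score correction. Off by
#'   default: separation is reported, not repaired.
#' @return an object of class `gxewas_fit` with elements `coefficients`,
#'   `covariance`, `loglik`, `converged`, `n_used`, `separation_flag`,
#'   `dropped`, `fitted`, `family`, `iterations`.
#' @examples
#' x <- cbind(1, rnorm(100))
#' y <- rbinom(100, 1, plogis(x[, 2]))
#' f <- fit_logistic(x, y)
#' f$coefficients
#' @export
fit_logistic <- function(x, y, max_iter = 50L, tol = 1e-8, firth = FALSE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (anyNA(x) || anyNA(y)) stop("missing values in design or outcome; remove complete cases first")
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")

  keep <- qr_keep(x)
  dropped <- colnames(x)[!keep]
  xk <- x[, keep, drop = FALSE]
  p <- ncol(xk)
  n <- nrow(xk)

  beta <- numeric(p)
  eta <- drop(xk %*% beta)
  mu <- stats::plogis(eta)
  ll <- bernoulli_loglik(y, mu)
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    score <- crossprod(xk, y - mu)
    if (isTRUE(firth)) {
      info <- crossprod(xk * w, xk)
      hch <- tryCatch(chol(info), error = function(e) NULL)
      if (!is.null(hch)) {
        xw <- xk * sqrt(w)
        hat <- rowSums((xw %*% chol2inv(hch)) * xw)
        score <- crossprod(xk, y - mu + hat * (0.5 - mu))
      }
    }
    info <- crossprod(xk * w, xk)
    step <- tryCatch(drop(solve(info, score)), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving: the (penalized) loglik must not decrease
    lam <- 1
    for (h in 0:10) {
      cand <- beta + lam * step
      eta_c <- drop(xk %*% cand)
      mu_c <- stats::plogis(eta_c)
      ll_c <- bernoulli_loglik(y, mu_c)
      if (is.finite(ll_c) && ll_c >= ll - 1e-12) break
      lam <- lam / 2
    }
    beta <- beta + lam * step
    eta <- drop(xk %*% beta)
    mu <- stats::plogis(eta)
    ll_new <- bernoulli_loglik(y, mu)
    rel <- abs(ll_new - ll) / (abs(ll) + 1e-10)
    ll <- ll_new
    if (max(abs(crossprod(xk, y - mu))) < tol || rel < tol) {
      converged <- TRUE
      break
    }
  }

  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(xk * w, xk)
  vcov <- tryCatch(chol2inv(chol(info)), error = function(e) {
    matrix(NA_real_, p, p)
  })
  dimnames(vcov) <- list(colnames(xk), colnames(xk))
  names(beta) <- colnames(xk)

  sep <- any(mu < 1e-8 | mu > 1 - 1e-8) && any(abs(beta) > 10)

  new_gxewas_fit(
    coefficients = beta, covariance = vcov, loglik = ll,
    converged = converged, n_used = n, separation_flag = sep,
    dropped = dropped, fitted = mu, family = "binomial", iterations = iter
  )
}

#' Fit ordinary least squares with model-based covariance
#'
#' Linear regression used for the gene-environment correlation test when the
#' exposure is an ordinal quartile score. Collinear columns are dropped as in
#' [fit_logistic()].
#'
#' @inheritParams fit_logistic
#' @param y numeric response.
#' @return a `gxewas_fit`; `covariance` uses the usual unbiased residual
#'   variance estimator.
#' @export
fit_linear <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (anyNA(x) || anyNA(y)) stop("missing values in design or response; remove complete cases first")

  keep <- qr_keep(x)
  dropped <- colnames(x)[!keep]
  xk <- x[, keep, drop = FALSE]
  n <- nrow(xk)
  p <- ncol(xk)
  qx <- qr(xk)
  beta <- qr.coef(qx, y)
  res <- y - drop(xk %*% beta)
  df_res <- n - p
  s2 <- if (df_res > 0) sum(res^2) / df_res else 0
  xtx_inv <- chol2inv(qr.R(qx))
  vcov <- s2 * xtx_inv
  dimnames(vcov) <- list(colnames(xk), colnames(xk))
  names(beta) <- colnames(xk)
  # gaussian loglik at the ML variance estimate
  s2_ml <- max(sum(res^2) / n, .Machine$double.eps)
  ll <- -n / 2 * (log(2 * pi * s2_ml) + 1)

  new_gxewas_fit(
    coefficients = beta, covariance = vcov, loglik = ll,
    converged = TRUE, n_used = n, separation_flag = FALSE,
    dropped = dropped, fitted = drop(xk %*% beta), family = "gaussian",
    iterations = 1L
  )
}

#' Wald chi-square test on a subset of coefficients
#'
#' Computes `t(beta) %*% solve(V) %*% beta` on the selected coefficients and
#' refers it to a chi-square distribution with as many degrees of freedom as
#' coefficients tested.
#'
#' @param fit a `gxewas_fit`.
#' @param idx integer or character indices of the coefficients to test jointly.
#' @return list with `chi2`, `df`, `p`.
#' @export
wald_test <- function(fit, idx) {
  stopifnot(inherits(fit, "gxewas_fit"))
  if (is.character(idx)) idx <- match(idx, names(fit$coefficients))
  if (anyNA(idx) || any(idx < 1L) || any(idx > length(fit$coefficients))) {
    stop("invalid coefficient indices")
  }
  b <- fit$coefficients[idx]
  v <- fit$covariance[idx, idx, drop = FALSE]
  vi <- tryCatch(solve(v), error = function(e) NULL)
  if (is.null(vi) || anyNA(v)) {
    stop("singular sub-covariance for coefficients: ",
         paste(names(fit$coefficients)[idx], collapse = ", "))
  }
  chi2 <- drop(t(b) %*% vi %*% b)
  df <- length(idx)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

bernoulli_loglik <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-15), 1 - 1e-15)
  sum(y * log(mu) + (1 - y) * log(1 - mu))
}

# columns to keep after pivoted-QR collinearity check, preserving input order
qr_keep <- function(x) {
  qx <- qr(x, tol = 1e-9, LAPACK = FALSE)
  keep <- logical(ncol(x))
  keep[qx$pivot[seq_len(qx$rank)]] <- TRUE
  keep
}

new_gxewas_fit <- function(...) {
  structure(list(...), class = "gxewas_fit")
}

#' @export
print.gxewas_fit <- function(x, ...) {
  cat(sprintf("<gxewas_fit> %s, n = %d, converged = %s%s\n", x$family,
              x$n_used, x$converged,
              if (x$separation_flag) ", SEPARATION" else ""))
  se <- sqrt(diag(x$covariance))
  print(cbind(estimate = x$coefficients, se = se))
  invisible(x)
}

#' @export
coef.gxewas_fit <- function(object, ...) object$coefficients

#' @export
vcov.gxewas_fit <- function(object, ...) object$covariance
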