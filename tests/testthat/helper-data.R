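options(gxewas.quiet = TRUE)

# binomial 99% acceptance interval for an empirical rate
binom99 <- function(n, p = 0.05) {
  c(qbinom(0.005, n, p), qbinom(0.995, n, p)) / n
}

# expand a genotype x exposure count table into subject-level vectors
counts_to_data <- function(tab) {
  # tab: data.frame(genotype, exposure, cases, controls)
  g <- rep(tab$genotype, tab$cases + tab$controls)
  e <- rep(tab$exposure, tab$cases + tab$controls)
  d <- unlist(mapply(function(ca, co) c(rep(1L, ca), rep(0L, co)),
                     tab$cases, tab$controls, SIMPLIFY = FALSE))
  data.frame(g = g, e = e, d = d)
}

# small null case-control dataset with one or more HWE variants
sim_null_data <- function(n = 600, m = 1, maf = 0.3, prev_e = 0.4, seed = 1) {
  set.seed(seed)
  g <- matrix(rbinom(n * m, 2, maf), n, m)
  e <- rbinom(n, 1, prev_e)
  d <- rbinom(n, 1, 0.5)
  list(g = g, e = e, d = d)
}

# direct Bernoulli loglik used by the Nelder-Mead oracle
nll_logistic <- function(beta, x, y) {
  mu <- plogis(drop(x %*% beta))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -sum(y * log(mu) + (1 - y) * log(1 - mu))
}
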