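# Shared fixtures: small synthetic cohorts built in code at test time.

small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_cd = 15, n_control = 15, n_taxa = 40, n_snps = 30,
         n_metabolites = 80, seed = seed),
    list(...))
  do.call(cohort_config, args)
}

small_null_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_cd = 15, n_control = 15, n_taxa = 40, n_snps = 30,
         n_metabolites = 80, seed = seed),
    list(...))
  do.call(null_cohort_config, args)
}

# Direct-formula oracles, independent of the package implementations.

oracle_chao1 <- function(x) {
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  sum(x > 0) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

oracle_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

oracle_bray_curtis <- function(a, b) {
  1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

oracle_auc <- function(scores, pos) {
  s1 <- scores[pos]; s0 <- scores[!pos]
  mean(outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Exact Wilcoxon two-sided p by enumeration of all group assignments.
oracle_wilcoxon_exact <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(n, nx)
  ws <- apply(splits, 2, function(i) sum(r[i])) - nx * (nx + 1) / 2
  mean(abs(ws - nx * (n - nx) / 2) >= abs(w_obs - nx * (n - nx) / 2) - 1e-9)
}

# NB log-likelihood for the brute-force GLM oracle.
oracle_nb_loglik <- function(beta, y, X, offset, alpha) {
  mu <- exp(drop(X %*% beta) + offset)
  sum(dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}
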