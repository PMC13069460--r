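# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Cox-de Boor recursion for a single B-spline basis function N_{i,d} on a
# knot vector (half-open intervals, standard convention).
cox_de_boor <- function(x, knots, i, d) {
  if (d == 0) {
    return(as.numeric(knots[i] <= x & x < knots[i + 1]))
  }
  den1 <- knots[i + d] - knots[i]
  den2 <- knots[i + d + 1] - knots[i + 1]
  a <- if (den1 > 0) (x - knots[i]) / den1 * cox_de_boor(x, knots, i, d - 1) else 0
  b <- if (den2 > 0) (knots[i + d + 1] - x) / den2 * cox_de_boor(x, knots, i + 1, d - 1) else 0
  a + b
}

# Full basis row at x by the recursion.
cox_de_boor_row <- function(x, knots, K, degree) {
  vapply(seq_len(K), function(i) cox_de_boor(x, knots, i, degree), numeric(1))
}

# Exact cumulative-logit log-likelihood for brute-force optimization.
cumlogit_loglik <- function(par, y, X, C) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  alpha <- par[(p + 1):(p + C)]
  if (any(diff(alpha) <= 0)) return(-Inf)
  eta <- as.numeric(X %*% beta)
  sv <- cbind(1, plogis(outer(eta, alpha, `-`)), 0)
  pr <- sv[cbind(seq_along(y), y + 1L)] - sv[cbind(seq_along(y), y + 2L)]
  if (any(pr <= 0)) return(-Inf)
  sum(log(pr))
}

# Small complete synthetic dataset for fit tests: lag design built from a
# basis, plus a couple of covariates.
make_fit_fixture <- function(n = 500, K = 5, seed = 42, scenario = "flat",
                             role = "maternal", binary = TRUE) {
  set.seed(seed)
  sched <- default_schedule(role)
  truth <- simulation_truth(
    sched, lag_weights = lag_weight_scenario(sched, scenario),
    covariate_effects = c(sex = 0.2, prs_mdd = 0.15),
    cutpoints = if (binary) NULL else epds_outcome_cutpoints(),
    intercept = if (binary) qlogis(0.3) else NULL)
  x <- simulate_exposures(n, sched, truth)
  cov <- simulate_covariates(n)
  y <- simulate_outcomes(x, cov, truth,
                         if (binary) "logit" else "cumulative_logit")
  basis <- pspline_basis(sched, K = K)
  list(schedule = sched, truth = truth, exposures = x, covariates = cov,
       y = y, basis = basis, U = dlm_design(x, basis),
       Z = as.matrix(cov[c("sex", "prs_mdd")]))
}
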