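fit_fx <- local({
  fx <- make_fit_fixture(n = 800, K = 6, seed = 201, scenario = "late_ramp")
  fit <- fit_penalized_logistic(fx$U, fx$Z, fx$y, fx$basis$P,
                                model_spec("binary", "fixed", lambda = 2))
  c(fx, list(fit = fit))
})

test_that("null coefficients give AOR = 1 everywhere with symmetric log-scale CIs", {
  f0 <- fit_fx$fit
  f0$coefficients[f0$idx$lag] <- 0
  tc <- time_response(f0, fit_fx$basis)
  expect_equal(tc$aor, rep(1, 12))
  expect_equal(log(tc$conf.high) + log(tc$conf.low), rep(0, 12), tolerance = 1e-12)
  expect_false(any(tc$significant))
  ce <- cumulative_effect(f0, fit_fx$basis)
  expect_equal(ce$aor, 1)
})

test_that("log AOR is linear in the contrast level", {
  t13 <- time_response(fit_fx$fit, fit_fx$basis, contrast = 13)
  t1 <- time_response(fit_fx$fit, fit_fx$basis, contrast = 1)
  expect_equal(t13$log_aor, 13 * t1$log_aor, tolerance = 1e-12)
  expect_equal(t13$se, 13 * t1$se, tolerance = 1e-12)
})

test_that("cumulative log-AOR equals the sum of per-occasion log-AORs", {
  ce <- cumulative_effect(fit_fx$fit, fit_fx$basis)
  tc <- time_response(fit_fx$fit, fit_fx$basis)
  expect_lt(abs(ce$log_aor - sum(tc$log_aor)), 1e-10)
})

test_that("pointwise CIs agree with a parametric bootstrap from (theta, V)", {
  fit <- fit_fx$fit
  idx <- fit$idx$lag
  set.seed(202)
  draws <- MASS::mvrnorm(2000, fit$coefficients[idx], fit$V[idx, idx])
  tc <- time_response(fit, fit_fx$basis)
  B <- fit_fx$basis$B
  for (t in c(1, 6, 12)) {
    boot <- 13 * as.numeric(draws %*% B[t, ])
    qs <- quantile(boot, c(0.025, 0.975))
    width <- diff(qs)
    expect_lt(abs(log(tc$conf.low[t]) - qs[1]), 0.05 * width)
    expect_lt(abs(log(tc$conf.high[t]) - qs[2]), 0.05 * width)
  }
})

test_that("simulation truth is recovered by the cumulative estimate at scale", {
  sched <- default_schedule("maternal")
  truth <- simulation_truth(sched,
                            lag_weights = lag_weight_scenario(sched, "late_ramp"),
                            covariate_effects = c(sex = 0.2),
                            cutpoints = NULL, intercept = qlogis(0.25))
  target <- 13 * sum(truth$lag_weights)
  basis <- pspline_basis(sched, K = 8)
  set.seed(203)
  est <- replicate(30, {
    x <- simulate_exposures(3000, sched, truth)
    cov <- simulate_covariates(3000)
    y <- simulate_outcomes(x, cov, truth, "logit")
    f <- fit_penalized_logistic(dlm_design(x, basis), as.matrix(cov["sex"]),
                                y, basis$P,
                                model_spec("binary", "fixed", lambda = 10))
    cumulative_effect(f, basis)$log_aor
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - target), 3 * mc_se + 0.02)
})

test_that("DLNM surface is anchored at zero exposure and matches cell-wise oracles", {
  fx <- make_fit_fixture(n = 800, K = 5, seed = 204)
  spec <- exposure_basis_spec("bspline", K_e = 4, degree = 2)
  cb <- crossbasis_design(fx$exposures, fx$basis, spec)
  fit <- fit_penalized_logistic(cb$design, fx$Z, fx$y, cb$penalties,
                                model_spec("binary", "fixed", lambda = c(1, 1)))
  surf <- dlnm_surface(fit, cb, levels = c(0, 5, 13, 30))
  at0 <- dplyr::filter(surf$surface, level == 0)
  expect_equal(at0$aor, rep(1, 12))
  # brute-force per-cell contrast
  fvals <- parentlag:::exposure_basis_at(spec, c(0, 5, 13, 30))
  theta <- fit$coefficients[fit$idx$lag]
  B <- fx$basis$B
  for (j in 1:4) for (t in c(1, 7)) {
    s <- 0
    for (k in 1:4) for (l in 1:5) {
      s <- s + fvals[j, k] * B[t, l] * theta[(k - 1) * 5 + l]
    }
    row <- dplyr::filter(surf$surface, level == c(0, 5, 13, 30)[j])[t, ]
    expect_lt(abs(row$log_aor - s), 1e-10)
  }
  # cumulative = column sums over occasions
  cum13 <- dplyr::filter(surf$cumulative, level == 13)
  expect_lt(abs(cum13$log_aor -
                  sum(dplyr::filter(surf$surface, level == 13)$log_aor)), 1e-10)
  expect_error(dlnm_surface(fit, cb, levels = 31), "\\[0, 30\\]")
})

test_that("linear-exposure DLNM reproduces the DLM time-response exactly", {
  fx <- make_fit_fixture(n = 600, K = 6, seed = 205)
  cb <- crossbasis_design(fx$exposures, fx$basis, exposure_basis_spec("linear"))
  expect_equal(unname(cb$design), unname(fx$U))
  fit <- fit_penalized_logistic(cb$design, fx$Z, fx$y, cb$penalties$lag,
                                model_spec("binary", "fixed", lambda = 2))
  fit_dlm <- fit_penalized_logistic(fx$U, fx$Z, fx$y, fx$basis$P,
                                    model_spec("binary", "fixed", lambda = 2))
  surf <- dlnm_surface(fit, cb, levels = 13)
  tc <- time_response(fit_dlm, fx$basis, contrast = 13)
  expect_lt(max(abs(surf$surface$log_aor - tc$log_aor)), 1e-10)
  expect_lt(max(abs(surf$surface$se - tc$se)), 1e-10)
  # proportionality across exposure levels
  s5 <- dlnm_surface(fit, cb, levels = 5)
  expect_equal(s5$surface$log_aor, 5 / 13 * surf$surface$log_aor,
               tolerance = 1e-12)
})

test_that("moderation Wald statistic behaves in the scalar and null cases", {
  fit <- fit_fx$fit
  # scalar block: chi2 equals the squared z statistic
  j <- fit$idx$cov[1]
  w <- moderation_wald(fit, j)
  z2 <- (fit$coefficients[j] / sqrt(fit$V[j, j]))^2
  expect_lt(abs(w$chi2 - z2), 1e-10)
  expect_equal(w$df, 1L)
  # exactly-zero deviations with identity covariance: chi2 = 0
  f0 <- fit
  f0$coefficients[fit$idx$lag] <- 0
  f0$V[fit$idx$lag, fit$idx$lag] <- diag(length(fit$idx$lag))
  w0 <- moderation_wald(f0, fit$idx$lag)
  expect_equal(w0$chi2, 0)
  expect_equal(w0$p.value, 1)
})

test_that("contrast machinery refuses a non-converged fit", {
  f <- fit_fx$fit
  f$converged <- FALSE
  expect_error(time_response(f, fit_fx$basis), "converge")
  expect_error(cumulative_effect(f, fit_fx$basis), "converge")
})

test_that("tidy and glance expose the fit in broom shape", {
  td <- tidy(fit_fx$fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  expect_equal(nrow(td), length(fit_fx$fit$coefficients))
  expect_setequal(unique(td$term_type), c("lag", "covariate", "cutpoint"))
  gl <- glance(fit_fx$fit)
  expect_equal(gl$n, 800L)
  expect_true(gl$converged)
})
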