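test_that("exclusion filter enforces the 95%-or-more boundary and matches brute force", {
  nc <- 20
  dat <- tibble::as_tibble(setNames(as.data.frame(matrix(1, 3, nc)),
                                    paste0("v", 1:nc)))
  dat[1, ] <- NA                       # 100% missing -> removed
  dat[2, 1:19] <- NA                   # exactly 95% -> removed
  dat[3, 1:18] <- NA                   # 90% -> kept
  out <- exclusion_filter(dat, paste0("v", 1:nc))
  expect_equal(nrow(out), 1)
  expect_equal(exclusion_report(out)$n_excluded, 2)

  set.seed(301)
  big <- tibble::as_tibble(as.data.frame(matrix(
    ifelse(runif(500 * 12) < 0.5, 1, NA), 500, 12)))
  names(big) <- paste0("v", 1:12)
  out2 <- exclusion_filter(big, names(big), threshold = 0.75)
  brute <- sum(vapply(seq_len(500), function(i) {
    mean(is.na(unlist(big[i, ]))) < 0.75
  }, logical(1)))
  expect_equal(nrow(out2), brute)
  expect_error(exclusion_filter(big, c("v1", "nope")), "absent")
  expect_error(exclusion_filter(big, names(big), threshold = 0), "threshold")
})

test_that("low-rank item imputation is a no-op without missingness and stays in range", {
  set.seed(302)
  items <- matrix(sample(0:3, 40 * 10, replace = TRUE), 40, 10)
  out <- lowrank_item_impute(items, ncp = 2, m = 3, seed = 1)
  expect_length(out, 3)
  for (o in out) {
    expect_equal(unclass(o)[, ], items[, ])
    expect_equal(attr(o, "scores"), rowSums(items))
  }
})

test_that("low-rank item imputation beats the marginal-mode baseline on rank-1 structure", {
  set.seed(303)
  n <- 300; J <- 10
  severity <- 2.5 * rnorm(n)                 # one strong latent dimension
  probs <- plogis(outer(severity, c(-2.5, 0, 2.5), `-`))  # P(item >= k)
  full <- matrix(0L, n, J)
  for (j in 1:J) {
    u <- runif(n)
    full[, j] <- rowSums(probs > u)
  }
  mask <- matrix(runif(n * J) < 0.10, n, J)
  obs <- full; obs[mask] <- NA
  imp <- lowrank_item_impute(obs, ncp = 2, m = 5, seed = 7)
  acc <- mean(vapply(imp, function(o) mean(o[mask] == full[mask]), numeric(1)))
  mode_cat <- as.integer(names(which.max(table(full[!mask]))))
  acc_mode <- mean(mode_cat == full[mask])
  expect_gt(acc, acc_mode)
  for (o in imp) expect_true(all(o %in% 0:3))
  expect_error(lowrank_item_impute(cbind(obs[, 1] * NA, obs[, -1])), "entirely missing")
})

test_that("chained random-forest imputation is deterministic and beats mean imputation", {
  sched <- default_schedule("maternal")
  truth <- simulation_truth(sched, ar_rho = 0.85)  # strongly informative neighbours
  full <- simulate_cohort(800, seed = 304, maternal_truth = truth,
                          apply_entry = FALSE)
  cols <- schedule_columns(sched)
  dat <- full[c(cols, "mat_education", "mat_age", "sex")]
  # 20% MCAR on one exposure column
  set.seed(305)
  target <- cols[7]
  mask_rows <- runif(nrow(dat)) < 0.2
  dat[[target]][mask_rows] <- NA

  set.seed(1)  # deterministic regardless of ambient RNG state
  a <- rf_chained_impute(dat, m = 2, iterations = 2, seed = 11, num_trees = 50)
  set.seed(99)
  b <- rf_chained_impute(dat, m = 2, iterations = 2, seed = 11, num_trees = 50)
  expect_identical(a$imputations, b$imputations)

  # accuracy against the pre-deletion values, vs column-mean baseline
  truth_vals <- full[[target]][mask_rows]
  imp_vals <- a$imputations[[1]][[target]][mask_rows]
  rmse_rf <- sqrt(mean((imp_vals - truth_vals)^2))
  rmse_mean <- sqrt(mean((mean(dat[[target]], na.rm = TRUE) - truth_vals)^2))
  expect_lt(rmse_rf, rmse_mean)

  # imputed EPDS values stay in the observed integer range
  expect_true(all(imp_vals %in% 0:30))

  # complete data: M identical copies
  cd <- rf_chained_impute(full[c(cols, "sex")], m = 3, seed = 2)
  expect_identical(cd$imputations[[1]], cd$imputations[[3]])
  expect_error(rf_chained_impute(tibble::tibble(a = c(NA, NA), b = c(1, 2))),
               "no observed values")
})

test_that("Rubin rules reproduce the closed-form hand computation", {
  pe <- rubin_pool(c(1.0, 1.2, 0.8), c(0.04, 0.04, 0.04))
  expect_equal(pe$estimate, 1.0)
  expect_equal(pe$W, 0.04)
  expect_equal(pe$B, 0.04)
  expect_equal(pe$T, 0.04 + (1 + 1 / 3) * 0.04)
  expect_false(pe$degenerate)

  # identical estimates: B = 0, T = W
  pe0 <- rubin_pool(rep(0.5, 4), rep(0.02, 4))
  expect_equal(pe0$B, 0)
  expect_equal(pe0$T, pe0$W)

  # T >= W always
  set.seed(305)
  for (i in 1:20) {
    M <- sample(2:10, 1)
    p <- rubin_pool(rnorm(M), runif(M, 0.01, 1))
    expect_gte(p$T, p$W)
    expect_true(p$conf.low < p$estimate & p$estimate < p$conf.high)
    expect_gt(p$df, 0)
  }
  # M = 1 degenerate pooling
  p1 <- rubin_pool(0.3, 0.04, df_com = 100)
  expect_true(p1$degenerate)
  expect_equal(p1$T, 0.04)

  # Barnard-Rubin df never exceeds the complete-data df
  pbr <- rubin_pool(c(0.1, 0.5, 0.3), c(0.02, 0.02, 0.02), df_com = 50)
  expect_lt(pbr$df, 50)
})

test_that("D2 pooling matches its closed forms and a step-by-step evaluation", {
  # single imputation: D2 = chi2 / k against F(k, Inf)
  d1 <- d2_pool(7.8, k = 2)
  expect_equal(d1$D2, 3.9)
  expect_true(d1$degenerate)
  expect_equal(d1$p.value, pchisq(7.8, 2, lower.tail = FALSE), tolerance = 1e-12)

  # equal statistics: r = 0, D2 = wbar / k
  de <- d2_pool(rep(6.2, 4), k = 3)
  expect_equal(de$r, 0)
  expect_equal(de$D2, 6.2 / 3)

  # M = 5 hand-listed statistics, spreadsheet-style transcription
  w <- c(4.1, 6.3, 5.2, 7.9, 3.6); k <- 3; M <- 5
  wbar <- mean(w)
  r <- (1 + 1 / M) * var(sqrt(w))
  D2 <- (wbar / k - (M + 1) / (M - 1) * r) / (1 + r)
  nu <- k^(-3 / M) * (M - 1) * (1 + 1 / r)^2
  got <- d2_pool(w, k)
  expect_equal(got$wbar, wbar)
  expect_equal(got$r, r)
  expect_equal(got$D2, D2)
  expect_equal(got$df2, nu)
  expect_equal(got$p.value, pf(D2, k, nu, lower.tail = FALSE))
  expect_error(d2_pool(c(-1, 2), 2))
})

test_that("curve and cumulative pooling act on the log-odds scale, order-preserved", {
  fx <- make_fit_fixture(n = 500, K = 5, seed = 306)
  fits <- lapply(c(1, 2, 4), function(l) {
    fit_penalized_logistic(fx$U, fx$Z, fx$y, fx$basis$P,
                           model_spec("binary", "fixed", lambda = l))
  })
  curves <- lapply(fits, time_response, basis = fx$basis)
  cums <- lapply(fits, cumulative_effect, basis = fx$basis)
  pc <- pool_time_response(curves)
  pe <- pool_cumulative_effect(cums)
  # pooled point estimate = exp(mean of log AORs)
  expect_equal(pc$log_aor, rowMeans(sapply(curves, function(cv) cv$log_aor)))
  expect_equal(pc$aor, exp(pc$log_aor))
  expect_true(all(pc$conf.low < pc$aor & pc$aor < pc$conf.high))
  expect_equal(pe$log_aor, mean(sapply(cums, function(x) x$log_aor)))
  expect_equal(pe$aor, exp(pe$log_aor))
})
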