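#' Pool estimates across imputations by Rubin's rules
#'
#' `Qbar = mean(estimates)`, within-imputation variance `W =
#' mean(variances)`, between-imputation variance `B = var(estimates)`,
#' total `T = W + (1 + 1/M) B`, with Barnard--Rubin small-sample degrees
#' of freedom and a t-based 95% interval. Pooling is done on the
#' coefficient (log-odds) scale; exponentiate afterwards.
#'
#' @param estimates Numeric vector of per-imputation point estimates.
#' @param variances Matching vector of per-imputation (squared-SE)
#'   variances, all positive.
#' @param df_com Complete-data degrees of freedom (default `Inf`, giving
#'   the classic large-sample Rubin df).
#' @param level Confidence level.
#' @return A one-row tibble of class `pooled_estimate`: `estimate`
#'   (`Qbar`), `W`, `B`, `T`, `se`, `df`, `conf.low`, `conf.high`, `m`,
#'   `degenerate` (TRUE when `M = 1`: no between-imputation component).
#' @export
rubin_pool <- function(estimates, variances, df_com = Inf, level = 0.95) {
  M <- length(estimates)
  stopifnot(M >= 1, length(variances) == M, all(variances > 0))
  Qbar <- mean(estimates)
  W <- mean(variances)
  if (M == 1L) {
    Tt <- W
    df <- df_com
    B <- 0
  } else {
    B <- stats::var(estimates)
    Tt <- W + (1 + 1 / M) * B
    lam <- (1 + 1 / M) * B / Tt
    df <- if (lam <= 0) Inf else {
      df_old <- (M - 1) / lam^2
      if (is.finite(df_com)) {
        df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lam)
        df_old * df_obs / (df_old + df_obs)
      } else df_old
    }
  }
  tq <- stats::qt(1 - (1 - level) / 2, df)
  tibble::tibble(estimate = Qbar, W = W, B = B, T = Tt, se = sqrt(Tt),
                 df = df, conf.low = Qbar - tq * sqrt(Tt),
                 conf.high = Qbar + tq * sqrt(Tt), m = M,
                 degenerate = M == 1L) |>
    structure(class = c("pooled_estimate", class(tibble::tibble())))
}

#' Pool Wald chi-square statistics across imputations (D2)
#'
#' The D2 combination of Li, Meng, Raghunathan and Rubin: with mean
#' statistic `wbar` and between-imputation variability of the
#' root statistics `r = (1 + 1/M) * var(sqrt(w))`,
#' `D2 = (wbar/k - (M+1)/(M-1) * r) / (1 + r)` (floored at 0), referred to
#' an `F(k, nu)` distribution with `nu = k^(-3/M) (M-1) (1 + 1/r)^2`.
#' With a single imputation this reduces to `chi2/k` against `F(k, Inf)`.
#'
#' @param chi2 Numeric vector of per-imputation Wald chi-square statistics
#'   (all >= 0).
#' @param k Numerator degrees of freedom of the test.
#' @return A one-row tibble of class `pooled_chi2`: `wbar`, `r`, `D2`,
#'   `df1` (`k`), `df2` (`nu`), `p.value`, `m`, `degenerate`.
#' @export
d2_pool <- function(chi2, k) {
  stopifnot(all(chi2 >= 0), k >= 1)
  M <- length(chi2)
  wbar <- mean(chi2)
  if (M == 1L) {
    D2 <- wbar / k
    return(tibble::tibble(wbar = wbar, r = 0, D2 = D2, df1 = k, df2 = Inf,
                          p.value = stats::pf(D2, k, Inf, lower.tail = FALSE),
                          m = 1L, degenerate = TRUE) |>
             structure(class = c("pooled_chi2", class(tibble::tibble()))))
  }
  r <- (1 + 1 / M) * stats::var(sqrt(chi2))
  D2 <- max((wbar / k - (M + 1) / (M - 1) * r) / (1 + r), 0)
  nu <- if (r > 0) k^(-3 / M) * (M - 1) * (1 + 1 / r)^2 else Inf
  tibble::tibble(wbar = wbar, r = r, D2 = D2, df1 = k, df2 = nu,
                 p.value = stats::pf(D2, k, nu, lower.tail = FALSE),
                 m = M, degenerate = FALSE) |>
    structure(class = c("pooled_chi2", class(tibble::tibble())))
}

#' Pool a set of per-imputation lag-model summaries
#'
#' Applies [rubin_pool()] element-wise to per-imputation time-response
#' curves and cumulative effects (on the log-AOR scale), returning the
#' same tidy shapes with pooled estimates, SEs and intervals.
#'
#' @param curves List of `time_response_curve` tibbles, one per imputation
#'   (same occasions in the same order).
#' @param df_com Complete-data df passed to [rubin_pool()].
#' @return A `time_response_curve` tibble with pooled columns.
#' @export
pool_time_response <- function(curves, df_com = Inf) {
  stopifnot(length(curves) >= 1)
  Tn <- nrow(curves[[1]])
  est <- sapply(curves, function(cv) cv$log_aor)
  se2 <- sapply(curves, function(cv) cv$se^2)
  est <- matrix(est, nrow = Tn); se2 <- matrix(se2, nrow = Tn)
  pooled <- lapply(seq_len(Tn), function(tt) rubin_pool(est[tt, ], se2[tt, ], df_com))
  pooled <- dplyr::bind_rows(pooled)
  out <- tibble::tibble(label = curves[[1]]$label, age = curves[[1]]$age,
                        log_aor = pooled$estimate, se = pooled$se,
                        aor = exp(pooled$estimate),
                        conf.low = exp(pooled$conf.low),
                        conf.high = exp(pooled$conf.high))
  out$significant <- out$conf.low > 1 | out$conf.high < 1
  class(out) <- c("time_response_curve", class(out))
  out
}

#' @rdname pool_time_response
#' @param effects List of `cumulative_effect` tibbles, one per imputation.
#' @export
pool_cumulative_effect <- function(effects, df_com = Inf) {
  stopifnot(length(effects) >= 1)
  pe <- rubin_pool(vapply(effects, function(e) e$log_aor, numeric(1)),
                   vapply(effects, function(e) e$se^2, numeric(1)), df_com)
  out <- tibble::tibble(contrast = effects[[1]]$contrast,
                        n_occasions = effects[[1]]$n_occasions,
                        log_aor = pe$estimate, se = pe$se,
                        aor = exp(pe$estimate),
                        conf.low = exp(pe$conf.low),
                        conf.high = exp(pe$conf.high),
                        significant = exp(pe$conf.low) > 1 | exp(pe$conf.high) < 1,
                        m = pe$m)
  class(out) <- c("cumulative_effect", class(out))
  out
}
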