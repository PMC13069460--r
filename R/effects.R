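#' Time-response curve: per-occasion adjusted odds ratios
#'
#' The lag-weight curve `w = B theta` expressed as odds ratios for a
#' sustained exposure contrast (default EPDS 13 vs 0) at each measurement
#' occasion: `log AOR_t = contrast * w_t`, with pointwise 95% intervals
#' from the quadratic form `contrast^2 * B[t,] V_theta B[t,]'` computed on
#' the log scale and exponentiated. Significance flags are pointwise (CI
#' excluding 1), matching the "NS" annotation style of sensitive-period
#' figures; no multiplicity adjustment.
#'
#' @param fit A converged `plag_fit` with a [dlm_design()] lag block.
#' @param basis The [pspline_basis()] used to build the design.
#' @param contrast Exposure contrast level (default 13).
#' @param ages Optional dense age grid for plotting; default: the
#'   schedule's observed occasions.
#' @return A tibble of class `time_response_curve`: `label`, `age`,
#'   `log_aor`, `se`, `aor`, `conf.low`, `conf.high`, `significant`.
#' @export
time_response <- function(fit, basis, contrast = 13, ages = NULL) {
  check_converged(fit)
  if (is.null(ages)) {
    B <- basis$B
    label <- basis$schedule$label
    age <- basis$schedule$age
  } else {
    B <- evaluate_basis(basis, ages)
    label <- sprintf("age_%.3g", ages)
    age <- ages
  }
  ci <- lag_contrast_ci(fit, B, contrast)
  out <- tibble::tibble(label = label, age = age, !!!ci)
  class(out) <- c("time_response_curve", class(out))
  attr(out, "contrast") <- contrast
  out
}

#' Cumulative adjusted odds ratio
#'
#' The odds of elevated offspring symptoms contrasting sustained exposure
#' at `contrast` (default EPDS 13) at every occasion versus 0 at every
#' occasion: `log AOR = contrast * 1'B theta`, identically the sum of the
#' per-occasion log AORs.
#'
#' @inheritParams time_response
#' @return A one-row tibble of class `cumulative_effect`.
#' @export
cumulative_effect <- function(fit, basis, contrast = 13) {
  check_converged(fit)
  b <- matrix(colSums(basis$B), nrow = 1)
  ci <- lag_contrast_ci(fit, b, contrast)
  out <- tibble::tibble(contrast = contrast, n_occasions = nrow(basis$B), !!!ci)
  class(out) <- c("cumulative_effect", class(out))
  out
}

# Shared CI machinery: rows of A define linear functionals of the lag
# coefficients; log AOR = contrast * A theta.
lag_contrast_ci <- function(fit, A, contrast, level = 0.95) {
  idx <- fit$idx$lag
  theta <- fit$coefficients[idx]
  Vth <- fit$V[idx, idx, drop = FALSE]
  log_aor <- contrast * as.numeric(A %*% theta)
  se <- contrast * sqrt(pmax(rowSums((A %*% Vth) * A), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- exp(log_aor - z * se)
  hi <- exp(log_aor + z * se)
  list(log_aor = log_aor, se = se, aor = exp(log_aor),
       conf.low = lo, conf.high = hi,
       significant = lo > 1 | hi < 1)
}

#' DLNM contrast surface over exposure level and occasion
#'
#' For a cross-basis fit, the adjusted odds ratio contrasting a sustained
#' EPDS score of `e` versus 0, per occasion and cumulatively:
#' `log AOR(e, t) = sum_k f_k(e) * (B theta_k)_t` (the exposure basis is
#' anchored at 0, so `AOR(0, t) = 1` exactly). With the linear exposure
#' basis the surface reduces to `exp(e * w_t)`.
#'
#' @param fit A converged `plag_fit` whose lag block is the matching
#'   [crossbasis_design()].
#' @param cross The `cross_basis` object.
#' @param levels Exposure levels (default `1:30`); must lie in \[0, 30\].
#' @return A list of class `dlnm_surface`: `surface` (tibble: `level`,
#'   `label`, `age`, `log_aor`, `se`, `aor`, `conf.low`, `conf.high`,
#'   `significant`) and `cumulative` (tibble: one row per level).
#' @export
dlnm_surface <- function(fit, cross, levels = 1:30) {
  check_converged(fit)
  if (any(levels < 0 | levels > 30)) {
    stop("exposure levels must lie in [0, 30]", call. = FALSE)
  }
  lb <- cross$lag_basis
  Tn <- nrow(lb$B)
  Fe <- exposure_basis_at(cross$exposure_basis, levels)  # n_lev x K_e
  surf <- vector("list", length(levels))
  cum <- vector("list", length(levels))
  for (j in seq_along(levels)) {
    A <- kronecker(matrix(Fe[j, ], 1), lb$B)    # T x (K_e * K)
    ci <- lag_contrast_ci(fit, A, contrast = 1)
    surf[[j]] <- tibble::tibble(level = levels[j], label = lb$schedule$label,
                                age = lb$schedule$age, !!!ci)
    Ac <- matrix(colSums(A), nrow = 1)
    cic <- lag_contrast_ci(fit, Ac, contrast = 1)
    cum[[j]] <- tibble::tibble(level = levels[j], n_occasions = Tn, !!!cic)
  }
  structure(list(surface = dplyr::bind_rows(surf),
                 cumulative = dplyr::bind_rows(cum)),
            class = "dlnm_surface")
}

#' Wald test for moderation of the lag structure
#'
#' For a fit containing moderator-specific deviation coefficients
#' (moderator x lag-basis block), the Wald statistic
#' `chi2 = delta' V_delta^{-1} delta` with df equal to the block size.
#' Per-imputation statistics are pooled with [d2_pool()].
#'
#' @param fit A converged `plag_fit`.
#' @param block Integer indices or coefficient names of the deviation
#'   block.
#' @return A one-row tibble: `chi2`, `df`, `p.value` (complete-data
#'   chi-square reference).
#' @export
moderation_wald <- function(fit, block) {
  check_converged(fit)
  if (is.character(block)) block <- match(block, names(fit$coefficients))
  delta <- fit$coefficients[block]
  Vd <- fit$V[block, block, drop = FALSE]
  ch <- tryCatch(chol(Vd), error = function(e) NULL)
  if (is.null(ch)) stop("deviation-block covariance is singular", call. = FALSE)
  chi2 <- as.numeric(crossprod(backsolve(ch, delta, transpose = TRUE)))
  df <- length(block)
  tibble::tibble(chi2 = chi2, df = df,
                 p.value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

check_converged <- function(fit) {
  stopifnot(inherits(fit, "plag_fit"))
  if (!isTRUE(fit$converged)) {
    stop(sprintf("fit did not converge (%d iterations, |grad| = %.3g); refusing to compute contrasts",
                 fit$iterations, fit$grad_norm), call. = FALSE)
  }
  invisible(fit)
}
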