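#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a penalized distributed-lag fit
#'
#' One row per coefficient (lag block, covariates, cutpoints) with
#' penalized-information standard errors and Wald z tests. Lag-block
#' rows are labelled `term_type = "lag"`; note their individual values are
#' basis coefficients -- use [time_response()] for the interpretable
#' per-occasion curve.
#'
#' @param x A `plag_fit`.
#' @param ... Unused.
#' @return A tibble: `term`, `term_type`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.plag_fit <- function(x, ...) {
  est <- x$coefficients
  se <- sqrt(pmax(diag(x$V), 0))
  type <- rep("lag", length(est))
  type[x$idx$cov] <- "covariate"
  type[x$idx$alpha] <- "cutpoint"
  z <- est / se
  tibble::tibble(term = names(est), term_type = type, estimate = est,
                 std.error = se, statistic = z,
                 p.value = 2 * stats::pnorm(-abs(z)))
}

#' One-row fit summary
#'
#' @param x A `plag_fit`.
#' @param ... Unused.
#' @return A tibble: `outcome_type`, `n`, `n_categories`, `lambda`
#'   (first penalty), `edf`, `logLik`, `converged`, `iterations`,
#'   `separation`.
#' @method glance plag_fit
#' @export
glance.plag_fit <- function(x, ...) {
  tibble::tibble(outcome_type = x$outcome_type, n = x$n,
                 n_categories = x$n_categories, lambda = x$lambda[1],
                 edf = x$edf, logLik = x$loglik, converged = x$converged,
                 iterations = x$iterations, separation = x$separation)
}
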