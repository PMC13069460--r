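#' Model-fitting specification
#'
#' @param outcome_type `"binary"` (logistic) or `"ordinal"` (proportional
#'   odds / cumulative logit).
#' @param lambda_rule `"fixed"` (use `lambda` as given), `"REML"`
#'   (Laplace-approximate restricted likelihood over log-lambda) or
#'   `"target_edf"` (solve `edf(lambda) = edf_target`).
#' @param lambda Smoothing parameter(s) for `"fixed"`; scalar, or one per
#'   penalty matrix.
#' @param edf_target Target effective degrees of freedom for `"target_edf"`.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance: the fit stops when the sup-norm of the
#'   penalized-score vector falls below `tol` (and the relative change in
#'   the penalized log-likelihood below `1e-8`).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(outcome_type = c("binary", "ordinal"),
                       lambda_rule = c("fixed", "REML", "target_edf"),
                       lambda = 1, edf_target = NULL,
                       max_iter = 200L, tol = 1e-6) {
  outcome_type <- match.arg(outcome_type)
  lambda_rule <- match.arg(lambda_rule)
  if (lambda_rule == "target_edf" && is.null(edf_target)) {
    stop("target_edf rule needs edf_target", call. = FALSE)
  }
  structure(list(outcome_type = outcome_type, lambda_rule = lambda_rule,
                 lambda = lambda, edf_target = edf_target,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "model_spec")
}

# Normalize a penalty argument (matrix, or list of matrices possibly with
# rank attributes) into a list; lambda recycled to its length.
normalize_penalties <- function(penalty, K_lag, lambda) {
  if (is.null(penalty)) return(list(mats = list(), lambda = numeric(0)))
  if (is.matrix(penalty)) penalty <- list(penalty)
  for (P in penalty) {
    if (!is.matrix(P) || nrow(P) != K_lag || ncol(P) != K_lag) {
      stop("each penalty matrix must be K_lag x K_lag", call. = FALSE)
    }
  }
  lambda <- rep_len(lambda, length(penalty))
  list(mats = penalty, lambda = lambda)
}

# Combined lag-block penalty sum(lambda_j * P_j), embedded at `idx` in a
# p x p matrix.
embed_penalty <- function(pen, idx, p) {
  S <- matrix(0, p, p)
  if (length(pen$mats)) {
    Sl <- Reduce(`+`, Map(function(P, l) l * P, pen$mats, pen$lambda))
    S[idx, idx] <- Sl
  }
  S
}

# --- Newton engine for the penalized cumulative-logit likelihood ---------
#
# y in 0..C (C >= 1); eta_i = X_i beta; P(Y >= k) = plogis(eta - alpha_k).
# C = 1 is the logistic model with intercept -alpha_1. The penalty
# S (p x p) acts on beta only. Cutpoints are optimized through the
# log-increment parameterization tau (alpha_1 = tau_1,
# alpha_k = alpha_{k-1} + exp(tau_k)), which enforces monotonicity; the
# reported covariance is the inverse penalized observed information on the
# natural (beta, alpha) scale.
cumlogit_engine <- function(y, X, S, max_iter = 200L, tol = 1e-6) {
  n <- length(y); p <- ncol(X)
  C <- max(y)
  stopifnot(min(y) == 0L, C >= 1L, all(y == round(y)), nrow(X) == n)
  counts <- tabulate(y + 1L, nbins = C + 1L)
  if (any(counts == 0L)) {
    stop("all categories 0..C must be observed (collapse first)", call. = FALSE)
  }
  surv <- rev(cumsum(rev(counts / n)))[-1]          # P(Y >= k), k = 1..C
  alpha <- -stats::qlogis(surv)
  beta <- rep(0, p)
  tau <- c(alpha[1], if (C > 1) log(diff(alpha)))

  has1 <- y >= 1L            # s1 = eta - alpha_y defined
  has2 <- y <= C - 1L        # s2 = eta - alpha_{y+1} defined
  E1 <- matrix(0, n, C); E1[cbind(which(has1), y[has1])] <- 1
  E2 <- matrix(0, n, C); E2[cbind(which(has2), y[has2] + 1L)] <- 1
  M1 <- cbind(X, -E1)
  M2 <- cbind(X, -E2)

  pen_obj <- function(beta, alpha) {
    eta <- as.numeric(X %*% beta)
    sv <- cbind(1, stats::plogis(outer(eta, alpha, `-`)), 0)
    pr <- sv[cbind(seq_len(n), y + 1L)] - sv[cbind(seq_len(n), y + 2L)]
    ll <- sum(log(pmax(pr, 1e-300)))
    ll - 0.5 * as.numeric(beta %*% S %*% beta)
  }
  alpha_of_tau <- function(tau) cumsum(c(tau[1], exp(tau[-1])))

  obj_trace <- numeric(0)
  obj <- pen_obj(beta, alpha)
  converged <- FALSE; it <- 0L; gnorm <- Inf
  repeat {
    it <- it + 1L
    eta <- as.numeric(X %*% beta)
    s1 <- eta - ifelse(has1, alpha[pmax(y, 1L)], 0)
    s2 <- eta - ifelse(has2, alpha[pmin(y + 1L, C)], 0)
    sg1 <- stats::plogis(s1); sg2 <- stats::plogis(s2)
    p1 <- ifelse(has1, sg1, 1)
    p2 <- ifelse(has2, sg2, 0)
    pr <- pmax(p1 - p2, 1e-12)
    d1s <- ifelse(has1, sg1 * (1 - sg1), 0)
    d2s <- ifelse(has2, sg2 * (1 - sg2), 0)
    dd1 <- ifelse(has1, d1s * (1 - 2 * sg1), 0)
    dd2 <- ifelse(has2, d2s * (1 - 2 * sg2), 0)
    d1 <- d1s / pr
    d2 <- -d2s / pr
    h11 <- dd1 / pr - (d1s / pr)^2
    h22 <- -dd2 / pr - (d2s / pr)^2
    h12 <- d1s * d2s / pr^2

    g <- as.numeric(crossprod(M1, d1) + crossprod(M2, d2))
    H <- crossprod(M1, M1 * h11) + crossprod(M2, M2 * h22) +
      crossprod(M1, M2 * h12) + crossprod(M2, M1 * h12)
    H <- (H + t(H)) / 2
    g[1:p] <- g[1:p] - as.numeric(S %*% beta)
    H[1:p, 1:p] <- H[1:p, 1:p] - S

    # chain rule (beta, alpha) -> (beta, tau)
    J <- matrix(0, C, C)
    J[, 1] <- 1
    if (C > 1) for (j in 2:C) J[j:C, j] <- exp(tau[j])
    Jf <- rbind(cbind(diag(p), matrix(0, p, C)),
                cbind(matrix(0, C, p), J))
    g_tau <- as.numeric(crossprod(Jf, g))
    H_tau <- crossprod(Jf, H %*% Jf)
    if (C > 1) {
      ga <- g[(p + 1):(p + C)]
      for (j in 2:C) {
        H_tau[p + j, p + j] <- H_tau[p + j, p + j] + exp(tau[j]) * sum(ga[j:C])
      }
    }
    H_tau <- (H_tau + t(H_tau)) / 2

    gnorm <- max(abs(g_tau))
    obj_trace <- c(obj_trace, obj)
    if (gnorm < tol && it > 1L) { converged <- TRUE; break }
    if (it > max_iter) break

    A <- -H_tau
    ridge <- 0
    step <- NULL
    repeat {
      ch <- tryCatch(chol(A + ridge * diag(p + C)), error = function(e) NULL)
      if (!is.null(ch)) { step <- backsolve(ch, forwardsolve(t(ch), g_tau)); break }
      ridge <- max(ridge * 10, 1e-8 * max(abs(diag(A)), 1))
      if (ridge > 1e12) stop("Hessian irreparably singular", call. = FALSE)
    }

    # scale-free stopping rule for stiff penalties: Newton decrement
    if (abs(sum(step * g_tau)) / 2 < 1e-11 * (abs(obj) + 1)) {
      converged <- TRUE
      break
    }

    # step-halving on the penalized objective
    fac <- 1; improved <- FALSE
    for (h in 1:40) {
      beta_new <- beta + fac * step[1:p]
      tau_new <- tau + fac * step[(p + 1):(p + C)]
      alpha_new <- alpha_of_tau(tau_new)
      obj_new <- pen_obj(beta_new, alpha_new)
      if (is.finite(obj_new) && obj_new >= obj - 1e-12) { improved <- TRUE; break }
      fac <- fac / 2
    }
    if (!improved) break
    beta <- beta_new; tau <- tau_new; alpha <- alpha_new; obj <- obj_new
  }

  # information matrices on the natural (beta, alpha) scale at the solution
  eta <- as.numeric(X %*% beta)
  s1 <- eta - ifelse(has1, alpha[pmax(y, 1L)], 0)
  s2 <- eta - ifelse(has2, alpha[pmin(y + 1L, C)], 0)
  sg1 <- stats::plogis(s1); sg2 <- stats::plogis(s2)
  p1 <- ifelse(has1, sg1, 1); p2 <- ifelse(has2, sg2, 0)
  pr <- pmax(p1 - p2, 1e-12)
  d1s <- ifelse(has1, sg1 * (1 - sg1), 0)
  d2s <- ifelse(has2, sg2 * (1 - sg2), 0)
  dd1 <- ifelse(has1, d1s * (1 - 2 * sg1), 0)
  dd2 <- ifelse(has2, d2s * (1 - 2 * sg2), 0)
  h11 <- dd1 / pr - (d1s / pr)^2
  h22 <- -dd2 / pr - (d2s / pr)^2
  h12 <- d1s * d2s / pr^2
  H <- crossprod(M1, M1 * h11) + crossprod(M2, M2 * h22) +
    crossprod(M1, M2 * h12) + crossprod(M2, M1 * h12)
  H <- (H + t(H)) / 2
  I_obs <- -H                               # unpenalized observed information
  S_aug <- matrix(0, p + C, p + C); S_aug[1:p, 1:p] <- S
  I_pen <- I_obs + S_aug
  ll <- sum(log(pr))

  list(beta = beta, alpha = alpha, I_obs = I_obs, I_pen = I_pen,
       loglik = ll, penalized_obj = obj, objective_trace = obj_trace,
       converged = converged, iterations = it, grad_norm = gnorm,
       eta = eta, n = n, C = C)
}

# edf of the lag block: trace over lag indices of (I_obs + S)^-1 I_obs.
# With an over-complete basis (K > occasions) and a tiny lambda the
# penalized information can be numerically singular; a relative ridge
# keeps the trace well defined without visibly moving it.
edf_lag_block <- function(I_obs, S_aug, idx_lag) {
  A <- I_obs + S_aug
  Fm <- tryCatch(solve(A, I_obs), error = function(e) {
    ridge <- 1e-10 * mean(abs(diag(A)))
    solve(A + ridge * diag(nrow(A)), I_obs)
  })
  sum(diag(Fm)[idx_lag])
}

build_fit <- function(eng, K_lag, p, pen, penalty_arg, outcome_type,
                      colnames_lag, colnames_cov, y_levels = NULL) {
  C <- eng$C
  idx_lag <- seq_len(K_lag)
  idx_cov <- if (p > K_lag) (K_lag + 1):p else integer(0)
  idx_alpha <- (p + 1):(p + C)
  nm <- c(colnames_lag, colnames_cov, paste0("alpha", seq_len(C)))
  V <- tryCatch(solve(eng$I_pen), error = function(e) NULL)
  if (is.null(V)) {
    # near-singular penalized information (e.g. under separation): ridge it
    ridge <- 1e-8 * max(abs(diag(eng$I_pen)), 1)
    V <- solve(eng$I_pen + ridge * diag(nrow(eng$I_pen)))
  }
  V <- (V + t(V)) / 2
  dimnames(V) <- list(nm, nm)
  S_aug <- eng$I_pen - eng$I_obs
  edf <- edf_lag_block(eng$I_obs, S_aug, idx_lag)
  coefs <- c(eng$beta, eng$alpha)
  names(coefs) <- nm
  separation <- max(abs(eng$eta)) > 30 || max(abs(eng$beta)) > 50
  structure(list(
    coefficients = coefs,
    theta = stats::setNames(eng$beta[idx_lag], colnames_lag),
    gamma = stats::setNames(eng$beta[idx_cov], colnames_cov),
    alpha = eng$alpha,
    intercept = if (outcome_type == "binary") -eng$alpha[1] else NULL,
    V = V, lambda = pen$lambda, penalty = penalty_arg,
    edf = edf, loglik = eng$loglik, penalized_obj = eng$penalized_obj,
    objective_trace = eng$objective_trace,
    converged = eng$converged, iterations = eng$iterations,
    grad_norm = eng$grad_norm, separation = separation,
    outcome_type = outcome_type, n = eng$n, n_categories = C + 1L,
    y_levels = y_levels,
    idx = list(lag = idx_lag, cov = idx_cov, alpha = idx_alpha)),
    class = "plag_fit")
}

#' Penalized logistic regression with a distributed-lag block
#'
#' Maximizes `loglik(theta, gamma, alpha) - 0.5 * lambda * theta' P theta`
#' by Newton iteration with step-halving; only the lag block is
#' penalized. The reported covariance `V` is the inverse penalized
#' observed information (the Bayesian covariance standard for penalized
#' spline intervals), and `edf` is the trace of the lag block of
#' `(I + lambda P)^{-1} I`.
#'
#' @param design_lag Lag-block design matrix (`n x K`, from [dlm_design()]
#'   or a [crossbasis_design()]).
#' @param design_cov Unpenalized covariate matrix (`n x q`) or `NULL`.
#' @param y Binary 0/1 outcome vector.
#' @param penalty Penalty matrix for the lag block (or list of matrices,
#'   e.g. the two marginal cross-basis penalties).
#' @param spec A [model_spec()]; its `lambda_rule` decides whether
#'   `lambda` is fixed or selected by REML / target-edf before fitting.
#' @return A `plag_fit` object.
#' @export
fit_penalized_logistic <- function(design_lag, design_cov = NULL, y,
                                   penalty, spec = model_spec("binary")) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("y must be 0/1", call. = FALSE)
  fit_plag(design_lag, design_cov, y, penalty, spec, outcome_type = "binary")
}

#' Penalized proportional-odds (cumulative logit) regression
#'
#' Ordinal model `logit P(Y >= k) = theta'u + gamma'z - alpha_k` with one
#' shared coefficient vector across thresholds. Categories observed zero
#' times are collapsed into their lower neighbour before fitting (the
#' likelihood is otherwise degenerate; odds-ratio contrasts are invariant
#' to collapsing under proportional odds). Cutpoints are kept strictly
#' increasing through a log-increment parameterization. With two
#' categories the model is exactly the penalized logistic regression.
#'
#' @inheritParams fit_penalized_logistic
#' @param y Integer ordinal outcome (any integer coding; at least 2
#'   distinct observed values).
#' @return A `plag_fit` object; `y_levels` records the collapsed category
#'   coding.
#' @export
fit_proportional_odds <- function(design_lag, design_cov = NULL, y,
                                  penalty, spec = model_spec("ordinal")) {
  y <- as.integer(y)
  lev <- sort(unique(y))
  if (length(lev) < 2L) stop("need at least 2 observed categories", call. = FALSE)
  y_dense <- match(y, lev) - 1L
  fit_plag(design_lag, design_cov, y_dense, penalty, spec,
           outcome_type = "ordinal", y_levels = lev)
}

fit_plag <- function(design_lag, design_cov, y, penalty, spec, outcome_type,
                     y_levels = NULL) {
  design_lag <- as.matrix(design_lag)
  K_lag <- ncol(design_lag)
  X <- if (is.null(design_cov)) design_lag else cbind(design_lag, as.matrix(design_cov))
  p <- ncol(X)
  cl_lag <- colnames(design_lag) %||% paste0("lag", seq_len(K_lag))
  cl_cov <- if (p > K_lag) {
    colnames(design_cov) %||% paste0("z", seq_len(p - K_lag))
  } else character(0)

  lambda <- spec$lambda
  if (spec$lambda_rule != "fixed") {
    lambda <- select_lambda(design_lag, design_cov, y, penalty, spec)
  }
  pen <- normalize_penalties(penalty, K_lag, lambda)
  S <- embed_penalty(pen, seq_len(K_lag), p)
  eng <- cumlogit_engine(y, X, S, max_iter = spec$max_iter, tol = spec$tol)
  if (!eng$converged) {
    stop(sprintf("fit did not converge after %d iterations (|grad| = %.3g)",
                 eng$iterations, eng$grad_norm), call. = FALSE)
  }
  fit <- build_fit(eng, K_lag, p, pen, penalty, outcome_type, cl_lag, cl_cov,
                   y_levels)
  if (fit$separation) {
    warning("possible quasi-complete separation: diverging coefficients",
            call. = FALSE)
  }
  fit
}

#' Effective degrees of freedom of the lag block
#'
#' Trace over the lag block of `(I + S_lambda)^{-1} I` at the fitted
#' solution, where `I` is the unpenalized observed information and
#' `S_lambda` the lambda-scaled penalty. Lies in
#' `(penalty null-space dimension, K]`: `K` at `lambda = 0`, the null-space
#' dimension in the `lambda -> Inf` limit.
#'
#' @param fit A `plag_fit`.
#' @return Scalar effective df.
#' @export
effective_df <- function(fit) {
  stopifnot(inherits(fit, "plag_fit"))
  fit$edf
}

#' Select the smoothing parameter
#'
#' `"REML"` maximizes the Laplace-approximate restricted log-likelihood
#' `loglik(beta_hat) - 0.5 lambda theta' P theta + 0.5 rank(P) log lambda
#' - 0.5 log det(I_pen)` over `log(lambda)` by golden-section search
#' ([stats::optimize()]); with two penalty matrices (cross-basis fits) the
#' two log-lambdas are chosen jointly on a grid. `"target_edf"` solves
#' `edf(lambda) = edf_target` by root bisection (edf is monotone
#' decreasing in lambda).
#'
#' @inheritParams fit_penalized_logistic
#' @param spec A [model_spec()] with `lambda_rule` `"REML"` or
#'   `"target_edf"`.
#' @param lower,upper Search range for `log(lambda)`.
#' @param grid_n Per-dimension grid size for the two-penalty joint search.
#' @return Selected lambda (scalar, or vector of two).
#' @export
select_lambda <- function(design_lag, design_cov = NULL, y, penalty, spec,
                          lower = log(1e-4), upper = log(1e8), grid_n = 7L) {
  design_lag <- as.matrix(design_lag)
  K_lag <- ncol(design_lag)
  X <- if (is.null(design_cov)) design_lag else cbind(design_lag, as.matrix(design_cov))
  p <- ncol(X)
  y <- as.integer(y)
  if (spec$outcome_type == "ordinal") y <- match(y, sort(unique(y))) - 1L
  mats <- if (is.matrix(penalty)) list(penalty) else penalty
  ranks <- vapply(mats, function(P) {
    r <- attr(P, "rank")
    if (is.null(r)) r <- qr(P)$rank
    as.numeric(r)
  }, numeric(1))

  eng_at <- function(lambda) {
    pen <- normalize_penalties(mats, K_lag, lambda)
    S <- embed_penalty(pen, seq_len(K_lag), p)
    eng <- cumlogit_engine(y, X, S, max_iter = spec$max_iter, tol = spec$tol)
    list(eng = eng, S_aug = eng$I_pen - eng$I_obs)
  }

  if (spec$lambda_rule == "target_edf") {
    target <- spec$edf_target
    edf_at <- function(loglam) {
      e <- eng_at(exp(loglam))
      edf_lag_block(e$eng$I_obs, e$S_aug, seq_len(K_lag)) - target
    }
    lo <- lower; hi <- upper
    if (edf_at(lo) < 0) stop("edf_target above edf at the lower lambda bound",
                             call. = FALSE)
    if (edf_at(hi) > 0) stop("edf_target below the penalty null-space dimension",
                             call. = FALSE)
    r <- stats::uniroot(edf_at, c(lo, hi), tol = 1e-4)
    return(exp(r$root))
  }

  rll <- function(loglam) {
    lam <- exp(loglam)
    e <- eng_at(lam)
    ld <- as.numeric(determinant(e$eng$I_pen, logarithm = TRUE)$modulus)
    e$eng$penalized_obj + 0.5 * sum(ranks * loglam) - 0.5 * ld
  }
  if (length(mats) == 1L) {
    opt <- stats::optimize(rll, c(lower, upper), maximum = TRUE, tol = 1e-3)
    exp(opt$maximum)
  } else {
    gr <- seq(lower, upper, length.out = grid_n)
    combos <- as.matrix(expand.grid(rep(list(gr), length(mats))))
    vals <- apply(combos, 1, rll)
    exp(combos[which.max(vals), ])
  }
}

#' @export
print.plag_fit <- function(x, ...) {
  cat(sprintf("<plag_fit: %s, n = %d, %d lag + %d covariate coefficients, %d categories>\n",
              x$outcome_type, x$n, length(x$theta), length(x$gamma),
              x$n_categories))
  cat(sprintf("  lambda = %s, lag edf = %.2f, loglik = %.2f, converged in %d iterations\n",
              paste(signif(x$lambda, 4), collapse = ", "), x$edf, x$loglik,
              x$iterations))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
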