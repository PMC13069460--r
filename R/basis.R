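#' P-spline basis over exposure time
#'
#' B-spline basis of dimension `K` evaluated at the schedule's
#' developmental ages, with an order-`penalty_order` difference penalty on
#' the basis coefficients (Eilers--Marx P-spline). Knots are equally
#' spaced on the age axis: the span `[min(age), max(age)]` is divided into
#' `K - degree` intervals of width `h` and the knot sequence is extended
#' `degree` intervals beyond each boundary, so the basis is a partition of
#' unity on the observed span. Smoothness is controlled downstream by the
#' penalty, not the basis size: with 12 maternal occasions and the default
#' `K = 15` the unpenalized basis is deliberately over-complete.
#'
#' @param schedule An [exposure_schedule()].
#' @param K Basis dimension (default 15); must satisfy `K >= degree + 1`.
#' @param degree Spline degree (default cubic).
#' @param penalty_order Difference-penalty order `d` (default 2: deviations
#'   from a line in age are penalized).
#' @return A list of class `lag_basis`: `B` (`T x K`), `P` (`K x K`),
#'   `knots`, `schedule`, `K`, `degree`, `penalty_order`.
#' @export
pspline_basis <- function(schedule, K = 15L, degree = 3L, penalty_order = 2L) {
  stopifnot(inherits(schedule, "exposure_schedule"))
  if (K < degree + 1) stop("K must be at least degree + 1", call. = FALSE)
  if (any(!is.finite(schedule$age))) stop("schedule ages must be finite", call. = FALSE)
  knots <- pspline_knots(range(schedule$age), K, degree)
  B <- splines::splineDesign(knots, schedule$age, ord = degree + 1)
  colnames(B) <- paste0("b", seq_len(K))
  structure(list(B = B, P = difference_penalty(K, penalty_order),
                 knots = knots, schedule = schedule, K = as.integer(K),
                 degree = as.integer(degree),
                 penalty_order = as.integer(penalty_order)),
            class = "lag_basis")
}

pspline_knots <- function(rng, K, degree) {
  nseg <- K - degree
  h <- diff(rng) / nseg
  knots <- seq(rng[1] - degree * h, rng[2] + degree * h,
               length.out = nseg + 2L * degree + 1L)
  # pin the support boundary knots to the data range exactly
  knots[degree + 1L] <- rng[1]
  knots[nseg + degree + 1L] <- rng[2]
  knots
}

#' Evaluate a lag basis at arbitrary ages
#'
#' Used for dense-grid plotting of lag curves; ages must lie within the
#' schedule span.
#'
#' @param basis A [pspline_basis()].
#' @param ages Numeric ages within `range(basis$schedule$age)`.
#' @return Matrix `length(ages) x K`.
#' @export
evaluate_basis <- function(basis, ages) {
  rng <- range(basis$schedule$age)
  if (any(ages < rng[1] | ages > rng[2])) {
    stop("ages outside the schedule span", call. = FALSE)
  }
  splines::splineDesign(basis$knots, ages, ord = basis$degree + 1)
}

#' Difference penalty matrix
#'
#' `P = D' D` where `D` is the order-`d` finite-difference operator on the
#' coefficient index. `P` is symmetric positive semidefinite with null
#' space of dimension `d` (polynomials of degree `d - 1` in the index are
#' unpenalized).
#'
#' @param K Coefficient count.
#' @param d Difference order, `1 <= d < K`.
#' @return `K x K` penalty matrix.
#' @export
difference_penalty <- function(K, d = 2L) {
  if (d < 1 || d >= K) stop("difference order must satisfy 1 <= d < K", call. = FALSE)
  D <- diff(diag(K), differences = d)
  crossprod(D)
}

#' Distributed-lag design matrix
#'
#' `U = X B`: with lag coefficients `theta`, the linear-predictor
#' contribution of subject `i` is `sum_t x_it w_t` where the lag-weight
#' curve is `w = B theta`.
#'
#' @param exposures Complete numeric matrix `n x T` (occasions in schedule
#'   order).
#' @param basis A [pspline_basis()] built on the matching schedule.
#' @return Matrix `n x K`.
#' @export
dlm_design <- function(exposures, basis) {
  exposures <- as.matrix(exposures)
  if (ncol(exposures) != nrow(basis$B)) {
    stop("exposure columns do not match the basis schedule", call. = FALSE)
  }
  if (anyNA(exposures)) {
    bad <- which(rowSums(is.na(exposures)) > 0)
    stop("exposures contain missing cells (impute upstream); rows: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) ", ..." else "", call. = FALSE)
  }
  U <- exposures %*% basis$B
  colnames(U) <- colnames(basis$B)
  U
}

#' Cross-basis design for distributed lag nonlinear models
#'
#' Tensor expansion over exposure level and exposure time: column `(k, l)`
#' for subject `i` is `sum_t f_k(x_it) B[t, l]`, with the exposure basis
#' `f` anchored at the reference score 0 (`f_k(0) = 0`), so a subject with
#' all-zero exposure contributes nothing. With the linear exposure basis
#' (`f(x) = x`, one function) the design reduces exactly to [dlm_design()].
#'
#' @param exposures Complete numeric matrix `n x T`, values in \[0, 30\].
#' @param lag_basis A [pspline_basis()].
#' @param exposure_basis `exposure_basis_spec()`: `"linear"` or a B-spline
#'   over the score range.
#' @return A list of class `cross_basis`: `design` (`n x K_e*K`),
#'   `penalties` (named list `lag`, `exposure` of full-size marginal
#'   penalty matrices with `rank` attributes), `lag_basis`,
#'   `exposure_basis`, `K_e`.
#' @export
crossbasis_design <- function(exposures, lag_basis,
                              exposure_basis = exposure_basis_spec("linear")) {
  exposures <- as.matrix(exposures)
  if (anyNA(exposures)) stop("exposures contain missing cells", call. = FALSE)
  if (any(exposures < 0 | exposures > 30)) {
    stop("exposure values must lie in [0, 30]", call. = FALSE)
  }
  Fx <- eval_exposure_basis(exposure_basis, exposures)  # list of n x T, one per k
  K <- lag_basis$K
  K_e <- length(Fx)
  blocks <- lapply(Fx, function(f) f %*% lag_basis$B)
  design <- do.call(cbind, blocks)
  colnames(design) <- as.vector(outer(paste0("b", seq_len(K)),
                                      paste0("f", seq_len(K_e)),
                                      function(b, f) paste0(f, ".", b)))
  P_lag <- kronecker(diag(K_e), lag_basis$P)
  rk_lag <- K_e * (K - lag_basis$penalty_order)
  pen <- list(lag = structure(P_lag, rank = rk_lag))
  if (K_e > 1) {
    d_e <- min(2L, K_e - 1L)
    P_exp <- kronecker(difference_penalty(K_e, d_e), diag(K))
    pen$exposure <- structure(P_exp, rank = (K_e - d_e) * K)
  }
  structure(list(design = design, penalties = pen, lag_basis = lag_basis,
                 exposure_basis = exposure_basis, K_e = K_e),
            class = "cross_basis")
}

#' Exposure-dimension basis specification for the cross-basis
#'
#' @param type `"linear"` (`f(x) = x`, a single function: the DLM special
#'   case) or `"bspline"` (degree-`degree` B-splines with `K_e` functions
#'   over \[0, 30\], each centred so `f_k(0) = 0`).
#' @param K_e Number of exposure basis functions (bspline only).
#' @param degree Spline degree (bspline only).
#' @return A list of class `exposure_basis_spec`.
#' @export
exposure_basis_spec <- function(type = c("linear", "bspline"), K_e = 4L, degree = 2L) {
  type <- match.arg(type)
  if (type == "bspline" && K_e < degree + 1) {
    stop("K_e must be at least degree + 1", call. = FALSE)
  }
  structure(list(type = type,
                 K_e = if (type == "linear") 1L else as.integer(K_e),
                 degree = as.integer(degree),
                 range = c(0, 30)),
            class = "exposure_basis_spec")
}

# Evaluate the exposure basis functions f_k (anchored at f_k(0) = 0) on a
# matrix of scores; returns a list of matrices, one per basis function.
# A raw B-spline basis sums to one at every score, so its anchored version
# sums to zero (exact collinearity); the first basis function is dropped,
# leaving K_e linearly independent functions vanishing at the reference.
eval_exposure_basis <- function(spec, x) {
  x <- as.matrix(x)
  if (spec$type == "linear") return(list(x))
  M <- exposure_basis_at(spec, as.vector(x))
  lapply(seq_len(spec$K_e), function(k) matrix(M[, k], nrow(x), ncol(x)))
}

# Exposure-basis values at scalar levels (for contrast surfaces).
exposure_basis_at <- function(spec, levels) {
  if (spec$type == "linear") return(matrix(levels, ncol = 1))
  knots <- pspline_knots(spec$range, spec$K_e + 1L, spec$degree)
  M <- splines::splineDesign(knots, levels, ord = spec$degree + 1)
  M0 <- splines::splineDesign(knots, 0, ord = spec$degree + 1)
  sweep(M, 2, as.vector(M0))[, -1, drop = FALSE]
}
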