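#' Exclude rows missing (almost) all required data
#'
#' Removes rows whose missing fraction across the required columns is at
#' or above `threshold` ("95% or more" at the default).
#'
#' @param data A data frame.
#' @param required Character vector of required column names.
#' @param threshold Missing-fraction cutoff in (0, 1\]; rows with fraction
#'   `>= threshold` are removed.
#' @return The filtered tibble; attribute `"exclusion_report"` holds a
#'   one-row tibble of counts.
#' @export
exclusion_filter <- function(data, required, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]", call. = FALSE)
  miss <- setdiff(required, names(data))
  if (length(miss)) stop("required columns absent: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  frac <- rowMeans(is.na(data[required]))
  keep <- frac < threshold
  out <- tibble::as_tibble(data[keep, ])
  attr(out, "exclusion_report") <- tibble::tibble(
    n_input = nrow(data), n_retained = sum(keep), n_excluded = sum(!keep),
    threshold = threshold, n_required_columns = length(required))
  out
}

#' @rdname exclusion_filter
#' @param x A tibble returned by [exclusion_filter()].
#' @export
exclusion_report <- function(x) attr(x, "exclusion_report")

#' Multiple imputation of questionnaire items by regularized low-rank fits
#'
#' The computational core of multiple-correspondence-analysis imputation
#' for categorical items: the items (EPDS items, categories 0--3) are
#' one-hot expanded, the centred indicator matrix is completed by
#' iterating a regularized rank-`ncp` SVD (singular values shrunk by the
#' residual variance estimate) until the fitted values change by less than
#' `tol`, and each of the `m` multiple-imputation variants adds resampled
#' observed-cell residuals before assigning every missing item the
#' category with the largest reconstructed indicator.
#'
#' @param items Integer matrix/data frame `n x J`, entries in 0..3, `NA`
#'   allowed; no column may be entirely missing.
#' @param ncp Rank of the low-rank fit (>= 1).
#' @param m Number of imputed copies.
#' @param seed Integer seed (reproducible).
#' @param tol,max_iter Convergence control for the iterative fit.
#' @return A list of `m` completed integer matrices (attribute `"scores"`:
#'   row sums). With no missing cells all copies equal the input.
#' @export
lowrank_item_impute <- function(items, ncp = 2L, m = 5L, seed = 1L,
                                tol = 1e-6, max_iter = 500L) {
  X <- as.matrix(items)
  if (ncp < 1) stop("ncp must be >= 1", call. = FALSE)
  if (any(colSums(!is.na(X)) == 0)) stop("a column is entirely missing", call. = FALSE)
  rng <- range(X, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 3) stop("item categories must be in 0..3", call. = FALSE)
  n <- nrow(X); J <- ncol(X)
  if (!anyNA(X)) {
    out <- replicate(m, {
      Y <- X; storage.mode(Y) <- "integer"
      attr(Y, "scores") <- rowSums(Y); Y
    }, simplify = FALSE)
    return(out)
  }
  set.seed(seed)
  # one-hot indicator, 4 levels per item
  Z <- matrix(0, n, 4L * J)
  obs_cell <- !is.na(X)
  for (j in seq_len(J)) {
    for (k in 0:3) Z[, 4L * (j - 1L) + k + 1L] <- as.numeric(X[, j] == k)
  }
  Zmask <- matrix(TRUE, n, 4L * J)
  for (j in seq_len(J)) Zmask[, (4L * j - 3L):(4L * j)] <- obs_cell[, j]
  # initialize missing indicator cells at observed column proportions
  for (cc in seq_len(ncol(Z))) {
    mu <- mean(Z[Zmask[, cc], cc])
    Z[!Zmask[, cc], cc] <- mu
  }
  fitted_old <- Z
  for (it in seq_len(max_iter)) {
    mu <- colMeans(Z)
    Zc <- sweep(Z, 2, mu)
    sv <- svd(Zc)
    d <- sv$d
    keep <- seq_len(min(ncp, length(d)))
    # shrink retained singular values by the mean residual eigenvalue
    sigma2 <- if (length(d) > ncp) mean(d[-keep]^2) else 0
    dshr <- pmax((d[keep]^2 - sigma2) / d[keep], 0)
    fit <- sv$u[, keep, drop = FALSE] %*% (dshr * t(sv$v[, keep, drop = FALSE]))
    fit <- sweep(fit, 2, mu, `+`)
    Z[!Zmask] <- fit[!Zmask]
    delta <- sum((fit - fitted_old)^2) / (sum(fitted_old^2) + 1e-12)
    fitted_old <- fit
    if (delta < tol) break
  }
  resid <- (Z - fitted_old)[Zmask]
  out <- vector("list", m)
  for (im in seq_len(m)) {
    noisy <- fitted_old
    nmiss <- sum(!Zmask)
    noisy[!Zmask] <- noisy[!Zmask] + sample(resid, nmiss, replace = TRUE)
    Xi <- X
    for (j in seq_len(J)) {
      rows <- which(!obs_cell[, j])
      if (!length(rows)) next
      blk <- noisy[rows, (4L * j - 3L):(4L * j), drop = FALSE]
      Xi[rows, j] <- max.col(blk, ties.method = "first") - 1L
    }
    storage.mode(Xi) <- "integer"
    attr(Xi, "scores") <- rowSums(Xi)
    out[[im]] <- Xi
  }
  out
}

#' Chained random-forest multiple imputation
#'
#' Chained equations with randomized-tree ensembles (ranger): each
#' incomplete variable is regressed on all other variables, and missing
#' values are drawn by predictive mean matching against out-of-bag
#' predictions for numeric variables (k nearest donors) or by
#' class-probability sampling for factors. Variables are visited in order
#' of increasing missingness; the cycle is repeated `iterations` times per
#' imputation. Deterministic under a fixed seed (single-threaded forests).
#'
#' @param data A data frame; incomplete columns numeric or factor. At
#'   least one column must be fully observed, and every column must have
#'   some observed values.
#' @param m Number of imputations.
#' @param iterations Chained-equation cycles (default 3).
#' @param seed Integer seed.
#' @param num_trees Trees per forest (default 50).
#' @param pmm_k Donor pool size for predictive mean matching.
#' @return An `imputation_set`: list with `imputations` (list of `m`
#'   completed tibbles), `m`, `method`, `seed`, `iterations`, and
#'   per-variable missingness counts.
#' @export
rf_chained_impute <- function(data, m = 20L, iterations = 3L, seed = 1L,
                              num_trees = 50L, pmm_k = 5L) {
  stopifnot(m >= 1)
  data <- tibble::as_tibble(data)
  na_count <- vapply(data, function(x) sum(is.na(x)), integer(1))
  if (any(na_count == nrow(data))) {
    stop("a variable has no observed values", call. = FALSE)
  }
  if (all(na_count > 0)) stop("need at least one fully observed column", call. = FALSE)
  incomplete <- names(sort(na_count[na_count > 0]))
  if (!length(incomplete)) {
    return(structure(list(imputations = replicate(m, data, simplify = FALSE),
                          m = m, method = "rf_chained", seed = seed,
                          iterations = iterations, na_count = na_count),
                     class = "imputation_set"))
  }
  imps <- vector("list", m)
  for (im in seq_len(m)) {
    set.seed(seed + 1000L * im)
    cur <- data
    # initial fill: sample from observed values
    for (v in incomplete) {
      nas <- is.na(cur[[v]])
      cur[[v]][nas] <- sample(cur[[v]][!nas], sum(nas), replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (v in incomplete) {
        nas <- is.na(data[[v]])
        train <- cur[!nas, , drop = FALSE]
        pred_data <- cur[nas, setdiff(names(cur), v), drop = FALSE]
        rf <- ranger::ranger(
          x = as.data.frame(train[setdiff(names(train), v)]),
          y = train[[v]], num.trees = num_trees, num.threads = 1L,
          seed = seed + 1000L * im + 17L * it + match(v, incomplete),
          respect.unordered.factors = "order")
        if (is.factor(data[[v]])) {
          # class-probability sampling via per-tree votes
          pr <- stats::predict(rf, data = as.data.frame(pred_data),
                               predict.all = TRUE, num.threads = 1L)$predictions
          lev <- levels(train[[v]])
          draw <- apply(pr, 1, function(votes) {
            tab <- tabulate(votes, nbins = length(lev))
            sample(lev, 1, prob = tab / sum(tab))
          })
          cur[[v]][nas] <- factor(draw, levels = levels(data[[v]]))
        } else {
          oob <- rf$predictions
          ok <- !is.na(oob)
          pred_mis <- stats::predict(rf, data = as.data.frame(pred_data),
                                     num.threads = 1L)$predictions
          donors_y <- train[[v]][ok]; donors_p <- oob[ok]
          k <- min(pmm_k, length(donors_y))
          cur[[v]][nas] <- vapply(pred_mis, function(pm) {
            idx <- order(abs(donors_p - pm))[seq_len(k)]
            donors_y[idx[sample.int(k, 1)]]
          }, donors_y[1])
        }
      }
    }
    imps[[im]] <- cur
  }
  structure(list(imputations = imps, m = m, method = "rf_chained",
                 seed = seed, iterations = iterations, na_count = na_count),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set: %d imputations, method %s, %d incomplete variables>\n",
              x$m, x$method, sum(x$na_count > 0)))
  invisible(x)
}
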