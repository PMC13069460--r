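#' Simulate repeated EPDS exposures on a schedule
#'
#' Draws a latent Gaussian AR(1) process across the schedule occasions
#' around the truth's mean curve (stationary marginal SD `exposure_sd`,
#' lag-1 correlation `ar_rho`), then rounds to the nearest integer and
#' clips to the 0--30 EPDS range. The discretization mimics an integer
#' questionnaire total with strong serial correlation.
#'
#' @param n Number of subjects.
#' @param schedule An [exposure_schedule()].
#' @param truth A [simulation_truth()] (uses `exposure_mean_curve`,
#'   `exposure_sd`, `ar_rho`).
#' @return Integer matrix `n x T`, column names from [schedule_columns()].
#'   The latent (pre-discretization) draws are attached as attribute
#'   `"latent"` for diagnostics.
#' @export
simulate_exposures <- function(n, schedule, truth) {
  stopifnot(n >= 1, inherits(schedule, "exposure_schedule"))
  if (truth$exposure_sd <= 0) stop("exposure_sd must be positive", call. = FALSE)
  T <- nrow(schedule)
  rho <- truth$ar_rho
  sd <- truth$exposure_sd
  z <- matrix(stats::rnorm(n * T), n, T)
  lat <- matrix(0, n, T)
  lat[, 1] <- z[, 1]
  if (T > 1) {
    innov_sd <- sqrt(1 - rho^2)
    for (t in 2:T) lat[, t] <- rho * lat[, t - 1] + innov_sd * z[, t]
  }
  lat <- sweep(lat * sd, 2, truth$exposure_mean_curve, `+`)
  x <- pmin(pmax(round(lat), 0), 30)
  storage.mode(x) <- "integer"
  colnames(x) <- schedule_columns(schedule)
  attr(x, "latent") <- lat
  x
}

#' Simulate the confounder roster
#'
#' Parental ages, 5-level maternal education, social class, parity,
#' household crowding, marital status, offspring sex (1 = female), six
#' standardized polygenic scores, prenatal smoking and alcohol use
#' (secondary covariates, generated independent of exposure), birth
#' weight (g) and gestational age (weeks). All columns are numeric;
#' ordinal scales are coded 1..5.
#'
#' @param n Number of subjects.
#' @return A tibble with one row per subject.
#' @export
simulate_covariates <- function(n) {
  tibble::tibble(
    mat_age = round(stats::rnorm(n, 28, 4.5), 1),
    pat_age = round(stats::rnorm(n, 30, 5.5), 1),
    mat_education = sample(1:5, n, replace = TRUE,
                           prob = c(0.12, 0.25, 0.33, 0.20, 0.10)),
    social_class = sample(1:5, n, replace = TRUE,
                          prob = c(0.10, 0.25, 0.35, 0.20, 0.10)),
    parity = pmin(stats::rpois(n, 0.8), 4L),
    crowding = stats::rbinom(n, 1, 0.15),
    married = stats::rbinom(n, 1, 0.75),
    sex = stats::rbinom(n, 1, 0.49),
    prs_mdd = stats::rnorm(n), prs_gad = stats::rnorm(n),
    prs_panic = stats::rnorm(n), prs_scz = stats::rnorm(n),
    prs_bipolar = stats::rnorm(n), prs_aud = stats::rnorm(n),
    mat_smoking = stats::rbinom(n, 1, 0.22),
    mat_alcohol = stats::rbinom(n, 1, 0.30),
    birth_weight = round(pmax(stats::rnorm(n, 3400, 520), 500)),
    gestational_age = round(pmin(pmax(stats::rnorm(n, 39.4, 1.8), 24), 43))
  )
}

#' Simulate an outcome from exposures and covariates
#'
#' Linear predictor `eta_i = sum_t w_t x_it + beta' z_i` (plus the
#' moderation shift for the moderated subgroup, if configured). Binary
#' outcomes are Bernoulli with `plogis(eta + intercept)`; ordinal outcomes
#' with categories `0..C` use the cumulative-logit model
#' `P(Y >= k) = plogis(eta - alpha_k)` sampled by inverse CDF.
#'
#' @param exposures Complete integer matrix `n x T` (no missing cells).
#' @param covariates Data frame containing the columns named in
#'   `truth$covariate_effects`.
#' @param truth A [simulation_truth()].
#' @param link `"cumulative_logit"` (needs `truth$cutpoints`) or `"logit"`
#'   (needs `truth$intercept`).
#' @return Integer outcome vector.
#' @export
simulate_outcomes <- function(exposures, covariates, truth,
                              link = c("cumulative_logit", "logit")) {
  link <- match.arg(link)
  if (anyNA(exposures)) stop("exposures must be complete", call. = FALSE)
  n <- nrow(exposures)
  w <- truth$lag_weights
  stopifnot(ncol(exposures) == length(w))
  eta <- as.numeric(exposures %*% w)
  be <- truth$covariate_effects
  if (length(be)) {
    miss <- setdiff(names(be), names(covariates))
    if (length(miss)) stop("covariates missing columns: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    Z <- as.matrix(covariates[names(be)])
    eta <- eta + as.numeric(Z %*% be)
  }
  mod <- truth$moderation
  if (!is.null(mod)) {
    sel <- covariates[[mod$var]] == mod$level
    eta[sel] <- eta[sel] + as.numeric(exposures[sel, , drop = FALSE] %*% mod$shift)
  }
  if (link == "logit") {
    if (is.null(truth$intercept)) stop("binary link needs truth$intercept", call. = FALSE)
    return(stats::rbinom(n, 1, stats::plogis(eta + truth$intercept)))
  }
  alpha <- truth$cutpoints
  if (is.null(alpha)) stop("cumulative_logit link needs truth$cutpoints", call. = FALSE)
  if (any(diff(alpha) <= 0)) stop("cutpoints must be strictly increasing", call. = FALSE)
  # P(Y >= k) for k = 1..C; inverse-CDF draw: Y = #{k : U < P(Y >= k)}
  surv <- stats::plogis(outer(eta, alpha, `-`))
  u <- stats::runif(n)
  as.integer(rowSums(surv > u))
}

#' Delete exposure cells according to the truth's missingness mechanism
#'
#' MCAR deletes each exposure cell independently at the configured rate.
#' MAR makes cell missingness a logistic function of fully observed
#' covariates only (maternal education and maternal age: lower education
#' and younger mothers more likely missing), with intercept calibrated so
#' the marginal rate is approximately the configured rate. Outcomes and
#' covariates are never deleted.
#'
#' @param cohort A cohort tibble (see [simulate_cohort()]).
#' @param truth A [simulation_truth()]; its `missingness` spec and
#'   schedule drive the deletion.
#' @return The cohort with `NA`s punched into that parent's exposure columns.
#' @export
apply_missingness <- function(cohort, truth) {
  ms <- truth$missingness
  if (ms$mechanism == "none" || ms$rate == 0) return(cohort)
  cols <- intersect(schedule_columns(truth$schedule), names(cohort))
  if (!length(cols)) stop("cohort has no exposure columns for this schedule", call. = FALSE)
  n <- nrow(cohort)
  for (cl in cols) {
    if (ms$mechanism == "MCAR") {
      p <- rep(ms$rate, n)
    } else {
      # logit p = a + 0.35*(3 - education) + 0.03*(28 - mat_age), a set so mean(p) ~ rate
      lin <- 0.35 * (3 - cohort$mat_education) + 0.03 * (28 - cohort$mat_age)
      a <- stats::uniroot(function(a) mean(stats::plogis(a + lin)) - ms$rate,
                          c(-20, 20))$root
      p <- stats::plogis(a + lin)
    }
    drop <- stats::runif(n) < p
    cohort[[cl]][drop] <- NA_integer_
  }
  cohort
}

#' Apply the cohort entry criteria
#'
#' Retains offspring with gestational age strictly greater than 32 weeks
#' and birth weight strictly greater than 1500 g.
#'
#' @param cohort A cohort tibble with `gestational_age` and `birth_weight`.
#' @return Filtered tibble; attribute `"entry_report"` records counts
#'   removed by reason (a row can fail both criteria).
#' @export
apply_entry_criteria <- function(cohort) {
  need <- c("gestational_age", "birth_weight")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort is missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ok_ga <- cohort$gestational_age > 32
  ok_bw <- cohort$birth_weight > 1500
  keep <- ok_ga & ok_bw
  out <- cohort[keep, ]
  attr(out, "entry_report") <- tibble::tibble(
    n_input = nrow(cohort), n_retained = sum(keep),
    n_removed = sum(!keep),
    n_low_gestational_age = sum(!ok_ga), n_low_birth_weight = sum(!ok_bw))
  out
}

#' Simulate a full synthetic cohort
#'
#' One row per offspring: maternal and paternal EPDS trajectories on their
#' schedules, the confounder roster, and four adult outcomes generated
#' from known distributed-lag truths -- depression (EPDS total, 0--30,
#' cumulative logit), anxiety (SCAARED-like 0--88), hazardous alcohol use
#' (AUDIT-like 0--40) and a binary psychotic-experience indicator whose
#' generating weights use only occasions at age <= 11. By default all
#' outcomes are driven by the maternal exposure trajectory; paternal
#' trajectories are generated with matching marginal structure.
#'
#' @param n Number of offspring before entry-criteria filtering.
#' @param seed Integer seed; the cohort is bit-reproducible given
#'   `(n, seed, truths)`.
#' @param maternal_truth,paternal_truth [simulation_truth()] objects for
#'   the two exposure processes (and, for `maternal_truth`, the default
#'   outcome-generating lag weights).
#' @param outcome_truths Optional named list overriding the per-outcome
#'   truths (`depression`, `anxiety`, `audit` cumulative-logit;
#'   `psychosis` logit). Defaults are built from `maternal_truth`.
#' @param apply_entry Apply [apply_entry_criteria()] before returning.
#' @return A tibble with attribute `"truth"` (list of the truths used) and
#'   `"schedules"`.
#' @export
simulate_cohort <- function(n, seed = 1L,
                            maternal_truth = simulation_truth(default_schedule("maternal")),
                            paternal_truth = simulation_truth(default_schedule("paternal"),
                                                              lag_weights = lag_weight_scenario(default_schedule("paternal"), "null")),
                            outcome_truths = NULL,
                            apply_entry = TRUE) {
  set.seed(seed)
  mat_sched <- maternal_truth$schedule
  pat_sched <- paternal_truth$schedule
  cov <- simulate_covariates(n)
  xm <- simulate_exposures(n, mat_sched, maternal_truth)
  xp <- simulate_exposures(n, pat_sched, paternal_truth)

  if (is.null(outcome_truths)) outcome_truths <- default_outcome_truths(maternal_truth)
  # psychosis truth uses the schedule truncated at 11 y
  psy_truth <- outcome_truths$psychosis
  psy_cols <- schedule_columns(psy_truth$schedule)
  out <- tibble::as_tibble(cbind(tibble::tibble(id = seq_len(n)), cov,
                                 tibble::as_tibble(unclass(xm)[seq_len(n), , drop = FALSE]),
                                 tibble::as_tibble(unclass(xp)[seq_len(n), , drop = FALSE])))
  out$out_depression <- simulate_outcomes(xm, cov, outcome_truths$depression, "cumulative_logit")
  out$out_anxiety    <- simulate_outcomes(xm, cov, outcome_truths$anxiety, "cumulative_logit")
  out$out_audit      <- simulate_outcomes(xm, cov, outcome_truths$audit, "cumulative_logit")
  out$out_psychosis  <- simulate_outcomes(xm[, psy_cols, drop = FALSE], cov,
                                          psy_truth, "logit")
  out <- apply_missingness(out, maternal_truth)
  out <- apply_missingness(out, paternal_truth)
  if (apply_entry) out <- apply_entry_criteria(out)
  attr(out, "truth") <- list(maternal = maternal_truth, paternal = paternal_truth,
                             outcomes = outcome_truths)
  attr(out, "schedules") <- list(maternal = mat_sched, paternal = pat_sched)
  attr(out, "seed") <- seed
  out
}

#' Default per-outcome generating truths
#'
#' Depression, anxiety and AUDIT reuse the maternal truth's lag weights
#' with cumulative-logit cutpoints matched to plausible score
#' distributions; psychosis is binary (baseline prevalence ~12%) with the
#' maternal weights restricted to occasions at age <= 11 and rescaled so
#' its 13-vs-0 cumulative odds ratio is 1.90.
#'
#' @param maternal_truth A maternal [simulation_truth()].
#' @return Named list of truths.
#' @export
default_outcome_truths <- function(maternal_truth) {
  sched <- maternal_truth$schedule
  anx_probs <- stats::dnbinom(0:88, mu = 14, size = 2.2)
  aud_probs <- stats::dnbinom(0:40, mu = 5, size = 1.8)
  psy_sched <- truncate_schedule(sched, 11)
  keep <- sched$age <= 11
  w_psy <- maternal_truth$lag_weights[keep]
  if (sum(abs(w_psy)) > 0) w_psy <- w_psy * log(1.90) / (13 * sum(w_psy))
  list(
    depression = maternal_truth,
    anxiety = simulation_truth(sched, lag_weights = maternal_truth$lag_weights,
                               covariate_effects = maternal_truth$covariate_effects,
                               cutpoints = epds_outcome_cutpoints(anx_probs / sum(anx_probs)),
                               exposure_mean_curve = maternal_truth$exposure_mean_curve,
                               ar_rho = maternal_truth$ar_rho,
                               exposure_sd = maternal_truth$exposure_sd),
    audit = simulation_truth(sched, lag_weights = maternal_truth$lag_weights,
                             covariate_effects = maternal_truth$covariate_effects,
                             cutpoints = epds_outcome_cutpoints(aud_probs / sum(aud_probs)),
                             exposure_mean_curve = maternal_truth$exposure_mean_curve,
                             ar_rho = maternal_truth$ar_rho,
                             exposure_sd = maternal_truth$exposure_sd),
    psychosis = simulation_truth(psy_sched, lag_weights = w_psy,
                                 covariate_effects = maternal_truth$covariate_effects,
                                 cutpoints = NULL, intercept = stats::qlogis(0.12),
                                 exposure_mean_curve = maternal_truth$exposure_mean_curve[keep],
                                 ar_rho = maternal_truth$ar_rho,
                                 exposure_sd = maternal_truth$exposure_sd)
  )
}

#' Retrieve the generating truth stored on a synthetic cohort
#' @param cohort A tibble from [simulate_cohort()].
#' @return The truth list.
#' @export
cohort_truth <- function(cohort) attr(cohort, "truth")
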