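#' Analysis configuration
#'
#' A single structured object fully determining a pipeline run:
#' exclusion -> imputation -> per-(parent, outcome) penalized
#' distributed-lag fits on each imputation -> Rubin/D2 pooling ->
#' curves and tables.
#'
#' @param cohort Cohort source: `list(source = "synthetic", n =, scenario =,
#'   missingness = missingness_spec(...))` or `list(source = "csv", path =)`.
#' @param parents Parents to analyze (`"maternal"`, `"paternal"`).
#' @param outcomes Outcome cells; subset of `"depression"`, `"anxiety"`,
#'   `"psychosis"`, `"audit"`.
#' @param covariate_set `"primary"` (socioeconomic + demographic + PRS) or
#'   `"secondary"` (adds prenatal smoking, alcohol use, birth weight,
#'   gestational age).
#' @param basis `list(K =, degree =, penalty_order =)`.
#' @param lambda_rule,lambda,edf_target Smoothing-parameter control, see
#'   [model_spec()].
#' @param m Number of imputations when the cohort has missing exposure
#'   data.
#' @param contrast EPDS contrast level for AORs (default 13 vs 0).
#' @param truncation Named list of outcome -> maximum exposure age;
#'   default truncates the psychosis cell at 11 years (psychotic
#'   experiences are assessed from age 12).
#' @param moderators Covariate names whose interaction with the lag curve
#'   is Wald-tested and D2-pooled (e.g. `"sex"`, `"prs_mdd"`).
#' @param dlnm `NULL`, or an [exposure_basis_spec()] to add
#'   nonlinear-exposure (cross-basis) fits.
#' @param seed Integer seed covering cohort generation and imputation.
#' @param out_dir Optional directory for CSV/plot/manifest output.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(cohort = list(source = "synthetic", n = 2000,
                                          scenario = "flat",
                                          missingness = missingness_spec("none")),
                            parents = c("maternal", "paternal"),
                            outcomes = c("depression", "anxiety", "psychosis", "audit"),
                            covariate_set = c("primary", "secondary"),
                            basis = list(K = 15L, degree = 3L, penalty_order = 2L),
                            lambda_rule = "REML", lambda = 1, edf_target = NULL,
                            m = 20L, contrast = 13,
                            truncation = list(psychosis = 11),
                            moderators = character(0),
                            dlnm = NULL, seed = 1L, out_dir = NULL) {
  covariate_set <- match.arg(covariate_set)
  parents <- match.arg(parents, several.ok = TRUE)
  outcomes <- match.arg(outcomes,
                        c("depression", "anxiety", "psychosis", "audit"),
                        several.ok = TRUE)
  thresholds <- c(depression = 13, anxiety = 23, audit = 8)
  truncation <- truncation[intersect(names(truncation), outcomes)]
  structure(list(cohort = cohort, parents = parents, outcomes = outcomes,
                 covariate_set = covariate_set, basis = basis,
                 lambda_rule = lambda_rule, lambda = lambda,
                 edf_target = edf_target, m = as.integer(m),
                 contrast = contrast, thresholds = thresholds,
                 truncation = truncation, moderators = moderators,
                 dlnm = dlnm, seed = as.integer(seed), out_dir = out_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#' @param path YAML file with keys matching [analysis_config()] arguments.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$cohort$missingness)) {
    ms <- raw$cohort$missingness
    raw$cohort$missingness <- missingness_spec(ms$mechanism %||% "none",
                                               ms$rate %||% 0)
  }
  if (!is.null(raw$dlnm)) {
    raw$dlnm <- exposure_basis_spec(raw$dlnm$type %||% "bspline",
                                    raw$dlnm$K_e %||% 4L,
                                    raw$dlnm$degree %||% 2L)
  }
  do.call(analysis_config, raw)
}

primary_covariates <- function() {
  c("mat_age", "pat_age", "mat_education", "social_class", "parity",
    "crowding", "married", "sex", "prs_mdd", "prs_gad", "prs_panic",
    "prs_scz", "prs_bipolar", "prs_aud")
}
secondary_covariates <- function() {
  c(primary_covariates(), "mat_smoking", "mat_alcohol", "birth_weight",
    "gestational_age")
}

outcome_column <- function(outcome) paste0("out_", outcome)
outcome_type <- function(outcome) if (outcome == "psychosis") "binary" else "ordinal"

#' Validate a cohort table against the analysis schema
#'
#' Report-only checks: required columns present, EPDS exposures integer in
#' 0--30, outcome scores within their declared ranges (depression 0--30,
#' anxiety 0--88, AUDIT 0--40, psychosis 0/1), entry-criteria columns
#' usable.
#'
#' @param data Cohort tibble.
#' @param config An [analysis_config()] (decides which columns are
#'   required).
#' @return A tibble of issues (`type`, `column`, `row`, `message`); zero
#'   rows when the cohort is well formed.
#' @export
validate_cohort <- function(data, config = analysis_config()) {
  issues <- list()
  add <- function(type, column, row, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      type = type, column = column, row = row, message = message)
  }
  covs <- if (config$covariate_set == "secondary") secondary_covariates() else primary_covariates()
  required <- c(covs, unlist(lapply(config$parents, function(p)
    schedule_columns(default_schedule(p)))),
    outcome_column(config$outcomes))
  for (cl in required) {
    if (!cl %in% names(data)) add("missing_column", cl, NA_integer_,
                                  sprintf("required column '%s' absent", cl))
  }
  ranges <- list()
  for (p in config$parents) {
    for (cl in intersect(schedule_columns(default_schedule(p)), names(data)))
      ranges[[cl]] <- c(0, 30)
  }
  out_rng <- list(depression = c(0, 30), anxiety = c(0, 88),
                  audit = c(0, 40), psychosis = c(0, 1))
  for (o in config$outcomes) {
    cl <- outcome_column(o)
    if (cl %in% names(data)) ranges[[cl]] <- out_rng[[o]]
  }
  for (cl in names(ranges)) {
    v <- data[[cl]]
    bad <- which(!is.na(v) & (v < ranges[[cl]][1] | v > ranges[[cl]][2] |
                                v != round(v)))
    for (rw in bad) add("range_violation", cl, rw,
                        sprintf("value %s outside %g..%g integer range",
                                format(v[rw]), ranges[[cl]][1], ranges[[cl]][2]))
  }
  if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(type = character(), column = character(),
                   row = integer(), message = character())
}

#' Run the full distributed-lag analysis pipeline
#'
#' Executes, reproducibly from `config` (including its seed):
#' entry criteria and the >= 95%-missing exclusion rule; chained
#' random-forest multiple imputation of incomplete exposures (M sets);
#' per-imputation penalized DLM fits (proportional odds for score
#' outcomes, logistic for psychosis) for every configured
#' (parent, outcome) cell with outcome-specific schedule truncation;
#' Rubin pooling of the cumulative and per-occasion log-AORs; optional
#' moderation Wald tests pooled by D2 and cross-basis (DLNM) fits. A
#' failing cell is recorded with its diagnostic message without aborting
#' the other cells.
#'
#' @param config An [analysis_config()].
#' @return An `analysis_report`: list with tibbles `cumulative`, `curves`,
#'   `moderation`, list `dlnm` (per cell, when configured), `cells`
#'   (status per cell), and `manifest` (resolved config, seed, counts,
#'   timings). When `config$out_dir` is set the tables, plots and manifest
#'   are also written there.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  t0 <- Sys.time()
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  # --- cohort ------------------------------------------------------------
  if (identical(config$cohort$source, "synthetic")) {
    ms <- config$cohort$missingness %||% missingness_spec("none")
    msched <- default_schedule("maternal")
    psched <- default_schedule("paternal")
    mtruth <- simulation_truth(msched,
                               lag_weights = lag_weight_scenario(msched, config$cohort$scenario %||% "flat"),
                               missingness = ms)
    ptruth <- simulation_truth(psched,
                               lag_weights = lag_weight_scenario(psched, "null"),
                               missingness = ms)
    cohort <- simulate_cohort(config$cohort$n, seed = config$seed,
                              maternal_truth = mtruth, paternal_truth = ptruth)
    say("simulated cohort: n = %d after entry criteria", nrow(cohort))
  } else {
    cohort <- readr::read_csv(config$cohort$path, show_col_types = FALSE)
    cohort <- apply_entry_criteria(cohort)
    say("loaded cohort from %s: n = %d after entry criteria",
        config$cohort$path, nrow(cohort))
  }

  issues <- validate_cohort(cohort, config)
  if (nrow(issues)) {
    stop("cohort fails validation; first issue: ", issues$message[1], call. = FALSE)
  }

  covs <- if (config$covariate_set == "secondary") secondary_covariates() else primary_covariates()
  exp_cols <- unlist(lapply(config$parents, function(p)
    schedule_columns(default_schedule(p))))
  required <- c(exp_cols, outcome_column(config$outcomes))
  cohort <- exclusion_filter(cohort, required, threshold = 0.95)
  er <- exclusion_report(cohort)
  say("exclusion filter (>= 95%% missing of %d required columns): removed %d, retained %d",
      er$n_required_columns, er$n_excluded, er$n_retained)

  # --- imputation --------------------------------------------------------
  analysis_cols <- unique(c(exp_cols, covs, outcome_column(config$outcomes)))
  working <- cohort[analysis_cols]
  if (anyNA(working)) {
    iset <- rf_chained_impute(working, m = config$m, iterations = 2L,
                              seed = config$seed + 1L)
    say("random-forest chained imputation: M = %d, %d incomplete variables",
        iset$m, sum(iset$na_count > 0))
  } else {
    iset <- structure(list(imputations = list(working), m = 1L,
                           method = "complete_data", seed = config$seed,
                           iterations = 0L,
                           na_count = vapply(working, function(x) 0L, integer(1))),
                      class = "imputation_set")
    say("no missing cells in analysis columns; complete-data analysis (M = 1)")
  }

  # --- per-cell fits -----------------------------------------------------
  cum_rows <- list(); curve_rows <- list(); mod_rows <- list()
  dlnm_out <- list(); cell_rows <- list()
  for (parent in config$parents) {
    for (outc in config$outcomes) {
      cell <- paste(parent, outc, sep = ":")
      res <- tryCatch(
        run_cell(parent, outc, iset, config, say),
        error = function(e) e)
      if (inherits(res, "error")) {
        cell_rows[[cell]] <- tibble::tibble(parent = parent, outcome = outc,
                                            status = "failed",
                                            message = conditionMessage(res))
        say("cell %s FAILED: %s", cell, conditionMessage(res))
        next
      }
      cell_rows[[cell]] <- tibble::tibble(parent = parent, outcome = outc,
                                          status = "ok", message = "")
      cum_rows[[cell]] <- dplyr::mutate(res$cumulative, parent = parent,
                                        outcome = outc, .before = 1)
      curve_rows[[cell]] <- dplyr::mutate(res$curve, parent = parent,
                                          outcome = outc, .before = 1)
      if (!is.null(res$moderation)) {
        mod_rows[[cell]] <- dplyr::mutate(res$moderation, parent = parent,
                                          outcome = outc, .before = 1)
      }
      if (!is.null(res$dlnm)) dlnm_out[[cell]] <- res$dlnm
    }
  }

  report <- structure(list(
    cumulative = dplyr::bind_rows(cum_rows),
    curves = dplyr::bind_rows(curve_rows),
    moderation = if (length(mod_rows)) dplyr::bind_rows(mod_rows) else NULL,
    dlnm = if (length(dlnm_out)) dlnm_out else NULL,
    cells = dplyr::bind_rows(cell_rows),
    manifest = list(config = config, seed = config$seed,
                    n_cohort = nrow(cohort), m = iset$m, log = log,
                    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# One (parent, outcome) cell across all imputations.
run_cell <- function(parent, outc, iset, config, say = function(...) NULL) {
  sched <- default_schedule(parent)
  if (!is.null(config$truncation[[outc]])) {
    sched <- truncate_schedule(sched, config$truncation[[outc]])
  }
  basis <- pspline_basis(sched, K = config$basis$K %||% 15L,
                         degree = config$basis$degree %||% 3L,
                         penalty_order = config$basis$penalty_order %||% 2L)
  covs <- if (config$covariate_set == "secondary") secondary_covariates() else primary_covariates()
  ycol <- outcome_column(outc)
  type <- outcome_type(outc)
  cols <- schedule_columns(sched)

  fits <- vector("list", iset$m)
  curves <- vector("list", iset$m)
  cums <- vector("list", iset$m)
  mods <- list()
  lambda <- config$lambda
  for (im in seq_len(iset$m)) {
    dat <- iset$imputations[[im]]
    U <- dlm_design(as.matrix(dat[cols]), basis)
    Z <- as.matrix(dat[covs])
    y <- dat[[ycol]]
    rule <- if (im == 1L) config$lambda_rule else "fixed"
    spec <- model_spec(type, lambda_rule = rule, lambda = lambda,
                       edf_target = config$edf_target)
    fit <- if (type == "binary") {
      fit_penalized_logistic(U, Z, y, basis$P, spec)
    } else {
      fit_proportional_odds(U, Z, y, basis$P, spec)
    }
    lambda <- fit$lambda          # selected on imputation 1, reused after
    fits[[im]] <- fit
    curves[[im]] <- time_response(fit, basis, config$contrast)
    cums[[im]] <- cumulative_effect(fit, basis, config$contrast)

    for (mod in config$moderators) {
      z <- dat[[mod]]
      zc <- z - mean(z)
      # deviation curve gets its own modest basis: an unpenalized block of
      # the full dimension would be rank-deficient (K can exceed the
      # number of occasions) and moderation is a low-df question
      K_dev <- min(6L, config$basis$K %||% 15L, nrow(sched) - 1L)
      basis_dev <- pspline_basis(sched, K = max(K_dev, 4L))
      Udev <- dlm_design(as.matrix(dat[cols]), basis_dev) * zc
      colnames(Udev) <- paste0("dev_", colnames(Udev))
      Zi <- cbind(Z, Udev)        # deviation block unpenalized
      fit_i <- if (type == "binary") {
        fit_penalized_logistic(U, Zi, y, basis$P,
                               model_spec(type, "fixed", lambda = lambda))
      } else {
        fit_proportional_odds(U, Zi, y, basis$P,
                              model_spec(type, "fixed", lambda = lambda))
      }
      wt <- moderation_wald(fit_i, colnames(Udev))
      mods[[mod]] <- c(mods[[mod]], list(wt))
    }
  }
  say("cell %s:%s fitted on %d imputation(s), lambda = %s, edf = %.2f",
      parent, outc, iset$m, paste(signif(fits[[1]]$lambda, 3), collapse = ","),
      fits[[1]]$edf)

  moderation <- NULL
  if (length(config$moderators)) {
    moderation <- dplyr::bind_rows(lapply(names(mods), function(mod) {
      stats <- vapply(mods[[mod]], function(w) w$chi2, numeric(1))
      k <- mods[[mod]][[1]]$df
      dplyr::mutate(d2_pool(stats, k), moderator = mod, .before = 1)
    }))
  }

  dl <- NULL
  if (!is.null(config$dlnm)) {
    dat <- iset$imputations[[1]]
    cb <- crossbasis_design(as.matrix(dat[cols]), basis, config$dlnm)
    spec <- model_spec(type, lambda_rule = config$lambda_rule,
                       lambda = config$lambda, edf_target = config$edf_target)
    fit_cb <- if (type == "binary") {
      fit_penalized_logistic(cb$design, as.matrix(dat[covs]), dat[[ycol]],
                             cb$penalties, spec)
    } else {
      fit_proportional_odds(cb$design, as.matrix(dat[covs]), dat[[ycol]],
                            cb$penalties, spec)
    }
    dl <- dlnm_surface(fit_cb, cb)
  }

  list(curve = pool_time_response(curves),
       cumulative = pool_cumulative_effect(cums),
       moderation = moderation, dlnm = dl, schedule = sched)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$cumulative, file.path(out_dir, "cumulative_effects.csv"))
  readr::write_csv(report$curves, file.path(out_dir, "time_response_curves.csv"))
  if (!is.null(report$moderation)) {
    readr::write_csv(report$moderation, file.path(out_dir, "moderation_tests.csv"))
  }
  readr::write_csv(report$cells, file.path(out_dir, "cells.csv"))
  man <- report$manifest
  man$config <- unclass_deep(man$config)
  yaml::write_yaml(man, file.path(out_dir, "manifest.yaml"))
  for (i in seq_len(nrow(report$cells))) {
    if (report$cells$status[i] != "ok") next
    p <- report$cells$parent[i]; o <- report$cells$outcome[i]
    cv <- dplyr::filter(report$curves, .data$parent == p, .data$outcome == o)
    class(cv) <- c("time_response_curve", class(tibble::tibble()))
    plot_time_response(cv, file.path(out_dir, sprintf("curve_%s_%s.png", p, o)))
  }
  invisible(out_dir)
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  if (is.function(x)) return(NULL)
  unclass(x)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report: %d cell(s), M = %d, n = %d>\n",
              nrow(x$cells), x$manifest$m, x$manifest$n_cohort))
  print(x$cumulative)
  invisible(x)
}
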