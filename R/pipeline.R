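# One-call orchestration of the full analysis:
#   grid -> select m -> robust r band -> select (tau, r) -> biomarkers ->
#   features -> tune sigma -> N-fold cross-validation (+ optional holdout),
# with every warning captured in a machine-readable run record.

#' Run the full optimized-MSE pipeline
#'
#' Accepts either a loaded [study_cohort()] or a path to a manifest CSV.
#' All stages are deterministic given the cohort, the grids and `seed`.
#'
#' @param cohort A `study_cohort`, or a manifest path for [read_manifest()].
#' @param m,r,tau Parameter grids (defaults: m 1..2, r 0.05..0.60 step
#'   0.05, tau 1..6).
#' @param alpha Significance level for region tests (default 0.05).
#' @param min_regions Robust-band threshold (see [robust_r_band()]).
#' @param sigma_grid Smoothing-factor candidates (default 0.1..2 step 0.1).
#' @param n_folds Cross-validation folds N (default 10).
#' @param holdout Optional named test-set sizes per class for an
#'   additional stratified holdout evaluation, e.g. `c("0" = 9, "1" = 11)`;
#'   `NULL` (default) skips it.
#' @param seed Seed for every random stage (sigma tuning folds, CV folds,
#'   holdout draw).
#' @param out_dir Optional directory; when given, the grid, selection
#'   trace, biomarker table, feature matrix and run record are written
#'   there as TSV/JSON.
#' @return An `mse_run` record: list with `params`, `biomarkers`,
#'   `features`, `sigma`, `cv`, optional `holdout`, `config`, `warnings`.
#' @export
run_pipeline <- function(cohort, m = 1:2, r = seq(0.05, 0.60, by = 0.05),
                         tau = 1:6, alpha = 0.05, min_regions = 1,
                         sigma_grid = seq(0.1, 2, by = 0.1), n_folds = 10,
                         holdout = NULL, seed = 1, out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_manifest(cohort)
  stopifnot(inherits(cohort, "study_cohort"))
  warnings_seen <- character(0)
  catch <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        abort(paste0("stage ", stage, ": ", conditionMessage(e)))),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen,
                            paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  grid <- catch("entropy_grid", entropy_grid(cohort, m = m, r = r, tau = tau))
  params <- catch("optimize_params",
                  optimize_params(grid, alpha = alpha,
                                  min_regions = min_regions))
  biomarkers <- catch("select_biomarkers",
                      select_biomarkers(grid, params, alpha = alpha))
  features <- catch("build_features",
                    build_features(cohort, params, biomarkers))
  sigma <- catch("tune_sigma",
                 tune_sigma(features, sigma_grid, seed = seed))
  cv <- catch("cross_validate",
              cross_validate(features, n_folds = n_folds, sigma = sigma,
                             seed = seed))
  hold <- NULL
  if (!is.null(holdout)) {
    hold <- catch("holdout", {
      split <- holdout_split(features, holdout, seed = seed)
      model <- pnn(split$train, sigma = sigma)
      pred <- predict(model, split$test)
      list(n_train = nrow(split$train), n_test = nrow(split$test),
           accuracy = 100 * mean(pred$.pred_class == split$test$group))
    })
  }

  record <- list(
    version = as.character(utils::packageVersion("entroscan")),
    config = list(m = m, r = r, tau = tau, alpha = alpha,
                  min_regions = min_regions, sigma_grid = sigma_grid,
                  n_folds = n_folds, holdout = holdout, seed = seed,
                  n_subjects = nrow(cohort),
                  n_regions = length(region_labels(cohort)),
                  n_timepoints = attr(cohort, "n_timepoints")),
    params = list(m = params$m, r = params$r, tau = params$tau,
                  band = params$selection_trace$band),
    biomarkers = as_tibble(biomarkers),
    features = features,
    sigma = as.numeric(sigma),
    cv = cv,
    holdout = hold,
    warnings = warnings_seen,
    grid = grid,
    params_full = params)
  class(record) <- "mse_run"

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_report(as_tibble(grid), file.path(out_dir, "grid.tsv"))
    write_report(list(m = params$m, r = params$r, tau = params$tau,
                      band = params$selection_trace$band,
                      scores = params$selection_trace$scores),
                 file.path(out_dir, "selection_trace.json"))
    write_report(as_tibble(biomarkers), file.path(out_dir, "biomarkers.tsv"))
    write_report(as_tibble(features), file.path(out_dir, "features.tsv"))
    write_report(list(version = record$version, config = record$config,
                      params = record$params, sigma = record$sigma,
                      cv = list(fold_accuracies = cv$accuracy,
                                mean = attr(cv, "mean"),
                                std = attr(cv, "std"),
                                n_folds = attr(cv, "n_folds"),
                                seed = attr(cv, "seed")),
                      holdout = hold, warnings = warnings_seen),
                 file.path(out_dir, "run_record.json"))
  }
  record
}

#' @export
print.mse_run <- function(x, ...) {
  cat("<mse_run> ", x$config$n_subjects, " subjects, ",
      x$config$n_regions, " regions\n",
      "  optimal params: m = ", x$params$m, ", r = ", format(x$params$r),
      ", tau = ", x$params$tau, "\n",
      "  biomarkers (", nrow(x$biomarkers), "): ",
      paste(head(x$biomarkers$region, 9), collapse = ", "), "\n",
      "  sigma = ", format(x$sigma), "; ", attr(x$cv, "n_folds"),
      "-fold CV accuracy ", sprintf("%.2f%% +/- %.2f%%",
                                    attr(x$cv, "mean"), attr(x$cv, "std")),
      if (!is.null(x$holdout))
        sprintf("; holdout accuracy %.2f%%", x$holdout$accuracy) else "",
      "\n", sep = "")
  if (length(x$warnings))
    cat("  warnings: ", length(x$warnings), " (see $warnings)\n", sep = "")
  invisible(x)
}

#' @method glance mse_run
#' @export
glance.mse_run <- function(x, ...) {
  tibble(m = x$params$m, r = x$params$r, tau = x$params$tau,
         n_biomarkers = nrow(x$biomarkers), sigma = x$sigma,
         cv_mean_accuracy = attr(x$cv, "mean"),
         cv_std_accuracy = attr(x$cv, "std"),
         holdout_accuracy = if (is.null(x$holdout)) NA_real_
                            else x$holdout$accuracy)
}
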