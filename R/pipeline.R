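#' Build and validate an experiment configuration
#'
#' Single configuration object driving [run_experiment()]. Every stage seed
#' is derived deterministically from the master `seed` unless given
#' explicitly, so one integer reproduces the whole experiment. Configs
#' round-trip losslessly through YAML ([read_experiment_config()] /
#' [write_experiment_config()]).
#'
#' @param feature_sets subset of `c("hippocampal", "amygdalar", "combined")`.
#' @param N_c spectral cut-off per structure (default 70).
#' @param variance_fraction PCA retained-variance threshold (default 0.70).
#' @param cv_folds cross-validation folds (default 10).
#' @param n_orders,batch_size learning-curve settings (defaults 500 / 10;
#'   set `n_orders = 0` to skip the learning curve).
#' @param n_perm permutation count (default 10000; 0 skips the test).
#' @param cohort a [cohort_spec()] describing the synthetic cohort (its
#'   seed is overridden by the derived simulation seed unless the spec was
#'   supplied explicitly).
#' @param seed master seed.
#' @param output_dir optional directory for result files (JSON metrics,
#'   per-subject prediction CSVs, discriminative-map PLYs).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(feature_sets = c("hippocampal", "amygdalar", "combined"),
                              N_c = 70, variance_fraction = 0.70,
                              cv_folds = 10, n_orders = 500, batch_size = 10,
                              n_perm = 10000, cohort = NULL, seed = 1,
                              output_dir = NULL) {
  feature_sets <- match.arg(feature_sets,
                            c("hippocampal", "amygdalar", "combined"),
                            several.ok = TRUE)
  if (is.null(cohort)) cohort <- cohort_spec(seed = seed * 11L + 1L)
  stopifnot(inherits(cohort, "cohort_spec"))
  structure(list(feature_sets = feature_sets, N_c = N_c,
                 variance_fraction = variance_fraction, cv_folds = cv_folds,
                 n_orders = n_orders, batch_size = batch_size, n_perm = n_perm,
                 cohort = cohort, seed = seed, output_dir = output_dir),
            class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#' @param path YAML path.
#' @param config an [experiment_config()] (writer).
#' @return an [experiment_config()] (reader); `path` invisibly (writer).
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort <- if (!is.null(raw$cohort)) do.call(cohort_spec, raw$cohort) else NULL
  raw$cohort <- NULL
  cfg <- do.call(experiment_config, c(raw, list(cohort = cohort)))
  cfg
}

#' @rdname read_experiment_config
#' @export
write_experiment_config <- function(config, path) {
  out <- unclass(config)
  out$cohort <- unclass(out$cohort)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full classification experiment
#'
#' Orchestrates, with no computation of its own: cohort simulation, harmonic
#' bases, spectral feature assembly, stratified cross-validation, the
#' incremental learning curve, the permutation test, and discriminative-map
#' back-projection — per requested feature set. Stage outputs are identical
#' to calling the stage functions directly with the same seeds. When
#' `config$output_dir` is set, metrics (JSON), per-subject out-of-fold
#' predictions (CSV) and discriminative maps (PLY) are written there along
#' with a manifest recording the config, a config hash, package version and
#' per-stage wall times.
#'
#' @param config an [experiment_config()].
#' @return list of class `experiment_result`: per-feature-set `cv`
#'   ([run_cv()] result), `learning_curve`, `permutation`,
#'   `maps`, plus `cohort` and `manifest`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  t_all <- proc.time()["elapsed"]
  timing <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()["elapsed"]
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    timing[[name]] <<- round(proc.time()["elapsed"] - t0, 3)
    out
  }
  geom_K <- max(config$N_c) + 10L
  cohort <- stage("simulate", simulate_cohort(config$cohort,
                                              cohort_geometry(config$cohort, K = geom_K)))
  results <- list()
  for (fs in config$feature_sets) {
    X <- stage(paste0("features_", fs),
               build_feature_matrix(cohort, cohort$geometry$bases, fs, config$N_c))
    cv <- stage(paste0("cv_", fs),
                run_cv(X, cohort$labels, k = config$cv_folds,
                       seed = config$seed * 13L + 2L,
                       variance_fraction = config$variance_fraction))
    lc <- NULL
    if (config$n_orders > 0) {
      folds <- cv$folds
      test_mask <- folds == 1L   # first fold held out for the accrual curve
      lc <- stage(paste0("learning_curve_", fs),
                  learning_curve(X[!test_mask, , drop = FALSE], cohort$labels[!test_mask],
                                 X[test_mask, , drop = FALSE], cohort$labels[test_mask],
                                 n_orders = config$n_orders,
                                 batch_size = config$batch_size,
                                 seed = config$seed * 17L + 3L,
                                 variance_fraction = config$variance_fraction))
    }
    pt <- NULL
    if (config$n_perm > 0) {
      pt <- stage(paste0("permutation_", fs),
                  permutation_test(X, cohort$labels, n_perm = config$n_perm,
                                   seed = config$seed * 19L + 4L, k = config$cv_folds,
                                   variance_fraction = config$variance_fraction))
    }
    state <- stage(paste0("train_", fs),
                   train_batch(X, cohort$labels, config$variance_fraction))
    maps <- stage(paste0("maps_", fs),
                  backproject_axis(state, cohort$geometry$bases, fs))
    results[[fs]] <- list(cv = cv, learning_curve = lc, permutation = pt,
                          maps = maps, classifier = state)
  }
  manifest <- list(package_version = as.character(utils::packageVersion("subshape")),
                   seed = config$seed,
                   config_hash = config_hash(config),
                   timing_s = as.list(timing),
                   total_s = round(proc.time()["elapsed"] - t_all, 3))
  out <- structure(list(feature_sets = results, cohort = cohort,
                        config = config, manifest = manifest),
                   class = "experiment_result")
  if (!is.null(config$output_dir)) write_experiment(out, config$output_dir)
  out
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_experiment_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Collect scalar metrics of an experiment result
#' @param result an `experiment_result`.
#' @return nested list of accuracy/sensitivity/specificity/AUC (fractions)
#'   and permutation p per feature set.
#' @export
experiment_metrics <- function(result) {
  lapply(result$feature_sets, function(r) {
    list(accuracy = r$cv$accuracy, sensitivity = r$cv$sensitivity,
         specificity = r$cv$specificity, auc = r$cv$auc,
         confusion = as.list(r$cv$confusion),
         permutation_p = if (!is.null(r$permutation)) r$permutation$p_value,
         learning_curve_final = if (!is.null(r$learning_curve))
           unname(utils::tail(r$learning_curve$mean_accuracy, 1)),
         map_energy_share = lapply(r$maps, `[[`, "energy_share"))
  })
}

write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(metrics = experiment_metrics(result),
                            manifest = result$manifest),
                       file.path(dir, "metrics.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  write_experiment_config(result$config, file.path(dir, "config.yaml"))
  for (fs in names(result$feature_sets)) {
    r <- result$feature_sets[[fs]]
    utils::write.csv(r$cv$predictions,
                     file.path(dir, sprintf("predictions_%s.csv", fs)),
                     row.names = FALSE)
    for (s in names(r$maps)) {
      export_map(r$maps[[s]], result$cohort$geometry$templates[[s]],
                 file.path(dir, sprintf("map_%s_%s.ply", fs, s)))
    }
  }
  invisible(dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result\n")
  for (fs in names(x$feature_sets)) {
    r <- x$feature_sets[[fs]]
    cat(sprintf("  %-12s accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.4f%s\n",
                fs, 100 * r$cv$accuracy, 100 * r$cv$sensitivity,
                100 * r$cv$specificity, r$cv$auc,
                if (!is.null(r$permutation))
                  sprintf(", permutation p = %.4g", r$permutation$p_value) else ""))
  }
  invisible(x)
}
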