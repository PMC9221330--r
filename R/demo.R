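# End-to-end synthetic study: simulate the 14-subject cohort, preprocess,
# fuse features, screen, train and cross-validate, and write report files.

#' Run the full synthetic study end to end
#'
#' Simulates a 14-subject cohort driven by the packaged difficulty table,
#' executes preprocessing and feature fusion, writes the fused matrix, the
#' difficulty-association report and classification reports (k-fold CV of the
#' four base members and the fused model, before and after feature selection),
#' and prints the per-behavior mean-difficulty check.
#'
#' @param seed run seed.
#' @param out_dir writable output directory.
#' @param n_subjects cohort size (default 14).
#' @param k folds for the CV report.
#' @param loo also run leave-one-subject-out CV (slower).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the feature matrix, association report and
#'   evaluation reports.
#' @export
run_demo <- function(seed = 1L, out_dir = tempfile("physiofuse_demo"),
                     n_subjects = 14, k = 10, loo = FALSE, quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  cfg <- pf_config(random_seed = seed)
  t0 <- Sys.time()

  say("[1/5] simulating %d subjects ...", n_subjects)
  plan <- sim_plan(n_subjects = n_subjects, seed = seed)
  sets <- simulate_cohort(plan)

  say("[2/5] preprocessing + feature fusion ...")
  fm <- cohort_features(sets, cfg)
  write_feature_matrix(fm, file.path(out_dir, "features.tsv"))

  say("[3/5] screening ...")
  tab <- load_difficulty_fixture()
  means <- mean_difficulty(tab)
  say("per-behavior mean difficulty: %s",
      paste(sprintf("%s=%.2f", names(means), means), collapse = " "))
  assoc <- if (n_subjects == nrow(tab)) difficulty_association(fm, tab) else NULL
  sel <- select_features(fm, mode = "paper")
  say("features: %d fused, %d after selection",
      length(feature_names()), length(sel$names))

  say("[4/5] %d-fold cross-validation (all features and selected) ...", k)
  specs <- default_classifier_specs(seed = seed)
  ev_all <- kfold_cv(fm, specs, selected = feature_names(), k = k, seed = seed)
  ev_sel <- kfold_cv(fm, specs, selected = sel$names, k = k, seed = seed)
  ev_loo <- if (loo) loo_subject_cv(fm, specs, selected = sel$names) else NULL

  say("[5/5] writing reports ...")
  fmt_eval <- function(ev) {
    lapply(ev$reports, function(r) {
      list(scheme = r$scheme, mean_accuracy = r$mean_accuracy,
           lowest_accuracy = r$lowest_accuracy, mse = r$mse,
           per_class = r$per_class, confusion = r$confusion)
    })
  }
  summary <- list(
    seed = seed, n_subjects = n_subjects,
    config_hash = config_hash(cfg),
    mean_difficulty = as.list(means),
    n_features_fused = length(feature_names()),
    n_features_selected = length(sel$names),
    association = if (!is.null(assoc)) assoc$pooled else NULL,
    cv_all_features = fmt_eval(ev_all),
    cv_selected_features = fmt_eval(ev_sel),
    loo_selected_features = if (!is.null(ev_loo)) fmt_eval(ev_loo) else NULL,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  acc <- vapply(ev_sel$reports, function(r) r$mean_accuracy, numeric(1))
  say("k-fold mean accuracy (selected features): %s",
      paste(sprintf("%s=%.3f", names(acc), acc), collapse = " "))
  invisible(list(features = fm, association = assoc, cv_all = ev_all,
                 cv_selected = ev_sel, loo = ev_loo, out_dir = out_dir))
}
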