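# Evaluation: stratified 10-fold CV, leave-one-subject-out CV, per-class
# precision/recall/F1, accuracy, label-code MSE, confusion matrices. One CV
# run fits the four base members once per fold and reports them alongside the
# fused model. Note the protocol being reproduced allows windows of the same
# subject in both train and test folds under k-fold CV; the subject-wise
# scheme is the leakage-free counterpart.

#' Per-class precision / recall / F1 and accuracy
#'
#' Standard definitions; a zero denominator yields 0 with a warning.
#'
#' @param y_true,y_pred equal-length character vectors of behavior labels.
#' @return list with `per_class` (data.frame), `accuracy`, `confusion`
#'   (true x predicted counts over all six labels).
#' @export
classification_report <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  labels <- behavior_labels()
  cm <- table(factor(y_true, levels = labels),
              factor(y_pred, levels = labels))
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  zero <- predicted == 0 | support == 0
  if (any(zero[support > 0 | predicted > 0])) {
    warning("zero division in precision/recall; reporting 0")
  }
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(per_class = data.frame(label = labels, precision = as.numeric(precision),
                              recall = as.numeric(recall), f1 = as.numeric(f1),
                              support = as.numeric(support),
                              stringsAsFactors = FALSE),
       accuracy = sum(tp) / sum(cm),
       confusion = unclass(cm))
}

#' Mean squared error over integer label codes
#'
#' Labels are encoded 0-5 in the fixed behavior order; the statistic is the
#' mean squared code difference (order-sensitive by construction; see
#' vignette).
#'
#' @param y_true,y_pred character vectors of behavior labels.
#' @param codebook optional named integer vector overriding the default
#'   behavior-order codes.
#' @return scalar MSE.
#' @export
label_mse <- function(y_true, y_pred, codebook = NULL) {
  if (is.null(codebook)) {
    ct <- behavior_code(y_true)
    cp <- behavior_code(y_pred)
  } else {
    ct <- codebook[y_true]
    cp <- codebook[y_pred]
  }
  mean((ct - cp)^2)
}

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

eval_from_preds <- function(y_true, y_pred, fold, scheme) {
  rep_ <- classification_report(y_true, y_pred)
  fold_acc <- vapply(sort(unique(fold)), function(f) {
    mean(y_pred[fold == f] == y_true[fold == f])
  }, numeric(1))
  list(scheme = scheme, per_class = rep_$per_class,
       mean_accuracy = mean(fold_acc), lowest_accuracy = min(fold_acc),
       pooled_accuracy = rep_$accuracy,
       mse = label_mse(y_true, y_pred), confusion = rep_$confusion,
       fold_accuracy = fold_acc)
}

run_cv <- function(df, selected, specs, fold, scheme) {
  y_true <- df$label
  model_names <- c(vapply(specs, function(s) s$name, character(1)), "ensemble")
  preds <- matrix(NA_character_, nrow(df), length(model_names),
                  dimnames = list(NULL, model_names))
  for (f in sort(unique(fold))) {
    tr <- df[fold != f, , drop = FALSE]
    te <- df[fold == f, , drop = FALSE]
    if (length(unique(tr$label)) < 2) stop("degenerate labels in training fold")
    model <- fit_ensemble(tr, specs = specs, selected = selected)
    p <- predict(model, te)
    preds[fold == f, "ensemble"] <- p$label
    for (nm in names(model$models)) {
      preds[fold == f, nm] <- p$base_labels[, nm]
    }
  }
  reports <- lapply(model_names, function(nm) {
    eval_from_preds(y_true, preds[, nm], fold, scheme)
  })
  names(reports) <- model_names
  structure(list(scheme = scheme, reports = reports, n = nrow(df)),
            class = "pf_eval")
}

#' Stratified k-fold cross-validation of the ensemble and its members
#'
#' Folds are stratified by class and shuffled with `seed`; out-of-fold
#' predictions are pooled for the confusion matrix, and mean / minimum
#' per-fold accuracy are reported.
#'
#' @param fm a `pf_feature_matrix` or data.frame with feature columns and
#'   `label`.
#' @param specs base member specifications.
#' @param selected feature subset to train on.
#' @param k number of folds (default 10).
#' @param seed fold-shuffling seed.
#' @return object of class `pf_eval`: per-model reports (the four members and
#'   `"ensemble"`), each with per-class metrics, accuracies, MSE and the
#'   pooled confusion matrix.
#' @export
kfold_cv <- function(fm, specs = default_classifier_specs(),
                     selected = selected_feature_names(), k = 10, seed = 1L) {
  df <- if (inherits(fm, "pf_feature_matrix")) {
    complete_rows(fm, selected)
  } else {
    fm[stats::complete.cases(fm[, selected, drop = FALSE]), , drop = FALSE]
  }
  if (k > nrow(df)) stop("k exceeds the number of rows")
  fold <- stratified_folds(df$label, k, seed)
  run_cv(df, selected, specs, fold, sprintf("kfold%d", k))
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: train on all other subjects, test on the held-out
#' one; reports the mean accuracy across subject folds and the pooled MSE.
#' A held-out subject carrying a single class is kept, with a warning.
#'
#' @inheritParams kfold_cv
#' @return a `pf_eval` (scheme `"loo_subject"`), with `fold_accuracy` ordered
#'   by subject.
#' @export
loo_subject_cv <- function(fm, specs = default_classifier_specs(),
                           selected = selected_feature_names()) {
  df <- if (inherits(fm, "pf_feature_matrix")) {
    complete_rows(fm, selected)
  } else {
    fm[stats::complete.cases(fm[, selected, drop = FALSE]), , drop = FALSE]
  }
  subjects <- unique(df$subject)
  if (length(subjects) < 2) stop("need at least 2 subjects")
  fold <- match(df$subject, subjects)
  single <- vapply(subjects, function(s) {
    length(unique(df$label[df$subject == s])) == 1
  }, logical(1))
  if (any(single)) {
    warning("subject(s) with a single class kept: ",
            paste(subjects[single], collapse = ", "))
  }
  out <- run_cv(df, selected, specs, fold, "loo_subject")
  for (nm in names(out$reports)) {
    names(out$reports[[nm]]$fold_accuracy) <- subjects
  }
  out
}
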