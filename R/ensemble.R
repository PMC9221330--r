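# Decision-layer fusion: each base classifier votes for its argmax class,
# weighted by the confidence it assigns to that class (its maximum class
# probability); the ensemble returns the class with the largest summed
# confidence.

#' Probabilistic prediction of one classifier for one window
#'
#' @param probs named numeric vector over behavior labels, summing to 1.
#' @return object of class `pf_prediction` with `probs`, `predicted` (argmax
#'   label) and `confidence` (max probability).
#' @export
probabilistic_prediction <- function(probs) {
  stopifnot(abs(sum(probs) - 1) < 1e-9, !is.null(names(probs)))
  i <- which.max(probs)
  structure(list(probs = probs, predicted = names(probs)[i],
                 confidence = unname(probs[i])),
            class = "pf_prediction")
}

#' Confidence-weighted vote over base predictions
#'
#' For each label L, `g(L)` is the sum of the confidences of the classifiers
#' whose predicted label is L (0 if no voter); the winner is `argmax g`, ties
#' broken by the lowest label code (a tie event is recorded in
#' `attr(res, "tie")`).
#'
#' @param predictions list of [probabilistic_prediction()]s over a shared
#'   label set.
#' @return list with `label` (winner) and `g` (named score map).
#' @export
weighted_vote <- function(predictions) {
  stopifnot(length(predictions) >= 1)
  labels <- names(predictions[[1]]$probs)
  for (p in predictions) {
    if (!identical(names(p$probs), labels)) stop("label mismatch")
  }
  g <- setNames(numeric(length(labels)), labels)
  for (p in predictions) {
    g[p$predicted] <- g[p$predicted] + p$confidence
  }
  top <- which(g == max(g))
  tie <- length(top) > 1
  winner <- labels[min(top)]  # labels are ordered by code
  res <- list(label = winner, g = g)
  attr(res, "tie") <- tie
  res
}

#' Fit the voting ensemble
#'
#' Fits each base member independently on the identical rows (the complete
#' cases of the selected features), deterministically given the member seeds.
#'
#' @param fm a `pf_feature_matrix` or a data.frame with feature columns plus
#'   `label`.
#' @param specs list of [base_classifier_spec()]s (default the four members).
#' @param selected character vector of feature names to train on.
#' @return object of class `pf_ensemble`.
#' @export
fit_ensemble <- function(fm, specs = default_classifier_specs(),
                         selected = selected_feature_names()) {
  df <- if (inherits(fm, "pf_feature_matrix")) as.data.frame(fm) else fm
  if (nrow(df) == 0) stop("empty matrix")
  missing_f <- setdiff(selected, names(df))
  if (length(missing_f) > 0) {
    stop("unknown feature: ", paste(missing_f, collapse = ", "))
  }
  df <- df[stats::complete.cases(df[, selected, drop = FALSE]), , drop = FALSE]
  if (nrow(df) == 0) stop("empty matrix")
  if (length(unique(df$label)) < 2) stop("degenerate labels")
  X <- as.matrix(df[, selected, drop = FALSE])
  y <- behavior_code(df$label)
  models <- lapply(specs, function(sp) {
    fit_base_classifier(sp, X, y, n_classes = 6L)
  })
  names(models) <- vapply(specs, function(s) s$name, character(1))
  structure(list(models = models, selected = selected,
                 labels = behavior_labels(),
                 specs = specs),
            class = "pf_ensemble")
}

#' Predict with the ensemble
#'
#' Returns per row the base members' probabilistic predictions, the score map
#' `g`, and the fused label; full transparency output for evaluation.
#'
#' @param object a `pf_ensemble`.
#' @param newdata data.frame or matrix carrying the model's feature columns.
#' @param soft use full soft voting (argmax of the summed per-class
#'   probabilities) instead of the default confidence-weighted argmax votes;
#'   provided for comparison only.
#' @param ... unused.
#' @return list with `label` (character vector), `g` (matrix rows x labels),
#'   `base_probs` (list of per-member probability matrices), `base_labels`
#'   (matrix of per-member argmax labels), `ties` (logical vector).
#' @export
predict.pf_ensemble <- function(object, newdata, soft = FALSE, ...) {
  df <- if (inherits(newdata, "pf_feature_matrix")) as.data.frame(newdata) else newdata
  missing_f <- setdiff(object$selected, colnames(df))
  if (length(missing_f) > 0) {
    stop("schema mismatch: missing ", paste(missing_f, collapse = ", "))
  }
  X <- as.matrix(as.data.frame(df)[, object$selected, drop = FALSE])
  base_probs <- lapply(object$models, function(m) predict_proba(m, X))
  n <- nrow(X)
  labels <- object$labels
  g <- matrix(0, n, length(labels), dimnames = list(NULL, labels))
  base_labels <- matrix(NA_character_, n, length(object$models),
                        dimnames = list(NULL, names(object$models)))
  out_label <- character(n)
  ties <- logical(n)
  for (i in seq_len(n)) {
    preds <- lapply(base_probs, function(P) {
      probabilistic_prediction(setNames(P[i, ], labels))
    })
    if (soft) {
      gs <- Reduce(`+`, lapply(preds, function(p) p$probs))
      out_label[i] <- labels[which.max(gs)]
      g[i, ] <- gs
      ties[i] <- sum(gs == max(gs)) > 1
    } else {
      v <- weighted_vote(preds)
      out_label[i] <- v$label
      g[i, ] <- v$g
      ties[i] <- attr(v, "tie")
    }
    base_labels[i, ] <- vapply(preds, function(p) p$predicted, character(1))
  }
  list(label = out_label, g = g, base_probs = base_probs,
       base_labels = base_labels, ties = ties)
}

#' Feature importance report across the ensemble
#'
#' @param model a `pf_ensemble`.
#' @return object of class `pf_importance_report`: `per_member` (matrix
#'   members x features, rows summing to 1) and `aggregate_rank` (mean rank,
#'   1 = most important).
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "pf_ensemble"))
  per <- t(vapply(model$models, importances,
                  numeric(length(model$selected))))
  colnames(per) <- model$selected
  ranks <- t(apply(-per, 1, rank, ties.method = "average"))
  agg <- colMeans(ranks)
  structure(list(per_member = per, aggregate_rank = sort(agg)),
            class = "pf_importance_report")
}
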