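# The four tree-based base classifiers behind a uniform contract
# (fit / predict_proba / importances), built on the native Rcpp tree kernel:
#   DTC  - single exhaustive CART (Gini)
#   ETC  - extremely randomized trees (random thresholds, sqrt-mtry, no
#          bootstrap, probability averaging)
#   GBC  - multinomial gradient boosting (first-order, shallow trees,
#          shrinkage 0.1)
#   XGBC - second-order Newton boosting (hessian-weighted trees, L2-regularized
#          leaf values), the "enhanced" boosting flavour
# Hyperparameters mirror the common library defaults and are pinned in the
# spec object for reproducibility.

#' Base classifier specification
#'
#' @param name one of `"ETC"`, `"DTC"`, `"GBC"`, `"XGBC"`.
#' @param seed RNG seed for this member.
#' @param ... hyperparameter overrides (`n_trees`, `max_depth`, `min_split`,
#'   `learning_rate`, `lambda`, `mtry`).
#' @return object of class `pf_classifier_spec`.
#' @export
base_classifier_spec <- function(name = c("ETC", "DTC", "GBC", "XGBC"),
                                 seed = 1L, ...) {
  name <- match.arg(name)
  hp <- switch(name,
    DTC = list(max_depth = 30L, min_split = 2L),
    ETC = list(n_trees = 100L, max_depth = 30L, min_split = 2L, mtry = NA),
    GBC = list(n_trees = 100L, max_depth = 3L, min_split = 2L,
               learning_rate = 0.1),
    XGBC = list(n_trees = 100L, max_depth = 6L, min_split = 2L,
                learning_rate = 0.3, lambda = 1))
  over <- list(...)
  hp[names(over)] <- over
  structure(list(name = name, hyperparameters = hp, seed = as.integer(seed)),
            class = "pf_classifier_spec")
}

#' Default ensemble member specifications (m = 4)
#' @param seed base seed; members get `seed + 0:3`.
#' @return named list of four [base_classifier_spec()].
#' @export
default_classifier_specs <- function(seed = 1L) {
  nm <- c("ETC", "DTC", "GBC", "XGBC")
  specs <- lapply(seq_along(nm), function(i) {
    base_classifier_spec(nm[i], seed = seed + i - 1L)
  })
  names(specs) <- nm
  specs
}

softmax_rows <- function(F) {
  F <- F - apply(F, 1, max)
  E <- exp(F)
  E / rowSums(E)
}

#' Fit one base classifier
#'
#' @param spec a [base_classifier_spec()].
#' @param X numeric matrix (rows = windows, columns = features).
#' @param y integer class codes `0..K-1`.
#' @param n_classes number of classes (default: observed).
#' @return object of class `pf_base_model`.
#' @export
fit_base_classifier <- function(spec, X, y, n_classes = max(y) + 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) > 0)
  if (length(unique(y)) < 2) stop("degenerate labels")
  hp <- spec$hyperparameters
  w <- rep(1, nrow(X))
  set.seed(spec$seed)
  model <- switch(spec$name,
    DTC = {
      list(tree = cpp_grow_cls_tree(X, as.integer(y), n_classes, w,
                                    hp$max_depth, hp$min_split,
                                    ncol(X), FALSE))
    },
    ETC = {
      mtry <- if (is.na(hp$mtry)) max(1L, floor(sqrt(ncol(X)))) else hp$mtry
      trees <- lapply(seq_len(hp$n_trees), function(i) {
        cpp_grow_cls_tree(X, as.integer(y), n_classes, w,
                          hp$max_depth, hp$min_split, mtry, TRUE)
      })
      list(trees = trees)
    },
    GBC = {
      fit_gradient_boost(X, as.integer(y), n_classes, hp, newton = FALSE)
    },
    XGBC = {
      fit_gradient_boost(X, as.integer(y), n_classes, hp, newton = TRUE)
    })
  structure(c(model, list(spec = spec, n_classes = n_classes,
                          n_features = ncol(X),
                          feature_names = colnames(X))),
            class = "pf_base_model")
}

# Multinomial boosting. First-order (GBC): trees fit to the residual
# y_k - p_k with the classic terminal-region Newton step. Second-order (XGBC):
# hessian-weighted trees on -g/h with L2-regularized leaf values.
fit_gradient_boost <- function(X, y, K, hp, newton) {
  n <- nrow(X)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  F <- matrix(0, n, K)
  rounds <- vector("list", hp$n_trees)
  for (m in seq_len(hp$n_trees)) {
    P <- softmax_rows(F)
    round_m <- vector("list", K)
    for (k in seq_len(K)) {
      if (newton) {
        g <- P[, k] - Y[, k]
        h <- pmax(P[, k] * (1 - P[, k]), 1e-6)
        tree <- cpp_grow_reg_tree(X, -g / h, h, hp$max_depth, hp$min_split,
                                  ncol(X), FALSE)
        leaves <- cpp_leaf_ids(tree, X)
        gs <- rowsum(g, leaves)
        hs <- rowsum(h, leaves)
        vals <- -as.numeric(gs) / (as.numeric(hs) + hp$lambda)
        names(vals) <- rownames(gs)
      } else {
        r <- Y[, k] - P[, k]
        tree <- cpp_grow_reg_tree(X, r, rep(1, n), hp$max_depth, hp$min_split,
                                  ncol(X), FALSE)
        leaves <- cpp_leaf_ids(tree, X)
        num <- rowsum(r, leaves)
        den <- rowsum(abs(r) * (1 - abs(r)), leaves)
        vals <- (K - 1) / K * as.numeric(num) / pmax(as.numeric(den), 1e-10)
        names(vals) <- rownames(num)
      }
      tree$leaf_value <- vals
      F[, k] <- F[, k] + hp$learning_rate * vals[as.character(leaves)]
      round_m[[k]] <- tree
    }
    rounds[[m]] <- round_m
  }
  list(rounds = rounds, K = K, learning_rate = hp$learning_rate)
}

boost_scores <- function(model, X) {
  K <- model$n_classes
  F <- matrix(0, nrow(X), K)
  for (round_m in model$rounds) {
    for (k in seq_len(K)) {
      tree <- round_m[[k]]
      leaves <- cpp_leaf_ids(tree, X)
      F[, k] <- F[, k] + model$learning_rate *
        tree$leaf_value[as.character(leaves)]
    }
  }
  F
}

#' Per-class probabilities from a fitted base model
#'
#' @param model a `pf_base_model`.
#' @param X feature matrix with the training feature columns.
#' @return numeric matrix (rows x classes), rows summing to 1.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "pf_base_model"))
  if (ncol(X) != model$n_features) stop("schema mismatch")
  if (!is.null(model$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$feature_names)) {
    if (!all(model$feature_names %in% colnames(X))) stop("schema mismatch")
    X <- X[, model$feature_names, drop = FALSE]
  }
  P <- switch(model$spec$name,
    DTC = cpp_predict_cls_tree(model$tree, X),
    ETC = {
      acc <- 0
      for (tr in model$trees) acc <- acc + cpp_predict_cls_tree(tr, X)
      acc / length(model$trees)
    },
    GBC = softmax_rows(boost_scores(model, X)),
    XGBC = softmax_rows(boost_scores(model, X)))
  # numerical guard: renormalize
  P / rowSums(P)
}

#' Normalized feature importances of a fitted base model
#'
#' Total impurity decrease per feature, normalized to sum to 1 (averaged over
#' trees / boosting rounds).
#'
#' @param model a `pf_base_model`.
#' @return named numeric vector over the training features.
#' @export
importances <- function(model) {
  stopifnot(inherits(model, "pf_base_model"))
  imp <- switch(model$spec$name,
    DTC = model$tree$importance,
    ETC = Reduce(`+`, lapply(model$trees, function(t) t$importance)),
    Reduce(`+`, lapply(model$rounds, function(rm) {
      Reduce(`+`, lapply(rm, function(t) t$importance))
    })))
  if (sum(imp) <= 0) imp <- rep(1, length(imp))
  imp <- imp / sum(imp)
  names(imp) <- model$feature_names
  imp
}
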