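# Base classifiers, the confidence-weighted voting combiner, importances.

mk_pred <- function(label, conf, labels = behavior_labels()) {
  rest <- (1 - conf) / (length(labels) - 1)
  probs <- setNames(rep(rest, length(labels)), labels)
  probs[label] <- conf
  probabilistic_prediction(probs)
}

test_that("weighted voting reproduces hand-traced score maps", {
  v <- weighted_vote(list(mk_pred("takeoff", 0.9), mk_pred("roll", 0.6),
                          mk_pred("roll", 0.55)))
  expect_equal(unname(v$g["takeoff"]), 0.9)
  expect_equal(unname(v$g["roll"]), 1.15)
  expect_identical(v$label, "roll")

  # unanimity wins regardless of confidences
  v2 <- weighted_vote(list(mk_pred("stall", 0.3), mk_pred("stall", 0.9),
                           mk_pred("stall", 0.5), mk_pred("stall", 0.4)))
  expect_identical(v2$label, "stall")

  # tie -> lowest label code, flagged
  v3 <- weighted_vote(list(mk_pred("roll", 0.5), mk_pred("takeoff", 0.5)))
  expect_identical(v3$label, "takeoff")
  expect_true(attr(v3, "tie"))

  bad <- mk_pred("stall", 0.9, labels = rev(behavior_labels()))
  expect_error(weighted_vote(list(mk_pred("stall", 0.9), bad)),
               "label mismatch")
})

test_that("score conservation and the majority-vote reduction hold on random
           vote sets", {
  set.seed(30)
  labels <- behavior_labels()
  for (i in 1:100) {
    m <- sample(2:6, 1)
    preds <- lapply(seq_len(m), function(j) {
      p <- runif(6)
      probabilistic_prediction(setNames(p / sum(p), labels))
    })
    v <- weighted_vote(preds)
    conf <- vapply(preds, function(p) p$confidence, numeric(1))
    voted <- vapply(preds, function(p) p$predicted, character(1))
    expect_equal(sum(v$g), sum(conf), tolerance = 1e-12)
    o <- bf_weighted_vote(voted, conf, labels)
    expect_equal(unname(v$g), unname(o$g), tolerance = 1e-12)
    expect_identical(v$label, o$label)
    # equal confidences reduce to simple majority voting
    eq <- lapply(voted, function(l) mk_pred(l, 0.5))
    veq <- weighted_vote(eq)
    counts <- table(factor(voted, levels = labels))
    expect_identical(veq$label, labels[which.max(counts)])
  }
})

test_that("probabilistic predictions validate their invariants", {
  p <- mk_pred("roll", 0.7)
  expect_identical(p$predicted, "roll")
  expect_equal(p$confidence, 0.7)
  expect_error(probabilistic_prediction(
    setNames(rep(0.5, 6), behavior_labels())))
})

test_that("ensemble fit/predict contract: members, determinism, composition,
           degenerate cases", {
  df <- blob_data()
  feats <- paste0("f", 1:5)
  model <- fit_ensemble(df, selected = feats)
  expect_length(model$models, 4)
  expect_named(model$models, c("ETC", "DTC", "GBC", "XGBC"))

  p1 <- predict(model, df)
  model2 <- fit_ensemble(df, selected = feats)
  p2 <- predict(model2, df)
  expect_identical(p1$label, p2$label)
  expect_equal(p1$g, p2$g)

  # separable blobs: essentially perfect in-sample
  expect_gt(mean(p1$label == df$label), 0.99)

  # row-wise composition: ensemble label == weighted_vote of base outputs
  labels <- model$labels
  for (i in sample(nrow(df), 10)) {
    preds <- lapply(p1$base_probs, function(P) {
      probabilistic_prediction(setNames(P[i, ], labels))
    })
    expect_identical(p1$label[i], weighted_vote(preds)$label)
    expect_equal(unname(p1$g[i, ]), unname(weighted_vote(preds)$g))
  }

  # g recomputed from logged base outputs matches; sum g = sum confidences
  conf_sum <- Reduce(`+`, lapply(p1$base_probs, function(P) apply(P, 1, max)))
  expect_equal(unname(rowSums(p1$g)), unname(conf_sum), tolerance = 1e-9)

  # one-member ensemble equals that base classifier
  spec1 <- list(DTC = base_classifier_spec("DTC", seed = 2))
  m1 <- fit_ensemble(df, specs = spec1, selected = feats)
  pm <- predict(m1, df)
  base_lab <- behavior_labels()[apply(pm$base_probs$DTC, 1, which.max)]
  expect_identical(pm$label, base_lab)

  one_class <- df[df$label == df$label[1], ]
  expect_error(fit_ensemble(one_class, selected = feats), "degenerate labels")
  expect_error(fit_ensemble(df[0, ], selected = feats), "empty matrix")
  expect_error(predict(model, df[, 1:3]), "schema mismatch")
})

test_that("per-member probabilities are proper distributions", {
  df <- blob_data(n_per = 30)
  feats <- paste0("f", 1:5)
  model <- fit_ensemble(df, selected = feats)
  X <- as.matrix(df[feats])
  for (nm in names(model$models)) {
    P <- predict_proba(model$models[[nm]], X)
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-9,
                 info = nm)
    expect_true(all(P >= 0), info = nm)
  }
})

test_that("importances are normalized and demote pure-noise features", {
  df <- blob_data(n_per = 50)
  set.seed(31)
  df$noise1 <- rnorm(nrow(df))
  df$noise2 <- rnorm(nrow(df))
  feats <- c(paste0("f", 1:5), "noise1", "noise2")
  model <- fit_ensemble(df, selected = feats)
  rep_ <- feature_importance(model)
  expect_equal(unname(rowSums(rep_$per_member)), rep(1, 4), tolerance = 1e-9)
  expect_true(all(rep_$per_member >= 0))
  # noise features in the bottom quartile of the aggregate rank
  ranks <- rank(rep_$aggregate_rank[feats])
  expect_gte(min(ranks[c("noise1", "noise2")]), length(feats) * 0.75 - 1)
})

test_that("the soft-voting comparison variant sums full probability
           vectors", {
  df <- blob_data(n_per = 20)
  feats <- paste0("f", 1:5)
  model <- fit_ensemble(df, selected = feats)
  p <- predict(model, df, soft = TRUE)
  manual <- Reduce(`+`, p$base_probs)
  expect_equal(unname(p$g), unname(manual), tolerance = 1e-12)
  expect_identical(p$label,
                   behavior_labels()[apply(manual, 1, which.max)])
})
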