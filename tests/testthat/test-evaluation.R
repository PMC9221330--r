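# Classification reports, label-code MSE, k-fold and subject-wise CV.

test_that("classification report matches hand-derived counts", {
  y <- behavior_labels()[c(1, 1, 2, 2, 3, 3)]
  r <- classification_report(y, y)
  expect_equal(r$accuracy, 1)
  expect_true(all(r$per_class$f1[r$per_class$support > 0] == 1))

  # hand-built 3-class confusion: rows true, cols predicted
  yt <- rep(behavior_labels()[1:3], times = c(4, 3, 3))
  yp <- c("takeoff", "takeoff", "takeoff", "level_flight",
          "level_flight", "level_flight", "turn_and_hover",
          "turn_and_hover", "turn_and_hover", "takeoff")
  r2 <- classification_report(yt, yp)
  cm <- r2$confusion[1:3, 1:3]
  o <- bf_prf(cm)
  sel <- match(behavior_labels()[1:3], r2$per_class$label)
  expect_equal(r2$per_class$precision[sel], unname(o[, "precision"]),
               tolerance = 1e-12)
  expect_equal(r2$per_class$recall[sel], unname(o[, "recall"]),
               tolerance = 1e-12)
  expect_equal(r2$per_class$f1[sel], unname(o[, "f1"]), tolerance = 1e-12)
  expect_equal(sum(r2$confusion), length(yt))
  expect_equal(unname(rowSums(r2$confusion)[1:3]), c(4, 3, 3))

  # class absent from y_true -> recall 0 with a warning
  expect_warning(r3 <- classification_report(
    rep("takeoff", 3), c("takeoff", "takeoff", "stall")))
  expect_equal(r3$per_class$recall[r3$per_class$label == "stall"], 0)
})

test_that("F1 is the harmonic mean of reported precision and recall", {
  set.seed(40)
  for (i in 1:20) {
    yt <- sample(behavior_labels(), 60, replace = TRUE)
    yp <- ifelse(runif(60) < 0.6, yt, sample(behavior_labels(), 60, TRUE))
    r <- suppressWarnings(classification_report(yt, yp))
    pc <- r$per_class
    both <- pc$precision + pc$recall > 0
    expect_equal(pc$f1[both],
                 2 * pc$precision[both] * pc$recall[both] /
                   (pc$precision[both] + pc$recall[both]),
                 tolerance = 1e-12)
  }
})

test_that("label MSE uses squared code differences", {
  y <- behavior_labels()
  expect_equal(label_mse(y, y), 0)
  expect_equal(label_mse(rep("takeoff", 4), rep("stall", 4)), 25)
  yt <- rep("takeoff", 4)
  yp <- c("takeoff", "takeoff", "takeoff", "turn_and_hover")  # distance 2
  expect_equal(label_mse(yt, yp), 1)
  # alternative codebook changes the statistic (order-sensitivity)
  cb <- setNames(c(5L, 4L, 3L, 2L, 1L, 0L), behavior_labels())
  expect_equal(label_mse(rep("takeoff", 2), rep("level_flight", 2), cb), 1)
})

test_that("k-fold CV is stratified, deterministic and error-guarded", {
  df <- blob_data(n_per = 30)
  feats <- paste0("f", 1:5)
  ev <- kfold_cv(df, selected = feats, k = 5, seed = 2)
  ev2 <- kfold_cv(df, selected = feats, k = 5, seed = 2)
  expect_equal(ev$reports$ensemble$mean_accuracy,
               ev2$reports$ensemble$mean_accuracy)
  expect_identical(ev$reports$ensemble$confusion,
                   ev2$reports$ensemble$confusion)
  expect_gt(ev$reports$ensemble$mean_accuracy, 0.95)  # separable blobs
  expect_equal(sum(ev$reports$ensemble$confusion), nrow(df))
  expect_named(ev$reports, c("ETC", "DTC", "GBC", "XGBC", "ensemble"))
  expect_length(ev$reports$DTC$fold_accuracy, 5)
  expect_gte(ev$reports$ensemble$lowest_accuracy, 0)
  expect_error(kfold_cv(df, selected = feats, k = 500), "k exceeds")
})

test_that("subject-wise CV builds one fold per subject", {
  df <- rbind(cbind(blob_data(n_per = 25, seed = 50), subject = "A"),
              cbind(blob_data(n_per = 25, seed = 51), subject = "B"))
  feats <- paste0("f", 1:5)
  ev <- loo_subject_cv(df, selected = feats)
  expect_length(ev$reports$ensemble$fold_accuracy, 2)
  expect_named(ev$reports$ensemble$fold_accuracy, c("A", "B"))
  # identical generating process -> held-out subjects classify well
  expect_gt(ev$reports$ensemble$mean_accuracy, 0.9)

  # a held-out subject with a single class is kept, with a warning
  # (third subject so every training fold still sees >= 2 classes)
  extra <- cbind(blob_data(n_per = 10, seed = 52), subject = "C")
  dfc <- rbind(df, extra[extra$label == "takeoff", ])
  expect_warning(loo_subject_cv(dfc, selected = feats), "single class")
  expect_error(loo_subject_cv(df[df$subject == "A", ], selected = feats),
               "at least 2 subjects")
})
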