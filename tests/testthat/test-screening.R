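# Pearson / Kendall statistics, the correlation report, difficulty
# association and feature selection.

test_that("pearson matches the definitional oracle on random vectors", {
  expect_equal(pearson_r(1:10, 1:10), 1, tolerance = 1e-12)
  expect_equal(pearson_r(1:10, -(1:10)), -1, tolerance = 1e-12)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)),
               bf_pearson(c(1, 2, 3), c(1, 2, 4)), tolerance = 1e-12)
  expect_true(is.na(pearson_r(rep(2, 5), 1:5)))
  set.seed(20)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    expect_equal(pearson_r(x, y), bf_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("kendall tau-b matches exhaustive pair enumeration", {
  expect_equal(kendall_tau(1:6, 1:6), 1)
  expect_equal(kendall_tau(1:6, 6:1), -1)
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4)),
               bf_kendall_b(c(1, 2, 3, 4), c(1, 3, 2, 4)), tolerance = 1e-12)
  expect_true(is.na(kendall_tau(rep(1, 5), 1:5)))
  set.seed(21)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    x <- sample(1:4, n, replace = TRUE)   # heavy ties, like ratings
    y <- rnorm(n)
    if (length(unique(x)) < 2) next
    expect_equal(kendall_tau(x, y), bf_kendall_b(x, y), tolerance = 1e-12)
  }
})

test_that("the correlation report is symmetric with a unit diagonal", {
  fm <- mini_fm()
  rep_ <- correlation_report(fm)
  m <- rep_$matrix
  expect_equal(dim(m), c(28, 28))
  expect_equal(unname(diag(m)), rep(1, 28))
  expect_equal(m, t(m))
  expect_true(all(abs(m) <= 1 + 1e-12, na.rm = TRUE))
  if (nrow(rep_$pairs_flagged) > 0) {
    expect_true(all(abs(rep_$pairs_flagged$r) > rep_$flag_threshold))
  }
})

test_that("per-behavior mean difficulties reproduce the published row", {
  m <- mean_difficulty(load_difficulty_fixture())
  expect_equal(m[["stall"]], 7.29)
  expect_equal(m[["somersault"]], 7.36)
  expect_equal(m[["takeoff"]], 3.43)
  expect_equal(m[["turn_and_hover"]], 5.14)
  expect_equal(m[["level_flight"]], 3.50)
  expect_equal(m[["roll"]], 3.36)
})

test_that("difficulty association excludes constants and collapses under
           permutation", {
  fm <- mini_fm()
  df <- as.data.frame(fm)
  df$skt_value <- 1  # constant feature
  fm2 <- feature_matrix(df)
  tab <- load_difficulty_fixture()["1", , drop = FALSE]
  rownames(tab) <- unique(df$subject)
  class(tab) <- class(load_difficulty_fixture())
  a <- difficulty_association(fm2, tab)
  expect_true("skt_value" %in% a$excluded)
  expect_true(is.na(a$pooled$tau[a$pooled$feature == "skt_value"]))

  # permuting the difficulty column kills the association
  set.seed(22)
  perm <- tab
  strong <- c("nn", "resp_freq", "sc_mean")
  orig <- a$pooled$tau[match(strong, a$pooled$feature)]
  taus <- replicate(5, {
    perm[1, ] <- sample(as.integer(tab))
    ap <- difficulty_association(fm2, perm)
    ap$pooled$tau[match(strong, ap$pooled$feature)]
  })
  expect_lt(mean(abs(taus)), mean(abs(orig)) / 2)
})

test_that("feature selection modes behave as specified", {
  fm <- mini_fm()
  sel <- select_features(fm, mode = "paper")
  expect_length(sel$names, 19)
  expect_identical(sel$names, selected_feature_names())
  expect_identical(setdiff(colnames(sel$matrix),
                           c("subject", "window_start_s", "label")),
                   sel$names)

  # duplicate column: threshold mode drops exactly one of the pair
  # (independent random columns so only the injected pair is flagged)
  set.seed(23)
  n <- 40
  dfr <- data.frame(subject = "1", window_start_s = seq(0, by = 10,
                                                        length.out = n))
  for (f in feature_names()) dfr[[f]] <- rnorm(n)
  dfr$skt_value <- dfr$nn  # perfect duplicate pair
  dfr$label <- rep(behavior_labels(), length.out = n)
  fm2 <- feature_matrix(dfr)
  sel2 <- select_features(fm2, mode = "threshold", r_threshold = 0.9)
  expect_true(xor("nn" %in% sel2$names, "skt_value" %in% sel2$names))
  expect_length(sel2$names, 27)

  # nothing can exceed an impossible threshold
  sel3 <- select_features(fm, mode = "threshold", r_threshold = 1.01)
  expect_length(sel3$names, 28)

  expect_error(
    select_features(fm2, mode = "threshold", r_threshold = 0.9,
                    importance = c(bogus = 1)),
    "unknown feature")
})
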