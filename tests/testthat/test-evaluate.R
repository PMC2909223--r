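test_that("confusion metrics reproduce worked-example arithmetic", {
  # a validation table of 27 binding / 62 non-binding interactions with
  # 25 and 46 classified correctly
  m <- confusion_metrics(tp = 25, fp = 16, tn = 46, fn = 2)
  expect_equal(m$accuracy, 71 / 89)
  expect_equal(round(100 * m$accuracy, 1), 79.8)
  expect_equal(m$tpr, 25 / 27)
  expect_equal(m$fpr, 16 / 62)
  expect_equal(m$precision, 25 / 41)
})

test_that("confusion metrics handle edge cases", {
  perfect <- confusion_metrics(1, 0, 1, 0)
  expect_equal(unlist(perfect[c("tpr", "precision", "accuracy")]),
               c(tpr = 1, precision = 1, accuracy = 1))
  expect_equal(perfect$fpr, 0)
  nopos <- confusion_metrics(0, 3, 5, 0)
  expect_true(is.na(nopos$tpr))  # undefined, not zero
  expect_error(confusion_metrics(0, 0, 0, 0), "zero")
  expect_error(confusion_metrics(-1, 0, 1, 0), "non-negative")
})

test_that("multiclass accuracy pools per-class counts", {
  expect_equal(multiclass_accuracy(c(43, 16, 19), c(45, 20, 21)), 78 / 86)
  expect_equal(round(100 * multiclass_accuracy(c(43, 16, 19),
                                               c(45, 20, 21)), 1), 90.7)
  expect_equal(multiclass_accuracy(c(5, 5), c(5, 5)), 1)
  expect_equal(multiclass_accuracy(0, 10), 0)
  expect_error(multiclass_accuracy(numeric(0), numeric(0)), "non-empty")
  expect_error(multiclass_accuracy(6, 5), "correct <= total")
})

test_that("roc_curve handles canonical cases", {
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c("+", "+", "-", "-"),
                       positive = "+")
  expect_equal(perfect$auc, 1)
  flat <- roc_curve(rep(0.5, 10), rep(c("+", "-"), 5), positive = "+")
  expect_equal(flat$auc, 0.5)
  mixed <- roc_curve(c(0.9, 0.8, 0.4, 0.3), c("+", "-", "+", "-"),
                     positive = "+")
  expect_equal(mixed$auc, 0.75)  # 3 of 4 concordant pairs
  expect_error(roc_curve(c(0.1, 0.2), c("+", "+")), "both classes")
})

test_that("roc points run monotonically from (0,0) to (1,1)", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(5:60, 1)
      scores <- round(runif(n), sample(1:3, 1))  # force some ties
      labs <- sample(c("+", "-"), n, TRUE)
      if (length(unique(labs)) < 2) next
      roc <- roc_curve(scores, labs, positive = "+")
      pts <- roc$points
      expect_equal(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
      expect_equal(c(pts$fpr[nrow(pts)], pts$tpr[nrow(pts)]), c(1, 1))
      expect_true(all(diff(pts$fpr) >= 0))
      expect_true(all(diff(pts$tpr) >= 0))
      expect_true(roc$auc >= 0 && roc$auc <= 1)
    }
  })
})

test_that("trapezoid AUC equals the pairwise-concordance oracle", {
  withr::with_seed(17, {
    for (i in 1:50) {
      n <- sample(4:80, 1)
      scores <- round(runif(n), sample(1:2, 1))
      is_pos <- sample(c(TRUE, FALSE), n, TRUE)
      if (!any(is_pos) || all(is_pos)) next
      labs <- ifelse(is_pos, "+", "-")
      expect_equal(roc_curve(scores, labs, positive = "+")$auc,
                   oracle_auc(scores, is_pos), tolerance = 1e-12)
    }
  })
})

test_that("our AUC agrees with pROC on random score sets", {
  skip_if_not_installed("pROC")
  withr::with_seed(23, {
    for (i in 1:10) {
      scores <- runif(40)
      labs <- sample(c("a", "b"), 40, TRUE)
      if (length(unique(labs)) < 2) next
      ours <- roc_curve(scores, labs, positive = "b")$auc
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = labs, predictor = scores, levels = c("a", "b"),
        direction = "<", quiet = TRUE)))
      expect_equal(ours, ref, tolerance = 1e-10)
    }
  })
})

test_that("pr_curve sweeps thresholds with non-decreasing recall", {
  perfect <- pr_curve(c(0.9, 0.8, 0.2), c("+", "+", "-"), positive = "+")
  expect_equal(perfect$precision[perfect$recall == 1][1], 1)
  flat <- pr_curve(rep(0.7, 8), c(rep("+", 2), rep("-", 6)),
                   positive = "+")
  expect_equal(nrow(flat), 1)
  expect_equal(flat$recall, 1)
  expect_equal(flat$precision, 0.25)  # prevalence
  mixed <- pr_curve(c(0.9, 0.8, 0.4, 0.3), c("+", "-", "+", "-"),
                    positive = "+")
  expect_equal(mixed$precision[mixed$recall == 1][1], 2 / 3)
  expect_true(all(diff(mixed$recall) >= 0))
  expect_error(pr_curve(c(0.1, 0.2), c("-", "-")), "both classes")
})

test_that("cross-validation tests every instance exactly once, stratified", {
  ds <- separable_gram_dataset(10)  # 20 rows
  cv <- cross_validate(ds, k = 5, params = forest_params(30, 10, seed = 1),
                       seed = 9, resample = "none")
  expect_equal(sort(cv$predictions$.row), 1:20)
  expect_equal(sum(cv$confusion), 20)  # pooled counts sum to dataset size
  # stratification: each fold's label counts within 1 of 2/2
  by_fold <- table(cv$predictions$.fold, cv$predictions$.truth)
  expect_true(all(abs(by_fold - 2) <= 1))
  # leave-one-out = k equal to the dataset size
  loo <- cross_validate(ds, k = 20, params = forest_params(20, 10, seed = 1),
                        seed = 9, resample = "none")
  expect_equal(sort(loo$predictions$.row), 1:20)
  expect_equal(as.integer(table(loo$predictions$.fold)), rep(1L, 20))
})

test_that("cross-validation is deterministic and rejects starved classes", {
  ds <- separable_gram_dataset(8)
  a <- cross_validate(ds, k = 4, params = forest_params(20, 10, seed = 2),
                      seed = 7, resample = "none")
  b <- cross_validate(ds, k = 4, params = forest_params(20, 10, seed = 2),
                      seed = 7, resample = "none")
  expect_equal(a$predictions, b$predictions)
  expect_equal(a$metrics, b$metrics)
  expect_error(cross_validate(ds, k = 10), "smaller k")
})

test_that("multi-class OVR AUC reduces to the binary AUC for two classes", {
  withr::with_seed(41, {
    scores <- runif(30)
    labs <- sample(c("binding", "non-binding"), 30, TRUE)
    binary <- roc_curve(scores, labs, positive = "binding")$auc
    # one-vs-rest from both directions, weighted by class size
    a1 <- roc_curve(scores, labs, positive = "binding")$auc
    a2 <- roc_curve(1 - scores, labs, positive = "non-binding")$auc
    w <- table(labs)[c("binding", "non-binding")]
    expect_equal(unname((a1 * w[1] + a2 * w[2]) / sum(w)), binary)
  })
})

test_that("evaluate_model reports validation metrics for a held-out table", {
  train <- separable_gram_dataset(10, seed = 1)
  test <- separable_gram_dataset(8, seed = 2)
  fit <- train_forest(train, params = forest_params(50, 10, seed = 1))
  ev <- evaluate_model(fit, test)
  expect_s3_class(ev, "pdz_eval")
  expect_gte(ev$metrics$accuracy, 0.9)  # same planted rule, easy transfer
  expect_equal(sum(ev$confusion), nrow(test))
  expect_gte(ev$auc, 0.95)
})
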