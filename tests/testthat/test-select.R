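test_that("feature-class correlation matches closed forms", {
  y <- rep(c("a", "b"), each = 10)
  x <- as.numeric(y == "a")
  expect_equal(feature_class_correlation(x, y), 1)
  # constant within class with equal means: no association
  expect_equal(feature_class_correlation(rep(2, 20), y), 0)
  # random case equals |Pearson| against the 0/1 label
  withr::with_seed(8, {
    for (i in 1:10) {
      xr <- rnorm(20)
      expect_equal(feature_class_correlation(xr, y),
                   abs(cor(xr, as.numeric(y == "a"))), tolerance = 1e-12)
    }
  })
})

test_that("multi-class correlation is the one-hot multiple correlation", {
  withr::with_seed(12, {
    y <- sample(c("I", "II", "I-II"), 30, TRUE)
    x <- rnorm(30) + 2 * (y == "I")
    # reference: sqrt(R^2) of lm on class indicators
    ref <- sqrt(summary(stats::lm(x ~ factor(y)))$r.squared)
    expect_equal(feature_class_correlation(x, y), ref, tolerance = 1e-10)
  })
})

test_that("cfs merit follows the stated formula", {
  y <- rep(c("a", "b"), each = 6)
  lab01 <- as.numeric(y == "a")
  X <- cbind(f1 = lab01, f2 = lab01, f3 = rep(0.5, 12))
  # k = 1 reduces to the feature's own class correlation
  expect_equal(cfs_merit(1, X, y), 1)
  withr::with_seed(3, {
    xr <- rnorm(12)
    expect_equal(cfs_merit(1, cbind(xr), y),
                 feature_class_correlation(xr, y))
  })
  # k = 2 duplicated perfect features: 2 * 1 / sqrt(2 + 2 * 1) = 1
  expect_equal(cfs_merit(c(1, 2), X, y), 1)
  # r_cf = 0 gives merit 0
  expect_equal(cfs_merit(3, X, y), 0)
  expect_error(cfs_merit(integer(0), X, y), "non-empty")
})

test_that("cfs merit is invariant to positive rescaling of a column", {
  withr::with_seed(21, {
    y <- sample(c("a", "b"), 25, TRUE)
    X <- matrix(rnorm(100), 25, 4)
    base <- cfs_merit(1:4, X, y)
    X2 <- X
    X2[, 2] <- X2[, 2] * 37.5
    expect_equal(cfs_merit(1:4, X2, y), base, tolerance = 1e-10)
  })
})

test_that("searches find the informative feature among noise", {
  withr::with_seed(14, {
    y <- rep(c("a", "b"), each = 15)
    X <- matrix(rnorm(30 * 8), 30, 8)
    X[, 3] <- as.numeric(y == "a")  # the label itself
    for (st in c("best-first", "greedy-forward")) {
      fs <- cfs_search(X, y, strategy = st)
      expect_true(3 %in% fs$indices)
    }
  })
})

test_that("duplicated informative features are penalized to one copy", {
  withr::with_seed(15, {
    y <- rep(c("a", "b"), each = 12)
    signal <- as.numeric(y == "a") + rnorm(24, sd = 0.2)
    X <- cbind(signal, signal, matrix(rnorm(24 * 4, sd = 1), 24, 4))
    fs <- cfs_search(X, y, strategy = "best-first")
    expect_equal(sum(c(1, 2) %in% fs$indices), 1)
    # exhaustive enumeration confirms the optimum excludes the duplicate
    ex <- exhaustive_cfs_best(X, y)
    expect_equal(sum(c(1, 2) %in% ex$subset), 1)
    expect_equal(fs$merit, ex$merit, tolerance = 1e-9)
  })
})

test_that("single-feature matrices are returned as-is", {
  y <- rep(c("a", "b"), each = 5)
  X <- matrix(rnorm(10), 10, 1)
  fs <- cfs_search(X, y)
  expect_equal(fs$indices, 1L)
})

test_that("best-first never returns lower merit than greedy forward", {
  withr::with_seed(33, {
    for (i in 1:30) {
      n <- 24
      p <- sample(4:9, 1)
      y <- sample(c("a", "b"), n, TRUE)
      if (length(unique(y)) < 2) next
      X <- matrix(rnorm(n * p), n, p)
      X[, 1] <- X[, 1] + (y == "a") * runif(1, 0, 2)
      bf <- cfs_search(X, y, strategy = "best-first")
      gr <- cfs_search(X, y, strategy = "greedy-forward")
      expect_gte(bf$merit + 1e-12, gr$merit)
    }
  })
})

test_that("selection on encoded blocks reports per-block grams", {
  ds <- separable_gram_dataset(10)
  sel <- select_features(ds)
  expect_true(all(c("feature", "block", "gram", "merit", "strategy") %in%
                    names(sel)))
  expect_true(all(sel$block == "pdz"))
  # the planted discriminative grams ("111" vs "555") dominate
  expect_true(any(sel$gram %in% c("111", "555")))
})

test_that("consensus keeps bigrams contained in selected trigrams", {
  out <- consensus_features(c("125", "612"), c("12", "25", "34"))
  expect_equal(sort(out$bigram), c("12", "25"))
  expect_equal(out$hosts[out$bigram == "12"], "125,612")
  expect_equal(out$hosts[out$bigram == "25"], "125")
  # disjoint sets give an empty result
  expect_equal(nrow(consensus_features("345", "12")), 0)
  # prefix+suffix containment counts once
  out2 <- consensus_features("111", "11")
  expect_equal(nrow(out2), 1)
  expect_equal(out2$hosts, "111")
  expect_error(consensus_features("128", "12"), "malformed")
})
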