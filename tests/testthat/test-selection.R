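test_that("t-test filter is calibrated under the null and detects plants", {
  set.seed(30)
  n <- 200
  X <- matrix(rnorm(n * 5000), n, 5000)
  labels <- rep(c("low", "high"), each = n / 2)
  f <- ttest_filter(mk_bank(X), labels, 0.01)
  rate <- length(f$candidates) / 5000
  expect_gt(rate, 0.004)
  expect_lt(rate, 0.017)

  # planted mean shift d = 2 at n = 120 per group: cross-check against the
  # closed-form pooled t statistic
  set.seed(31)
  x <- c(rnorm(120), rnorm(120, mean = 2))
  labels2 <- rep(c("a", "b"), each = 120)
  f2 <- ttest_filter(mk_bank(cbind(x)), labels2, 0.01, t_var = "pooled")
  m <- tapply(x, labels2, mean)
  v <- tapply(x, labels2, var)
  tt <- (m[1] - m[2]) / sqrt(((119 * v[1] + 119 * v[2]) / 238) * (2 / 120))
  p_oracle <- 2 * pt(abs(tt), 238, lower.tail = FALSE)
  expect_lt(f2$p_values[1], 1e-10)
  expect_equal(unname(f2$p_values[1]), unname(p_oracle), tolerance = 1e-12)
})

test_that("the filter threshold is strictly 'below alpha'", {
  set.seed(32)
  X <- cbind(c(rnorm(20), rnorm(20, 0.8)), rnorm(40))
  labels <- rep(c("a", "b"), each = 20)
  f <- ttest_filter(mk_bank(X), labels, 0.5)
  p1 <- f$p_values[1]
  # alpha set to the column's own p-value: not selected (strict <)
  f_at <- ttest_filter(mk_bank(X), labels, alpha = p1)
  expect_false(1 %in% f_at$candidates)
  f_above <- ttest_filter(mk_bank(X), labels, alpha = p1 + 1e-12)
  expect_true(1 %in% f_above$candidates)
  expect_error(ttest_filter(mk_bank(X), rep(c("a", "b", "c"), length.out = 40)),
               "two levels")
  expect_error(ttest_filter(mk_bank(X[1:3, ]), c("a", "a", "b")),
               "at least 2")
})

test_that("SVM cross-validation separates the separable and not the null", {
  set.seed(33)
  n <- 60
  X <- rbind(matrix(rnorm(n * 2 / 2, mean = -6), n / 2, 2),
             matrix(rnorm(n * 2 / 2, mean = 6), n / 2, 2))
  labels <- rep(c("a", "b"), each = n / 2)
  cv <- svm_cv_accuracy(X, labels, quick_sel(k_folds = 5))
  expect_equal(cv$fold_accuracy, rep(1, 5))
  expect_equal(unname(cv$class_accuracy), c(1, 1))

  set.seed(34)
  X0 <- matrix(rnorm(240), 120, 2)
  labels0 <- sample(rep(c("a", "b"), 60))
  cv0 <- svm_cv_accuracy(X0, labels0, quick_sel(k_folds = 10))
  band <- 2.576 * sqrt(0.25 / 120)
  expect_gt(cv0$mean_accuracy, 0.5 - band - 0.05)
  expect_lt(cv0$mean_accuracy, 0.5 + band + 0.05)

  # a manually degenerate fold assignment is refused
  bad_folds <- c(rep(1, 60), rep(2, 60))  # fold 2 training set lacks class b?
  labs <- rep(c("a", "b"), each = 60)
  expect_error(svm_cv_accuracy(X0, labs, quick_sel(k_folds = 2),
                               folds = bad_folds), "single class")
})

test_that("stratified folds balance classes and grant 1/24 granularity at N=240", {
  labels <- rep(c("low", "high"), each = 120)
  folds <- make_folds(labels, 10, seed = 5)
  expect_equal(unname(table(folds)), rep(24L, 10), ignore_attr = TRUE)
  for (f in 1:10)
    expect_equal(sum(labels[folds == f] == "low"), 12)
  expect_identical(folds, make_folds(labels, 10, seed = 5))
})

test_that("confidence bounds follow the Student-t formula", {
  expect_equal(confidence_bounds(rep(0.7, 10)), c(0.7, 0.7))
  # k = 2, df = 1, hand-computed: 0.7 +- qt(.995, 1) * sd / sqrt(2)
  b <- confidence_bounds(c(0.6, 0.8), 0.99)
  expect_equal(b, c(0.7 - 6.36567411, 0.7 + 6.36567411), tolerance = 1e-6)
  expect_error(confidence_bounds(0.7), "at least 2")
  # interval contains its mean
  set.seed(35)
  for (i in 1:5) {
    acc <- runif(10, 0.4, 0.9)
    bb <- confidence_bounds(acc)
    expect_true(bb[1] <= mean(acc) && mean(acc) <= bb[2])
  }
})

test_that("interval disjointness decides significance, touching overlaps", {
  expect_true(bounds_overlap(c(0.60, 0.65), c(0.70, 0.75)))
  expect_false(bounds_overlap(c(0.60, 0.71), c(0.70, 0.75)))
  expect_false(bounds_overlap(c(0.6, 0.7), c(0.7, 0.8)))
})

test_that("SFFS selects the informative singleton, matching exhaustive search", {
  set.seed(36)
  n <- 50
  labels <- rep(c("low", "high"), each = n / 2)
  X <- matrix(rnorm(n * 6), n, 6)
  X[labels == "high", 4] <- X[labels == "high", 4] + 2
  bank <- zscore_features(mk_bank(X, normalized = FALSE))
  cfg <- quick_sel(k_folds = 5, max_features = 1, seed = 3)
  sel <- sffs(bank, labels, cfg, candidates = 1:6,
              filter = ttest_filter(bank, labels, 1))
  expect_equal(sel$selected, 4L)
  folds <- sel$folds
  singles <- vapply(1:6, function(j)
    svm_cv_accuracy(bank$X[, j, drop = FALSE], labels, cfg,
                    folds)$mean_accuracy, numeric(1))
  expect_equal(sel$steps$mean_accuracy[1], max(singles))

  # a single candidate is selected in one step
  sel1 <- sffs(bank, labels, cfg, candidates = 4L,
               filter = ttest_filter(bank, labels, 1))
  expect_equal(sel1$selected, 4L)
  expect_equal(nrow(sel1$steps), 1)
})

test_that("SFFS dominates plain SFS; best-of-size grows with plentiful signal", {
  for (seed in 1:3) {
    set.seed(seed * 11)
    n <- 60
    labels <- rep(c("low", "high"), each = n / 2)
    X <- matrix(rnorm(n * 8), n, 8)
    # three genuinely informative, complementary features
    for (j in 1:3)
      X[labels == "high", j] <- X[labels == "high", j] + 1.2
    bank <- zscore_features(mk_bank(X, normalized = FALSE))
    cfg <- quick_sel(k_folds = 5, max_features = 3, seed = seed)
    filt <- ttest_filter(bank, labels, 1)
    sel <- sffs(bank, labels, cfg, candidates = 1:8, filter = filt)
    folds <- sel$folds
    sfs <- sfs_best_of_size(bank, labels, cfg, 1:8, folds)
    got <- sel$steps$mean_accuracy[match(1:3, sel$steps$n_features)]
    expect_true(all(got + 1e-12 >= sfs))
    expect_true(all(diff(got) >= -1e-12))
  }
})

test_that("selection is deterministic given the seed", {
  set.seed(38)
  n <- 40
  labels <- rep(c("low", "high"), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10)
  X[labels == "high", 3] <- X[labels == "high", 3] + 1.2
  bank <- zscore_features(mk_bank(X, normalized = FALSE))
  cfg <- quick_sel(k_folds = 5, max_features = 2, seed = 7)
  s1 <- sffs(bank, labels, cfg, candidates = 1:10,
             filter = ttest_filter(bank, labels, 1))
  s2 <- sffs(bank, labels, cfg, candidates = 1:10,
             filter = ttest_filter(bank, labels, 1))
  expect_identical(s1$steps, s2$steps)
})
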