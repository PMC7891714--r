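test_that("feature ranking matches a brute-force correlation oracle", {
  set.seed(21)
  y <- rep(c(0, 1), each = 10)
  X <- cbind(rnorm(20), y + rnorm(20, sd = 2), rnorm(20),
             y * 2 + rnorm(20, sd = 0.4))
  rk <- rank_features(X, y)
  # oracle: direct correlation + sort
  r <- apply(X, 2, function(col) cor(col, y))
  expect_equal(rk$r, r)
  expect_equal(rk$order, order(-abs(r)))

  # a column equal to the label is ranked first with |r| = 1
  X2 <- cbind(rnorm(20), y, rnorm(20))
  rk2 <- rank_features(X2, y)
  expect_equal(rk2$order[1], 2L)
  expect_equal(abs(rk2$r[2]), 1)

  # zero-variance columns go last with r treated as 0
  X3 <- cbind(rep(1, 20), rnorm(20), y)
  rk3 <- rank_features(X3, y)
  expect_equal(rk3$order[3], 1L)
  expect_equal(rk3$r[1], 0)

  expect_error(rank_features(X, rep(1, 20)), "2 classes")
})

test_that("rankings on pure noise are valid permutations", {
  set.seed(31)
  y <- rep(c("a", "b"), 15)
  o1 <- rank_features(matrix(rnorm(30 * 12), 30), y)$order
  o2 <- rank_features(matrix(rnorm(30 * 12), 30), y)$order
  expect_equal(sort(o1), 1:12)
  expect_equal(sort(o2), 1:12)
  expect_false(identical(o1, o2))
})

test_that("linear SVM separates well-separated classes perfectly", {
  set.seed(3)
  n <- 20
  X <- rbind(cbind(rnorm(n, -5, 0.3), rnorm(n, -5, 0.3)),
             cbind(rnorm(n, 5, 0.3), rnorm(n, 5, 0.3)))
  y <- rep(c("neg", "pos"), each = n)
  fit <- svm_fit(X, y)
  expect_equal(predict(fit, X), y)
  expect_equal(cv_accuracy(X, y, seed = 1), 1.0)
})

test_that("cross-validated accuracy is at chance for label-free noise", {
  set.seed(13)
  accs <- vapply(1:200, function(i) {
    X <- matrix(rnorm(40 * 5), 40)
    y <- rep(c("a", "b"), each = 20)
    cv_accuracy(X, y, seed = 1000 + i)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("folds group rows by subject and stratify by class", {
  set.seed(8)
  sid <- rep(sprintf("S%02d", 1:20), each = 2)   # 2 episodes per subject
  lab <- rep(rep(c("a", "b"), each = 10), each = 2)
  for (i in 1:10) {
    folds <- nirsload:::make_folds(lab, sid, 5)
    # a subject's rows always share a fold
    expect_true(all(tapply(folds, sid, function(f) length(unique(f))) == 1))
    # every training set keeps both classes
    for (f in unique(folds))
      expect_equal(sort(unique(lab[folds != f])), c("a", "b"))
  }
})

test_that("cv_accuracy is deterministic given a seed", {
  set.seed(5)
  X <- matrix(rnorm(30 * 8), 30)
  y <- rep(c("a", "b"), 15)
  expect_identical(cv_accuracy(X, y, seed = 77), cv_accuracy(X, y, seed = 77))
  expect_false(identical(cv_accuracy(X, y, seed = 77),
                         cv_accuracy(X, y, seed = 78)))
})

test_that("accuracy curve honours the boundary and determinism contracts", {
  set.seed(23)
  y <- rep(c("a", "b"), 12)
  X <- matrix(rnorm(24 * 10), 24)
  X[, 4] <- X[, 4] + 2 * (y == "b")   # plant one informative column
  one <- accuracy_curve(X, y, n_features_grid = 1, n_reps = 5, seed = 2)
  expect_equal(nrow(one$curve), 1)
  expect_equal(one$peak$channels, one$ranking[1])
  expect_equal(one$ranking[1], 4L)
  r1 <- accuracy_curve(X, y, n_features_grid = c(1, 3), n_reps = 3, seed = 9)
  r2 <- accuracy_curve(X, y, n_features_grid = c(1, 3), n_reps = 3, seed = 9)
  expect_identical(r1$curve, r2$curve)
  expect_error(accuracy_curve(X, y, n_features_grid = 99), "exceeds")
})

test_that("selection-in-the-loop null is biased at small n and returns to
           chance when selection is vacuous (invariant)", {
  # NOTE: the null is NOT monotone in n: it rises while added features are
  # still spuriously selected and only collapses once selection is vacuous.
  # This shape was cross-checked against an independent scikit-learn
  # implementation of the identical protocol (same means within 0.01).
  set.seed(77)
  X <- matrix(rnorm(30 * 204), 30)
  y <- rep(c("lo", "hi"), 15)
  pn <- permutation_null(X, y, n_features_grid = c(2, 8, 32, 204),
                         n_perms = 200, seed = 11)
  m <- pn$null$mean
  expect_true(all(m[1:3] > 0.55))   # selection bias while n << p
  expect_lt(abs(m[4] - 0.5), 0.03)  # vacuous selection: back to chance
  expect_lt(m[4], m[3] - 0.1)       # decline toward 50% at the full set
})

test_that("in-fold (honest) selection removes the small-n null bias", {
  set.seed(78)
  X <- matrix(rnorm(30 * 204), 30)
  y <- rep(c("lo", "hi"), 15)
  pn <- permutation_null(X, y, n_features_grid = 4, n_perms = 200,
                         seed = 12, selection = "in_fold")
  expect_lt(abs(pn$null$mean[1] - 0.5), 0.03)
})

test_that("motion-only classification sits at chance without planted
           motion effects and detects a planted one", {
  coh <- tiny_cohort()
  acc <- motion_only_classification(coh, "skill", episodes = "task1",
                                    seed = 5)
  expect_lt(abs(acc - 0.5), 0.3)  # single small cohort: loose bound
  # across seeds the mean is at chance
  st <- coh$study
  accs <- vapply(1:10, function(s) {
    cc <- simulate_cohort(st, seed = 600 + s, ground_truth = "none")
    motion_only_classification(cc, "skill", episodes = "task1", seed = s)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.12)
  # positive control: group-dependent motion rate becomes classifiable
  st2 <- st
  st2$motion_rate_per_min <- c(student = 4, attending = 0.2)
  accs2 <- vapply(1:10, function(s) {
    cc <- simulate_cohort(st2, seed = 700 + s, ground_truth = "none")
    motion_only_classification(cc, "skill", episodes = "task1", seed = s)
  }, numeric(1))
  expect_gt(mean(accs2), mean(accs) + 2 * sd(accs))
})

test_that("zero motion events give near-zero motion features", {
  st <- scaled_study(layout_counts = c("1.5" = 2, "2.12" = 2, "3" = 2,
                                       "3.35" = 2))
  st$n_students <- 3; st$n_attendings <- 3
  st$motion_rate_per_min <- 0
  coh <- simulate_cohort(st, seed = 9, ground_truth = "none")
  mf <- motion_features(coh, episodes = "task1")
  # only baseline sensor noise remains
  expect_lt(max(mf$values), 0.05)
  acc <- motion_only_classification(coh, "skill", episodes = "task1",
                                    seed = 1)
  expect_lt(abs(acc - 0.5), 0.4)
})
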