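test_that("window statistics match closed forms", {
  # constant signal: sd 0, mean identity
  x <- rep(3, 500)
  expect_true(all(window_statistic(x, FS, 10, "sd") == 0))
  expect_true(all(window_statistic(x, FS, 10, "mean") == 3))
  # sinusoid with integer periods per window: sd = A / sqrt(2) within 1%
  wlen <- floor(10 * FS)
  A <- 1.7
  t <- seq_len(10 * wlen) - 1
  s <- A * sin(2 * pi * 4 * t / wlen)    # 4 periods per window
  sds <- window_statistic(s, FS, 10, "sd")
  expect_true(all(abs(sds - A / sqrt(2)) / (A / sqrt(2)) < 0.01))
  expect_error(window_statistic(s, FS, 10, "entropy"))
})

test_that("feature values ignore additive constants (SD-based)", {
  set.seed(2)
  x <- rnorm(1000)
  expect_equal(window_statistic(x, FS, 10, "sd"),
               window_statistic(x + 5, FS, 10, "sd"), tolerance = 1e-12)
})

test_that("episode averaging respects the mask and missingness rule", {
  sch <- protocol_schedule(task1_s = 60, task2_s = 60, rest_s = 60)
  # oracle: windows are 81 samples (~9.953 s); fully inside task1 (60-120 s)
  wlen <- floor(10 * FS)
  nw <- 18
  inside <- which((seq_len(nw) - 1) * wlen / FS >= 60 &
                  seq_len(nw) * wlen / FS <= 120)
  expect_equal(inside, 8:12)
  vals <- matrix(seq_len(nw), nw, 1)
  mask <- matrix(TRUE, nw, 1)
  expect_equal(episode_activation(vals, mask, sch, "task1", FS, 10),
               mean(inside))
  # equal values: the mean is the value
  expect_equal(episode_activation(matrix(2.5, nw, 1), mask, sch, "task1",
                                  FS, 10), 2.5)
  # masked mean: drop one window
  mask[9, 1] <- FALSE
  expect_equal(episode_activation(vals, mask, sch, "task1", FS, 10),
               mean(setdiff(inside, 9)))
  # fewer than 3 retained -> missing
  mask[, 1] <- FALSE; mask[8:9, 1] <- TRUE
  expect_true(is.na(episode_activation(vals, mask, sch, "task1", FS, 10)))
  expect_error(episode_activation(vals, NULL, sch, "task9", FS, 10),
               "task9")
})

test_that("the toy masked-mean example from the window rule holds", {
  sch <- protocol_schedule(task1_s = 60, task2_s = 60, rest_s = 60)
  # windows 8..12 lie inside task1; give them values 1,2,3,4,5 and flag
  # the windows holding 3 and 5 -> retained (1, 2, 4)
  vals <- matrix(0, 14, 1)
  vals[8:12, 1] <- 1:5
  mask <- matrix(TRUE, 14, 1)
  mask[c(10, 12), 1] <- FALSE
  got <- episode_activation(vals, mask, sch, "task1", FS, 10)
  expect_equal(got, mean(c(1, 2, 4)), tolerance = 1e-12)
})

test_that("SSR removes a shared regressor exactly and is orthogonal", {
  lay <- small_layout()
  n <- 800
  set.seed(31)
  hb <- matrix(rnorm(n * nrow(lay), sd = 0.1), n)
  short_col <- which(lay$class_cm == 1.5)[1]
  long_col <- which(lay$class_cm == 3.35)[1]
  pair <- ssr_pairs(lay)
  reg_col <- match(pair$short_id[pair$long_id == lay$channel_id[long_col]],
                   lay$channel_id)
  # perfect regressor: y_long = 2.5 * y_short
  hb[, long_col] <- 2.5 * hb[, reg_col]
  out <- ssr(hb, lay)
  expect_lt(sqrt(mean(out$hb[, long_col]^2)) /
            sqrt(mean(hb[, long_col]^2)), 1e-9)
  expect_equal(unname(out$beta[as.character(lay$channel_id[long_col])]),
               2.5, tolerance = 1e-9)
  # residual orthogonality for all long channels (property)
  for (i in seq_len(nrow(out$pairs))) {
    lc <- match(out$pairs$long_id[i], lay$channel_id)
    sc <- match(out$pairs$short_id[i], lay$channel_id)
    ip <- abs(sum(out$hb[, lc] * hb[, sc]))
    scale <- sqrt(sum(out$hb[, lc]^2) * sum(hb[, sc]^2))
    expect_lt(ip / max(scale, 1e-300), 1e-8)
  }
})

test_that("SSR recovers an orthogonal residual (least-squares oracle)", {
  lay <- small_layout()
  n <- 1000
  set.seed(8)
  hb <- matrix(rnorm(n * nrow(lay), sd = 0.05), n)
  pair <- ssr_pairs(lay)
  lc <- match(pair$long_id[1], lay$channel_id)
  sc <- match(pair$short_id[1], lay$channel_id)
  ys <- rnorm(n)
  cc <- rnorm(n)
  cc <- cc - sum(cc * ys) / sum(ys * ys) * ys   # c orthogonal to y_short
  hb[, sc] <- ys
  hb[, lc] <- ys + cc
  out <- ssr(hb, lay)
  # oracle: normal-equation solve
  beta_hat <- solve(crossprod(ys), crossprod(ys, hb[, lc]))[1]
  expect_equal(unname(out$beta[as.character(pair$long_id[1])]), beta_hat,
               tolerance = 1e-10)
  expect_lt(abs(cor(out$hb[, lc], ys)), 0.02)
  expect_equal(out$hb[, lc], cc, tolerance = 1e-8)
})

test_that("zero-variance regressor leaves the channel unchanged", {
  lay <- build_layout(c("1.5" = 1, "2.12" = 0, "3" = 1, "3.35" = 0))
  hb <- matrix(rnorm(1000), 500)
  hb[, lay$class_cm == 1.5] <- 0
  expect_warning(out <- ssr(hb, lay), "zero-variance")
  expect_equal(out$hb, hb)
})

test_that("feature matrix assembly, labels and imputation", {
  coh <- tiny_cohort()
  feat <- cohort_features(coh)
  expect_equal(dim(feat$values), c(18L, 28L))  # 9 subjects x 2 tasks
  expect_true(all(feat$values >= 0))
  expect_equal(feat$row_meta$load_label,
               median_split(feat$row_meta$tlx_mean, feat$row_meta$group))
  expect_equal(as.integer(colnames(feat$values)), coh$layout$channel_id)

  # imputation: one missing among (1, 2, NA, 4) -> column median 2
  acts <- list(S1 = matrix(c(1, 5), 1, 2, dimnames = list("task1")),
               S2 = matrix(c(2, 5), 1, 2, dimnames = list("task1")),
               S3 = matrix(c(NA, 5), 1, 2, dimnames = list("task1")),
               S4 = matrix(c(4, 5), 1, 2, dimnames = list("task1")))
  tlx <- data.frame(subject_id = c("S1", "S2", "S3", "S4"),
                    episode = "task1", mean_score = c(4, 9, 11, 16))
  groups <- setNames(rep("student", 4), names(acts))
  lay2 <- build_layout(c("1.5" = 1, "2.12" = 0, "3" = 1, "3.35" = 0))
  expect_message(fm <- build_feature_matrix(acts, tlx, groups, lay2,
                                            episodes = "task1"), "imputed")
  expect_equal(unname(fm$values[3, 1]), 2)
  expect_true(fm$imputed[3, 1])
  expect_equal(fm$row_meta$load_label, c("low", "low", "high", "high"))
})

test_that("rows without TLX records are dropped with a warning", {
  acts <- list(S1 = matrix(c(1, 2), 1, 2, dimnames = list("task1")),
               S2 = matrix(c(3, 4), 1, 2, dimnames = list("task1")))
  tlx <- data.frame(subject_id = "S1", episode = "task1", mean_score = 5)
  lay2 <- build_layout(c("1.5" = 1, "2.12" = 0, "3" = 1, "3.35" = 0))
  expect_warning(
    expect_warning(
      fm <- build_feature_matrix(acts, tlx, setNames(rep("student", 2),
                                                     c("S1", "S2")),
                                 lay2, episodes = "task1"),
      "no TLX record"),
    "fewer than 2")
  expect_equal(nrow(fm$values), 1)
})
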