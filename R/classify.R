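as_pm1 <- function(labels) {
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2)
    stop("labels must contain exactly 2 classes (got ",
         length(lv), ")")
  list(y = ifelse(as.character(labels) == lv[2], 1, -1), levels = lv)
}

#' Fit a linear support vector machine
#'
#' L2-regularised, L1-loss (hinge) linear SVM solved in the dual by
#' deterministic coordinate descent; the intercept is absorbed by a unit
#' bias column. Equivalent to the classic linear-kernel C-SVM for the
#' small problems this package handles.
#'
#' @param X numeric matrix (rows = observations).
#' @param labels binary labels (any two-valued vector).
#' @param cost soft-margin cost C (default 1).
#' @param max_passes,tol solver controls.
#' @return list of class `nirs_svm`: `w` (weights), `b` (intercept),
#'   `levels` (class order: negative, positive).
#' @export
svm_fit <- function(X, labels, cost = 1, max_passes = 2000, tol = 1e-6) {
  X <- as.matrix(X)
  yy <- as_pm1(labels)
  Xa <- cbind(X, 1)
  w <- cpp_svm_train(Xa, yy$y, cost, as.integer(max_passes), tol)
  structure(list(w = w[seq_len(ncol(X))], b = w[ncol(X) + 1],
                 levels = yy$levels), class = "nirs_svm")
}

#' @rdname svm_fit
#' @param object a `nirs_svm`.
#' @param newdata matrix of observations to classify.
#' @param ... unused.
#' @return `predict`: character vector of predicted labels.
#' @export
predict.nirs_svm <- function(object, newdata, ...) {
  s <- as.matrix(newdata) %*% object$w + object$b
  ifelse(drop(s) >= 0, object$levels[2], object$levels[1])
}

#' Rank features by absolute Pearson correlation with the labels
#'
#' Columns are ordered by decreasing `|r|` between the column and the
#' binary label vector; ties are broken by ascending column index, and
#' zero-variance columns (undefined correlation) are ranked last with
#' `r` treated as 0.
#'
#' @param X numeric matrix (rows = observations, columns = features).
#' @param labels binary labels.
#' @return list with `order` (column indices, best first) and `r`
#'   (signed correlations in original column order).
#' @export
rank_features <- function(X, labels) {
  X <- as.matrix(X)
  yy <- as_pm1(labels)
  r <- suppressWarnings(as.vector(cor(X, yy$y)))
  zerovar <- !is.finite(r)
  r[zerovar] <- 0
  list(order = order(zerovar, -abs(r), seq_len(ncol(X))), r = r)
}

# Subject-grouped, class-stratified k-fold assignment. Subjects (not rows)
# are dealt to folds so a subject never appears in both train and test;
# stratification uses each subject's first row label. Returns a fold id
# per row. Retries (fresh draw) until every training set contains both
# classes, at most max_tries times.
make_folds <- function(labels, subject_ids, k) {
  subj <- unique(subject_ids)
  slab <- labels[match(subj, subject_ids)]
  fold_of <- integer(length(subj))
  names(fold_of) <- subj
  for (lv in unique(slab)) {
    idx <- which(slab == lv)
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- rep(seq_len(k), length.out = length(idx))[
      sample.int(length(idx))]
  }
  fold_of[subject_ids]
}

#' Cross-validated linear-SVM accuracy
#'
#' Mean held-out accuracy over stratified k-fold cross-validation. Folds
#' are grouped by subject, so all rows (episodes) of a subject land in
#' the same fold and a subject in the training set is automatically
#' excluded from the test set. Features are standardised using
#' training-fold means and SDs only.
#'
#' With `in_fold_rank_n`, feature ranking is re-run inside each training
#' fold ("honest" selection); otherwise the caller passes a fixed
#' `feature_subset` (typically the top of a full-matrix ranking).
#'
#' @param X numeric matrix (rows = subject-episodes).
#' @param labels binary labels, one per row.
#' @param feature_subset column indices to use (`NULL` = all).
#' @param subject_ids one id per row (`NULL` = each row its own subject).
#' @param n_folds number of folds (default 5).
#' @param cost SVM cost.
#' @param seed integer seed for the fold draw (`NULL` = use current RNG
#'   stream).
#' @param in_fold_rank_n if non-`NULL`, rank features on the training
#'   rows of each fold and keep this many.
#' @param max_tries refold attempts when a training fold loses a class.
#' @return mean of the per-fold held-out accuracies.
#' @export
cv_accuracy <- function(X, labels, feature_subset = NULL,
                        subject_ids = NULL, n_folds = 5, cost = 1,
                        seed = NULL, in_fold_rank_n = NULL,
                        max_tries = 10) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (is.null(subject_ids)) subject_ids <- seq_len(nrow(X))
  if (!is.null(feature_subset)) X <- X[, feature_subset, drop = FALSE]
  run <- function() {
    for (try in seq_len(max_tries)) {
      folds <- make_folds(labels, subject_ids, n_folds)
      used <- sort(unique(folds))   # folds may be empty when subjects < k
      ok <- length(used) >= 2 && all(vapply(used, function(f)
        length(unique(labels[folds != f])) == 2, logical(1)))
      if (ok) break
      if (try == max_tries)
        stop("could not build folds with both classes in every training set")
    }
    acc <- vapply(used, function(f) {
      tr <- folds != f
      Xtr <- X[tr, , drop = FALSE]
      Xte <- X[!tr, , drop = FALSE]
      if (!is.null(in_fold_rank_n)) {
        rk <- rank_features(Xtr, labels[tr])
        keep <- rk$order[seq_len(min(in_fold_rank_n, ncol(Xtr)))]
        Xtr <- Xtr[, keep, drop = FALSE]
        Xte <- Xte[, keep, drop = FALSE]
      }
      mu <- colMeans(Xtr)
      sg <- apply(Xtr, 2, sd)
      sg[sg == 0 | !is.finite(sg)] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, `/`)
      Xte <- sweep(sweep(Xte, 2, mu), 2, sg, `/`)
      fit <- svm_fit(Xtr, labels[tr], cost = cost)
      mean(predict(fit, Xte) == labels[!tr])
    }, numeric(1))
    mean(acc)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Accuracy as a function of the number of features
#'
#' Replicates the incremental-feature classification study: features are
#' ranked once on the full matrix by |Pearson r| with the labels (note:
#' this full-matrix selection is what biases the matching permutation
#' null above chance), then for each feature count `n` the cross-validated
#' accuracy of the top-`n` features is recomputed `n_reps` times with
#' fresh subject-grouped fold partitions.
#'
#' @param X numeric matrix.
#' @param labels binary labels per row.
#' @param subject_ids one id per row (`NULL` = rows independent).
#' @param n_features_grid feature counts to evaluate (default
#'   `1..min(20, ncol)`).
#' @param n_reps repetitions per count (the full study used 2000; scale
#'   down for interactive use).
#' @param n_folds,cost,seed see [cv_accuracy()].
#' @return list of class `nirs_accuracy_curve`: `curve` (data.frame
#'   `n_features`, `mean`, `sd`), `ranking`, `r`, `peak`
#'   (`n_features`, `mean`, selected channel columns).
#' @export
accuracy_curve <- function(X, labels, subject_ids = NULL,
                           n_features_grid = NULL, n_reps = 100,
                           n_folds = 5, cost = 1, seed = 1) {
  X <- as.matrix(X)
  if (is.null(n_features_grid))
    n_features_grid <- seq_len(min(20, ncol(X)))
  if (max(n_features_grid) > ncol(X))
    stop("n_features_grid exceeds the number of columns")
  rk <- rank_features(X, labels)
  res <- lapply(n_features_grid, function(n) {
    subset <- rk$order[seq_len(n)]
    accs <- vapply(seq_len(n_reps), function(rep)
      cv_accuracy(X, labels, subset, subject_ids, n_folds, cost,
                  seed = derive_seed(seed, paste0("rep-", n, "-", rep))),
      numeric(1))
    c(mean = mean(accs), sd = sd(accs))
  })
  curve <- data.frame(n_features = n_features_grid,
                      mean = vapply(res, `[[`, 0, "mean"),
                      sd = vapply(res, `[[`, 0, "sd"))
  ipk <- which.max(curve$mean)
  structure(list(
    curve = curve, ranking = rk$order, r = rk$r,
    peak = list(n_features = curve$n_features[ipk], mean = curve$mean[ipk],
                channels = rk$order[seq_len(curve$n_features[ipk])])),
    class = "nirs_accuracy_curve")
}

#' Selection-in-the-loop permutation null
#'
#' For each permutation the labels are shuffled and the *entire* analysis
#' is repeated on the surrogate labels: feature ranking on the shuffled
#' labels (full-matrix, by default, exactly like the real analysis)
#' followed by cross-validated accuracy of the top-`n` features. Because
#' spuriously correlated features are re-selected on every shuffle, the
#' null mean exceeds 50% at small `n` and relaxes toward 50% as `n`
#' approaches the full feature count. `selection = "in_fold"` instead
#' nests the ranking within each training fold, which removes the
#' selection bias (an internal consistency check).
#'
#' @param X numeric matrix.
#' @param labels binary labels per row.
#' @param subject_ids one id per row (`NULL` = rows independent).
#' @param n_features_grid feature counts at which to evaluate the null.
#' @param n_perms number of label permutations (>= 50 recommended).
#' @param n_folds,cost,seed see [cv_accuracy()].
#' @param selection `"full"` (ranking on the full shuffled matrix,
#'   replicating the biased null) or `"in_fold"`.
#' @return list of class `nirs_permutation_null`: `null` (data.frame
#'   `n_features`, `mean`, `sd`) and `accuracies` (perms x counts
#'   matrix).
#' @export
permutation_null <- function(X, labels, subject_ids = NULL,
                             n_features_grid = 4, n_perms = 200,
                             n_folds = 5, cost = 1, seed = 1,
                             selection = c("full", "in_fold")) {
  selection <- match.arg(selection)
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (max(n_features_grid) > ncol(X))
    stop("n_features_grid exceeds the number of columns")
  acc <- matrix(NA_real_, n_perms, length(n_features_grid))
  for (p in seq_len(n_perms)) {
    acc[p, ] <- with_seed(derive_seed(seed, paste0("perm-", p)), {
      yp <- sample(labels)
      vapply(seq_along(n_features_grid), function(i) {
        n <- n_features_grid[i]
        if (selection == "in_fold") {
          cv_accuracy(X, yp, NULL, subject_ids, n_folds, cost,
                      seed = NULL, in_fold_rank_n = n)
        } else {
          rk <- rank_features(X, yp)
          cv_accuracy(X, yp, rk$order[seq_len(n)], subject_ids,
                      n_folds, cost, seed = NULL)
        }
      }, numeric(1))
    })
  }
  structure(list(
    null = data.frame(n_features = n_features_grid,
                      mean = colMeans(acc),
                      sd = apply(acc, 2, sd)),
    accuracies = acc), class = "nirs_permutation_null")
}

#' Motion-trace features per subject-episode
#'
#' Summarises the six accelerometer/gyroscope traces with the same
#' procedure as the hemodynamic features: window SD over 10 s windows,
#' averaged per episode. Used as a negative control: if motion artifacts
#' drove the hemodynamic classification, these features would classify
#' above chance too.
#'
#' @param cohort a `nirs_cohort`.
#' @param episodes episodes kept as rows.
#' @param window_s window length in seconds.
#' @return list: `values` (rows x 6), `row_meta` (`subject_id`, `group`,
#'   `episode`).
#' @export
motion_features <- function(cohort, episodes = c("task1", "task2"),
                            window_s = 10) {
  stopifnot(inherits(cohort, "nirs_cohort"))
  rows <- list(); meta <- list()
  for (rec in cohort$recordings) {
    win <- window_statistic(rec$motion, rec$fs, window_s, "sd")
    for (ep in episodes) {
      v <- episode_activation(win, NULL, rec$schedule, ep, rec$fs,
                              window_s, min_windows = 1)
      key <- paste(rec$subject_id, ep)
      rows[[key]] <- v
      meta[[key]] <- data.frame(subject_id = rec$subject_id,
                                group = rec$group, episode = ep,
                                stringsAsFactors = FALSE)
    }
  }
  values <- do.call(rbind, rows)
  colnames(values) <- colnames(cohort$recordings[[1]]$motion)
  row_meta <- do.call(rbind, meta)
  rownames(values) <- rownames(row_meta) <- NULL
  list(values = values, row_meta = row_meta)
}

#' Classification from motion traces only
#'
#' Cross-validated accuracy of a linear SVM given only the six
#' motion-trace features. With label-independent motion rates this sits
#' at chance, supporting the claim that motion artifacts do not carry the
#' class signal.
#'
#' @param cohort a `nirs_cohort`.
#' @param labels binary labels, one per (subject, episode) row in the
#'   order produced by [motion_features()]; alternatively the string
#'   `"skill"` to use the group labels.
#' @param episodes episodes kept as rows.
#' @param n_folds,cost,seed see [cv_accuracy()].
#' @return mean cross-validated accuracy.
#' @export
motion_only_classification <- function(cohort, labels = "skill",
                                       episodes = "task1", n_folds = 5,
                                       cost = 1, seed = 1) {
  mf <- motion_features(cohort, episodes)
  if (identical(labels, "skill")) labels <- mf$row_meta$group
  cv_accuracy(mf$values, labels, NULL, mf$row_meta$subject_id,
              n_folds, cost, seed = seed)
}
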