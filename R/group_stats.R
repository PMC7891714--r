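#' Within-group median split of task-load scores
#'
#' Dichotomises NASA-TLX mean scores into `"high"` / `"low"` using the
#' group median as cut-off, with separate cut-offs per group. Scores
#' strictly above the group median are `"high"`; ties at the median go
#' `"low"` (deterministic convention).
#'
#' @param scores numeric vector of mean scores.
#' @param groups optional grouping vector (same length); `NULL` = one
#'   group.
#' @return character vector of `"high"` / `"low"` labels.
#' @export
median_split <- function(scores, groups = NULL) {
  if (length(scores) == 0) stop("empty score vector")
  if (is.null(groups)) groups <- rep("all", length(scores))
  stopifnot(length(groups) == length(scores))
  out <- character(length(scores))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2)
      warning("group '", g, "' has fewer than 2 scores; ",
              "median split is degenerate (all labelled low)")
    out[idx] <- ifelse(scores[idx] > median(scores[idx]), "high", "low")
  }
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param a,b numeric samples (each of size >= 2).
#' @return list with `D` (statistic) and `p` (asymptotic two-sided
#'   p-value).
#' @export
ks_compare <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("both samples must have at least 2 values")
  res <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test on paired observations (normal
#' approximation with continuity correction); zero differences are
#' dropped. If every difference is zero the comparison is vacuous and
#' `p = 1` is returned with a warning.
#'
#' @param a,b equal-length numeric vectors, paired element-wise.
#' @return list with `W` (signed-rank statistic, sum of positive ranks)
#'   and `p`.
#' @export
wilcoxon_paired <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(list(W = 0, p = 1))
  }
  res <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                      correct = TRUE))
  list(W = unname(res$statistic), p = res$p.value)
}

#' Bonferroni significance flags
#'
#' Flags `p < alpha / k`, which bounds the family-wise false rejection
#' probability by `alpha` over `k` tests (here k = 16 by default: four
#' separation classes times two hemispheres).
#'
#' @param p numeric vector of p-values.
#' @param alpha family-wise error rate (default 0.05).
#' @param k number of tests in the family (default 16).
#' @return logical vector of significance flags.
#' @export
bonferroni <- function(p, alpha = 0.05, k = 16) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (k < 1) stop("k must be >= 1")
  p < alpha / k
}

#' Channel-wise group comparison over the 16 (class, hemisphere) cells
#'
#' Reproduces the descriptive box-plot comparisons: within each of the
#' 16 cells (4 separation classes x 2 hemispheres), channels are the
#' paired observations. For each channel the activation is averaged over
#' the rows of each side of the comparison (high vs low load within a
#' group, or student vs attending), and the paired channel values are
#' compared by Wilcoxon signed-rank (default) or Kolmogorov-Smirnov, with
#' Bonferroni control at `alpha / k`.
#'
#' @param features a `nirs_features`.
#' @param what `"skill"` (student v attending) or `"load"` (high v low
#'   within one group).
#' @param group for `what = "load"`: which group to compare within.
#' @param episode episode(s) to analyse: each yields its own block of
#'   8 (class, hemisphere) cells, so `c("task1", "task2")` gives the
#'   16-cell family matching the Bonferroni `k = 16`; `NULL` pools all
#'   rows into one block.
#' @param test `"wilcoxon"` or `"ks"`.
#' @param observations pairing unit. `"channels"` (default) replicates the
#'   descriptive figures: per channel, activations are averaged over the
#'   rows of each side and the paired channel values are compared
#'   (signed-rank). Because all channels of a cell share each subject's
#'   common activation fluctuation, this test is anti-conservative on
#'   null data; `"subjects"` instead averages each subject's activation
#'   over the cell's channels and compares the two independent subject
#'   samples (rank-sum), which is calibrated and is what the
#'   planted/zero-effect recovery checks use.
#' @param alpha,k Bonferroni parameters.
#' @return data.frame of class `nirs_comparison` with one row per cell:
#'   `class_cm`, `hemisphere`, `n_channels`, `statistic`, `p`,
#'   `significant`, plus the comparison descriptor as attribute
#'   `"comparison"`.
#' @export
compare_groups <- function(features, what = c("skill", "load"),
                           group = NULL, episode = "task1",
                           test = c("wilcoxon", "ks"),
                           observations = c("channels", "subjects"),
                           alpha = 0.05, k = 16) {
  what <- match.arg(what)
  test <- match.arg(test)
  observations <- match.arg(observations)
  stopifnot(inherits(features, "nirs_features"))
  if (length(episode) > 1) {
    blocks <- lapply(episode, function(ep) {
      b <- compare_groups(features, what, group, ep, test, observations,
                          alpha, k)
      cbind(episode = ep, as.data.frame(b))
    })
    out <- do.call(rbind, blocks)
    attr(out, "comparison") <- attr(blocks[[1]], "comparison")
    class(out) <- c("nirs_comparison", "data.frame")
    return(out)
  }
  rm <- features$row_meta
  keep <- if (is.null(episode)) rep(TRUE, nrow(rm)) else rm$episode == episode
  if (what == "load") {
    if (is.null(group)) stop("'group' is required for the load comparison")
    keep <- keep & rm$group == group
    side_a <- keep & rm$load_label == "high"
    side_b <- keep & rm$load_label == "low"
    desc <- paste0("high-v-low TLX within ", group)
  } else {
    side_a <- keep & rm$group == "student"
    side_b <- keep & rm$group == "attending"
    desc <- "student-v-attending"
  }
  if (!any(side_a) || !any(side_b))
    stop("one side of the comparison has no rows")
  cm <- features$col_meta
  cells <- expand.grid(class_cm = sort(unique(cm$class_cm)),
                       hemisphere = c("L", "R"),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    ch <- which(cm$class_cm == cells$class_cm[i] &
                cm$hemisphere == cells$hemisphere[i])
    if (length(ch) < 2)
      return(data.frame(cells[i, ], n_channels = length(ch),
                        statistic = NA_real_, p = NA_real_,
                        delta = NA_real_))
    if (observations == "channels") {
      va <- colMeans(features$values[side_a, ch, drop = FALSE])
      vb <- colMeans(features$values[side_b, ch, drop = FALSE])
      r <- if (test == "wilcoxon") {
        w <- wilcoxon_paired(va, vb); list(stat = w$W, p = w$p)
      } else {
        kk <- ks_compare(va, vb); list(stat = kk$D, p = kk$p)
      }
    } else {
      va <- rowMeans(features$values[side_a, ch, drop = FALSE])
      vb <- rowMeans(features$values[side_b, ch, drop = FALSE])
      r <- if (test == "wilcoxon") {
        w <- suppressWarnings(wilcox.test(va, vb, exact = FALSE,
                                          correct = TRUE))
        list(stat = unname(w$statistic), p = w$p.value)
      } else {
        kk <- ks_compare(va, vb); list(stat = kk$D, p = kk$p)
      }
    }
    data.frame(cells[i, ], n_channels = length(ch),
               statistic = r$stat, p = r$p,
               delta = mean(va) - mean(vb))
  })
  out <- do.call(rbind, res)
  out$significant <- !is.na(out$p) & bonferroni(out$p, alpha, k)
  attr(out, "comparison") <- desc
  class(out) <- c("nirs_comparison", "data.frame")
  out
}

# ---- Delaunay triangulation (Bowyer-Watson) for topographic mapping ----

circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)  # centre and squared radius
}

delaunay <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points")
  # super-triangle enclosing all points
  span <- max(apply(pts, 2, function(v) diff(range(v))), 1e-9)
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  sup <- rbind(c(cx - 30 * span, cy - 10 * span),
               c(cx + 30 * span, cy - 10 * span),
               c(cx, cy + 30 * span))
  P <- rbind(pts, sup)
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  for (ip in seq_len(n)) {
    p <- P[ip, ]
    bad <- logical(length(tris))
    for (it in seq_along(tris)) {
      cc <- circumcircle(P[tris[[it]][1], ], P[tris[[it]][2], ],
                         P[tris[[it]][3], ])
      bad[it] <- !is.null(cc) &&
        ((p[1] - cc[1])^2 + (p[2] - cc[2])^2) <= cc[3] * (1 + 1e-12)
    }
    # boundary of the cavity: edges of bad triangles not shared by two
    edges <- do.call(rbind, lapply(tris[bad], function(tr)
      rbind(sort(tr[1:2]), sort(tr[2:3]), sort(tr[c(1, 3)]))))
    tris <- tris[!bad]
    if (is.null(edges)) next
    key <- paste(edges[, 1], edges[, 2])
    uniq <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    for (ie in seq_len(nrow(uniq)))
      tris[[length(tris) + 1L]] <- c(uniq[ie, 1], uniq[ie, 2], ip)
  }
  tris <- Filter(function(tr) all(tr <= n), tris)
  if (length(tris) == 0) stop("all points are collinear; cannot triangulate")
  do.call(rbind, tris)
}

#' Topographic interpolation of channel activations
#'
#' Piecewise-linear (barycentric) interpolation of per-channel activation
#' values over the channel midpoints, evaluated on a regular grid.
#' Grid points outside the convex hull of the midpoints are `NA`,
#' mimicking the masked continuous activation fields of topographic
#' plots. Within each triangle the field is linear, so interpolated
#' values are bounded by the input range and exact at the channel
#' midpoints.
#'
#' @param values numeric vector, one activation per channel.
#' @param layout a `nirs_layout` (uses `x_cm`, `y_cm`); subset it first to
#'   map a single separation class.
#' @param grid_resolution number of grid points per axis.
#' @return list with `x`, `y` (grid axes) and `z`
#'   (`grid_resolution x grid_resolution` matrix, `NA` outside the hull).
#' @export
topographic_map <- function(values, layout, grid_resolution = 60) {
  pts <- cbind(layout$x_cm, layout$y_cm)
  if (nrow(pts) < 3) stop("need at least 3 channels")
  if (length(values) != nrow(pts))
    stop("one value per channel required")
  tri <- delaunay(pts)
  gx <- seq(min(pts[, 1]), max(pts[, 1]), length.out = grid_resolution)
  gy <- seq(min(pts[, 2]), max(pts[, 2]), length.out = grid_resolution)
  z <- matrix(NA_real_, grid_resolution, grid_resolution)
  for (it in seq_len(nrow(tri))) {
    a <- pts[tri[it, 1], ]; b <- pts[tri[it, 2], ]; cc <- pts[tri[it, 3], ]
    det <- (b[2] - cc[2]) * (a[1] - cc[1]) + (cc[1] - b[1]) * (a[2] - cc[2])
    if (abs(det) < 1e-12) next
    xi <- which(gx >= min(a[1], b[1], cc[1]) - 1e-9 &
                gx <= max(a[1], b[1], cc[1]) + 1e-9)
    yi <- which(gy >= min(a[2], b[2], cc[2]) - 1e-9 &
                gy <= max(a[2], b[2], cc[2]) + 1e-9)
    for (i in xi) for (j in yi) {
      l1 <- ((b[2] - cc[2]) * (gx[i] - cc[1]) +
             (cc[1] - b[1]) * (gy[j] - cc[2])) / det
      l2 <- ((cc[2] - a[2]) * (gx[i] - cc[1]) +
             (a[1] - cc[1]) * (gy[j] - cc[2])) / det
      l3 <- 1 - l1 - l2
      if (l1 >= -1e-9 && l2 >= -1e-9 && l3 >= -1e-9)
        z[i, j] <- l1 * values[tri[it, 1]] + l2 * values[tri[it, 2]] +
          l3 * values[tri[it, 3]]
    }
  }
  list(x = gx, y = gy, z = z)
}
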