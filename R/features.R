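#' Per-window statistics of a time series
#'
#' Computes a summary statistic over non-overlapping windows of
#' `window_s` seconds. The standard deviation is the activation measure
#' used downstream (greater evoked hemodynamic response inflates the
#' within-window SD); mean, skewness and kurtosis are provided as
#' alternatives. A trailing partial window is dropped.
#'
#' @param x numeric vector or time x channel matrix.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds.
#' @param statistic one of `"sd"`, `"mean"`, `"skewness"`, `"kurtosis"`.
#' @return window x channel matrix of statistic values.
#' @export
window_statistic <- function(x, fs, window_s = 10,
                             statistic = c("sd", "mean", "skewness",
                                           "kurtosis")) {
  statistic <- match.arg(statistic)
  x <- as.matrix(x)
  wlen <- floor(window_s * fs)
  nw <- floor(nrow(x) / wlen)
  if (nw < 1) stop("no complete window fits in the series")
  out <- matrix(NA_real_, nw, ncol(x))
  stat_fun <- switch(statistic,
    sd = function(v) sd(v),
    mean = function(v) mean(v),
    skewness = function(v) {
      s <- sd(v); if (s == 0) return(0)
      mean((v - mean(v))^3) / s^3
    },
    kurtosis = function(v) {
      s <- sd(v); if (s == 0) return(0)
      mean((v - mean(v))^4) / s^4
    })
  for (ch in seq_len(ncol(x))) {
    m <- matrix(x[seq_len(nw * wlen), ch], wlen, nw)
    out[, ch] <- apply(m, 2, stat_fun)
  }
  out
}

# Index of windows lying fully inside an episode (window w spans samples
# [(w-1)*wlen+1, w*wlen], i.e. time [(w-1)*wlen, w*wlen] / fs).
windows_in_episode <- function(n_windows, fs, window_s, schedule, episode) {
  ep <- schedule$episodes[schedule$episodes$name == episode, ]
  if (nrow(ep) == 0)
    stop("episode '", episode, "' not present in the schedule")
  wlen <- floor(window_s * fs)
  w <- seq_len(n_windows)
  start_t <- (w - 1) * wlen / fs
  end_t <- w * wlen / fs
  w[start_t >= ep$start_s & end_t <= ep$end_s]
}

#' Episode-averaged activation per channel
#'
#' Averages retained window statistics over the windows lying fully
#' inside one episode. Channels with fewer than `min_windows` retained
#' windows in the episode are marked missing (`NA`).
#'
#' @param win_values window x channel matrix ([window_statistic()]).
#' @param mask logical window x channel retention mask
#'   ([detect_artifact_windows()]); `NULL` retains everything.
#' @param schedule a `nirs_schedule`.
#' @param episode episode name.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds.
#' @param min_windows minimum retained windows for a valid average.
#' @return numeric vector, one activation value per channel (`NA` =
#'   missing).
#' @export
episode_activation <- function(win_values, mask, schedule, episode,
                               fs, window_s = 10, min_windows = 3) {
  win_values <- as.matrix(win_values)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(win_values), ncol(win_values))
  mask <- as.matrix(mask)
  stopifnot(all(dim(mask) == dim(win_values)))
  idx <- windows_in_episode(nrow(win_values), fs, window_s, schedule, episode)
  vapply(seq_len(ncol(win_values)), function(ch) {
    keep <- idx[mask[idx, ch]]
    if (length(keep) < min_windows) NA_real_
    else mean(win_values[keep, ch])
  }, numeric(1))
}

#' Superficial signal regression
#'
#' Removes the scalp/skull hemodynamic component from long-separation
#' (3 / 3.35 cm) channels by regressing out the nearest short-separation
#' (1.5 cm) channel: for each long channel, `beta` is the least-squares
#' projection coefficient `<y_long, y_short> / <y_short, y_short>`
#' computed over the whole recording, and the residual
#' `y_long - beta * y_short` replaces the channel. Short and intermediate
#' channels are returned unchanged. A zero-variance regressor leaves the
#' channel untouched with a warning.
#'
#' @param hb time x channel matrix of (filtered) hemoglobin series.
#' @param layout a `nirs_layout` matching the matrix columns.
#' @return list with `hb` (matrix with long channels replaced by SSR
#'   residuals), `pairs` (the pairing table from [ssr_pairs()]) and
#'   `beta` (named per long channel).
#' @export
ssr <- function(hb, layout) {
  hb <- as.matrix(hb)
  stopifnot(ncol(hb) == nrow(layout))
  pairs <- ssr_pairs(layout)
  col_of <- match(pairs$long_id, layout$channel_id)
  col_short <- match(pairs$short_id, layout$channel_id)
  beta <- numeric(nrow(pairs))
  names(beta) <- pairs$long_id
  out <- hb
  for (i in seq_len(nrow(pairs))) {
    ys <- hb[, col_short[i]]
    den <- sum(ys * ys)
    if (den == 0) {
      warning("zero-variance regressor for channel ", pairs$long_id[i],
              "; channel left unchanged")
      beta[i] <- 0
      next
    }
    beta[i] <- sum(hb[, col_of[i]] * ys) / den
    out[, col_of[i]] <- hb[, col_of[i]] - beta[i] * ys
  }
  list(hb = out, pairs = pairs, beta = beta)
}

#' Episode activations for one preprocessed subject
#'
#' Convenience wrapper: window SD of (optionally SSR-corrected)
#' oxyhemoglobin, masked episode averaging, one row per requested episode.
#'
#' @param hb a `nirs_hb` ([preprocess_recording()]).
#' @param episodes character vector of episode names.
#' @param use_ssr apply [ssr()] to the filtered HbO before featurizing.
#' @param statistic window statistic, default `"sd"`.
#' @return episodes x channels matrix of activations (possibly `NA`).
#' @export
subject_activations <- function(hb, episodes = c("task1", "task2"),
                                use_ssr = FALSE, statistic = "sd") {
  stopifnot(inherits(hb, "nirs_hb"))
  series <- if (use_ssr) ssr(hb$hbo, hb$layout)$hb else hb$hbo
  win <- window_statistic(series, hb$fs, hb$window_s, statistic)
  acts <- vapply(episodes, function(ep)
    episode_activation(win, hb$window_mask, hb$schedule, ep,
                       hb$fs, hb$window_s),
    numeric(ncol(series)))
  t(acts)
}

#' Assemble the labelled activation feature matrix
#'
#' Builds the subject-episode x channel matrix of episode-averaged window
#' SDs with row metadata (subject, group, episode, NASA-TLX mean score and
#' the within-group median-split load label) and column metadata (channel
#' id, separation class, hemisphere, region). Missing entries (channels
#' with too few retained windows) are imputed with the column median over
#' non-missing rows; rows whose subject lacks a TLX record for the episode
#' are dropped with a warning.
#'
#' @param activations named list (by subject id) of episodes x channels
#'   activation matrices ([subject_activations()]).
#' @param tlx TLX data.frame with `subject_id`, `episode`, `mean_score`.
#' @param groups named character vector mapping subject id to group.
#' @param layout a `nirs_layout`.
#' @param episodes episodes to keep as rows.
#' @return list of class `nirs_features`: `values` (rows x channels),
#'   `row_meta`, `col_meta`, `imputed` (logical matrix marking imputed
#'   cells).
#' @export
build_feature_matrix <- function(activations, tlx, groups, layout,
                                 episodes = c("task1", "task2")) {
  rows <- list(); meta <- list()
  for (sid in names(activations)) {
    for (ep in intersect(episodes, rownames(activations[[sid]]))) {
      rec <- tlx[tlx$subject_id == sid & tlx$episode == ep, , drop = FALSE]
      if (nrow(rec) == 0) {
        warning("subject ", sid, " has no TLX record for ", ep,
                "; row dropped")
        next
      }
      rows[[paste(sid, ep)]] <- activations[[sid]][ep, ]
      meta[[paste(sid, ep)]] <- data.frame(
        subject_id = sid, group = unname(groups[sid]), episode = ep,
        tlx_mean = rec$mean_score[1], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no usable rows")
  values <- do.call(rbind, rows)
  row_meta <- do.call(rbind, meta)
  rownames(values) <- rownames(row_meta) <- NULL
  colnames(values) <- layout$channel_id

  imputed <- is.na(values)
  if (any(imputed)) {
    for (ch in which(colSums(imputed) > 0)) {
      med <- unname(median(unname(values[!imputed[, ch], ch])))
      if (!is.finite(med)) med <- 0  # whole column missing
      values[imputed[, ch], ch] <- med
    }
    message(sum(imputed), " missing activation value(s) imputed with ",
            "column medians")
  }
  row_meta$load_label <- median_split(row_meta$tlx_mean, row_meta$group)
  col_meta <- layout[, c("channel_id", "class_cm", "hemisphere", "region")]
  structure(list(values = values, row_meta = row_meta, col_meta = col_meta,
                 imputed = imputed), class = "nirs_features")
}

#' Full cohort-to-features pipeline
#'
#' Preprocesses every recording of a cohort and assembles the feature
#' matrix. Memory-friendly: recordings are processed one at a time.
#'
#' @param cohort a `nirs_cohort`.
#' @param config preprocessing configuration.
#' @param use_ssr apply superficial signal regression.
#' @param episodes episodes kept as rows.
#' @return a `nirs_features`.
#' @export
cohort_features <- function(cohort, config = default_preprocess_config(),
                            use_ssr = FALSE,
                            episodes = c("task1", "task2")) {
  stopifnot(inherits(cohort, "nirs_cohort"))
  acts <- lapply(cohort$recordings, function(rec) {
    hb <- preprocess_recording(rec, config)
    subject_activations(hb, episodes, use_ssr = use_ssr)
  })
  groups <- setNames(cohort$truth$group, cohort$truth$subject_id)
  build_feature_matrix(acts, cohort$tlx, groups, cohort$layout, episodes)
}
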