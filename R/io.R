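sig9 <- function(x) signif(x, 9)

#' Write a cohort to the plain-text interchange layout
#'
#' One directory per cohort: `layout.csv` (channel table),
#' `od_<id>.csv` (long format: `time_s`, `channel_id`, `wavelength_nm`,
#' `delta_od`), `motion_<id>.csv`, `tlx.csv`, `schedule.json` and
#' `ground_truth.json` (the per-subject latent parameter table; full
#' component traces are in-memory objects only and are not serialised).
#' All floating-point values are written with 9 significant digits.
#'
#' @param cohort a `nirs_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nirs_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lay <- as.data.frame(cohort$layout)
  lay$x_cm <- sig9(lay$x_cm); lay$y_cm <- sig9(lay$y_cm)
  data.table::fwrite(lay, file.path(dir, "layout.csv"))
  tlx <- cohort$tlx
  num <- vapply(tlx, is.numeric, TRUE)
  tlx[num] <- lapply(tlx[num], sig9)
  data.table::fwrite(tlx, file.path(dir, "tlx.csv"))
  truth <- cohort$truth
  num <- vapply(truth, is.numeric, TRUE)
  truth[num] <- lapply(truth[num], sig9)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  jsonlite::write_json(
    list(episodes = cohort$schedule$episodes, fs = cohort$schedule$fs),
    file.path(dir, "schedule.json"), dataframe = "rows", digits = NA,
    auto_unbox = TRUE)
  for (rec in cohort$recordings) {
    n <- dim(rec$od)[1]; C <- dim(rec$od)[2]
    tt <- sig9((seq_len(n) - 1) / rec$fs)
    long <- data.table::data.table(
      time_s = rep(tt, 2 * C),
      channel_id = rep(rep(cohort$layout$channel_id, each = n), 2),
      wavelength_nm = rep(c(780L, 850L), each = n * C),
      delta_od = sig9(c(rec$od[, , 1], rec$od[, , 2])))
    data.table::fwrite(long, file.path(dir, paste0("od_", rec$subject_id,
                                                   ".csv")))
    mot <- data.table::data.table(time_s = tt)
    for (cn in colnames(rec$motion)) mot[[cn]] <- sig9(rec$motion[, cn])
    data.table::fwrite(mot, file.path(dir, paste0("motion_", rec$subject_id,
                                                  ".csv")))
  }
  invisible(dir)
}

#' Read a cohort from the interchange layout
#'
#' Inverse of [write_cohort()] (lossless at 9 significant digits).
#' Recordings reference unknown channel ids, or missing mandatory files,
#' raise explicit schema errors.
#'
#' @param dir cohort directory.
#' @return a `nirs_cohort` (recordings carry no trace-level ground truth).
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("layout.csv", "tlx.csv", "schedule.json"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0)
    stop("missing cohort file(s): ", paste(basename(missing), collapse = ", "))
  lay <- as.data.frame(data.table::fread(file.path(dir, "layout.csv")))
  class(lay) <- c("nirs_layout", "data.frame")
  sj <- jsonlite::read_json(file.path(dir, "schedule.json"),
                            simplifyVector = TRUE)
  schedule <- structure(list(episodes = as.data.frame(sj$episodes),
                             fs = sj$fs), class = "nirs_schedule")
  tlx <- as.data.frame(data.table::fread(file.path(dir, "tlx.csv")))
  truth <- NULL
  if (file.exists(file.path(dir, "ground_truth.json")))
    truth <- as.data.frame(jsonlite::read_json(
      file.path(dir, "ground_truth.json"), simplifyVector = TRUE))
  od_files <- list.files(dir, pattern = "^od_.*\\.csv$")
  recordings <- list()
  for (f in od_files) {
    sid <- sub("^od_(.*)\\.csv$", "\\1", f)
    long <- data.table::fread(file.path(dir, f))
    bad <- setdiff(unique(long$channel_id), lay$channel_id)
    if (length(bad) > 0)
      stop("recording ", sid, " references unknown channel_id: ",
           paste(head(bad, 5), collapse = ", "))
    n <- length(unique(long$time_s))
    C <- nrow(lay)
    od <- array(NA_real_, dim = c(n, C, 2),
                dimnames = list(NULL, NULL, c("780", "850")))
    for (w in 1:2) {
      wl <- c(780L, 850L)[w]
      sub <- long[long$wavelength_nm == wl, ]
      od[, , w] <- matrix(sub$delta_od[
        order(match(sub$channel_id, lay$channel_id))], n, C)
    }
    mot <- as.data.frame(data.table::fread(
      file.path(dir, paste0("motion_", sid, ".csv"))))
    motion <- as.matrix(mot[, -1, drop = FALSE])
    grp <- if (!is.null(truth)) truth$group[truth$subject_id == sid][1]
           else NA_character_
    recordings[[sid]] <- structure(
      list(subject_id = sid, group = grp, od = od, motion = motion,
           layout = lay, schedule = schedule, fs = schedule$fs,
           profile = NULL, ground_truth = NULL),
      class = "nirs_recording")
  }
  structure(list(recordings = recordings, tlx = tlx, truth = truth,
                 layout = lay, schedule = schedule, study = NULL,
                 seed = NA_integer_), class = "nirs_cohort")
}

#' Write / read the labelled feature matrix as CSV
#'
#' `features.csv` carries the row metadata followed by one column per
#' channel id; the round-trip is lossless at 9 significant digits.
#'
#' @param features a `nirs_features`.
#' @param path CSV file path.
#' @param layout a `nirs_layout` (needed to rebuild column metadata).
#' @return `write_features`: `path` invisibly; `read_features`: a
#'   `nirs_features` (without the imputation map).
#' @export
write_features <- function(features, path) {
  df <- cbind(features$row_meta,
              as.data.frame(sig9(features$values)))
  names(df)[-seq_len(ncol(features$row_meta))] <-
    paste0("ch", features$col_meta$channel_id)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path, layout) {
  df <- as.data.frame(data.table::fread(path))
  meta_cols <- c("subject_id", "group", "episode", "tlx_mean", "load_label")
  values <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  colnames(values) <- sub("^ch", "", colnames(values))
  structure(list(values = values, row_meta = df[, meta_cols],
                 col_meta = layout[, c("channel_id", "class_cm",
                                       "hemisphere", "region")],
                 imputed = NULL), class = "nirs_features")
}

# Order-insensitive-free, content-stable hash of an R object (FNV-1a over
# its deparsed form); enough to fingerprint configs in manifests.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- ((bitwXor(h, b)) * 16777619) %% 4294967296
  sprintf("%08x", h)
}

write_manifest <- function(dir, config, seed, stages) {
  jsonlite::write_json(
    list(config_hash = config_hash(config), seed = seed,
         stages = stages, timestamp = format(Sys.time(), tz = "UTC")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}
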