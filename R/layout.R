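#' Build a deterministic multi-distance channel layout
#'
#' Constructs the channel table for a high-density prefrontal fNIRS montage
#' with four source-detector separation classes. The default reproduces the
#' device configuration used throughout the package: 204 channels, of which
#' 52 have 1.5 cm separation, 36 have 2.12 cm, 68 have 3 cm and 48 have
#' 3.35 cm, laid over both hemispheres of a flattened forehead plane.
#'
#' True optode geometry is not required by any downstream computation (only
#' the separation class, hemisphere side and midpoint proximity are used),
#' so midpoints are placed on a deterministic per-class grid spanning about
#' +/- 6 cm laterally and 6 cm vertically. The grid guarantees that every
#' long-separation (3 / 3.35 cm) channel has a short (1.5 cm) channel
#' within 3 cm of its midpoint, which makes superficial signal regression
#' ([ssr()]) feasible everywhere.
#'
#' @param class_counts named integer vector of channels per separation
#'   class; names must be the four class labels in cm
#'   (`"1.5"`, `"2.12"`, `"3"`, `"3.35"`). Default `c(52, 36, 68, 48)`.
#' @param half_width lateral half extent of the montage in cm.
#' @param height vertical extent in cm.
#' @return A `data.frame` of class `nirs_layout` with columns `channel_id`,
#'   `source_id` (1..24), `detector_id` (1..32), `class_cm`, `x_cm`,
#'   `y_cm`, `hemisphere` (`"L"`/`"R"`) and `region` (one of
#'   `dorsolateral`, `ventrolateral`, `medial`, `orbitofrontal`).
#' @examples
#' lay <- build_layout()
#' table(lay$class_cm)
#' @export
build_layout <- function(class_counts = c("1.5" = 52, "2.12" = 36,
                                          "3" = 68, "3.35" = 48),
                         half_width = 6, height = 6) {
  classes <- c(1.5, 2.12, 3, 3.35)
  if (length(class_counts) != 4L)
    stop("class_counts must give one count per separation class (4 values)")
  if (is.null(names(class_counts)))
    names(class_counts) <- as.character(classes)
  if (!setequal(names(class_counts), as.character(classes)))
    stop("class_counts names must be '1.5', '2.12', '3', '3.35'")
  class_counts <- class_counts[as.character(classes)]
  if (any(class_counts < 0) || any(class_counts != round(class_counts)))
    stop("invalid-config: class counts must be non-negative integers")
  if (sum(class_counts) <= 0)
    stop("invalid-config: class counts must sum to a positive total")

  rows <- vector("list", 0L)
  for (ci in seq_along(classes)) {
    n <- as.integer(class_counts[ci])
    if (n == 0L) next
    n_left <- ceiling(n / 2)
    n_right <- n - n_left
    # tiny per-class stagger so classes do not collide exactly on the grid
    off <- (ci - 1) * 0.11
    for (side in c("L", "R")) {
      nh <- if (side == "L") n_left else n_right
      if (nh == 0L) next
      ncx <- ceiling(sqrt(nh))
      ncy <- ceiling(nh / ncx)
      xs <- seq(0.4 + off, half_width - 0.4, length.out = max(ncx, 1L))
      ys <- seq(0.3 + off, height - 0.3, length.out = max(ncy, 1L))
      g <- expand.grid(x = xs, y = ys)[seq_len(nh), , drop = FALSE]
      sgn <- if (side == "L") -1 else 1
      rows[[length(rows) + 1L]] <- data.frame(
        class_cm = classes[ci], x_cm = sgn * g$x, y_cm = g$y,
        hemisphere = side, stringsAsFactors = FALSE)
    }
  }
  lay <- do.call(rbind, rows)
  # stable channel ordering: by class, then left-to-right, bottom-to-top
  lay <- lay[order(lay$class_cm, lay$x_cm, lay$y_cm), , drop = FALSE]
  n_tot <- nrow(lay)
  lay$channel_id <- seq_len(n_tot)
  lay$source_id <- ((lay$channel_id - 1L) %% 24L) + 1L
  lay$detector_id <- ((lay$channel_id * 7L - 1L) %% 32L) + 1L
  lay$region <- ifelse(abs(lay$x_cm) > 2.5,
                       ifelse(lay$y_cm > 3, "dorsolateral", "ventrolateral"),
                       ifelse(lay$y_cm > 3, "medial", "orbitofrontal"))
  lay <- lay[, c("channel_id", "source_id", "detector_id", "class_cm",
                 "x_cm", "y_cm", "hemisphere", "region")]
  rownames(lay) <- NULL
  class(lay) <- c("nirs_layout", "data.frame")
  lay
}

#' Check the structural invariants of a channel layout
#'
#' Verifies that no channel sits on the midline, that hemisphere labels
#' agree with the sign of `x_cm`, and (when both long and short channels
#' are present) that every 3 / 3.35 cm channel has a 1.5 cm channel within
#' `pair_radius_cm` of its midpoint.
#'
#' @param layout a `nirs_layout`.
#' @param pair_radius_cm maximum short-channel pairing distance in cm.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_layout <- function(layout, pair_radius_cm = 3) {
  stopifnot(inherits(layout, "nirs_layout") || is.data.frame(layout))
  need <- c("channel_id", "class_cm", "x_cm", "y_cm", "hemisphere")
  if (!all(need %in% names(layout)))
    stop("layout is missing columns: ",
         paste(setdiff(need, names(layout)), collapse = ", "))
  if (any(layout$x_cm == 0))
    stop("midline channels (x = 0) are forbidden")
  if (!all(layout$hemisphere == ifelse(layout$x_cm < 0, "L", "R")))
    stop("hemisphere labels inconsistent with x sign")
  if (anyDuplicated(layout$channel_id))
    stop("duplicate channel ids")
  long <- layout[layout$class_cm >= 3, , drop = FALSE]
  short <- layout[layout$class_cm == 1.5, , drop = FALSE]
  if (nrow(long) > 0 && nrow(short) > 0) {
    for (i in seq_len(nrow(long))) {
      d <- sqrt((short$x_cm - long$x_cm[i])^2 + (short$y_cm - long$y_cm[i])^2)
      if (min(d) > pair_radius_cm)
        stop("channel ", long$channel_id[i],
             " has no 1.5 cm channel within ", pair_radius_cm, " cm")
    }
  }
  invisible(TRUE)
}

#' Nearest short-separation channel for each long channel
#'
#' For every 3 / 3.35 cm channel, returns the 1.5 cm channel with nearest
#' midpoint (ties broken by lowest channel id). This pairing defines the
#' regressor used by [ssr()].
#'
#' @param layout a `nirs_layout`.
#' @return data.frame with columns `long_id`, `short_id`, `distance_cm`.
#' @export
ssr_pairs <- function(layout) {
  long <- layout[layout$class_cm >= 3, , drop = FALSE]
  short <- layout[layout$class_cm == 1.5, , drop = FALSE]
  if (nrow(short) == 0)
    stop("layout has no 1.5 cm channels to serve as regressors")
  short <- short[order(short$channel_id), , drop = FALSE]
  out <- lapply(seq_len(nrow(long)), function(i) {
    d <- sqrt((short$x_cm - long$x_cm[i])^2 + (short$y_cm - long$y_cm[i])^2)
    j <- which.min(d)  # which.min takes the first minimum = lowest id
    data.frame(long_id = long$channel_id[i], short_id = short$channel_id[j],
               distance_cm = d[j])
  })
  do.call(rbind, out)
}
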