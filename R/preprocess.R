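#' Default preprocessing configuration
#'
#' Differential pathlength factors (5.075 at 780 nm, 4.64 at 850 nm), the
#' extinction matrix, the 0.01-0.5 Hz analysis band, the 10 s artifact
#' window and the 4.5 MAD outlier multiplier.
#'
#' @return named list with `dpf`, `extinction`, `band`, `filter_order`,
#'   `window_s`, `mad_multiplier`.
#' @export
default_preprocess_config <- function() {
  list(dpf = default_dpf(),
       extinction = default_extinction_matrix(),
       band = c(0.01, 0.5),
       filter_order = 4,
       window_s = 10,
       mad_multiplier = 4.5)
}

poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' Analog prototype poles, lowpass-to-bandpass transform with the
#' pre-warped band edges, then the bilinear transform. `order` is the
#' prototype order, so the resulting transfer function has `2 * order`
#' poles (the usual convention of `butter(order, band)` designs).
#'
#' @param order prototype filter order (default 4).
#' @param low,high band edges in Hz.
#' @param fs sampling rate in Hz; must exceed `2 * high`.
#' @return list with numerator `b` and denominator `a` coefficients
#'   (`a[1] == 1`).
#' @export
butter_bandpass <- function(order = 4, low, high, fs) {
  if (low <= 0 || high <= low) stop("need 0 < low < high")
  if (fs <= 2 * high) stop("sampling rate must exceed twice the upper edge")
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # lowpass prototype -> bandpass: each pole splits in two
  half <- proto * bw / 2
  p_bp <- c(half + sqrt(half^2 - w0^2), half - sqrt(half^2 - w0^2))
  z_bp <- rep(complex(real = 0), order)
  k_bp <- bw^order
  # bilinear transform
  fs2 <- 2 * fs
  pd <- (fs2 + p_bp) / (fs2 - p_bp)
  zd <- c((fs2 + z_bp) / (fs2 - z_bp), rep(complex(real = -1), order))
  kd <- k_bp * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  b <- Re(kd * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  list(b = b / a[1], a = a / a[1])
}

# Steady-state filter initial conditions for a unit-step input, so that a
# constant signal produces its steady-state response from the first sample.
lfilter_zi <- function(b, a) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (n == 1) return(numeric(0))
  A <- rbind(-a[2:n], cbind(diag(1, n - 2), 0))
  if (n == 2) A <- matrix(-a[2], 1, 1)
  B <- b[2:n] - a[2:n] * b[1]
  drop(solve(diag(1, n - 1) - t(A), B))
}

#' Zero-phase forward-backward IIR filtering
#'
#' Applies the filter forward and backward with odd (reflected) end
#' padding and steady-state initial conditions, giving zero phase
#' distortion and squared magnitude response.
#'
#' @param b,a filter coefficients.
#' @param x numeric vector.
#' @param padlen number of reflected samples at each end.
#' @return filtered vector, same length as `x`.
#' @export
filtfilt <- function(b, a, x, padlen = 3 * (max(length(a), length(b)) - 1)) {
  n <- NROW(x)
  if (n <= padlen)
    stop("series too short for the requested padding (", n, " <= ", padlen, ")")
  m <- max(length(a), length(b))
  b <- c(b, rep(0, m - length(b)))
  a <- c(a, rep(0, m - length(a)))
  zi <- lfilter_zi(b, a)
  out <- cpp_filtfilt_mat(b, a, as.matrix(x), zi, as.integer(padlen))
  if (is.matrix(x)) out else drop(out)
}

#' Band-pass filter hemoglobin time series
#'
#' Zero-phase Butterworth band-pass in the stated analysis band
#' (default 0.01-0.5 Hz), removing slow drift and the respiratory and
#' cardiac oscillations while preserving task-evoked dynamics and window
#' statistics (no phase distortion).
#'
#' @param x numeric vector, or time x channel matrix (filtered per column).
#' @param fs sampling rate in Hz.
#' @param band length-2 numeric, band edges in Hz.
#' @param order Butterworth prototype order per pass.
#' @return filtered object of the same shape.
#' @export
bandpass <- function(x, fs, band = c(0.01, 0.5), order = 4) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1])
    stop("band must be (low, high) with 0 < low < high")
  if (fs <= 2 * band[2]) stop("sampling rate must exceed twice the upper edge")
  coefs <- butter_bandpass(order, band[1], band[2], fs)
  ntaps <- length(coefs$a)
  nmin <- 3 * ntaps
  nr <- if (is.matrix(x)) nrow(x) else length(x)
  if (nr < nmin)
    stop("series too short to filter: ", nr, " samples < ", nmin,
         " (3 filter lengths)")
  filtfilt(coefs$b, coefs$a, x)
}

#' Flag motion-artifact windows by windowed standard deviation
#'
#' Splits each channel into non-overlapping windows of `window_s` seconds,
#' computes the standard deviation of each complete window, then the
#' median and the (raw, unscaled) median absolute deviation of those SDs.
#' A window is flagged as a motion artifact when its SD exceeds
#' `median + mad_multiplier * MAD`; only high-side excursions are flagged,
#' since unusually quiet windows are not artifacts. A trailing partial
#' window is ignored entirely. When the MAD is zero (degenerate
#' constant-variance channel) no window is flagged and a warning is
#' raised.
#'
#' @param x numeric vector or time x channel matrix.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 10).
#' @param mad_multiplier outlier threshold in MAD units (default 4.5).
#' @return logical window x channel matrix (vector input gives one
#'   column); `TRUE` means the window is retained.
#' @export
detect_artifact_windows <- function(x, fs, window_s = 10,
                                    mad_multiplier = 4.5) {
  if (window_s <= 0 || mad_multiplier <= 0)
    stop("window_s and mad_multiplier must be positive")
  x <- as.matrix(x)
  wlen <- floor(window_s * fs)
  nw <- floor(nrow(x) / wlen)
  if (nw < 3)
    stop("need at least 3 complete windows (", nw, " available)")
  keep <- matrix(TRUE, nw, ncol(x))
  degenerate <- FALSE
  for (ch in seq_len(ncol(x))) {
    m <- matrix(x[seq_len(nw * wlen), ch], wlen, nw)
    mu <- colMeans(m)
    sds <- sqrt(pmax(colSums(m * m) - wlen * mu^2, 0) / (wlen - 1))
    med <- median(sds)
    madv <- median(abs(sds - med))
    if (madv == 0) degenerate <- TRUE
    else keep[, ch] <- sds <= med + mad_multiplier * madv
  }
  if (degenerate)
    warning("zero MAD of window SDs in at least one channel; ",
            "no windows flagged there")
  keep
}

#' Preprocess a raw recording into hemoglobin time series
#'
#' Inverts the Beer-Lambert map per channel, band-pass filters both
#' chromophores, and computes the per-channel artifact window mask on the
#' filtered oxyhemoglobin (filtering precedes artifact detection).
#'
#' @param rec a `nirs_recording`.
#' @param config a preprocessing configuration
#'   ([default_preprocess_config()]).
#' @return list of class `nirs_hb` with `hbo`, `hbr` (time x channel, uM),
#'   `window_mask` (window x channel, `TRUE` = retained), `fs`,
#'   `schedule`, `layout`, `window_s`, `subject_id`, `group`.
#' @export
preprocess_recording <- function(rec, config = default_preprocess_config()) {
  stopifnot(inherits(rec, "nirs_recording"))
  if (config$band[1] <= 0 || config$band[2] <= config$band[1] ||
      config$band[2] >= rec$fs / 2)
    stop("invalid band: need 0 < low < high < fs/2")
  conc <- mbll_invert(rec$od, rec$layout$class_cm, config$dpf,
                      config$extinction)
  hbo <- bandpass(conc$hbo, rec$fs, config$band, config$filter_order)
  hbr <- bandpass(conc$hbr, rec$fs, config$band, config$filter_order)
  mask <- detect_artifact_windows(hbo, rec$fs, config$window_s,
                                  config$mad_multiplier)
  structure(list(hbo = hbo, hbr = hbr, window_mask = mask,
                 fs = rec$fs, schedule = rec$schedule, layout = rec$layout,
                 window_s = config$window_s, subject_id = rec$subject_id,
                 group = rec$group), class = "nirs_hb")
}
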