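# Frozen oracle: coefficients of the 0.01-0.5 Hz band-pass at 8.138 Hz,
# computed independently with scipy.signal.butter(4, [0.01, 0.5],
# btype="bandpass", fs=8.138) and frozen here.
SCIPY_B <- c(8.166114992733e-04, 0, -3.266445997093e-03, 0,
             4.899668995640e-03, 0, -3.266445997093e-03, 0,
             8.166114992733e-04)
SCIPY_A <- c(1, -7.003535749035e+00, 2.150053346494e+01,
             -3.780376731021e+01, 4.165024305556e+01, -2.944992310908e+01,
             1.305223574438e+01, -3.315288362273e+00, 3.695022657553e-01)

test_that("Butterworth design matches the independent reference", {
  co <- butter_bandpass(4, 0.01, 0.5, FS)
  expect_equal(co$b, SCIPY_B, tolerance = 1e-9)
  expect_equal(co$a, SCIPY_A, tolerance = 1e-9)
})

test_that("band-pass meets its frequency-response contract", {
  t <- seq(0, 300, by = 1 / FS)
  # DC removal: constant input is annihilated
  out <- bandpass(rep(2.5, length(t)), FS)
  expect_lt(max(abs(out)), 1e-6 * 2.5)
  # stop band: 1 Hz attenuated by >= 20 dB (RMS ratio <= 0.1)
  s1 <- sin(2 * pi * 1 * t)
  expect_lt(sd(bandpass(s1, FS)) / sd(s1), 0.1)
  # pass band: 0.1 Hz within 12% RMS (1 dB ripple)
  s01 <- sin(2 * pi * 0.1 * t)
  expect_lt(abs(sd(bandpass(s01, FS)) / sd(s01) - 1), 0.12)
})

test_that("band-pass rejects invalid inputs", {
  expect_error(bandpass(rnorm(10), FS), "too short")
  expect_error(bandpass(rnorm(1000), FS, band = c(0.5, 0.01)), "band")
  expect_error(bandpass(rnorm(1000), fs = 0.8, band = c(0.01, 0.5)),
               "twice the upper edge")
})

test_that("artifact rule reproduces a hand-computed MAD example", {
  wlen <- floor(10 * FS)  # 81 samples per window
  nw <- 12
  set.seed(5)
  x <- rnorm(nw * wlen)            # unit-variance noise
  x[wlen * 4 + 10] <- 30           # one 30-unit spike in window 5
  # independent oracle: direct computation of the rule
  sds <- vapply(seq_len(nw), function(w)
    sd(x[((w - 1) * wlen + 1):(w * wlen)]), numeric(1))
  med <- median(sds); madv <- median(abs(sds - med))
  expected <- sds <= med + 4.5 * madv
  expect_equal(which(!expected), 5L)
  mask <- detect_artifact_windows(x, FS)
  expect_equal(drop(mask), expected)
})

test_that("constant signals trigger the zero-MAD branch", {
  x <- rep(1, 400)
  expect_warning(mask <- detect_artifact_windows(x, FS), "zero MAD")
  expect_true(all(mask))
})

test_that("artifact mask is invariant under affine rescaling (property)", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(3000) * runif(1, 0.5, 5)
    x[sample(3000, 3)] <- 40
    m1 <- detect_artifact_windows(x, FS)
    m2 <- detect_artifact_windows(7.3 * x + 11, FS)
    expect_identical(m1, m2)
  }
})

test_that("too few windows is an error", {
  expect_error(detect_artifact_windows(rnorm(100), FS), "3 complete windows")
})

test_that("injected motion transients in simulated subjects are flagged", {
  # The spike criterion (>= 10x background SD) is evaluated in the domain
  # where the rule operates: the band-passed HbO series. The band-pass
  # removes most of a sharp transient's energy (that is part of its job),
  # so the raw OD spike amplitude is not the relevant scale.
  lay <- small_layout()
  sch <- short_schedule()
  physio <- default_physio_config()
  physio$motion$amp_meanlog <- log(0.05)
  cfg <- default_preprocess_config()
  hits <- 0; total <- 0
  for (s in 1:20) {
    prof <- make_subject_profile("M01", "student", seed = s)
    prof$motion_rate <- 1  # events/min: enough events, modest contamination
    rec <- simulate_subject(prof, lay, sch, physio, seed = 100 + s,
                            ground_truth = "traces")
    if (max(abs(rec$ground_truth$motion_od)) == 0) next
    hb <- preprocess_recording(rec, cfg)
    # motion component alone, pushed through the same linear pipeline
    mo_conc <- mbll_invert(rec$ground_truth$motion_od, lay$class_cm,
                           cfg$dpf, cfg$extinction)
    mo_hbo <- bandpass(mo_conc$hbo, rec$fs, cfg$band, cfg$filter_order)
    clean_sd <- apply(hb$hbo - mo_hbo, 2, sd)  # background scale
    wlen <- floor(hb$window_s * rec$fs)
    nw <- nrow(hb$window_mask)
    tau <- physio$motion$tau_s
    # per event and channel: a >= 10x-background transient counts as
    # detected when any window overlapping its support is flagged
    for (t0 in rec$ground_truth$motion_times) {
      idx <- max(1, floor(t0 * rec$fs)):min(nrow(mo_hbo),
                                            ceiling((t0 + 3 * tau) * rec$fs))
      ws <- unique(pmin((idx - 1) %/% wlen + 1L, nw))
      peak <- apply(abs(mo_hbo[idx, , drop = FALSE]), 2, max)
      big <- peak >= 10 * clean_sd
      if (any(big)) {
        total <- total + sum(big)
        flagged <- colSums(!hb$window_mask[ws, big, drop = FALSE]) > 0
        hits <- hits + sum(flagged)
      }
    }
  }
  expect_gt(total, 20)            # the scenario actually exercises the rule
  expect_gte(hits / total, 0.9)   # >= 90% sensitivity
})

test_that("preprocessing returns coherent hemoglobin series", {
  coh <- tiny_cohort()
  hb <- preprocess_recording(coh$recordings[[1]])
  expect_s3_class(hb, "nirs_hb")
  expect_equal(ncol(hb$hbo), nrow(coh$layout))
  expect_true(all(is.finite(hb$hbo)))
  n <- nrow(hb$hbo)
  expect_equal(nrow(hb$window_mask), floor(n / floor(10 * FS)))
  # band-passed output has (near-)zero mean per channel
  expect_lt(max(abs(colMeans(hb$hbo))), 0.05)
})
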