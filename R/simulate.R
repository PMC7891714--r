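#' Experimental protocol schedule
#'
#' The protocol alternates eyes-closed rest and laparoscopic-task episodes:
#' `rest1`, `task1`, `rest2`, `task2`. Rest episodes last exactly 60 s; a
#' task episode is capped at 6 minutes (the task is ended unfinished at
#' that point), so any task duration up to 360 s is valid.
#'
#' @param task1_s,task2_s task durations in seconds (<= 360).
#' @param rest_s rest duration in seconds (fixed at 60 by the protocol;
#'   changing it is allowed for reduced test scenes but warned about).
#' @param fs sampling rate in Hz (device default 8.138).
#' @return list of class `nirs_schedule` with `episodes` (data.frame
#'   `name`, `start_s`, `end_s`) and `fs`.
#' @export
protocol_schedule <- function(task1_s = 300, task2_s = 300, rest_s = 60,
                              fs = 8.138) {
  if (task1_s <= 0 || task2_s <= 0 || task1_s > 360 || task2_s > 360)
    stop("task episodes must be in (0, 360] seconds")
  if (rest_s <= 0) stop("rest episodes must be positive")
  if (fs <= 0) stop("sampling rate must be positive")
  starts <- cumsum(c(0, rest_s, task1_s, rest_s))
  ends <- starts + c(rest_s, task1_s, rest_s, task2_s)
  sch <- list(episodes = data.frame(
    name = c("rest1", "task1", "rest2", "task2"),
    start_s = starts, end_s = ends, stringsAsFactors = FALSE),
    fs = fs)
  class(sch) <- "nirs_schedule"
  sch
}

schedule_n_samples <- function(schedule) {
  floor(max(schedule$episodes$end_s) * schedule$fs)
}

#' Canonical hemodynamic response function
#'
#' Double-gamma HRF (positive lobe peaking near `peak_s`, small late
#' undershoot), normalised to unit peak. Used to turn the task boxcar into
#' the task-evoked cerebral component of the simulator.
#'
#' @param t time in seconds (vector).
#' @param peak_s time-to-peak of the positive lobe in seconds.
#' @return numeric vector of HRF values, max 1.
#' @export
canonical_hrf <- function(t, peak_s = 6) {
  h <- dgamma(t, shape = peak_s + 1, rate = 1) -
    dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Default physiological simulation parameters
#'
#' Encodes the stated world of the generator: per-class mixing weights for
#' the cerebral component (increasing with separation: deeper channels see
#' more cortex) and the superficial component (decreasing with
#' separation), systemic oscillations at the Mayer (~0.1 Hz), respiratory
#' (~0.3 Hz) and cardiac (~1 Hz) frequencies, slow drift, measurement
#' noise, an HbR/HbO coupling ratio, and motion-transient parameters.
#'
#' Amplitudes are in uM of equivalent hemoglobin change; all oscillation
#' frequencies sit below the Nyquist frequency of the 8.138 Hz device.
#'
#' @return named list of parameters; see source for fields.
#' @export
default_physio_config <- function() {
  list(
    mixing = list(
      cerebral = c("1.5" = 0.05, "2.12" = 0.15, "3" = 0.50, "3.35" = 0.65),
      superficial = c("1.5" = 1.00, "2.12" = 0.90, "3" = 0.70, "3.35" = 0.60)),
    oscillations = data.frame(
      freq_hz = c(0.1, 0.3, 1.0),          # Mayer, respiration, cardiac
      amp = c(0.50, 0.25, 0.15),           # uM
      freq_jitter = c(0.01, 0.03, 0.05)),
    drift_amp = 0.30,          # uM peak-to-peak scale of slow drift
    drift_freq_hz = 0.003,
    noise_sd = 0.10,           # uM, iid sample noise on HbO
    hbr_ratio = 1 / 3,         # HbR = -ratio * cerebral HbO + noise
    hbr_noise_sd = 0.05,
    hrf_peak_s = 6,
    task_event_rate_per_min = 6,  # sub-task hemodynamic events during tasks
    event_gain = 2,               # their amplitude relative to the boxcar lobe
    motion = list(
      amp_meanlog = log(0.02), # OD units of the spike peak
      amp_sdlog = 0.5,
      tau_s = 2,               # exponential decay constant
      shift_frac = 0.10,       # residual baseline shift after the spike
      trace_noise_sd = 0.01,   # accelerometer/gyro baseline noise
      trace_gain = 50))        # OD-to-sensor-unit scale of motion bumps
}

#' Default cohort-level study configuration
#'
#' Group sizes and planted effects for the synthetic cohort: 17 students
#' and 11 attending surgeons; students have a higher mean task-evoked
#' cerebral amplitude than attendings, with an additional left-hemisphere
#' multiplier in students only; the latent task load couples to cerebral
#' amplitude positively in students and negatively in attendings
#' (expertise reversal); superficial amplitudes are group-independent by
#' default but can be made group- or load-dependent for planted-effect
#' experiments.
#'
#' @return named list; see source for fields and units.
#' @export
default_study_config <- function() {
  list(
    n_students = 17, n_attendings = 11,
    student_amp = 1.0, attending_amp = 0.5,   # uM mean cerebral response
    student_left_mult = 1.3, attending_left_mult = 1.0,
    region_mult = c(dorsolateral = 1.2, ventrolateral = 1.1,
                    medial = 0.9, orbitofrontal = 0.8),
    amp_load_link = 0.3,     # amplitude ~ exp(link * sign * latent_load)
    amp_subject_sd = 0.2,    # lognormal between-subject amplitude spread
    superficial_amp_student = 1.0, superficial_amp_attending = 1.0,
    motion_rate_per_min = 0.5,
    tlx_link = list(intercept = 10.5, slope = 3, noise_sd = 1.5),
    schedule = list(task1_s = 300, task2_s = 300, rest_s = 60, fs = 8.138),
    layout_counts = NULL,    # NULL = full 204-channel default layout
    physio = NULL)           # NULL = default_physio_config()
}

#' Construct a subject profile
#'
#' Draws the per-subject latent quantities (latent load, cerebral
#' amplitude per region and hemisphere, superficial amplitude, motion
#' rate) from the cohort-level study configuration. The cerebral amplitude
#' is `group_amp * region_mult * hemi_mult * exp(link * sign * latent +
#' subject_noise)`, where `sign` is +1 for students and -1 for attendings,
#' so that across a cohort the NASA-TLX mean score correlates positively
#' with activation in students and negatively in attendings.
#'
#' @param subject_id character id.
#' @param group `"student"` or `"attending"`.
#' @param study study configuration list ([default_study_config()]).
#' @param seed integer seed for the subject's profile draw.
#' @return list of class `nirs_profile`.
#' @export
make_subject_profile <- function(subject_id, group,
                                 study = default_study_config(), seed = 1) {
  group <- match.arg(group, c("student", "attending"))
  with_seed(seed, {
    latent <- rnorm(1)
    subj_noise <- rnorm(1, 0, study$amp_subject_sd)
    sign <- if (group == "student") 1 else -1
    base <- if (group == "student") study$student_amp else study$attending_amp
    left_mult <- if (group == "student") study$student_left_mult
                 else study$attending_left_mult
    amp_scale <- exp(study$amp_load_link * sign * latent + subj_noise)
    regions <- c("dorsolateral", "ventrolateral", "medial", "orbitofrontal")
    A <- outer(study$region_mult[regions],
               c(L = left_mult, R = 1)) * base * amp_scale
    sup <- if (group == "student") study$superficial_amp_student
           else study$superficial_amp_attending
    mrate <- study$motion_rate_per_min
    if (length(mrate) > 1) mrate <- mrate[[group]]   # group-dependent rate
    structure(list(
      subject_id = subject_id, group = group, latent_load = latent,
      cerebral_amplitude = A, superficial_amplitude = sup,
      motion_rate = mrate,
      tlx_link_sign = sign), class = "nirs_profile")
  })
}

#' Simulate one subject's raw recording
#'
#' Generates a two-wavelength optical-density recording over the full
#' protocol. Per channel, the oxyhemoglobin change is
#' `w_c(class) * A(region, hemi) * x(t) + w_s(class) * s_sup(t) +
#' drift(t) + noise(t)`. The task regressor `x(t)` is the task boxcar
#' convolved with the canonical HRF plus an HRF-convolved train of
#' task-locked sub-events (Poisson arrivals during the task); the event
#' term makes the within-window SD of the evoked response scale with the
#' amplitude `A`, without which the activation measure used downstream
#' would be blind to `A` during the near-constant task plateau. `s_sup` is a
#' subject-shared sum of Mayer / respiratory / cardiac sinusoids with
#' frequency jitter; the deoxyhemoglobin change is `-rho *` (cerebral
#' part) plus its own noise. Optical densities follow by the forward
#' Beer-Lambert map ([forward_mbll()]); motion events (Poisson arrivals)
#' then inject exponential-decay spikes plus small baseline shifts into
#' the optical densities and simultaneous bumps into the six motion
#' traces.
#'
#' @param profile a `nirs_profile` ([make_subject_profile()]).
#' @param layout a `nirs_layout`.
#' @param schedule a `nirs_schedule`.
#' @param physio physiological parameter list ([default_physio_config()]).
#' @param seed integer seed; the draw is fully deterministic given it.
#' @param ground_truth `"traces"` stores full per-channel component time
#'   series (memory heavy), `"summary"` stores per-channel component SDs,
#'   `"none"` stores neither.
#' @return list of class `nirs_recording` with `od` (time x channel x 2),
#'   `motion` (time x 6), `layout`, `schedule`, `fs`, `subject_id`,
#'   `group`, and `ground_truth`.
#' @export
simulate_subject <- function(profile, layout, schedule,
                             physio = default_physio_config(), seed = 1,
                             ground_truth = c("summary", "traces", "none")) {
  ground_truth <- match.arg(ground_truth)
  if (!all(vapply(physio$oscillations$freq_hz, is.finite, TRUE)) ||
      any(physio$oscillations$freq_hz >= schedule$fs / 2))
    stop("oscillation frequencies must be finite and below Nyquist (",
         schedule$fs / 2, " Hz)")
  fs <- schedule$fs
  n <- schedule_n_samples(schedule)
  tt <- (seq_len(n) - 1) / fs
  C <- nrow(layout)
  cls <- as.character(layout$class_cm)
  w_c <- physio$mixing$cerebral[cls]
  w_s <- physio$mixing$superficial[cls]
  if (anyNA(w_c) || anyNA(w_s))
    stop("physio mixing weights missing for separation class: ",
         paste(unique(cls[is.na(w_c) | is.na(w_s)]), collapse = ", "))

  with_seed(seed, {
    # task regressor: boxcar over task episodes (x) canonical HRF, peak 1
    box <- numeric(n)
    for (i in seq_len(nrow(schedule$episodes))) {
      ep <- schedule$episodes[i, ]
      if (grepl("^task", ep$name))
        box[tt >= ep$start_s & tt < ep$end_s] <- 1
    }
    hrf_k <- canonical_hrf(seq(0, 32, by = 1 / fs), physio$hrf_peak_s)
    reg <- convolve(box, rev(hrf_k), type = "open")[seq_len(n)]
    if (max(reg) > 0) reg <- reg / max(reg)
    # task-locked sub-events: the evoked response fluctuates within the task
    # (discrete motor/cognitive events), which is what makes the window SD
    # sensitive to the activation amplitude
    ev_rate <- physio$task_event_rate_per_min
    if (!is.null(ev_rate) && ev_rate > 0 && physio$event_gain > 0 &&
        any(box > 0)) {
      task_idx <- which(box > 0)
      n_task_ev <- rpois(1, ev_rate * length(task_idx) / fs / 60)
      if (n_task_ev > 0) {
        impulses <- numeric(n)
        at <- sample(task_idx, n_task_ev, replace = TRUE)
        amps <- runif(n_task_ev, 0.5, 1.5)
        for (e in seq_len(n_task_ev))
          impulses[at[e]] <- impulses[at[e]] + amps[e]
        ev <- convolve(impulses, rev(hrf_k), type = "open")[seq_len(n)]
        if (max(abs(ev)) > 0) ev <- ev / max(abs(ev))
        reg <- reg + physio$event_gain * ev
      }
    }

    # per-channel cerebral amplitude from the profile's (region, hemi) grid
    A_ch <- profile$cerebral_amplitude[cbind(layout$region, layout$hemisphere)]
    cer <- outer(reg, w_c * A_ch)            # time x channel

    # shared superficial systemic signal with jittered oscillators
    osc <- physio$oscillations
    s_sup <- numeric(n)
    for (i in seq_len(nrow(osc))) {
      f <- osc$freq_hz[i] + rnorm(1, 0, osc$freq_jitter[i])
      s_sup <- s_sup + osc$amp[i] * sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
    }
    s_sup <- profile$superficial_amplitude * s_sup
    sup <- outer(s_sup, w_s)

    # per-channel slow drift: random linear trend + very slow sinusoid
    slope <- rnorm(C, 0, physio$drift_amp)
    ph <- runif(C, 0, 2 * pi)
    total_s <- max(schedule$episodes$end_s)
    drift <- outer(tt / total_s - 0.5, slope) +
      0.5 * physio$drift_amp * (physio$drift_amp > 0) *
      sin(outer(2 * pi * physio$drift_freq_hz * tt, rep(1, C)) +
          matrix(ph, n, C, byrow = TRUE))

    noise <- matrix(rnorm(n * C, 0, physio$noise_sd), n, C)
    noise_r <- matrix(rnorm(n * C, 0, physio$hbr_noise_sd), n, C)

    hbo <- cer + sup + drift + noise
    hbr <- -physio$hbr_ratio * cer + noise_r
    od <- forward_mbll(hbo, hbr, layout$class_cm)

    # motion transients: Poisson arrivals, lognormal amplitude, exponential
    # decay; mirrored into the accelerometer/gyroscope traces
    mo <- physio$motion
    motion <- matrix(rnorm(n * 6, 0, mo$trace_noise_sd), n, 6)
    colnames(motion) <- c("acc_x", "acc_y", "acc_z",
                          "gyr_x", "gyr_y", "gyr_z")
    motion_od <- array(0, dim = dim(od))
    n_ev <- rpois(1, profile$motion_rate * total_s / 60)
    ev_t <- numeric(0)
    if (n_ev > 0) {
      ev_t <- sort(runif(n_ev, 0, total_s))
      for (e in seq_len(n_ev)) {
        amp <- rlnorm(1, mo$amp_meanlog, mo$amp_sdlog) * sample(c(-1, 1), 1)
        i0 <- max(1L, min(n, floor(ev_t[e] * fs) + 1L))
        idx <- i0:n
        template <- amp * exp(-(tt[idx] - tt[i0]) / mo$tau_s) +
          amp * mo$shift_frac
        gain <- runif(C, 0.5, 1.5)
        for (w in 1:2)
          motion_od[idx, , w] <- motion_od[idx, , w] + outer(template, gain)
        ax_gain <- runif(6, 0.3, 1)
        motion[idx, ] <- motion[idx, ] +
          outer(abs(template) * mo$trace_gain, ax_gain)
      }
      od <- od + motion_od
    }

    gt <- switch(ground_truth,
      none = NULL,
      traces = list(cerebral = cer, superficial = sup, drift = drift,
                    noise = noise, noise_hbr = noise_r,
                    motion_od = motion_od, motion_times = ev_t,
                    hbr_ratio = physio$hbr_ratio,
                    amplitude = A_ch, regressor = reg),
      summary = list(
        cerebral_sd = col_sds(cer), superficial_sd = col_sds(sup),
        drift_sd = col_sds(drift), noise_sd = col_sds(noise),
        amplitude = A_ch, n_motion_events = n_ev))

    structure(list(
      subject_id = profile$subject_id, group = profile$group,
      od = od, motion = motion, layout = layout, schedule = schedule,
      fs = fs, profile = profile, ground_truth = gt),
      class = "nirs_recording")
  })
}

#' Generate a NASA-TLX record for one subject and episode
#'
#' The six subscale scores (mental, physical and temporal demand,
#' performance, effort, frustration) are an affine function of the
#' subject's latent load plus independent noise, clipped to the 1-20
#' response scale; the record carries their arithmetic mean. Because the
#' latent load also drives cerebral amplitude (with group-dependent sign),
#' cohort-level correlation between mean score and activation inherits the
#' profile's `tlx_link_sign`.
#'
#' @param profile a `nirs_profile`.
#' @param episode episode name (e.g. `"task1"`).
#' @param link list with `intercept`, `slope`, `noise_sd`.
#' @param seed integer seed.
#' @return one-row data.frame: subject_id, episode, the six subscales,
#'   `mean_score`.
#' @export
generate_tlx <- function(profile, episode,
                         link = default_study_config()$tlx_link, seed = 1) {
  if (!all(is.finite(c(link$intercept, link$slope, link$noise_sd))) ||
      link$noise_sd < 0)
    stop("invalid TLX link configuration")
  with_seed(seed, {
    sub <- link$intercept + link$slope * profile$latent_load +
      rnorm(6, 0, link$noise_sd)
    sub <- pmin(pmax(sub, 1), 20)
    out <- data.frame(subject_id = profile$subject_id, episode = episode,
                      mental = sub[1], physical = sub[2], temporal = sub[3],
                      performance = sub[4], effort = sub[5],
                      frustration = sub[6], mean_score = mean(sub),
                      stringsAsFactors = FALSE)
    out
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates one recording per subject over the whole protocol plus one
#' NASA-TLX record per subject per task episode, together with the
#' ground-truth table of latent parameters. Per-subject RNG streams are
#' derived from the root seed by a stable hash, so the cohort is
#' reproducible and individual subjects can be re-simulated in isolation.
#'
#' @param study study configuration ([default_study_config()]).
#' @param seed integer root seed.
#' @param ground_truth passed to [simulate_subject()].
#' @return list of class `nirs_cohort`: `recordings` (list of
#'   `nirs_recording`), `tlx` (data.frame), `truth` (per-subject latent
#'   parameter table), `layout`, `schedule`, `study`, `seed`.
#' @export
simulate_cohort <- function(study = default_study_config(), seed = 1,
                            ground_truth = c("summary", "traces", "none")) {
  ground_truth <- match.arg(ground_truth)
  if (study$n_students < 2 || study$n_attendings < 2)
    warning("group size < 2: downstream group statistics are degenerate")
  layout <- if (is.null(study$layout_counts)) build_layout()
            else build_layout(unlist(study$layout_counts))
  schedule <- do.call(protocol_schedule, study$schedule)
  physio <- if (is.null(study$physio)) default_physio_config() else study$physio

  ids <- c(sprintf("S%02d", seq_len(study$n_students)),
           sprintf("A%02d", seq_len(study$n_attendings)))
  groups <- rep(c("student", "attending"),
                c(study$n_students, study$n_attendings))
  recordings <- vector("list", length(ids))
  names(recordings) <- ids
  tlx <- list()
  truth <- list()
  for (i in seq_along(ids)) {
    prof <- make_subject_profile(ids[i], groups[i], study,
                                 seed = derive_seed(seed, paste0("prof-", ids[i])))
    recordings[[i]] <- simulate_subject(
      prof, layout, schedule, physio,
      seed = derive_seed(seed, paste0("rec-", ids[i])),
      ground_truth = ground_truth)
    for (ep in c("task1", "task2")) {
      tlx[[paste(ids[i], ep)]] <- generate_tlx(
        prof, ep, study$tlx_link,
        seed = derive_seed(seed, paste0("tlx-", ids[i], "-", ep)))
    }
    truth[[i]] <- data.frame(
      subject_id = ids[i], group = groups[i],
      latent_load = prof$latent_load,
      cerebral_amp_mean = mean(prof$cerebral_amplitude),
      superficial_amplitude = prof$superficial_amplitude,
      motion_rate = prof$motion_rate,
      tlx_link_sign = prof$tlx_link_sign, stringsAsFactors = FALSE)
  }
  tlx <- do.call(rbind, tlx)
  rownames(tlx) <- NULL
  truth <- do.call(rbind, truth)
  tlx$group <- groups[match(tlx$subject_id, ids)]
  structure(list(recordings = recordings, tlx = tlx, truth = truth,
                 layout = layout, schedule = schedule, study = study,
                 seed = seed), class = "nirs_cohort")
}
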