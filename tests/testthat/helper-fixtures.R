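# Shared reduced-scale fixtures. Scale-downs relative to the full study are
# problem-size reductions only (shorter tasks, proportionally thinned
# montage); every protocol constant (fs, band, window, MAD rule, DPFs,
# group structure) keeps its stated default.

FS <- 8.138

small_layout <- function() build_layout(c("1.5" = 8, "2.12" = 4,
                                          "3" = 10, "3.35" = 6))

half_layout_counts <- c("1.5" = 26, "2.12" = 18, "3" = 34, "3.35" = 24)

short_schedule <- function() protocol_schedule(task1_s = 120, task2_s = 120)

scaled_study <- function(layout_counts = half_layout_counts,
                         task_s = 120) {
  st <- default_study_config()
  st$schedule <- list(task1_s = task_s, task2_s = task_s, rest_s = 60,
                      fs = FS)
  st$layout_counts <- layout_counts
  st
}

# all group-dependent effects removed
zero_effect_study <- function(...) {
  st <- scaled_study(...)
  st$student_amp <- 0.75
  st$attending_amp <- 0.75
  st$student_left_mult <- 1
  st$attending_left_mult <- 1
  st$amp_load_link <- 0
  st
}

# skill signal planted ONLY in the superficial component
superficial_effect_study <- function(...) {
  st <- zero_effect_study(...)
  st$superficial_amp_student <- 1.5
  st$superficial_amp_attending <- 0.75
  st
}

# memoised tiny default cohort reused across test files
.fixture_env <- new.env()
tiny_cohort <- function() {
  if (is.null(.fixture_env$coh)) {
    st <- scaled_study(layout_counts = c("1.5" = 8, "2.12" = 4,
                                         "3" = 10, "3.35" = 6))
    st$n_students <- 5
    st$n_attendings <- 4
    .fixture_env$coh <- simulate_cohort(st, seed = 42)
  }
  .fixture_env$coh
}
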