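# Shared fixtures, built in code and memoized for the test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small 6-participant cohort + feature table for unit-level checks
small_cohort <- function() {
  memo("small_cohort", function() {
    coh <- generate_cohort(cohort_config(n_young = 2, n_middle = 2, n_old = 2,
                                         rate_hz = 30, duration_s = 120,
                                         seed = 101L))
    coh$features <- extract_feature_table(coh$recordings, coh$intervals)
    coh
  })
}

# 15-participant cohort at the experiment-grid scale
grid_cohort <- function() {
  memo("grid_cohort", function() {
    coh <- generate_cohort(cohort_config(n_young = 5, n_middle = 5, n_old = 5,
                                         rate_hz = 30, duration_s = 120,
                                         seed = 42L))
    coh$features <- extract_feature_table(coh$recordings, coh$intervals)
    coh
  })
}

# the full experiment-grid run used by structural and recovery checks
grid_experiment <- function() {
  memo("grid_experiment", function() {
    coh <- grid_cohort()
    run_experiment_grid(coh$features, coh$roster, seed = 7L)
  })
}

# enrollment fixture mirroring the study's accounting: 264 enrolled with
# 6 / 3 / 2 disjoint flag failures, 6 of the 253 included lacking valid
# calorimetry, and visit attendance 213x4 + 21x3 + 7x2 + 12x1
accounting_roster <- function() {
  n <- 264
  r <- data.frame(
    participant_id = sprintf("S%03d", seq_len(n)),
    age = rep(seq(25, 85, length.out = 24), length.out = n),
    sex = rep(c("F", "M"), length.out = n),
    has_start_end_times = TRUE, has_sufficient_activity_data = TRUE,
    has_demographics = TRUE, has_valid_ee = TRUE,
    visits_attended = 1L, stringsAsFactors = FALSE)
  r$has_start_end_times[1:6] <- FALSE
  r$has_sufficient_activity_data[7:9] <- FALSE
  r$has_demographics[10:11] <- FALSE
  inc <- which(r$has_start_end_times & r$has_sufficient_activity_data &
                 r$has_demographics)
  r$has_valid_ee[inc[1:6]] <- FALSE
  r$visits_attended[inc] <- rep(c(4L, 3L, 2L, 1L), times = c(213, 21, 7, 12))
  r$visits_attended[-inc] <- 1L
  r
}

# one full 60-s window slice with a pure tone riding on gravity
tone_slice <- function(freq_hz, amp = 0.3, rate_hz = 100, axis = "z",
                       window_s = 60) {
  n <- round(window_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  s <- list(x = rep(0, n), y = rep(0, n), z = rep(0, n), rate_hz = rate_hz)
  s[[axis]] <- 1 + amp * sin(2 * pi * freq_hz * t)
  s
}
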