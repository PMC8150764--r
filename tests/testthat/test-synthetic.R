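test_that("noiseless static profile yields a constant gravity signal", {
  prof <- activity_profile("still", "sedentary", met_mean = 1, met_sd = 0,
                           dom_freq_hz = 0.2, amp_g = 0,
                           gravity_axis = c(0, 0, 1), noise_sd_g = 0)
  sig <- generate_activity_signal(prof, 60, 100)
  expect_equal(nrow(sig), 6000)
  expect_equal(unname(sig[, "x"]), rep(0, 6000))
  expect_equal(unname(sig[, "y"]), rep(0, 6000))
  expect_equal(unname(sig[, "z"]), rep(1, 6000))
})

test_that("generated oscillation lands in the configured DFT bin", {
  prof <- activity_profile("walker", "locomotion", met_mean = 3.5,
                           dom_freq_hz = 1.5, amp_g = c(0, 0, 0.3),
                           gravity_axis = c(0, 0, 1), noise_sd_g = 0)
  set.seed(5)
  sig <- generate_activity_signal(prof, 60, 30)
  vm <- vector_magnitude(sig[, 1], sig[, 2], sig[, 3])
  mod <- bf_dft_mod(vm - mean(vm))    # independent naive DFT
  f <- seq_along(mod) * 30 / length(vm)
  expect_equal(f[which.max(mod)], 1.5)
})

test_that("signal generation and cohort generation are deterministic", {
  prof <- activity_profile("a", "lifestyle", dom_freq_hz = 1, amp_g = 0.1)
  set.seed(9); s1 <- generate_activity_signal(prof, 10, 30)
  set.seed(9); s2 <- generate_activity_signal(prof, 10, 30)
  expect_identical(s1, s2)

  cfg <- cohort_config(n_young = 1, n_middle = 1, n_old = 1, rate_hz = 30,
                       duration_s = 60, seed = 77L)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("signal generator rejects invalid durations and rates", {
  prof <- activity_profile("a", "lifestyle")
  expect_error(generate_activity_signal(prof, 0, 30), "duration")
  expect_error(generate_activity_signal(prof, 60, 50), "rate_hz")
  fast <- activity_profile("fast", "lifestyle", dom_freq_hz = 16)
  expect_error(generate_activity_signal(fast, 60, 30), "Nyquist")
})

test_that("cohort structure follows the configuration counts", {
  coh <- small_cohort()
  expect_equal(nrow(coh$roster), 6)
  expect_equal(nrow(coh$intervals), 6 * 33)
  expect_equal(length(coh$recordings), 6)
  expect_true(all(coh$roster$age >= 20 & coh$roster$age <= 89))
  expect_true(all(table(coh$intervals$participant_id) == 33))
  expect_error(cohort_config(catalog = list()), "empty")
})

test_that("drawn MET values track the configured activity means", {
  sed <- activity_profile("rest", "sedentary", met_mean = 1.0, met_sd = 0.05,
                          dom_freq_hz = 0.1, amp_g = 0.01)
  cfg <- cohort_config(n_young = 100, n_middle = 0, n_old = 0, rate_hz = 30,
                       duration_s = 60, catalog = list(rest = sed), seed = 5L)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$intervals), 100)
  expect_gt(mean(coh$intervals$met), 0.9)
  expect_lt(mean(coh$intervals$met), 1.1)
  expect_true(all(coh$intervals$met >= 0.1))
})

test_that("every generated MET is consistent with its configured intensity class", {
  coh <- grid_cohort()
  cat <- default_activity_catalog()
  configured <- vapply(cat, function(p) {
    as.character(intensity_from_met(p$met_mean))
  }, character(1))
  drawn <- as.character(intensity_from_met(coh$intervals$met))
  expect_equal(drawn, unname(configured[coh$intervals$activity_name]))
})

test_that("a cohort written to disk reads back through the ingest functions", {
  dir <- tempfile("cohort")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  coh <- small_cohort()
  write_cohort(coh, dir)
  roster <- read_roster(file.path(dir, "roster.csv"))
  expect_equal(roster$participant_id, coh$roster$participant_id)
  expect_true(all(roster$has_valid_ee))
  iv <- read_annotations(file.path(dir, "annotations.csv"))
  expect_equal(nrow(iv), nrow(coh$intervals))
  rec <- read_raw_recording(file.path(dir, "raw", "P001_V1.csv"),
                            declared_rate_hz = 30)
  expect_equal(length(rec$t), length(coh$recordings[[1]]$t))
  expect_equal(rec$x, coh$recordings[[1]]$x, tolerance = 1e-12)
})
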