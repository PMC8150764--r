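test_that("vector magnitude and vertical angle follow their closed forms", {
  expect_equal(vector_magnitude(0, 0, 1), 1)
  expect_equal(vector_magnitude(1, 2, 2), 3)
  expect_equal(vector_magnitude(0, 0, 0), 0)

  expect_equal(angle_to_vertical(c(0, 0), c(1, 1)), c(0, 0))
  expect_equal(angle_to_vertical(1, 1), 90)
  expect_equal(angle_to_vertical(0.5, 1), 30)
  expect_equal(angle_to_vertical(0, 0), 0)   # zero-magnitude guard
})

test_that("windows segment per interval with trailing data discarded", {
  n <- 700 * 100
  rec <- raw_recording("p", "v", 100, (0:(n - 1)) / 100,
                       rnorm(n, 0, 0.01), rnorm(n, 0, 0.01), rep(1, n))
  iv <- function(s, e) data.frame(activity_name = "a", start_s = s, end_s = e)
  expect_length(segment_windows(rec, iv(0, 600)), 10)
  expect_length(segment_windows(rec, iv(0, 59)), 0)
  sl <- segment_windows(rec, iv(10, 140))
  expect_length(sl, 2)
  expect_length(sl[[1]]$x, 6000)
  expect_equal(vapply(sl, `[[`, numeric(1), "window_index"), c(1, 2))
  expect_error(segment_windows(rec, iv(650, 720)), "outside")
})

test_that("time features handle constant and hand-computed inputs", {
  n <- 100
  f <- extract_time_features(rep(0, n), rep(0, n), rep(1, n))
  expect_equal(unname(f[c("mvm", "sdvm", "cv_vm", "min_vm", "max_vm")]),
               c(1, 0, 0, 1, 1))
  expect_equal(unname(f[c("mangle", "sdangle")]), c(0, 0))
  expect_equal(unname(f[c("third_moment_vm", "fourth_moment_vm",
                          "skewness_vm", "kurtosis_vm")]), c(0, 0, 0, 0))
  expect_equal(unname(f["cv_x"]), 0)  # zero-mean axis guard

  # hand-computed 4-sample case: z = {1, 1, 1, 5}
  # m3 = mean((v - 2)^3) = (3 * (-1) + 27) / 4 = 6; population m2 = 3
  f4 <- extract_time_features(rep(0, 4), rep(0, 4), c(1, 1, 1, 5))
  expect_equal(unname(f4["mean_z"]), 2)
  expect_equal(unname(f4["sd_z"]), 2)           # sample (n-1) estimator
  expect_equal(unname(f4["third_moment_z"]), 6)
  expect_equal(unname(f4["skewness_z"]), 6 / 3^1.5)
  expect_equal(unname(f4["third_moment_z"]),
               unname(bf_time_features(rep(0, 4), rep(0, 4),
                                       c(1, 1, 1, 5))["third_moment_z"]))
})

test_that("quantile features are ordered as order statistics demand", {
  set.seed(31)
  for (i in 1:20) {
    f <- extract_time_features(rnorm(200), rnorm(200), rnorm(200, 1))
    for (ch in c("vm", "x", "y", "z")) {
      lo <- f[paste0("lower_", ch, "_25")]
      hi <- f[paste0("upper_", ch, "_75")]
      expect_true(f[paste0("min_", ch)] <= lo)
      expect_true(lo <= hi)
      expect_true(hi <= f[paste0("max_", ch)])
    }
  }
})

test_that("spectral features recover tones and guard constant input", {
  inband <- tone_slice(1.5)   # 1.5 Hz is an exact bin (90/60)
  fr <- extract_freq_features(vector_magnitude(inband$x, inband$y, inband$z), 100)
  expect_equal(unname(fr["df"]), 1.5)
  expect_gte(fr["p625"], 0.99)
  expect_gte(fr["fpdf"], 0.99)

  out <- tone_slice(5)
  fr2 <- extract_freq_features(vector_magnitude(out$x, out$y, out$z), 100)
  expect_equal(unname(fr2["df"]), 5)
  expect_lte(fr2["p625"], 0.01)

  fr3 <- extract_freq_features(rep(1.02, 6000), 100)
  expect_equal(unname(fr3), c(0, 0, 0))
})

test_that("the feature map is a stable 49-key composition", {
  sl <- tone_slice(1.2, rate_hz = 100)
  f <- extract_features(sl)
  expect_length(f, 49)
  expect_identical(names(f), wpa_feature_names())
  expect_identical(f, extract_features(sl))   # deterministic
  vm <- vector_magnitude(sl$x, sl$y, sl$z)
  expect_identical(unname(f),
                   unname(c(extract_time_features(sl$x, sl$y, sl$z),
                            extract_freq_features(vm, 100))))
  short <- sl; short$x <- short$x[-1]
  expect_error(extract_features(short), "incomplete")

  # same key set and order at every supported rate
  for (r in c(30, 80)) {
    expect_identical(names(extract_features(tone_slice(1.2, rate_hz = r))),
                     wpa_feature_names())
  }
})

test_that("features scale as their physical dimensions dictate", {
  set.seed(17)
  sl <- tone_slice(0.9, rate_hz = 30)
  sl$x <- sl$x + rnorm(1800, 0.2, 0.05)
  sl$y <- sl$y + rnorm(1800, -0.1, 0.05)
  f1 <- extract_features(sl)
  c_ <- 2.5
  sl2 <- sl; sl2$x <- c_ * sl$x; sl2$y <- c_ * sl$y; sl2$z <- c_ * sl$z
  f2 <- extract_features(sl2)
  linear <- c("mvm", "sdvm", "min_vm", "max_vm", "lower_vm_25", "upper_vm_75",
              "mean_x", "sd_x", "min_x", "max_x")
  expect_equal(f2[linear], c_ * f1[linear], tolerance = 1e-12)
  cubic <- grep("^third_moment", names(f1), value = TRUE)
  quartic <- grep("^fourth_moment", names(f1), value = TRUE)
  expect_equal(f2[cubic], c_^3 * f1[cubic], tolerance = 1e-9)
  expect_equal(f2[quartic], c_^4 * f1[quartic], tolerance = 1e-9)
  invariant <- c("cv_x", "cv_y", "cv_z", "cv_vm", "mangle", "sdangle",
                 "skewness_vm", "kurtosis_vm", "p625", "df", "fpdf")
  expect_equal(f2[invariant], f1[invariant], tolerance = 1e-9)
})

test_that("spectral fractions stay within [0, 1] across random windows", {
  set.seed(23)
  for (i in 1:25) {
    vm <- 1 + stats::filter(rnorm(1800, 0, 0.2), rep(1 / 3, 3), circular = TRUE)
    fr <- extract_freq_features(as.numeric(vm), 30)
    expect_true(fr["p625"] >= 0 && fr["p625"] <= 1)
    expect_true(fr["fpdf"] >= 0 && fr["fpdf"] <= 1)
    expect_true(fr["df"] > 0 && fr["df"] <= 15)
  }
})
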