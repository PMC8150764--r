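#' Canonical feature order
#'
#' The 49 features computed per 60-s window, in their fixed canonical
#' order: 46 time-domain features followed by the 3 frequency-domain
#' features (`p625`, `df`, `fpdf`).
#'
#' @return Character vector of length 49.
#' @export
wpa_feature_names <- function() {
  ax <- c("x", "y", "z")
  c("mvm", "sdvm", "mangle", "sdangle",
    paste0("mean_", ax), paste0("sd_", ax), paste0("cv_", ax),
    paste0("min_", c("vm", ax)), paste0("max_", c("vm", ax)),
    paste0("lower_", c("vm", ax), "_25"), paste0("upper_", c("vm", ax), "_75"),
    paste0("third_moment_", c("vm", ax)), paste0("fourth_moment_", c("vm", ax)),
    paste0("skewness_", c("vm", ax)), paste0("kurtosis_", c("vm", ax)),
    "cv_vm", "p625", "df", "fpdf")
}

#' Per-sample vector magnitude
#'
#' @param x,y,z Acceleration per axis in g, equal length.
#' @return `sqrt(x^2 + y^2 + z^2)` per sample.
#' @export
vector_magnitude <- function(x, y, z) {
  if (length(y) != length(x) || length(z) != length(x)) {
    stop_input("x, y, z must have equal length")
  }
  sqrt(x^2 + y^2 + z^2)
}

#' Per-sample arm angle relative to the device x axis
#'
#' Angle between the x (vertical-on-device) axis and the acceleration
#' vector magnitude, in degrees: `asin(x / vm) * 180 / pi`, with the ratio
#' clamped to [-1, 1] against rounding and a zero angle emitted where
#' vm = 0.
#'
#' @param x Acceleration on the x axis, g.
#' @param vm Vector magnitude per sample, g.
#' @return Angles in degrees, same length.
#' @export
angle_to_vertical <- function(x, vm) {
  if (length(vm) != length(x)) stop_input("x and vm must have equal length")
  r <- ifelse(vm == 0, 0, pmin(1, pmax(-1, x / vm)))
  asin(r) * 180 / pi
}

# population central moment of order k
.cmoment <- function(v, k) mean((v - mean(v))^k)

# guarded coefficient of variation: 100 * sd / |mean|, 0 when the mean is
# numerically zero (per-axis means cross zero; an unbounded cv would poison
# the feature table)
.cv <- function(v) {
  m <- mean(v)
  if (abs(m) < 1e-6) return(0)
  100 * stats::sd(v) / abs(m)
}

.skewkurt <- function(v) {
  m2 <- .cmoment(v, 2)
  if (m2 < 1e-12) return(c(0, 0))   # constant-signal guard
  c(.cmoment(v, 3) / m2^1.5, .cmoment(v, 4) / m2^2)
}

#' Time-domain features of one window
#'
#' Computes the 46 time-domain window features: mean and SD of the vector
#' magnitude (VM) and of the arm angle; per-axis mean, SD and coefficient
#' of variation; min, max, 25% and 75% quantiles, third and fourth central
#' moments, skewness and kurtosis of VM and of each axis; and the CV of the
#' VM. SDs use the n-1 sample estimator; quantiles interpolate linearly
#' between order statistics; third/fourth moments are population central
#' moments and skewness/kurtosis are `m3/m2^1.5` and `m4/m2^2`
#' (non-excess), with a zero guard for constant signals.
#'
#' @param x,y,z One window's acceleration per axis, g.
#' @return Named numeric vector of length 46, in canonical order.
#' @export
extract_time_features <- function(x, y, z) {
  vm <- vector_magnitude(x, y, z)
  ang <- angle_to_vertical(x, vm)
  chans <- list(vm = vm, x = x, y = y, z = z)
  q <- lapply(chans, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
  sk <- lapply(chans, .skewkurt)
  mvm <- mean(vm)
  out <- c(
    mvm = mvm, sdvm = stats::sd(vm),
    mangle = mean(ang), sdangle = stats::sd(ang),
    mean_x = mean(x), mean_y = mean(y), mean_z = mean(z),
    sd_x = stats::sd(x), sd_y = stats::sd(y), sd_z = stats::sd(z),
    cv_x = .cv(x), cv_y = .cv(y), cv_z = .cv(z),
    min_vm = min(vm), min_x = min(x), min_y = min(y), min_z = min(z),
    max_vm = max(vm), max_x = max(x), max_y = max(y), max_z = max(z),
    lower_vm_25 = q$vm[1], lower_x_25 = q$x[1], lower_y_25 = q$y[1],
    lower_z_25 = q$z[1],
    upper_vm_75 = q$vm[2], upper_x_75 = q$x[2], upper_y_75 = q$y[2],
    upper_z_75 = q$z[2],
    third_moment_vm = .cmoment(vm, 3), third_moment_x = .cmoment(x, 3),
    third_moment_y = .cmoment(y, 3), third_moment_z = .cmoment(z, 3),
    fourth_moment_vm = .cmoment(vm, 4), fourth_moment_x = .cmoment(x, 4),
    fourth_moment_y = .cmoment(y, 4), fourth_moment_z = .cmoment(z, 4),
    skewness_vm = sk$vm[1], skewness_x = sk$x[1], skewness_y = sk$y[1],
    skewness_z = sk$z[1],
    kurtosis_vm = sk$vm[2], kurtosis_x = sk$x[2], kurtosis_y = sk$y[2],
    kurtosis_z = sk$z[2],
    cv_vm = if (mvm < 1e-6) 0 else 100 * stats::sd(vm) / mvm
  )
  if (!all(is.finite(out))) stop_input("non-finite time feature computed")
  out
}

#' Frequency-domain features of one window
#'
#' Discrete Fourier transform of the VM series with the DC bin excluded
#' (it encodes gravity, not movement). For a full 60-s window the spectral
#' bins sit at k/60 Hz, k = 1..N/2. Returns `p625`, the fraction of total
#' spectral modulus in the 0.6--2.5 Hz human-movement band (band edges
#' inclusive); `df`, the frequency of the largest modulus (smallest
#' frequency on ties); and `fpdf`, that bin's share of the total modulus.
#' A numerically zero spectrum (constant VM) yields (0, 0, 0).
#'
#' @param vm Vector-magnitude series of one full window.
#' @param rate_hz Sampling rate, Hz.
#' @return Named numeric vector `c(p625, df, fpdf)`.
#' @export
extract_freq_features <- function(vm, rate_hz) {
  n <- length(vm)
  mod <- Mod(stats::fft(vm))
  k <- seq_len(floor(n / 2))
  mod <- mod[k + 1]                 # DC bin excluded
  f <- k * rate_hz / n
  tot <- sum(mod)
  if (tot < 1e-9 * n) {
    return(c(p625 = 0, df = 0, fpdf = 0))
  }
  band <- f >= 0.6 - 1e-9 & f <= 2.5 + 1e-9
  i <- which.max(mod)               # which.max takes the first (lowest f) tie
  c(p625 = sum(mod[band]) / tot, df = f[i], fpdf = mod[i] / tot)
}

#' All 49 features of one window slice
#'
#' @param slice A window slice from [segment_windows()], or any list with
#'   elements `x`, `y`, `z` and `rate_hz` spanning a full window.
#' @param window_s Window length in seconds (60 by default).
#' @return Named numeric vector of length 49 in canonical order.
#' @export
extract_features <- function(slice, window_s = 60) {
  n_expect <- round(window_s * slice$rate_hz)
  if (length(slice$x) != n_expect) {
    stop_input("incomplete slice: expected ", n_expect, " samples, got ",
               length(slice$x))
  }
  vm <- vector_magnitude(slice$x, slice$y, slice$z)
  out <- c(extract_time_features(slice$x, slice$y, slice$z),
           extract_freq_features(vm, slice$rate_hz))
  stopifnot(identical(names(out), wpa_feature_names()))
  out
}

#' Segment a recording into non-overlapping 60-s window slices
#'
#' Windows are anchored at each labelled interval's start (never straddling
#' activities): an interval of length L yields `floor(L / window_s)`
#' consecutive slices of exactly `round(window_s * rate_hz)` samples;
#' trailing partial data are discarded.
#'
#' @param recording A [raw_recording()].
#' @param intervals Data frame of intervals for this recording
#'   (`activity_name`, `start_s`, `end_s`, optionally `met`).
#' @param window_s Window length in seconds.
#' @return List of slices; each slice is a list with the ids, activity
#'   name, `window_index`, `rate_hz`, `met` and the `x`, `y`, `z` samples.
#' @export
segment_windows <- function(recording, intervals, window_s = 60) {
  stopifnot(inherits(recording, "wpa_recording"))
  n <- length(recording$t)
  t0 <- recording$t[1]
  t_end <- recording$t[n] + 1 / recording$rate_hz
  w_n <- round(window_s * recording$rate_hz)
  out <- list()
  for (r in seq_len(nrow(intervals))) {
    iv <- intervals[r, ]
    if (iv$start_s < t0 - 1e-9 || iv$end_s > t_end + 1e-9) {
      stop_input("interval [", iv$start_s, ", ", iv$end_s,
                 "] outside recording extent")
    }
    k <- floor((iv$end_s - iv$start_s) / window_s)
    if (k < 1) next
    first <- which(recording$t >= iv$start_s - 1e-9)[1]
    for (j in seq_len(k)) {
      idx <- first + (j - 1) * w_n + seq_len(w_n) - 1
      if (max(idx) > n) break     # interval extent beyond recorded samples
      out[[length(out) + 1]] <- list(
        participant_id = recording$participant_id,
        visit_id = recording$visit_id,
        activity_name = iv$activity_name, window_index = j,
        rate_hz = recording$rate_hz,
        met = if ("met" %in% names(iv)) iv$met else NA_real_,
        x = recording$x[idx], y = recording$y[idx], z = recording$z[idx]
      )
    }
  }
  out
}

#' Build the window-level feature table for a cohort
#'
#' Segments every recording over its labelled intervals and extracts the
#' 49 features per window.
#'
#' @param recordings List of [raw_recording()]s.
#' @param intervals Interval annotations for all recordings.
#' @param window_s Window length in seconds.
#' @return Data frame: `participant_id`, `visit_id`, `activity_name`,
#'   `window_index`, `rate_hz`, `met`, then the 49 feature columns in
#'   canonical order.
#' @export
extract_feature_table <- function(recordings, intervals, window_s = 60) {
  rows <- list()
  for (rec in recordings) {
    iv <- intervals[intervals$participant_id == rec$participant_id &
                      intervals$visit_id == rec$visit_id, , drop = FALSE]
    if (nrow(iv) == 0) next
    for (sl in segment_windows(rec, iv, window_s)) {
      feats <- extract_features(sl, window_s)
      rows[[length(rows) + 1]] <- c(
        list(participant_id = sl$participant_id, visit_id = sl$visit_id,
             activity_name = sl$activity_name,
             window_index = sl$window_index, rate_hz = sl$rate_hz,
             met = sl$met),
        as.list(feats)
      )
    }
  }
  if (length(rows) == 0) stop_input("no complete windows found")
  do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
  }))
}
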