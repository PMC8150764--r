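#' Activity profile for the synthetic signal generator
#'
#' An activity profile describes how one scripted laboratory activity is
#' emulated on the wrist: a static gravity orientation, a single dominant
#' oscillation (frequency and per-axis amplitude) and additive Gaussian
#' sensor noise, plus the metabolic cost (mean and between-participant
#' spread, in METs) used to draw calorimetry labels.
#'
#' @param name Activity name (one of the scripted activity labels, or any
#'   string for custom profiles).
#' @param pa_type Physical-activity type: `"sedentary"`, `"locomotion"`,
#'   `"lifestyle"` or `"none"` (resistance/stretching activities that fit
#'   none of the three types).
#' @param met_mean,met_sd Mean and SD of the steady-state MET value drawn
#'   for each participant-interval. `met_mean` must be positive.
#' @param dom_freq_hz Dominant oscillation frequency in Hz; must lie below
#'   the Nyquist frequency of any sampling rate the profile is used with.
#' @param amp_g Oscillation amplitude in g; scalar (applied to all axes) or
#'   length-3 vector (x, y, z). Non-negative.
#' @param gravity_axis Unit 3-vector giving the static gravity orientation
#'   of the device during the activity.
#' @param noise_sd_g SD of i.i.d. Gaussian sensor noise per axis, in g.
#' @return An object of class `"wpa_profile"`.
#' @export
activity_profile <- function(name, pa_type = c("lifestyle", "sedentary", "locomotion", "none"),
                             met_mean = 2, met_sd = 0.1,
                             dom_freq_hz = 1, amp_g = 0.1,
                             gravity_axis = c(0, 0, 1), noise_sd_g = 0.01) {
  pa_type <- match.arg(pa_type)
  if (!is.numeric(met_mean) || met_mean <= 0) stop_input("met_mean must be > 0")
  if (met_sd < 0) stop_input("met_sd must be >= 0")
  if (dom_freq_hz < 0) stop_input("dom_freq_hz must be >= 0")
  if (length(amp_g) == 1) amp_g <- rep(amp_g, 3)
  if (length(amp_g) != 3 || any(amp_g < 0)) {
    stop_input("amp_g must be a non-negative scalar or length-3 vector")
  }
  if (length(gravity_axis) != 3) stop_input("gravity_axis must have length 3")
  nrm <- sqrt(sum(gravity_axis^2))
  if (!near(nrm, 1, 1e-9)) stop_input("gravity_axis must be a unit vector")
  if (noise_sd_g < 0) stop_input("noise_sd_g must be >= 0")
  structure(
    list(name = name, pa_type = pa_type, met_mean = met_mean, met_sd = met_sd,
         dom_freq_hz = dom_freq_hz, amp_g = as.numeric(amp_g),
         gravity_axis = as.numeric(gravity_axis), noise_sd_g = noise_sd_g),
    class = "wpa_profile"
  )
}

# Table of the 33 scripted activities: type and configured MET level.
# MET values are plausible defaults for each task (configuration, not
# measured ground truth); they are chosen so each activity sits well inside
# one default intensity class (low <= 1.5 < light <= 3.0 < moderate).
.activity_table <- function() {
  tab <- matrix(c(
    "leisure walk",                    "locomotion", "3.5",
    "rapid walk",                      "locomotion", "4.6",
    "light gardening",                 "lifestyle",  "2.30",
    "yard work",                       "lifestyle",  "3.8",
    "prepare serve meal",              "lifestyle",  "2.00",
    "digging",                         "lifestyle",  "4.2",
    "straightening up dusting",        "lifestyle",  "2.20",
    "washing dishes",                  "lifestyle",  "2.10",
    "unloading storing dishes",        "lifestyle",  "2.40",
    "walking at rpe 1",                "locomotion", "2.50",
    "personal care",                   "lifestyle",  "2.05",
    "dressing",                        "lifestyle",  "2.25",
    "walking at rpe 5",                "locomotion", "4.8",
    "sweeping",                        "lifestyle",  "2.50",
    "vacuuming",                       "lifestyle",  "2.60",
    "stair descent",                   "locomotion", "3.6",
    "stair ascent",                    "locomotion", "4.4",
    "trash removal",                   "lifestyle",  "2.45",
    "replacing sheets on a bed",       "lifestyle",  "2.35",
    "stretching yoga",                 "none",       "2.00",
    "mopping",                         "lifestyle",  "3.5",
    "light home maintenance",          "lifestyle",  "2.15",
    "computer work",                   "sedentary",  "1.20",
    "heavy lifting",                   "lifestyle",  "4.0",
    "shopping",                        "lifestyle",  "2.10",
    "ironing",                         "lifestyle",  "1.95",
    "laundry washing",                 "lifestyle",  "2.15",
    "strength exercise leg curl",      "none",       "2.60",
    "strength exercise chest press",   "none",       "2.50",
    "strength exercise leg extension", "none",       "2.70",
    "tv watching",                     "sedentary",  "1.10",
    "standing still",                  "sedentary",  "1.25",
    "washing windows",                 "lifestyle",  "2.60"
  ), ncol = 3, byrow = TRUE)
  data.frame(name = tab[, 1], pa_type = tab[, 2],
             met_mean = as.numeric(tab[, 3]), stringsAsFactors = FALSE)
}

#' Default catalog of the 33 scripted activities
#'
#' Returns one [activity_profile()] per scripted activity, as a list. Each
#' profile gets a distinct combination of dominant frequency, per-axis
#' amplitude and gravity orientation so the generated signals are separable
#' by activity and, more strongly, by activity type: sedentary activities
#' oscillate slowly (< 0.3 Hz) with tiny amplitude, locomotion in the
#' 1.4--2.4 Hz human movement band with large amplitude, lifestyle
#' activities in between. MET means and SDs place each activity inside one
#' default intensity class with a margin of at least four SDs.
#'
#' @param noise_sd_g Gaussian sensor-noise SD applied to every profile, in g.
#' @param met_sd Optional single MET SD overriding the per-class defaults
#'   (0.05 sedentary, 0.07 light, 0.12 moderate activities).
#' @return A named list of 33 `"wpa_profile"` objects.
#' @export
default_activity_catalog <- function(noise_sd_g = 0.01, met_sd = NULL) {
  tab <- .activity_table()
  n <- nrow(tab)
  # within-class indices drive distinct frequency/amplitude assignments
  idx_in_class <- stats::ave(seq_len(n), tab$pa_type, FUN = seq_along)
  n_in_class <- stats::ave(seq_len(n), tab$pa_type, FUN = length)
  spread <- ifelse(n_in_class == 1, 0.5, (idx_in_class - 1) / (n_in_class - 1))

  freq <- numeric(n); amp <- numeric(n)
  sed <- tab$pa_type == "sedentary"
  loc <- tab$pa_type == "locomotion"
  lif <- tab$pa_type == "lifestyle"
  non <- tab$pa_type == "none"
  freq[sed] <- 0.10 + 0.15 * spread[sed];  amp[sed] <- 0.008 + 0.012 * spread[sed]
  freq[loc] <- 1.40 + 1.00 * spread[loc];  amp[loc] <- 0.25 + 0.30 * spread[loc]
  freq[lif] <- 0.50 + 0.80 * spread[lif];  amp[lif] <- 0.06 + 0.16 * spread[lif]
  freq[non] <- 0.30 + 0.18 * spread[non];  amp[non] <- 0.08 + 0.06 * spread[non]

  sd_default <- ifelse(tab$met_mean <= 1.5, 0.05,
                       ifelse(tab$met_mean <= 3.0, 0.07, 0.12))
  if (!is.null(met_sd)) sd_default <- rep(met_sd, n)

  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    theta <- (20 + 2 * i) * pi / 180          # tilt from vertical
    phi <- ((i * 137.5) %% 360) * pi / 180    # golden-angle azimuth spread
    grav <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    grav <- grav / sqrt(sum(grav^2))
    pattern <- c(1, 0.35, 0.15)               # dominant axis cycles x, y, z
    rot <- ((seq_len(3) - 1 - (i %% 3)) %% 3) + 1
    profiles[[i]] <- activity_profile(
      name = tab$name[i], pa_type = tab$pa_type[i],
      met_mean = tab$met_mean[i], met_sd = sd_default[i],
      dom_freq_hz = freq[i], amp_g = amp[i] * pattern[rot],
      gravity_axis = grav, noise_sd_g = noise_sd_g
    )
  }
  names(profiles) <- tab$name
  profiles
}

#' Default activity-to-type mapping
#'
#' Named character vector mapping each of the 33 scripted activity names to
#' a physical-activity type. Walking and stair activities map to locomotion;
#' television watching, computer work and standing still to sedentary;
#' household chores to lifestyle; the three resistance exercises and
#' stretching yoga to `"none"` and are excluded from type recognition. This
#' mapping is configuration with sensible defaults, not a measured
#' assignment; pass any named vector with the same structure to override.
#'
#' @return Named character vector of length 33.
#' @export
default_type_mapping <- function() {
  tab <- .activity_table()
  stats::setNames(tab$pa_type, tab$name)
}

#' Intensity classification scheme
#'
#' MET cutoffs separating low, light and moderate intensity. A MET value m
#' is low when m <= `low_max`, light when `low_max` < m <= `light_max`, and
#' moderate above that (both upper bounds inclusive). Defaults follow the
#' conventional sedentary/light boundary of 1.5 METs and light/moderate
#' boundary of 3.0 METs.
#'
#' @param low_max Upper bound (inclusive) of the low class, METs.
#' @param light_max Upper bound (inclusive) of the light class, METs.
#' @return An object of class `"wpa_intensity_scheme"`.
#' @export
intensity_scheme <- function(low_max = 1.5, light_max = 3.0) {
  if (!(low_max > 0 && light_max > low_max)) {
    stop_input("need 0 < low_max < light_max")
  }
  structure(list(low_max = low_max, light_max = light_max),
            class = "wpa_intensity_scheme")
}
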