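#' Generate a synthetic tri-axial signal for one activity interval
#'
#' The signal model is deliberately simple: a static gravity component, one
#' sinusoid per axis at the profile's dominant frequency (shared random
#' phase offsets drawn per call, one per axis), and i.i.d. Gaussian noise.
#' This is the simplest generator that makes the amplitude, posture-angle
#' and spectral features of the extraction stage informative; it makes no
#' attempt at biomechanical realism (no gait harmonics, autocorrelated
#' noise or orientation drift).
#'
#' Randomness (phases, noise) comes from R's global RNG stream: seed the
#' stream, or use [generate_cohort()] which manages seeding, for
#' reproducible output.
#'
#' @param profile An [activity_profile()].
#' @param duration_s Positive duration in seconds.
#' @param rate_hz Sampling rate: 30, 80 or 100 Hz.
#' @return A numeric matrix with `round(duration_s * rate_hz)` rows and
#'   columns `x`, `y`, `z`, in g.
#' @export
generate_activity_signal <- function(profile, duration_s, rate_hz) {
  stopifnot(inherits(profile, "wpa_profile"))
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop_input("duration_s must be positive")
  }
  if (!rate_hz %in% c(30, 80, 100)) {
    stop_input("rate_hz must be one of 30, 80, 100")
  }
  if (profile$dom_freq_hz >= rate_hz / 2) {
    stop_input("dom_freq_hz must be below the Nyquist frequency rate_hz/2")
  }
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  phase <- stats::runif(3, 0, 2 * pi)
  sig <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (a in 1:3) {
    sig[, a] <- profile$gravity_axis[a] +
      profile$amp_g[a] * sin(2 * pi * profile$dom_freq_hz * t + phase[a])
    if (profile$noise_sd_g > 0) {
      sig[, a] <- sig[, a] + stats::rnorm(n, 0, profile$noise_sd_g)
    }
  }
  sig
}

#' Configuration for a synthetic cohort
#'
#' @param n_young,n_middle,n_old Participant counts per age group
#'   (ages drawn uniformly in 20--50, 51--70 and 71--89 years).
#' @param rate_hz Sampling rate for all recordings: 30, 80 or 100 Hz.
#' @param duration_s Duration of each activity interval in seconds; scalar
#'   or one value per catalog activity. At least one activity must last 60 s
#'   or more, otherwise no analysis window can be formed.
#' @param catalog List of [activity_profile()]s; defaults to the 33-activity
#'   [default_activity_catalog()].
#' @param seed Integer seed; a fixed seed makes [generate_cohort()] output
#'   fully reproducible.
#' @return An object of class `"wpa_cohort_config"`.
#' @export
cohort_config <- function(n_young = 2, n_middle = 2, n_old = 2,
                          rate_hz = 30, duration_s = 120,
                          catalog = default_activity_catalog(), seed = 1L) {
  if (length(catalog) == 0) stop_input("activity catalog must not be empty")
  if (!all(vapply(catalog, inherits, logical(1), "wpa_profile"))) {
    stop_input("catalog must be a list of activity_profile objects")
  }
  if (!rate_hz %in% c(30, 80, 100)) {
    stop_input("rate_hz must be one of 30, 80, 100")
  }
  duration_s <- rep_len(duration_s, length(catalog))
  if (!any(duration_s >= 60)) {
    stop_input("at least one activity must have duration_s >= 60")
  }
  if (any(c(n_young, n_middle, n_old) < 0)) stop_input("counts must be >= 0")
  structure(
    list(n_young = n_young, n_middle = n_middle, n_old = n_old,
         rate_hz = rate_hz, duration_s = duration_s, catalog = catalog,
         seed = as.integer(seed)),
    class = "wpa_cohort_config"
  )
}

#' Generate a labelled synthetic cohort
#'
#' Produces a participant roster, one recording per participant visit (all
#' catalog activities performed back to back in a single visit), and one
#' labelled interval per activity with a steady-state MET value drawn from
#' Normal(met_mean, met_sd) truncated below at 0.1 MET. Roster eligibility
#' flags are all `TRUE` by default; edit the returned roster to emulate
#' exclusions.
#'
#' @param config A [cohort_config()].
#' @return An object of class `"wpa_cohort"`: a list with elements `roster`
#'   (data frame), `recordings` (named list of recordings, see
#'   [raw_recording()]) and `intervals` (data frame of labelled activity
#'   intervals). The seed used is stored in attribute `"seed"`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "wpa_cohort_config"))
  n_tot <- config$n_young + config$n_middle + config$n_old
  if (n_tot == 0) stop_input("cohort has no participants")
  with_seed(config$seed, {
    ids <- sprintf("P%03d", seq_len(n_tot))
    group <- rep(c("young", "middle", "old"),
                 times = c(config$n_young, config$n_middle, config$n_old))
    age <- numeric(n_tot)
    age[group == "young"] <- stats::runif(sum(group == "young"), 20, 50)
    age[group == "middle"] <- stats::runif(sum(group == "middle"), 51, 70)
    age[group == "old"] <- stats::runif(sum(group == "old"), 71, 89)
    sex <- sample(c("F", "M"), n_tot, replace = TRUE, prob = c(0.62, 0.38))

    roster <- data.frame(
      participant_id = ids, age = age, sex = sex,
      has_start_end_times = TRUE, has_sufficient_activity_data = TRUE,
      has_demographics = TRUE, has_valid_ee = TRUE,
      visits_attended = 1L, stringsAsFactors = FALSE
    )

    cat <- config$catalog
    dur <- config$duration_s
    starts <- cumsum(c(0, dur[-length(dur)]))
    ends <- cumsum(dur)
    recordings <- vector("list", n_tot)
    iv <- vector("list", n_tot)
    for (p in seq_len(n_tot)) {
      sig <- do.call(rbind, lapply(seq_along(cat), function(i) {
        generate_activity_signal(cat[[i]], dur[i], config$rate_hz)
      }))
      n <- nrow(sig)
      recordings[[p]] <- raw_recording(
        participant_id = ids[p], visit_id = "V1", rate_hz = config$rate_hz,
        t = (seq_len(n) - 1) / config$rate_hz,
        x = sig[, "x"], y = sig[, "y"], z = sig[, "z"]
      )
      met <- stats::rnorm(length(cat),
                          vapply(cat, `[[`, numeric(1), "met_mean"),
                          vapply(cat, `[[`, numeric(1), "met_sd"))
      met[met < 0.1] <- 0.1
      iv[[p]] <- data.frame(
        participant_id = ids[p], visit_id = "V1",
        activity_name = vapply(cat, `[[`, character(1), "name"),
        start_s = starts, end_s = ends, met = met,
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
    names(recordings) <- paste(ids, "V1", sep = "_")
    structure(
      list(roster = roster, recordings = recordings,
           intervals = do.call(rbind, iv)),
      class = "wpa_cohort", seed = config$seed
    )
  })
}

#' Write a synthetic cohort to disk in the canonical text formats
#'
#' Writes one raw-recording CSV per participant visit (`raw/<id>_<visit>.csv`),
#' `annotations.csv` and `roster.csv`, plus a `metadata.csv` recording the
#' seed and sampling rate, so the files can be read back by the ingest
#' functions.
#'
#' @param cohort A `"wpa_cohort"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "wpa_cohort"))
  dir.create(file.path(dir, "raw"), recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings) {
    f <- file.path(dir, "raw",
                   paste0(rec$participant_id, "_", rec$visit_id, ".csv"))
    write_raw_recording(rec, f)
  }
  utils::write.csv(cohort$intervals, file.path(dir, "annotations.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$roster, file.path(dir, "roster.csv"),
                   row.names = FALSE, quote = FALSE)
  meta <- data.frame(key = c("seed", "rate_hz"),
                     value = c(attr(cohort, "seed"),
                               cohort$recordings[[1]]$rate_hz))
  utils::write.csv(meta, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
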