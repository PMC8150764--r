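#' Smooth a breath-by-breath VO2 series with a 30-s running average
#'
#' Centered moving average: the smoothed value at time t is the mean of all
#' samples within [t - 15, t + 15] seconds (inclusive); near the edges the
#' available partial window is used.
#'
#' @param time_s Sample times in seconds, increasing.
#' @param vo2 VO2 values (mL min^-1 kg^-1), same length.
#' @param width_s Window width in seconds (30 by default).
#' @return Smoothed series, same length.
#' @export
smooth_vo2 <- function(time_s, vo2, width_s = 30) {
  n <- length(time_s)
  if (n == 0) stop_input("empty VO2 series")
  if (length(vo2) != n) stop_input("time_s and vo2 must have equal length")
  if (n > 1 && any(diff(time_s) <= 0)) {
    stop_input("time_s must be strictly increasing")
  }
  half <- width_s / 2
  vapply(seq_len(n), function(i) {
    inwin <- time_s >= time_s[i] - half & time_s <= time_s[i] + half
    mean(vo2[inwin])
  }, numeric(1))
}

#' Convert steady-state VO2 to METs
#'
#' Divides by the conventional resting oxygen uptake of
#' 3.5 mL min^-1 kg^-1.
#'
#' @param vo2_ss Steady-state VO2, mL min^-1 kg^-1 (non-negative).
#' @return MET values.
#' @export
met_from_vo2 <- function(vo2_ss) {
  if (any(vo2_ss < 0)) stop_input("VO2 must be non-negative")
  vo2_ss / 3.5
}

#' Steady-state MET over a chosen sub-interval
#'
#' Smooths the breath series, averages it over the supplied sub-interval
#' (conventionally about 2 min of plateau) and converts to METs. The
#' sub-interval is user-supplied: plateau identification is a judgement
#' call this package does not automate.
#'
#' @param time_s,vo2 Breath-by-breath series as in [smooth_vo2()].
#' @param start_s,end_s Averaging sub-interval bounds in seconds.
#' @return A single MET value.
#' @export
steady_state_met <- function(time_s, vo2, start_s, end_s) {
  if (end_s <= start_s) stop_input("end_s must exceed start_s")
  sm <- smooth_vo2(time_s, vo2)
  sel <- time_s >= start_s & time_s <= end_s
  if (!any(sel)) stop_input("no samples in the steady-state interval")
  met_from_vo2(mean(sm[sel]))
}

#' Classify MET values into intensity classes
#'
#' Total monotone step function of the MET value: low for
#' `met <= low_max`, light up to `light_max` (both bounds inclusive),
#' moderate above.
#'
#' @param met Positive MET values.
#' @param scheme An [intensity_scheme()].
#' @return Ordered factor with levels `low < light < moderate`.
#' @export
intensity_from_met <- function(met, scheme = intensity_scheme()) {
  stopifnot(inherits(scheme, "wpa_intensity_scheme"))
  if (any(met <= 0)) stop_input("met must be positive")
  cls <- ifelse(met <= scheme$low_max, "low",
                ifelse(met <= scheme$light_max, "light", "moderate"))
  factor(cls, levels = c("low", "light", "moderate"), ordered = TRUE)
}

#' Assign ages to the study age groups
#'
#' Young is 20--50 years inclusive, middle (50, 70], old (70, 89].
#'
#' @param age Ages in years, within [20, 89].
#' @return Factor with levels `young`, `middle`, `old`.
#' @export
assign_age_group <- function(age) {
  if (any(age < 20 | age > 89)) stop_input("age must be within [20, 89]")
  g <- ifelse(age <= 50, "young", ifelse(age <= 70, "middle", "old"))
  factor(g, levels = c("young", "middle", "old"))
}

#' Assemble one task dataset from the window feature table
#'
#' Builds the design matrix, target and participant grouping for one of the
#' four modelling tasks:
#' \describe{
#'   \item{type_binary}{target vs. rest on activity type; windows of
#'     activities mapping to type `"none"` (resistance and stretching
#'     tasks) are dropped first.}
#'   \item{intensity_binary}{target vs. rest on the MET-derived intensity
#'     class; all 33 activities retained.}
#'   \item{individual_multiclass}{the activity name itself as a multi-class
#'     target.}
#'   \item{ee_regression}{the steady-state MET value as a continuous
#'     target, restricted to participants with valid calorimetry
#'     ([ee_eligible()]).}
#' }
#' Rows can additionally be restricted to one age stratum; `"all"` pools
#' the three groups.
#'
#' @param windows Feature table from [extract_feature_table()].
#' @param roster Exclusion-filtered roster with `age` and eligibility
#'   flags.
#' @param kind Task kind, one of the four above.
#' @param target Positive class for the binary kinds (`"sedentary"`,
#'   `"locomotion"`, `"lifestyle"` or `"low"`, `"light"`, `"moderate"`).
#' @param stratum `"young"`, `"middle"`, `"old"` or `"all"`.
#' @param mapping Activity-to-type mapping ([default_type_mapping()]).
#' @param scheme Intensity cutoffs ([intensity_scheme()]).
#' @return An object of class `"wpa_task"`: list with `kind`, `target`,
#'   `stratum`, feature matrix `x` (49 columns), target `y` (factor or
#'   numeric), `groups` (participant id per row) and, for binary kinds,
#'   `positive` (the positive class label).
#' @export
build_task_dataset <- function(windows, roster,
                               kind = c("type_binary", "intensity_binary",
                                        "individual_multiclass", "ee_regression"),
                               target = NULL, stratum = "all",
                               mapping = default_type_mapping(),
                               scheme = intensity_scheme()) {
  kind <- match.arg(kind)
  stopifnot(stratum %in% c("young", "middle", "old", "all"))
  age_of <- stats::setNames(roster$age, roster$participant_id)
  if (anyNA(age_of[windows$participant_id])) {
    stop_input("windows reference participants missing from the roster")
  }
  w <- windows
  w$age_group <- as.character(assign_age_group(age_of[w$participant_id]))
  if (stratum != "all") w <- w[w$age_group == stratum, , drop = FALSE]

  feat <- wpa_feature_names()
  make <- function(w, y, positive = NULL) {
    if (nrow(w) == 0) stop_input("empty task dataset")
    structure(list(kind = kind, target = target, stratum = stratum,
                   x = as.matrix(w[, feat, drop = FALSE]), y = y,
                   groups = w$participant_id, positive = positive),
              class = "wpa_task")
  }

  if (kind == "type_binary") {
    if (is.null(target) || !target %in% c("sedentary", "locomotion", "lifestyle")) {
      stop_input("target must be one of sedentary, locomotion, lifestyle")
    }
    unknown <- setdiff(unique(w$activity_name), names(mapping))
    if (length(unknown)) {
      stop_input("activities missing from type mapping: ",
                 paste(unknown, collapse = ", "))
    }
    type <- mapping[w$activity_name]
    w <- w[type != "none", , drop = FALSE]
    type <- type[type != "none"]
    if (nrow(w) == 0) stop_input("empty task dataset")
    pos <- target
    neg <- paste0("non_", target)
    y <- factor(ifelse(type == target, pos, neg), levels = c(neg, pos))
    make(w, y, positive = pos)
  } else if (kind == "intensity_binary") {
    if (is.null(target) || !target %in% c("low", "light", "moderate")) {
      stop_input("target must be one of low, light, moderate")
    }
    if (anyNA(w$met)) stop_input("intensity task requires MET labels")
    intens <- as.character(intensity_from_met(w$met, scheme))
    pos <- target
    neg <- paste0("non_", target)
    y <- factor(ifelse(intens == target, pos, neg), levels = c(neg, pos))
    make(w, y, positive = pos)
  } else if (kind == "individual_multiclass") {
    y <- factor(w$activity_name, levels = sort(unique(windows$activity_name)))
    d <- make(w, y)
    d$y <- droplevels(d$y)
    d
  } else {
    elig <- ee_eligible(roster)$participant_id
    w <- w[w$participant_id %in% elig, , drop = FALSE]
    if (nrow(w) == 0) stop_input("empty task dataset")
    if (anyNA(w$met) || any(w$met <= 0)) {
      stop_input("regression task requires positive MET labels")
    }
    make(w, w$met)
  }
}

#' @export
print.wpa_task <- function(x, ...) {
  cat(sprintf("<wpa_task> %s%s, stratum %s: %d windows x %d features, %d participants\n",
              x$kind, if (!is.null(x$target)) paste0(" [", x$target, "]") else "",
              x$stratum, nrow(x$x), ncol(x$x), length(unique(x$groups))))
  if (is.factor(x$y)) print(table(x$y))
  invisible(x)
}
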