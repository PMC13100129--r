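# The interpretable feature set: hypokinesia, bradykinesia, combined
# speed, sequence effect, hesitation-halts.

#' Canonical feature names
#'
#' The 12 motor-deficit features (average amplitude; average cycle
#' duration; average cycle average/maximum speed; amplitude, cycle-duration
#' and speed slopes; four coefficients of variation; interruption count)
#' plus the cycle count.
#' @export
FEATURE_NAMES <- c("amp_avg", "cd_avg", "cas_avg", "cms_avg",
                   "amp_slope", "cd_slope", "speed_slope",
                   "amp_cv", "cd_cv", "cms_cv", "cas_cv",
                   "n_interruptions", "n_cycles")

.cv <- function(x, method = "population") {
  m <- mean(x)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  s <- if (method == "sample") {
    if (length(x) < 2L) return(NA_real_)
    stats::sd(x)
  } else {
    sqrt(mean((x - m)^2))
  }
  s / m
}

.ols_slope <- function(y, x) {
  if (length(y) < 3L) return(NA_real_)
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

#' Hypokinesia feature: average amplitude
#'
#' Mean of the per-cycle opening amplitudes (the denominator is the number
#' of amplitudes actually computed, which can be smaller than the peak
#' count when a peak lacks a preceding trough).
#'
#' @param cycles a [segment_cycles()] result.
#' @return `amp_avg`.
#' @export
hypokinesia_features <- function(cycles) {
  stopifnot(inherits(cycles, "cycle_set"))
  if (length(cycles$amplitudes) == 0L) return(c(amp_avg = NA_real_))
  c(amp_avg = mean(cycles$amplitudes))
}

#' Bradykinesia feature: average cycle duration
#'
#' Mean time between successive peaks, in seconds.
#'
#' @param cycles a [segment_cycles()] result.
#' @return `cd_avg`.
#' @export
bradykinesia_features <- function(cycles) {
  stopifnot(inherits(cycles, "cycle_set"))
  if (length(cycles$durations) == 0L) return(c(cd_avg = NA_real_))
  c(cd_avg = mean(cycles$durations))
}

#' Combined hypo/bradykinesia features: average CAS and CMS
#'
#' Means of the per-cycle average speed and of the per-cycle 95th-percentile
#' speed, over the M - 1 peak-to-peak cycles.
#'
#' @param cycles a [segment_cycles()] result.
#' @return `c(cas_avg, cms_avg)`.
#' @export
combined_speed_features <- function(cycles) {
  stopifnot(inherits(cycles, "cycle_set"))
  c(cas_avg = mean(cycles$cas, na.rm = TRUE),
    cms_avg = mean(cycles$cms, na.rm = TRUE))
}

#' Sequence-effect features: linear trends across cycles
#'
#' Ordinary least-squares slopes of the amplitude, cycle-duration and
#' cycle-average-speed sequences. The default regressor is the cycle index
#' (0, 1, 2, ...), giving per-cycle slopes; `slope_on = "time"` regresses
#' on the cycle's closing peak time instead (per-second slopes). At least
#' 3 values are required: two points always fit exactly and carry no trend
#' information.
#'
#' @param cycles a [segment_cycles()] result.
#' @param slope_on `"index"` or `"time"`.
#' @return `c(amp_slope, cd_slope, speed_slope)` (NA where < 3 values).
#' @export
sequence_effect_features <- function(cycles, slope_on = c("index", "time")) {
  stopifnot(inherits(cycles, "cycle_set"))
  slope_on <- match.arg(slope_on)
  amp_x <- match(cycles$amplitude_peaks, cycles$peak_indices) - 1
  dur_x <- seq_along(cycles$durations) - 1
  if (slope_on == "time") {
    amp_x <- cycles$peak_times[match(cycles$amplitude_peaks,
                                     cycles$peak_indices)]
    dur_x <- cycles$peak_times[-1L]
  }
  ok <- is.finite(cycles$cas)
  c(amp_slope = .ols_slope(cycles$amplitudes, amp_x),
    cd_slope = .ols_slope(cycles$durations, dur_x),
    speed_slope = .ols_slope(cycles$cas[ok], dur_x[ok]))
}

#' Hesitation-halts features: variability and interruptions
#'
#' Coefficients of variation of amplitude, cycle duration, CMS and CAS
#' (standard deviation over mean of each per-cycle sequence; the default
#' `"population"` method divides each squared-deviation sum by its own term
#' count, `"sample"` by count - 1), plus the interruption count: the number
#' of cycle durations exceeding twice the median cycle duration.
#'
#' @param cycles a [segment_cycles()] result.
#' @param cv_method `"population"` (default) or `"sample"`.
#' @return `c(amp_cv, cd_cv, cms_cv, cas_cv, n_interruptions)`.
#' @export
hesitation_halt_features <- function(cycles,
                                     cv_method = c("population", "sample")) {
  stopifnot(inherits(cycles, "cycle_set"))
  cv_method <- match.arg(cv_method)
  dur <- cycles$durations
  c(amp_cv = .cv(cycles$amplitudes, cv_method),
    cd_cv = .cv(dur, cv_method),
    cms_cv = .cv(cycles$cms[is.finite(cycles$cms)], cv_method),
    cas_cv = .cv(cycles$cas[is.finite(cycles$cas)], cv_method),
    n_interruptions = sum(dur > 2 * median(dur)))
}

#' Count rhythm interruptions
#'
#' A cycle counts as an interruption when its peak-to-peak duration exceeds
#' twice the median of all cycle durations in the recording. The rule is
#' invariant under uniform time scaling.
#'
#' @param cycles a [segment_cycles()] result.
#' @return Integer count.
#' @export
count_interruptions <- function(cycles) {
  stopifnot(inherits(cycles, "cycle_set"))
  as.integer(sum(cycles$durations > 2 * median(cycles$durations)))
}

#' Extract the full feature vector from a distance signal
#'
#' Runs the pipeline end-to-end: peak/trough detection, cycle segmentation,
#' then all feature groups. Any stage failure (e.g. too few tapping cycles)
#' is materialized as an invalid feature vector carrying the reason; the
#' function never raises for data-quality problems.
#'
#' @param signal a [distance_signal()] (or [angle_signal()]).
#' @param params a [peak_params()].
#' @param cv_method,slope_on conventions passed to the feature groups.
#' @return An object of class `tap_features`: the named features of
#'   [FEATURE_NAMES] plus `valid` and `reason`.
#' @export
tap_features <- function(signal, params = peak_params(),
                         cv_method = c("population", "sample"),
                         slope_on = c("index", "time")) {
  cv_method <- match.arg(cv_method)
  slope_on <- match.arg(slope_on)
  empty <- setNames(rep(NA_real_, length(FEATURE_NAMES)), FEATURE_NAMES)
  res <- tryCatch({
    ext <- detect_extrema(signal, params)
    cycles <- segment_cycles(signal, NULL, ext$peaks, ext$troughs)
    v <- c(hypokinesia_features(cycles),
           bradykinesia_features(cycles),
           combined_speed_features(cycles),
           sequence_effect_features(cycles, slope_on),
           hesitation_halt_features(cycles, cv_method))
    v <- v[setdiff(FEATURE_NAMES, "n_cycles")]
    v[["n_cycles"]] <- length(cycles$peak_indices)
    list(values = v[FEATURE_NAMES], valid = TRUE, reason = NA_character_,
         cycles = cycles)
  }, fingertap_insufficient_cycles = function(e) {
    list(values = empty, valid = FALSE, reason = conditionMessage(e),
         cycles = NULL)
  }, error = function(e) {
    list(values = empty, valid = FALSE, reason = conditionMessage(e),
         cycles = NULL)
  })
  structure(list(features = res$values, valid = res$valid,
                 reason = res$reason, source_id = signal$source_id,
                 cycles = res$cycles),
            class = "tap_features")
}

#' @export
print.tap_features <- function(x, digits = 4, ...) {
  cat("<tap_features>", x$source_id, "\n")
  if (!x$valid) {
    cat("  invalid:", x$reason, "\n")
    return(invisible(x))
  }
  f <- x$features
  cat(sprintf("  hypokinesia      amp_avg  %.*g\n", digits, f[["amp_avg"]]))
  cat(sprintf("  bradykinesia     cd_avg   %.*g s\n", digits, f[["cd_avg"]]))
  cat(sprintf("  combined speed   cas_avg  %.*g   cms_avg %.*g\n",
              digits, f[["cas_avg"]], digits, f[["cms_avg"]]))
  cat(sprintf("  sequence effect  slopes   amp %.*g  cd %.*g  speed %.*g\n",
              digits, f[["amp_slope"]], digits, f[["cd_slope"]],
              digits, f[["speed_slope"]]))
  cat(sprintf("  hesitation-halts CV amp %.*g  cd %.*g  cms %.*g  cas %.*g\n",
              digits, f[["amp_cv"]], digits, f[["cd_cv"]],
              digits, f[["cms_cv"]], digits, f[["cas_cv"]]))
  cat(sprintf("                   interruptions %d over %d cycles\n",
              as.integer(f[["n_interruptions"]]),
              as.integer(f[["n_cycles"]])))
  invisible(x)
}

#' @export
as.data.frame.tap_features <- function(x, ...) {
  out <- as.data.frame(as.list(x$features))
  out$valid <- x$valid
  out$reason <- x$reason
  out$recording_id <- x$source_id
  out
}

#' Bind feature vectors into a feature table
#'
#' @param x a list of [tap_features()] objects.
#' @return data.frame with one row per recording.
#' @export
feature_table <- function(x) {
  stopifnot(is.list(x))
  do.call(rbind, lapply(x, as.data.frame))
}
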