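# Tapping-cycle segmentation: pair peaks with preceding troughs, derive
# per-cycle amplitudes, durations, and speed summaries.

#' Segment tapping cycles
#'
#' Given detected extrema, assembles the per-cycle quantities the feature
#' set is built on:
#' \itemize{
#'   \item amplitude: signal value at a peak minus the value at the nearest
#'     preceding trough (the opening amplitude of that tap). A peak with no
#'     preceding trough (signal starts fully open) contributes none.
#'   \item duration: time between successive peaks (peak-to-peak cycle).
#'   \item cycle average speed (CAS): mean of the speed samples with
#'     timestamps in the half-open window (T_prev, T_peak].
#'   \item cycle maximum speed (CMS): 95th percentile (linear
#'     interpolation) of the speed samples in the closed window
#'     \[T_prev, T_peak\], robust to incidental keypoint outliers.
#' }
#'
#' @param signal a [distance_signal()].
#' @param speed a [speed_signal()]; computed from `signal` if missing.
#' @param peaks,troughs integer sample indices, e.g. from
#'   [detect_extrema()].
#' @return An object of class `cycle_set`.
#' @export
segment_cycles <- function(signal, speed = NULL, peaks, troughs) {
  stopifnot(inherits(signal, "distance_signal"))
  if (length(peaks) < 2L) stop_insufficient_cycles(length(peaks))
  if (is.null(speed)) speed <- speed_signal(signal)
  x <- signal$values
  tt <- signal$times
  peaks <- sort(as.integer(peaks))
  troughs <- sort(as.integer(troughs))

  amp_peak <- integer(0)
  amplitudes <- numeric(0)
  for (p in peaks) {
    prev <- troughs[troughs < p]
    if (length(prev) == 0L) next
    t0 <- prev[length(prev)]
    amp_peak <- c(amp_peak, p)
    amplitudes <- c(amplitudes, x[p] - x[t0])
  }
  if (length(amplitudes) == 0L) stop_insufficient_cycles(0L)

  pt <- tt[peaks]
  durations <- diff(pt)
  m1 <- length(peaks) - 1L
  cas <- numeric(m1)
  cms <- numeric(m1)
  for (j in seq_len(m1)) {
    in_open <- speed$times > pt[j] & speed$times <= pt[j + 1L]
    in_closed <- speed$times >= pt[j] & speed$times <= pt[j + 1L]
    cas[j] <- if (any(in_open)) mean(speed$values[in_open]) else NA_real_
    cms[j] <- if (any(in_closed))
      quantile(speed$values[in_closed], 0.95, names = FALSE, type = 7)
    else NA_real_
  }
  structure(list(peak_indices = peaks, trough_indices = troughs,
                 peak_times = pt, amplitudes = amplitudes,
                 amplitude_peaks = amp_peak, durations = durations,
                 cas = cas, cms = cms, fps = signal$fps),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat("<cycle_set>\n")
  cat(sprintf("  peaks: %d, troughs: %d, amplitudes: %d\n",
              length(x$peak_indices), length(x$trough_indices),
              length(x$amplitudes)))
  cat(sprintf("  mean amplitude %.3f, mean duration %.3f s\n",
              mean(x$amplitudes), mean(x$durations)))
  invisible(x)
}

#' Per-cycle table of a cycle set
#'
#' One row per peak-to-peak cycle (indexed by its closing peak j = 2..M):
#' the closing peak time, the opening amplitude at that peak (NA when the
#' peak had no preceding trough), the cycle duration, and the CAS/CMS speed
#' summaries.
#'
#' @param x a [segment_cycles()] result.
#' @param ... unused.
#' @export
as.data.frame.cycle_set <- function(x, ...) {
  m <- length(x$peak_indices)
  closing <- x$peak_indices[-1L]
  amp <- x$amplitudes[match(closing, x$amplitude_peaks)]
  data.frame(cycle_index = seq_len(m - 1L),
             peak_time_s = x$peak_times[-1L],
             amplitude = amp,
             duration_s = x$durations,
             cas = x$cas, cms = x$cms)
}
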