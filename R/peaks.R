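# Prominence-based peak detection with a minimum-separation constraint.
# Written in R because no installed package offers prominence filtering;
# semantics follow the common topographic definition: the prominence of a
# local maximum is its height above the higher of the two lowest points one
# must descend to before reaching higher ground (or a signal end).

#' Peak-detection parameters
#'
#' @param min_separation_s minimum time between consecutive retained peaks,
#'   seconds. Default 0.1 s: voluntary tapping rarely exceeds 10 Hz.
#' @param min_prominence_frac minimum peak prominence, as a fraction of the
#'   robust signal range (5th to 95th percentile). Default 0.05.
#' @return An object of class `peak_params`.
#' @export
peak_params <- function(min_separation_s = 0.1, min_prominence_frac = 0.05) {
  stopifnot(min_separation_s > 0,
            min_prominence_frac >= 0, min_prominence_frac <= 1)
  structure(list(min_separation_s = min_separation_s,
                 min_prominence_frac = min_prominence_frac),
            class = "peak_params")
}

# local maxima of x; plateaus contribute their midpoint
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j <= n - 1L && x[j + 1L] < x[i]) {
        out <- c(out, as.integer(floor((i + j) / 2)))
        i <- j + 1L
      } else i <- j + 1L
    } else i <- i + 1L
  }
  out
}

.prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    lo_l <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) { lo_l <- min(lo_l, x[i]); i <- i - 1L }
    lo_r <- h
    i <- p + 1L
    while (i <= length(x) && x[i] <= h) { lo_r <- min(lo_r, x[i]); i <- i + 1L }
    # at a signal edge, the descent bound is the minimum reached on that side
    h - max(lo_l, lo_r)
  }, numeric(1))
}

# peaks: candidate local maxima filtered by prominence, then thinned by
# greedy selection in decreasing height so retained peaks are separated by
# at least min_sep (in the units of `pos`, here seconds).
.find_peaks <- function(x, pos, min_sep, min_prom) {
  cand <- .local_maxima(x)
  if (length(cand) == 0L) return(integer(0))
  prom <- .prominence(x, cand)
  cand <- cand[prom >= min_prom]
  if (length(cand) == 0L) return(integer(0))
  ord <- cand[order(-x[cand], pos[cand])]
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(pos[p] - pos[kept]) >= min_sep)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Detect peaks and troughs of a distance signal
#'
#' Peaks are local maxima passing prominence and minimum-separation
#' constraints; troughs come from applying the same detector to the negated
#' signal. Between any two consecutive peaks at least one trough is
#' guaranteed: the minimum of the inter-peak segment is inserted if the
#' detector missed it.
#'
#' @param signal a [distance_signal()].
#' @param params a [peak_params()].
#' @return A list with integer sample indices `peaks` and `troughs`.
#'   Fewer than 2 peaks raises a condition of class
#'   `fingertap_insufficient_cycles` carrying the count found.
#' @export
detect_extrema <- function(signal, params = peak_params()) {
  stopifnot(inherits(signal, "distance_signal"),
            inherits(params, "peak_params"))
  x <- signal$values
  if (length(x) < 3L) stop_insufficient_cycles(0L)
  rng <- diff(quantile(x, c(0.05, 0.95), names = FALSE, type = 7))
  min_prom <- params$min_prominence_frac * rng
  peaks <- .find_peaks(x, signal$times, params$min_separation_s, min_prom)
  if (length(peaks) < 2L) stop_insufficient_cycles(length(peaks))
  troughs <- .find_peaks(-x, signal$times, params$min_separation_s, min_prom)
  # guarantee a trough inside every inter-peak segment
  for (j in seq_len(length(peaks) - 1L)) {
    seg <- (peaks[j] + 1L):(peaks[j + 1L] - 1L)
    if (length(seg) == 0L) next
    if (!any(troughs > peaks[j] & troughs < peaks[j + 1L])) {
      troughs <- c(troughs, seg[which.min(x[seg])])
    }
  }
  troughs <- sort(unique(troughs))
  list(peaks = peaks, troughs = troughs)
}

stop_insufficient_cycles <- function(count) {
  stop(structure(class = c("fingertap_insufficient_cycles",
                           "error", "condition"),
                 list(message = sprintf(
                        "insufficient cycles: %d peak(s) detected", count),
                      call = sys.call(-1L), count = count)))
}
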