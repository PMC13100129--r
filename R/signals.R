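# Signal construction: palm-scaled thumb-index distance, frame-wise speed,
# and the wrist-angle alternative representation.

new_distance_signal <- function(values, fps, times = NULL, source_id = "",
                                excluded = integer(0)) {
  if (is.null(times)) times <- (seq_along(values) - 1L) / fps
  stopifnot(length(values) == length(times))
  structure(list(values = as.numeric(values), times = as.numeric(times),
                 fps = fps, source_id = source_id,
                 excluded = excluded),
            class = "distance_signal")
}

#' Palm-scaled thumb-index distance signal
#'
#' For each usable frame the Euclidean distance between the thumb tip and
#' the index-finger tip is divided by the palm length (distance between the
#' wrist and the index-finger MCP joint), measured in the same frame. The
#' frame-wise scaling makes the signal invariant to camera distance, image
#' resolution and rigid in-plane motion of the hand, so normalized or pixel
#' coordinates give identical signals.
#'
#' Frames that are missing, or whose palm length falls below `denom_tol`
#' (the ratio is undefined there), are excluded; remaining samples keep
#' their original timestamps `frame / fps`, so downstream time differences
#' use actual time gaps.
#'
#' @param track a [hand_track()] (gap-fill with [fill_gaps()] first if
#'   desired).
#' @param denom_tol palm lengths below this are treated as degenerate.
#' @param smooth_window optional odd moving-average window (samples);
#'   default `NULL`, no smoothing.
#' @return An object of class `distance_signal` with fields `values`
#'   (dimensionless, >= 0), `times` (seconds), `fps`, `source_id` and
#'   `excluded` (original frame indices dropped).
#' @export
distance_signal <- function(track, denom_tol = 1e-6, smooth_window = NULL) {
  stopifnot(inherits(track, "hand_track"))
  fr <- track$frames
  usable <- !fr$missing
  if (sum(usable) < 2L) stop("empty signal: fewer than 2 usable frames")
  fr <- fr[usable, , drop = FALSE]
  d1 <- sqrt((fr$thumb_x - fr$index_x)^2 + (fr$thumb_y - fr$index_y)^2)
  d2 <- sqrt((fr$wrist_x - fr$mcp_x)^2 + (fr$wrist_y - fr$mcp_y)^2)
  degen <- d2 < denom_tol
  if (mean(degen) > 0.2)
    stop("quality error: palm length degenerate on ",
         round(100 * mean(degen)), "% of frames")
  keep <- !degen
  if (sum(keep) < 2L) stop("empty signal: fewer than 2 valid frames")
  values <- d1[keep] / d2[keep]
  if (!is.null(smooth_window)) {
    stopifnot(smooth_window %% 2 == 1)
    if (smooth_window > 1) {
      k <- rep(1 / smooth_window, smooth_window)
      pad <- (smooth_window - 1) / 2
      v <- c(rep(values[1L], pad), values, rep(values[length(values)], pad))
      values <- as.numeric(stats::filter(v, k, sides = 2))[pad + seq_along(values)]
    }
  }
  new_distance_signal(values, fps = track$fps,
                      times = fr$frame[keep] / track$fps,
                      source_id = track$recording_id,
                      excluded = fr$frame[degen])
}

#' @export
print.distance_signal <- function(x, ...) {
  cat("<distance_signal>", x$source_id, "\n")
  cat(sprintf("  %d samples, %.2f s at %g fps; range [%.3f, %.3f]\n",
              length(x$values), diff(range(x$times)), x$fps,
              min(x$values), max(x$values)))
  if (length(x$excluded))
    cat("  excluded frames:", length(x$excluded), "\n")
  invisible(x)
}

#' @export
length.distance_signal <- function(x) length(x$values)

#' @export
as.data.frame.distance_signal <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values)
}

#' @export
plot.distance_signal <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l", xlab = "time (s)",
                 ylab = "scaled distance", main = x$source_id, ...)
}

#' Frame-wise speed of a distance signal
#'
#' The absolute displacement of the scaled distance between consecutive
#' samples divided by the elapsed time between them (1/fps on a gap-free
#' signal; actual time gaps where frames were excluded).
#'
#' @param signal a [distance_signal()].
#' @return An object of class `speed_signal` with `values` (dimensionless
#'   distance per second, >= 0, one fewer than the distance signal) and
#'   `times` (the timestamp of the later sample of each pair).
#' @export
speed_signal <- function(signal) {
  stopifnot(inherits(signal, "distance_signal"))
  if (length(signal$values) < 2L) stop("signal length must be >= 2")
  dt <- diff(signal$times)
  structure(list(values = abs(diff(signal$values)) / dt,
                 times = signal$times[-1L], fps = signal$fps),
            class = "speed_signal")
}

#' @export
print.speed_signal <- function(x, ...) {
  cat(sprintf("<speed_signal> %d samples at %g fps; mean %.3f /s\n",
              length(x$values), x$fps, mean(x$values)))
  invisible(x)
}

#' Wrist-angle signal (alternative representation)
#'
#' Per frame, the angle between the vector from the wrist to the thumb tip
#' and the vector from the wrist to the index tip, in radians. This is the
#' angle-based representation used by prior work on finger-tapping
#' quantification; the package computes it to allow the same feature set to
#' be extracted from either representation. Frames with a zero-length
#' vector are excluded and reported.
#'
#' @param track a [hand_track()].
#' @param tol vectors shorter than this are degenerate.
#' @return An object of class `angle_signal` (values in \[0, pi\]) which
#'   also inherits from `distance_signal` so the downstream cycle and
#'   feature machinery applies unchanged.
#' @export
angle_signal <- function(track, tol = 1e-9) {
  stopifnot(inherits(track, "hand_track"))
  fr <- track$frames
  usable <- !fr$missing
  if (sum(usable) < 2L) stop("empty signal: fewer than 2 usable frames")
  fr <- fr[usable, , drop = FALSE]
  v1x <- fr$thumb_x - fr$wrist_x; v1y <- fr$thumb_y - fr$wrist_y
  v2x <- fr$index_x - fr$wrist_x; v2y <- fr$index_y - fr$wrist_y
  n1 <- sqrt(v1x^2 + v1y^2); n2 <- sqrt(v2x^2 + v2y^2)
  keep <- n1 > tol & n2 > tol
  if (sum(keep) < 2L) stop("empty signal: fewer than 2 valid frames")
  cosang <- (v1x * v2x + v1y * v2y)[keep] / (n1 * n2)[keep]
  ang <- acos(pmin(1, pmax(-1, cosang)))
  out <- new_distance_signal(ang, fps = track$fps,
                             times = fr$frame[keep] / track$fps,
                             source_id = track$recording_id,
                             excluded = fr$frame[!keep])
  class(out) <- c("angle_signal", class(out))
  out
}

#' Write a signal as a two-column delimited table
#'
#' Columns `time_s` and `value`, comma separated, with a `# fps:` /
#' `# source_id:` key-value header so the file round-trips through
#' [read_signal()].
#'
#' @param signal a [distance_signal()] (or [angle_signal()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fps: %.10g", signal$fps),
               sprintf("# source_id: %s", signal$source_id),
               "time_s,value"), con)
  utils::write.table(
    data.frame(time_s = signal$times, value = signal$values),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a signal written by [write_signal()]
#'
#' Also accepts plain two-column `time_s,value` tables without the
#' key-value header, in which case `fps` must be supplied (or is inferred
#' from the median time step).
#'
#' @param path input path.
#' @param fps frames per second; overrides the header when given.
#' @return A [distance_signal()].
#' @export
read_signal <- function(path, fps = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  src <- ""
  for (h in hdr) {
    if (grepl("^#\\s*fps:", h) && is.null(fps))
      fps <- as.numeric(sub("^#\\s*fps:\\s*", "", h))
    if (grepl("^#\\s*source_id:", h))
      src <- trimws(sub("^#\\s*source_id:", "", h))
  }
  sep <- if (grepl("\t", body[1L])) "\t" else ","
  tab <- utils::read.table(text = body, header = TRUE, sep = sep)
  names(tab) <- tolower(names(tab))
  if (!all(c("time_s", "value") %in% names(tab)))
    stop("signal file must have columns time_s,value: ", path)
  if (nrow(tab) < 2L) stop("signal file too short: ", path)
  if (is.null(fps)) fps <- 1 / median(diff(tab$time_s))
  if (src == "") src <- basename(path)
  new_distance_signal(tab$value, fps = fps, times = tab$time_s,
                      source_id = src)
}
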