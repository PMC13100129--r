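# Fixtures built in code: synthetic signals and keypoint tracks.

# uniform-grid distance signal from a value vector
make_signal <- function(values, fps = 50, id = "test") {
  fingertap:::new_distance_signal(values, fps = fps, source_id = id)
}

# sinusoid offset + amp * sin(2*pi*freq*t): peaks at offset+amp every 1/freq
make_sine_signal <- function(freq = 2, amp = 0.5, offset = 1,
                             duration = 10, fps = 50) {
  t <- seq(0, duration - 1 / fps, by = 1 / fps)
  make_signal(offset + amp * sin(2 * pi * freq * t), fps = fps, id = "sine")
}

# triangle wave between lo and hi with given period, starting at lo
make_triangle_signal <- function(lo = 0.2, hi = 1.2, period = 0.4,
                                 duration = 10, fps = 50) {
  t <- seq(0, duration - 1 / fps, by = 1 / fps)
  u <- (t %% period) / period
  make_signal(lo + (hi - lo) * (1 - abs(2 * u - 1)), fps = fps, id = "tri")
}

# keypoint frame geometry: wrist at origin, index MCP 0.2 above it
# (palm length 0.2), index tip fixed, thumb tip placed so that the
# thumb-index distance is dist; the palm-scaled signal equals dist / 0.2.
make_track_frames <- function(dists, conf = NULL) {
  n <- length(dists)
  fr <- data.frame(frame = seq_len(n) - 1L,
                   wrist_x = 0.5, wrist_y = 0.0,
                   mcp_x = 0.5, mcp_y = 0.2,
                   index_x = 0.5, index_y = 0.5,
                   thumb_x = 0.5, thumb_y = 0.5 + dists)
  if (!is.null(conf)) fr$confidence <- conf
  fr
}

make_track <- function(dists, fps = 50, ...) {
  suppressMessages(hand_track(make_track_frames(dists), fps = fps, ...))
}

# rigid transform of all landmarks of a hand_track
transform_track <- function(track, angle = 0, scale = 1, dx = 0, dy = 0) {
  fr <- track$frames
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  for (p in c("wrist", "mcp", "index", "thumb")) {
    xy <- as.matrix(fr[paste0(p, c("_x", "_y"))]) %*% t(R) * scale
    fr[[paste0(p, "_x")]] <- xy[, 1L] + dx
    fr[[paste0(p, "_y")]] <- xy[, 2L] + dy
  }
  out <- track
  out$frames <- fr
  out
}

# long-format keypoint table for a track, for IO tests
track_to_table <- function(frames, path, shuffle = FALSE, seed = 1) {
  ids <- c(wrist = 0L, thumb = 4L, mcp = 5L, index = 8L)
  rows <- do.call(rbind, lapply(names(ids), function(p) {
    data.frame(frame = frames$frame, landmark = ids[[p]],
               x = frames[[paste0(p, "_x")]],
               y = frames[[paste0(p, "_y")]])
  }))
  if (shuffle) {
    set.seed(seed)
    rows <- rows[sample(nrow(rows)), ]
  }
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  path
}
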