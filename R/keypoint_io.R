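# Canonical landmark set: the four keypoints of the 21-landmark hand model
# needed for the palm-scaled thumb-index distance.
LANDMARK_IDS <- c(wrist = 0L, thumb_tip = 4L, index_mcp = 5L, index_tip = 8L)
LANDMARK_NAMES <- names(LANDMARK_IDS)

#' Construct a hand-keypoint track
#'
#' A `hand_track` holds per-frame coordinates of the four landmarks the
#' pipeline consumes (wrist, thumb tip, index-finger MCP joint, index tip)
#' plus recording metadata. Coordinates are treated as dimensionless
#' normalized image units; pixel units are equally acceptable because the
#' palm scaling removes the absolute unit.
#'
#' @param frames data.frame with columns `frame`, `wrist_x`, `wrist_y`,
#'   `thumb_x`, `thumb_y`, `mcp_x`, `mcp_y`, `index_x`, `index_y`, and
#'   optionally `confidence`. Rows with any non-finite required coordinate
#'   are flagged missing.
#' @param fps frames per second (> 0). 25 and 50 are the expected camera
#'   rates; other positive values are accepted with a notice.
#' @param recording_id,subject_id identifier strings.
#' @param hand `"left"`, `"right"` or `"unknown"`.
#' @param medication_state `"on"`, `"off"` or `"unknown"`.
#' @return An object of class `hand_track`.
#' @export
hand_track <- function(frames, fps, recording_id = "", subject_id = "",
                       hand = "unknown", medication_state = "unknown") {
  stopifnot(is.data.frame(frames), is.numeric(fps), length(fps) == 1L)
  if (!is.finite(fps) || fps <= 0) stop("fps must be a positive number")
  if (!fps %in% c(25, 50)) {
    message("fps = ", fps, " (expected camera rates are 25 or 50)")
  }
  coord_cols <- c("wrist_x", "wrist_y", "thumb_x", "thumb_y",
                  "mcp_x", "mcp_y", "index_x", "index_y")
  missing_cols <- setdiff(c("frame", coord_cols), names(frames))
  if (length(missing_cols) > 0)
    stop("frames lacks columns: ", paste(missing_cols, collapse = ", "))
  frames <- frames[order(frames$frame), , drop = FALSE]
  if (anyDuplicated(frames$frame))
    stop("duplicated frame indices in track")
  if (!"confidence" %in% names(frames)) frames$confidence <- NA_real_
  cm <- as.matrix(frames[coord_cols])
  frames$missing <- apply(cm, 1L, function(r) any(!is.finite(r)))
  rownames(frames) <- NULL
  structure(
    list(frames = frames, fps = fps, recording_id = recording_id,
         subject_id = subject_id, hand = hand,
         medication_state = medication_state),
    class = "hand_track")
}

#' @export
print.hand_track <- function(x, ...) {
  cat("<hand_track>", x$recording_id, "\n")
  cat("  frames:", nrow(x$frames),
      sprintf("(%d missing)", sum(x$frames$missing)), "\n")
  cat("  fps:", x$fps, " hand:", x$hand,
      " medication:", x$medication_state, "\n")
  invisible(x)
}

#' @export
length.hand_track <- function(x) nrow(x$frames)

.match_landmarks <- function(landmark) {
  lm <- trimws(as.character(landmark))
  out <- rep(NA_character_, length(lm))
  lower <- tolower(lm)
  for (nm in LANDMARK_NAMES) out[lower == nm] <- nm
  suppressWarnings(num <- as.integer(lm))
  for (nm in LANDMARK_NAMES) out[!is.na(num) & num == LANDMARK_IDS[[nm]]] <- nm
  known <- !is.na(out) | (!is.na(num) & num %in% 0:20)
  if (!all(known))
    stop("unknown landmark naming scheme: ",
         paste(utils::head(unique(lm[!known]), 5L), collapse = ", "))
  out
}

#' Read a hand-keypoint table
#'
#' Reads a long-format delimited table (comma or tab separated, header row
#' required) with one row per frame and landmark: columns `frame` (or
#' `frame_index`), `landmark`, `x`, `y` and optionally `confidence`.
#' Landmarks may be identified by the 21-landmark hand-model indices
#' (wrist = 0, thumb tip = 4, index MCP = 5, index tip = 8) or by the
#' canonical names `wrist`, `thumb_tip`, `index_mcp`, `index_tip`; rows for
#' other hand-model indices are ignored. Frames lacking any of the four
#' required landmarks are flagged missing. Row order does not affect the
#' result.
#'
#' @param path path to the table.
#' @param fps frames per second of the recording.
#' @param recording_id,subject_id,hand,medication_state metadata passed to
#'   [hand_track()].
#' @param conf_threshold optional confidence cutoff in \[0, 1\]; keypoint
#'   rows below it are treated as missing. Default `NULL` (no filtering).
#' @return A [hand_track()].
#' @export
read_keypoint_table <- function(path, fps, recording_id = basename(path),
                                subject_id = "", hand = "unknown",
                                medication_state = "unknown",
                                conf_threshold = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if ("frame_index" %in% names(tab) && !"frame" %in% names(tab))
    names(tab)[names(tab) == "frame_index"] <- "frame"
  need <- c("frame", "landmark", "x", "y")
  if (!all(need %in% names(tab)))
    stop("keypoint table must have columns: ", paste(need, collapse = ", "))
  tab$.lm <- .match_landmarks(tab$landmark)
  tab <- tab[!is.na(tab$.lm), , drop = FALSE]
  if (nrow(tab) == 0L) stop("no usable frames: no required landmarks found")
  if (!is.null(conf_threshold) && "confidence" %in% names(tab)) {
    drop <- !is.na(tab$confidence) & tab$confidence < conf_threshold
    tab$x[drop] <- NA_real_
    tab$y[drop] <- NA_real_
  }
  frames_idx <- sort(unique(tab$frame))
  col_of <- c(wrist = "wrist", thumb_tip = "thumb", index_mcp = "mcp",
              index_tip = "index")
  out <- data.frame(frame = frames_idx)
  for (nm in LANDMARK_NAMES) {
    sub <- tab[tab$.lm == nm, , drop = FALSE]
    i <- match(frames_idx, sub$frame)
    out[[paste0(col_of[[nm]], "_x")]] <- sub$x[i]
    out[[paste0(col_of[[nm]], "_y")]] <- sub$y[i]
  }
  if ("confidence" %in% names(tab)) {
    conf <- tapply(tab$confidence, tab$frame, function(v) {
      v <- v[is.finite(v)]
      if (length(v)) min(v) else NA_real_
    })
    out$confidence <- as.numeric(conf[as.character(frames_idx)])
  }
  hand_track(out, fps = fps, recording_id = recording_id,
             subject_id = subject_id, hand = hand,
             medication_state = medication_state)
}

#' Write a hand-keypoint table
#'
#' Inverse of [read_keypoint_table()]: writes the long-format dialect.
#' Coordinates of non-missing frames round-trip to input precision;
#' missing coordinates are written as empty cells.
#'
#' @param track a [hand_track()].
#' @param path output path; `.tsv` extension selects tab separation.
#' @param landmark_ids use numeric hand-model indices (default) instead of
#'   canonical names.
#' @return `path`, invisibly.
#' @export
write_keypoint_table <- function(track, path, landmark_ids = TRUE) {
  stopifnot(inherits(track, "hand_track"))
  fr <- track$frames
  col_of <- c(wrist = "wrist", thumb_tip = "thumb", index_mcp = "mcp",
              index_tip = "index")
  rows <- lapply(LANDMARK_NAMES, function(nm) {
    data.frame(frame = fr$frame,
               landmark = if (landmark_ids) LANDMARK_IDS[[nm]] else nm,
               x = fr[[paste0(col_of[[nm]], "_x")]],
               y = fr[[paste0(col_of[[nm]], "_y")]],
               confidence = fr$confidence)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$frame, out$landmark), , drop = FALSE]
  if (all(is.na(out$confidence))) out$confidence <- NULL
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Fill short keypoint gaps by linear interpolation
#'
#' Runs of at most `max_gap` consecutive missing frames are linearly
#' interpolated per coordinate; longer runs remain missing. Leading and
#' trailing missing frames are trimmed. A gap report (missing before/after,
#' frames filled, longest run) is attached as attribute `"gap_report"`.
#' The operation is idempotent and never alters non-missing frames.
#'
#' @param track a [hand_track()].
#' @param max_gap maximum run length (frames) to interpolate. Default
#'   0.2 s worth of frames.
#' @return A [hand_track()], possibly shorter than the input.
#' @export
fill_gaps <- function(track, max_gap = round(0.2 * track$fps)) {
  stopifnot(inherits(track, "hand_track"), max_gap >= 0)
  fr <- track$frames
  miss <- fr$missing
  n_before <- sum(miss)
  longest <- 0L
  if (any(!miss)) {
    keep <- seq(which(!miss)[1L], max(which(!miss)))
    fr <- fr[keep, , drop = FALSE]
    miss <- fr$missing
  } else {
    fr <- fr[0L, , drop = FALSE]
    miss <- logical(0)
  }
  n_filled <- 0L
  if (length(miss) && any(miss)) {
    r <- rle(miss)
    longest <- max(r$lengths[r$values])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    coord_cols <- c("wrist_x", "wrist_y", "thumb_x", "thumb_y",
                    "mcp_x", "mcp_y", "index_x", "index_y")
    for (g in which(r$values)) {
      len <- r$lengths[g]
      if (len > max_gap) next
      i0 <- starts[g] - 1L   # guaranteed interior after trimming
      i1 <- ends[g] + 1L
      # interpolate in frame-index space (handles non-unit frame steps)
      f <- fr$frame[c(i0, i1)]
      idx <- starts[g]:ends[g]
      for (cc in coord_cols) {
        fr[[cc]][idx] <- stats::approx(f, fr[[cc]][c(i0, i1)],
                                       xout = fr$frame[idx])$y
      }
      fr$missing[idx] <- FALSE
      n_filled <- n_filled + len
    }
  }
  rownames(fr) <- NULL
  out <- track
  out$frames <- fr
  attr(out, "gap_report") <- list(
    missing_before = n_before, filled = n_filled,
    missing_after = sum(fr$missing), longest_run = longest)
  out
}
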