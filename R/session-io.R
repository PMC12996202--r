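# Session container and on-disk landmark format.
#
# A session is stored in memory as four frames x 33 matrices (x, y, z,
# confidence); on disk as a long-form CSV with one row per
# (frame, landmark): participant_id, frame_idx, landmark_idx, x, y, z,
# confidence. Coordinates are normalized image units (not clamped to
# [0,1]: pose estimators can emit slightly out-of-frame values).

#' Construct a session recording
#'
#' @param participant_id Character scalar identifier.
#' @param fps Frames per second (> 0).
#' @param x,y,z Numeric matrices, frames x 33, in normalized image units
#'   (z is relative depth).
#' @param conf Numeric matrix, frames x 33, per-landmark tracking
#'   confidence in \[0, 1\].
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(participant_id, fps, x, y, z, conf) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a positive scalar")
  for (nm in c("x", "y", "z", "conf")) {
    m <- get(nm)
    if (!is.matrix(m) || ncol(m) != N_LANDMARKS)
      stop(sprintf("'%s' must be a matrix with %d columns", nm, N_LANDMARKS))
  }
  dims <- vapply(list(x, y, z, conf), nrow, integer(1))
  if (length(unique(dims)) != 1L) stop("coordinate matrices disagree on frame count")
  if (dims[1] < 1L) stop("session must contain at least one frame")
  if (anyNA(conf) || any(conf < 0) || any(conf > 1))
    stop("confidence values must lie in [0, 1]")
  structure(
    list(participant_id = participant_id, fps = fps,
         x = x, y = y, z = z, conf = conf),
    class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %s: %d frames x %d landmarks @ %g fps (%.1f s)\n",
              x$participant_id, n_frames(x), N_LANDMARKS, x$fps,
              n_frames(x) / x$fps))
  invisible(x)
}

#' Number of frames in a session
#' @param session A `session_recording`.
#' @export
n_frames <- function(session) nrow(session$x)

session_cols <- c("participant_id", "frame_idx", "landmark_idx",
                  "x", "y", "z", "confidence")

#' Write a session to the long-form landmark CSV
#'
#' One row per (frame, landmark), columns `participant_id, frame_idx,
#' landmark_idx, x, y, z, confidence`, frame and landmark indices
#' 0-based, full float precision. `read_session()` round-trips the
#' numeric fields exactly.
#'
#' @param session A `session_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  tf <- n_frames(session)
  dt <- data.table::data.table(
    participant_id = session$participant_id,
    frame_idx = rep(seq_len(tf) - 1L, times = N_LANDMARKS),
    landmark_idx = rep(0:(N_LANDMARKS - 1L), each = tf),
    x = as.vector(session$x), y = as.vector(session$y),
    z = as.vector(session$z), confidence = as.vector(session$conf))
  data.table::setorder(dt, frame_idx, landmark_idx)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a session from the long-form landmark CSV
#'
#' Validates the schema: every frame must carry exactly 33 landmarks,
#' frame indices must be contiguous from 0, and confidences must lie in
#' \[0, 1\]. Malformed frames are named in the error.
#'
#' @param path File written by [write_session()] (or following the same
#'   documented format).
#' @param fps Frames per second of the recording (the format does not
#'   embed it); default 30.
#' @return A `session_recording`.
#' @export
read_session <- function(path, fps = 30) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, colClasses = list(character = "participant_id"))
  missing_cols <- setdiff(session_cols, names(dt))
  if (length(missing_cols))
    stop("malformed session file, missing columns: ",
         paste(missing_cols, collapse = ", "))
  counts <- table(dt$frame_idx)
  bad <- which(counts != N_LANDMARKS)
  if (length(bad))
    stop(sprintf("malformed session: frame %s has %d landmarks (expected %d)",
                 names(counts)[bad[1]], counts[[bad[1]]], N_LANDMARKS))
  frames <- sort(unique(dt$frame_idx))
  if (!identical(as.integer(frames), seq_along(frames) - 1L))
    stop("malformed session: frame indices not contiguous from 0")
  if (anyDuplicated(dt[, c("frame_idx", "landmark_idx")]))
    stop("malformed session: duplicated (frame, landmark) rows")
  if (any(dt$confidence < 0 | dt$confidence > 1))
    stop("validation error: confidence outside [0, 1]")
  data.table::setorder(dt, landmark_idx, frame_idx)
  tf <- length(frames)
  as_mat <- function(v) matrix(v, nrow = tf, ncol = N_LANDMARKS)
  session_recording(
    participant_id = as.character(dt$participant_id[1]), fps = fps,
    x = as_mat(dt$x), y = as_mat(dt$y), z = as_mat(dt$z),
    conf = as_mat(dt$confidence))
}

#' Trim a session to a fixed-duration window
#'
#' Extracts exactly `fps * duration_s` frames starting at `onset_frame`
#' (0-based) and renumbers frames from 0. Sessions are trimmed to a
#' 180-s analysis window by default, mirroring the recording protocol
#' (onset detection is the caller's job; synthetic sessions use 0).
#'
#' @param session A `session_recording`.
#' @param onset_frame 0-based index of the first retained frame.
#' @param duration_s Window length in seconds.
#' @return The trimmed `session_recording`.
#' @export
trim_session <- function(session, onset_frame = 0L, duration_s = 180) {
  n_keep <- session$fps * duration_s
  if (abs(n_keep - round(n_keep)) > 1e-9)
    stop("fps * duration_s must be an integer frame count")
  n_keep <- as.integer(round(n_keep))
  if (onset_frame < 0) stop("onset_frame must be >= 0")
  if (onset_frame + n_keep > n_frames(session))
    stop(sprintf(
      "session too short: need %d frames from onset %d but only %d available",
      n_keep, onset_frame, n_frames(session)))
  idx <- seq.int(onset_frame + 1L, onset_frame + n_keep)
  session_recording(session$participant_id, session$fps,
                    session$x[idx, , drop = FALSE],
                    session$y[idx, , drop = FALSE],
                    session$z[idx, , drop = FALSE],
                    session$conf[idx, , drop = FALSE])
}

#' Read and write participant metadata tables
#'
#' Metadata CSV columns: `participant_id, group, age_months, sex,
#' conners_score`, with `group` in `{risk, control}`, `sex` in
#' `{boy, girl}` and `conners_score` an integer in \[0, 30\] (teacher
#' hyperactivity rating used dimensionally).
#'
#' @param metadata Data frame with the columns above.
#' @param path CSV path.
#' @return `read_metadata()` returns the validated data frame.
#' @export
write_metadata <- function(metadata, path) {
  validate_metadata(metadata)
  data.table::fwrite(metadata, path)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  md <- as.data.frame(data.table::fread(
    path, colClasses = list(character = "participant_id")))
  validate_metadata(md)
  md
}

validate_metadata <- function(md) {
  need <- c("participant_id", "group", "age_months", "sex", "conners_score")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols))
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(md$group %in% c("risk", "control")))
    stop("metadata group must be 'risk' or 'control'")
  if (!all(md$sex %in% c("boy", "girl")))
    stop("metadata sex must be 'boy' or 'girl'")
  if (any(md$conners_score < 0 | md$conners_score > 30))
    stop("conners_score must lie in [0, 30]")
  invisible(md)
}
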