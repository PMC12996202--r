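# Composite-point aggregation, pelvis-root centering, and windowed
# displacement activity indices.
#
# Subtract the per-frame pelvis midpoint from every landmark.
center_on_pelvis <- function(session) {
  li <- landmark_index[["left_hip"]] + 1L
  ri <- landmark_index[["right_hip"]] + 1L
  for (f in c("x", "y", "z")) {
    pelvis <- (session[[f]][, li] + session[[f]][, ri]) / 2
    session[[f]] <- session[[f]] - pelvis
  }
  session
}

# A composite series holds 17 named body-region points per frame (head;
# left/right shoulder, elbow, wrist, hand, hip, knee, ankle, foot),
# each the unweighted centroid of its member landmarks, expressed
# relative to the per-frame pelvis center (midpoint of the two hip
# landmarks). Regional activity indices are cumulative x-y
# displacements between successive non-overlapping window means; the
# global index is their exact sum.

#' Aggregate landmarks into the 17 composite region points
#'
#' Centroids are unweighted means of member landmarks: head = centroid
#' of the 11 facial landmarks, hand = centroid of thumb/index/pinky per
#' side, foot = centroid of heel/foot-index per side; other regions are
#' single joints. No centering is applied here (see [root_center()]).
#'
#' @param session A QC-processed `session_recording` (no missing samples).
#' @return A `composite_series`: list of frames x 17 matrices `x`, `y`,
#'   `z` (columns named by region) plus `fps`.
#' @export
aggregate_composites <- function(session) {
  agg <- function(m) {
    out <- vapply(region_members, function(idx) {
      cols <- m[, idx + 1L, drop = FALSE]
      if (ncol(cols) == 1L) cols[, 1] else rowMeans(cols)
    }, numeric(nrow(m)))
    colnames(out) <- regions_all
    out
  }
  structure(list(x = agg(session$x), y = agg(session$y), z = agg(session$z),
                 fps = session$fps),
            class = "composite_series")
}

#' Express a composite series in the pelvis-root frame
#'
#' The pelvis center is the per-frame midpoint of the left and right hip
#' landmarks; it is subtracted from every composite point of that frame,
#' so indices capture relative limb and segmental motion rather than
#' whole-body translation in the image.
#'
#' @param series A `composite_series` from [aggregate_composites()].
#' @param hips Optional list with per-frame hip positions (`left`,
#'   `right`, each frames x 3); by default the series' own hip columns
#'   are used.
#' @return The root-centered `composite_series`.
#' @export
root_center <- function(series, hips = NULL) {
  if (is.null(hips)) {
    hips <- list(
      left = cbind(series$x[, "left_hip"], series$y[, "left_hip"],
                   series$z[, "left_hip"]),
      right = cbind(series$x[, "right_hip"], series$y[, "right_hip"],
                    series$z[, "right_hip"]))
  }
  stopifnot(nrow(hips$left) == nrow(series$x))
  pelvis <- (hips$left + hips$right) / 2
  series$x <- series$x - pelvis[, 1]
  series$y <- series$y - pelvis[, 2]
  series$z <- series$z - pelvis[, 3]
  series
}

#' Windowed-displacement activity index of one region
#'
#' Frames are partitioned into consecutive non-overlapping windows
#' (default 5 frames, 167 ms at 30 fps; any trailing remainder is
#' dropped). Each window is summarized by its per-axis mean position and
#' the index is the sum of Euclidean distances between successive window
#' means, using x and y only: monocular depth is unreliable, so z never
#' enters the index.
#'
#' @param point Numeric matrix, frames x 2 or frames x 3 (x, y\[, z\]),
#'   of one region's root-centered positions.
#' @param window Window length in frames.
#' @return Non-negative scalar index (normalized units).
#' @export
window_displacement_index <- function(point, window = 5L) {
  tf <- nrow(point)
  if (is.null(tf) || tf < 2L * window)
    stop("insufficient data: need at least two full windows")
  n_win <- tf %/% window
  keep <- seq_len(n_win * window)
  grp <- rep(seq_len(n_win), each = window)
  mx <- rowsum(point[keep, 1], grp) / window
  my <- rowsum(point[keep, 2], grp) / window
  sum(sqrt(diff(mx)^2 + diff(my)^2))
}

#' Per-participant movement feature table
#'
#' Runs composite aggregation, pelvis-root centering and the windowed
#' displacement index for each of the 17 regions of each session, and
#' appends the global activity index (exact sum of the 17 regional
#' indices) and the participant metadata. Sessions must already be
#' QC-processed and excluded sessions removed.
#'
#' @param sessions List of `session_recording` objects.
#' @param metadata Metadata data frame (one row per session, matched by
#'   `participant_id`).
#' @param window Window length in frames (default 5).
#' @return Data frame with columns `participant_id`, the 17 regional
#'   indices (named by region), `global`, and the metadata columns.
#' @export
build_feature_table <- function(sessions, metadata, window = 5L) {
  rows <- lapply(sessions, function(s) {
    # pelvis centering is applied at the landmark level (algebraically
    # identical to centering the composites, since the hip composites
    # are the hip landmarks; the /2 midpoint keeps whole-body
    # translations exactly cancelled in floating point)
    cs <- root_center(aggregate_composites(center_on_pelvis(s)))
    idx <- vapply(regions_all, function(rg)
      window_displacement_index(cbind(cs$x[, rg], cs$y[, rg]), window),
      numeric(1))
    c(list(participant_id = s$participant_id), as.list(idx),
      list(global = sum(idx)))
  })
  ft <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out <- merge(ft, metadata, by = "participant_id", sort = FALSE)
  if (nrow(out) != length(sessions))
    stop("metadata does not cover every session")
  out
}
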