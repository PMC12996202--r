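# Trajectory quality control: confidence gating, session exclusion,
# two-tier gap repair (linear interpolation for short gaps, endpoint
# blended constant-velocity Kalman prediction for long ones) and One
# Euro adaptive low-pass smoothing.

#' QC configuration
#'
#' @param confidence_threshold Landmark-frame cells with confidence
#'   strictly below this are invalid (default 0.50).
#' @param exclusion_missingness Sessions whose global missingness
#'   exceeds this fraction are excluded (default 0.20).
#' @param max_linear_gap Longest invalid run (frames) repaired by linear
#'   interpolation; longer interior runs use the Kalman fill. Default 10
#'   frames (333 ms at 30 fps).
#' @param kalman_process_noise,kalman_measurement_noise Process and
#'   measurement noise scales of the constant-velocity Kalman filter
#'   (normalized-units scale).
#' @param kalman_blend `"both"` (default) cross-fades a forward pass
#'   initialized before the gap with a backward pass initialized after
#'   it, so the fill meets both endpoints; `"forward"` uses the forward
#'   prediction alone.
#' @param oneeuro_min_cutoff,oneeuro_beta,oneeuro_dcutoff One Euro
#'   filter parameters: minimum cutoff (Hz), speed coefficient, and
#'   derivative cutoff (Hz). Defaults are the filter's original
#'   reference defaults (1.0, 0.007, 1.0).
#' @return A `qc_config` list.
#' @export
qc_config <- function(confidence_threshold = 0.50,
                      exclusion_missingness = 0.20,
                      max_linear_gap = 10L,
                      kalman_process_noise = 1e-4,
                      kalman_measurement_noise = 1e-2,
                      kalman_blend = c("both", "forward"),
                      oneeuro_min_cutoff = 1.0,
                      oneeuro_beta = 0.007,
                      oneeuro_dcutoff = 1.0) {
  stopifnot(confidence_threshold > 0, confidence_threshold < 1,
            exclusion_missingness > 0, exclusion_missingness < 1,
            max_linear_gap >= 1,
            kalman_process_noise > 0, kalman_measurement_noise > 0,
            oneeuro_min_cutoff > 0, oneeuro_beta >= 0, oneeuro_dcutoff > 0)
  structure(list(confidence_threshold = confidence_threshold,
                 exclusion_missingness = exclusion_missingness,
                 max_linear_gap = as.integer(max_linear_gap),
                 kalman_process_noise = kalman_process_noise,
                 kalman_measurement_noise = kalman_measurement_noise,
                 kalman_blend = match.arg(kalman_blend),
                 oneeuro_min_cutoff = oneeuro_min_cutoff,
                 oneeuro_beta = oneeuro_beta,
                 oneeuro_dcutoff = oneeuro_dcutoff),
            class = "qc_config")
}

#' Per-landmark, per-frame validity mask
#'
#' A cell is valid iff its confidence is at or above the threshold
#' (strictly-below-0.50 cells are marked invalid).
#'
#' @param session A `session_recording`.
#' @param config A [qc_config()].
#' @return Logical frames x 33 matrix, `TRUE` = valid.
#' @export
compute_validity <- function(session, config = qc_config()) {
  session$conf >= config$confidence_threshold
}

#' Global missingness of a session
#'
#' Fraction of invalid (landmark, frame) cells over all cells. The
#' cellwise definition is used (rather than frames-with-any-invalid-
#' landmark, which is pathologically strict with 33 landmarks); the
#' exclusion decision is `global_missingness(mask) > exclusion_missingness`.
#'
#' @param mask Logical validity matrix from [compute_validity()].
#' @return Fraction in \[0, 1\].
#' @export
global_missingness <- function(mask) {
  if (!length(mask)) stop("empty validity mask")
  mean(!mask)
}

# Constant-velocity Kalman filter over observed samples, then pure
# prediction n_pred steps ahead. Returns predicted positions.
kalman_cv_predict <- function(obs, n_pred, q, r) {
  f_mat <- matrix(c(1, 0, 1, 1), 2, 2)   # [[1,1],[0,1]] row-wise
  q_mat <- q * matrix(c(0.25, 0.5, 0.5, 1), 2, 2)
  state <- c(obs[1], 0)
  p_cov <- diag(c(r, 1))
  for (t in seq_along(obs)) {
    if (t > 1) {
      state <- f_mat %*% state
      p_cov <- f_mat %*% p_cov %*% t(f_mat) + q_mat
    }
    innov <- obs[t] - state[1]
    s <- p_cov[1, 1] + r
    k_gain <- p_cov[, 1] / s
    state <- state + k_gain * innov
    p_cov <- p_cov - outer(as.vector(k_gain), p_cov[1, ])
  }
  state[1] + state[2] * seq_len(n_pred)
}

#' Repair invalid runs in one landmark trajectory
#'
#' Two-tier gap repair applied independently to each axis of a single
#' landmark's (x, y, z) series: maximal invalid runs of at most
#' `max_linear_gap` frames are replaced by linear interpolation between
#' the nearest valid neighbours; longer interior runs by a
#' constant-velocity Kalman forward pass (initialized on the valid
#' samples preceding the gap) cross-faded linearly with a backward pass
#' (initialized on the samples following it), so the fill stays anchored
#' at both ends. Leading/trailing invalid runs hold the nearest valid
#' value. Valid samples are never modified.
#'
#' @param trajectory Numeric matrix, frames x 3 (x, y, z), or a vector
#'   for a single axis.
#' @param valid Logical vector, `TRUE` where the sample is valid.
#' @param config A [qc_config()].
#' @return Repaired matrix (or vector) of the same shape.
#' @export
fill_gaps <- function(trajectory, valid, config = qc_config()) {
  vec_in <- is.null(dim(trajectory))
  traj <- if (vec_in) matrix(trajectory, ncol = 1) else trajectory
  tf <- nrow(traj)
  stopifnot(length(valid) == tf)
  if (!any(valid)) stop("unrepairable trajectory: no valid samples")
  if (all(valid)) return(trajectory)

  runs <- rle(!valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  init_win <- 15L
  for (k in which(runs$values)) {
    i0 <- starts[k]; i1 <- ends[k]; len <- i1 - i0 + 1L
    gap <- i0:i1
    if (i0 == 1L) {                       # leading run: hold first valid
      traj[gap, ] <- rep(traj[i1 + 1L, ], each = len)
    } else if (i1 == tf) {                # trailing run: hold last valid
      traj[gap, ] <- rep(traj[i0 - 1L, ], each = len)
    } else if (len <= config$max_linear_gap) {
      w <- seq_len(len) / (len + 1)
      for (a in seq_len(ncol(traj)))
        traj[gap, a] <- (1 - w) * traj[i0 - 1L, a] + w * traj[i1 + 1L, a]
    } else {
      before <- traj[max(1L, i0 - init_win):(i0 - 1L), , drop = FALSE]
      after <- traj[(i1 + 1L):min(tf, i1 + init_win), , drop = FALSE]
      w <- rev(seq_len(len)) / (len + 1)  # forward weight, 1 -> 0 across gap
      for (a in seq_len(ncol(traj))) {
        fwd <- kalman_cv_predict(before[, a], len,
                                 config$kalman_process_noise,
                                 config$kalman_measurement_noise)
        if (config$kalman_blend == "forward") {
          traj[gap, a] <- fwd
        } else {
          bwd <- rev(kalman_cv_predict(rev(after[, a]), len,
                                       config$kalman_process_noise,
                                       config$kalman_measurement_noise))
          traj[gap, a] <- w * fwd + (1 - w) * bwd
        }
      }
    }
  }
  if (vec_in) traj[, 1] else traj
}

#' One Euro adaptive low-pass smoothing
#'
#' Causal per-channel One Euro filtering: the cutoff frequency adapts to
#' the estimated signal speed, `f_c = min_cutoff + beta * |dx_hat|`,
#' with the derivative itself pre-smoothed at `dcutoff`, so slow jitter
#' is suppressed while fast genuine movement passes through. The filter
#' is the identity on constant signals and never overshoots a step.
#'
#' @param trajectory Numeric matrix (frames x channels) or vector; no
#'   missing samples (run [fill_gaps()] first).
#' @param fps Sampling rate in frames/second.
#' @param config A [qc_config()].
#' @return Smoothed series, same shape and length as the input.
#' @export
one_euro_smooth <- function(trajectory, fps, config = qc_config()) {
  vec_in <- is.null(dim(trajectory))
  x <- if (vec_in) matrix(trajectory, ncol = 1) else trajectory
  tf <- nrow(x)
  if (tf < 2L) return(trajectory)
  alpha_of <- function(cutoff) {
    tau <- 1 / (2 * pi * cutoff)
    1 / (1 + tau * fps)
  }
  a_d <- alpha_of(config$oneeuro_dcutoff)
  out <- x
  prev <- x[1, ]
  dx_hat <- rep(0, ncol(x))
  for (t in 2:tf) {
    dx <- (x[t, ] - prev) * fps
    dx_hat <- a_d * dx + (1 - a_d) * dx_hat
    cutoff <- config$oneeuro_min_cutoff + config$oneeuro_beta * abs(dx_hat)
    a <- alpha_of(cutoff)
    prev <- prev + a * (x[t, ] - prev)  # exact identity on constants
    out[t, ] <- prev
  }
  if (vec_in) out[, 1] else out
}

#' Run the full QC pipeline on one session
#'
#' Fixed stage order: validity gating, exclusion decision, gap repair,
#' One Euro smoothing. Excluded sessions are returned unrepaired with
#' `excluded = TRUE`. Landmarks with no valid sample at all make the
#' session unrepairable and force exclusion (recorded in the report).
#'
#' @param session A `session_recording`.
#' @param config A [qc_config()].
#' @return A list: `session` (repaired + smoothed recording), `mask`,
#'   `missingness`, `excluded` (logical), `reason` (character or NA) and
#'   `n_gaps_linear`, `n_gaps_kalman` (gap census).
#' @export
qc_session <- function(session, config = qc_config()) {
  mask <- compute_validity(session, config)
  miss <- global_missingness(mask)
  res <- list(session = session, mask = mask, missingness = miss,
              excluded = FALSE, reason = NA_character_,
              n_gaps_linear = 0L, n_gaps_kalman = 0L)
  if (miss > config$exclusion_missingness) {
    res$excluded <- TRUE
    res$reason <- sprintf("global missingness %.1f%% exceeds %.0f%%",
                          100 * miss, 100 * config$exclusion_missingness)
    return(res)
  }
  if (any(colSums(mask) == 0)) {
    res$excluded <- TRUE
    res$reason <- "landmark with no valid samples (unrepairable)"
    return(res)
  }
  x <- session$x; y <- session$y; z <- session$z
  for (lm in seq_len(N_LANDMARKS)) {
    v <- mask[, lm]
    if (all(v)) next
    runs <- rle(!v)
    interior <- runs$values
    # leading/trailing runs are holds, not gaps, for the census
    if (runs$values[1]) interior[1] <- FALSE
    if (runs$values[length(runs$values)]) interior[length(runs$values)] <- FALSE
    lens <- runs$lengths[interior]
    res$n_gaps_linear <- res$n_gaps_linear + sum(lens <= config$max_linear_gap)
    res$n_gaps_kalman <- res$n_gaps_kalman + sum(lens > config$max_linear_gap)
    repaired <- fill_gaps(cbind(x[, lm], y[, lm], z[, lm]), v, config)
    x[, lm] <- repaired[, 1]; y[, lm] <- repaired[, 2]; z[, lm] <- repaired[, 3]
  }
  x <- one_euro_smooth(x, session$fps, config)
  y <- one_euro_smooth(y, session$fps, config)
  z <- one_euro_smooth(z, session$fps, config)
  res$session <- session_recording(session$participant_id, session$fps,
                                   x, y, z, session$conf)
  res
}
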