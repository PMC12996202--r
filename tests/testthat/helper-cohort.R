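# Shared fixture builders. Everything is generated in code; sessions are
# kept short so the suite stays fast while exercising the full path.

# Small cohort spec: same structure as the study cohort, shorter sessions.
small_spec <- function(n_risk = 4L, n_control = 6L, duration_s = 10,
                       seed = 101L, ...) {
  cohort_spec(n_risk = n_risk, n_control = n_control,
              duration_s = duration_s, seed = seed, ...)
}

# Spec with all randomness off: static landmarks unless a drift is given.
static_spec <- function(duration_s = 10, drift = list(), seed = 1L, ...) {
  amp0 <- setNames(rep(0, length(regions_all)), regions_all)
  cohort_spec(n_risk = 1L, n_control = 1L, duration_s = duration_s,
              region_amplitude = amp0, jitter_sd = 0, z_amplitude = 0,
              dropout_rate = 0, drift = drift, seed = seed, ...)
}

# Hand-built session from coordinate matrices (frames x 33).
make_session <- function(x, y = x, z = x * 0, conf = NULL, fps = 30,
                         id = "T001") {
  if (is.null(conf)) conf <- matrix(1, nrow(x), ncol(x))
  session_recording(id, fps, x, y, z, conf)
}

# Static session: every landmark fixed at its base-pose position.
static_session <- function(tf = 60L, fps = 30, id = "T001") {
  bp <- povmotion:::base_pose_default
  make_session(matrix(rep(bp[, "x"], each = tf), tf),
               matrix(rep(bp[, "y"], each = tf), tf),
               matrix(rep(bp[, "z"], each = tf), tf), fps = fps, id = id)
}

# Feature table straight from sessions (clean generator output needs no
# gap repair, and smoothing is the identity on what these tests assert).
features_of <- function(cohort, window = 5L) {
  build_feature_table(cohort$sessions, cohort$metadata, window = window)
}
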