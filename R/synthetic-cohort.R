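# Synthetic cohort generator.
#
# Emulates seated-child pose-landmark recordings captured from a
# teacher-worn first-person camera: each body region fidgets around a
# seated base pose following a mean-reverting (Ornstein-Uhlenbeck style)
# displacement process with region- and group-specific amplitude,
# distal segments partially inherit proximal motion, frame-level
# Gaussian jitter emulates pose-estimator noise, and tracking-confidence
# dropouts arrive in bursts. The teacher hyperactivity rating is coupled
# linearly to each child's realized latent activity. This is a stand-in
# for real recordings, not a biomechanical model of child movement.

# Seated-child base pose (normalized image units, subject facing camera).
base_pose_default <- local({
  m <- matrix(0, nrow = N_LANDMARKS, ncol = 3,
              dimnames = list(names(landmark_index), c("x", "y", "z")))
  xy <- rbind(
    nose = c(0.500, 0.280),
    left_eye_inner = c(0.515, 0.265), left_eye = c(0.525, 0.265),
    left_eye_outer = c(0.535, 0.266),
    right_eye_inner = c(0.485, 0.265), right_eye = c(0.475, 0.265),
    right_eye_outer = c(0.465, 0.266),
    left_ear = c(0.552, 0.276), right_ear = c(0.448, 0.276),
    mouth_left = c(0.516, 0.301), mouth_right = c(0.484, 0.301),
    left_shoulder = c(0.600, 0.400), right_shoulder = c(0.400, 0.400),
    left_elbow = c(0.640, 0.520), right_elbow = c(0.360, 0.520),
    left_wrist = c(0.620, 0.620), right_wrist = c(0.380, 0.620),
    left_pinky = c(0.627, 0.656), right_pinky = c(0.373, 0.656),
    left_index = c(0.616, 0.661), right_index = c(0.384, 0.661),
    left_thumb = c(0.605, 0.646), right_thumb = c(0.395, 0.646),
    left_hip = c(0.570, 0.630), right_hip = c(0.430, 0.630),
    left_knee = c(0.600, 0.750), right_knee = c(0.400, 0.750),
    left_ankle = c(0.580, 0.880), right_ankle = c(0.420, 0.880),
    left_heel = c(0.585, 0.915), right_heel = c(0.415, 0.915),
    left_foot_index = c(0.600, 0.932), right_foot_index = c(0.400, 0.932))
  m[rownames(xy), c("x", "y")] <- xy
  # shallow depth profile: limbs slightly toward the camera
  m[, "z"] <- -0.02
  m[c("left_knee", "right_knee", "left_foot_index", "right_foot_index"), "z"] <- -0.08
  m
})

#' Default motion amplitudes and risk multipliers
#'
#' `region_amplitude_default` is the per-frame OU innovation scale per
#' region for the control arm (normalized units/frame); distal segments
#' fidget more than proximal ones. `risk_multiplier_default` carries the
#' group signal: distal limb segments (ankles, feet, hands, wrists) are
#' amplified x2.0 in the risk arm, elbows/knees x1.5, shoulders x1.1,
#' the head x1.4 and hips x1.0.
#'
#' @format Named numeric vectors over the 17 regions.
#' @rdname generator_defaults
#' @export
region_amplitude_default <- c(
  head = 0.0010,
  left_shoulder = 0.0006, right_shoulder = 0.0006,
  left_elbow = 0.0010, right_elbow = 0.0010,
  left_wrist = 0.0014, right_wrist = 0.0014,
  left_hand = 0.0014, right_hand = 0.0014,
  left_hip = 0.0003, right_hip = 0.0003,
  left_knee = 0.0010, right_knee = 0.0010,
  left_ankle = 0.0013, right_ankle = 0.0013,
  left_foot = 0.0013, right_foot = 0.0013)

#' @rdname generator_defaults
#' @export
risk_multiplier_default <- c(
  head = 1.4,
  left_shoulder = 1.1, right_shoulder = 1.1,
  left_elbow = 1.5, right_elbow = 1.5,
  left_wrist = 2.0, right_wrist = 2.0,
  left_hand = 2.0, right_hand = 2.0,
  left_hip = 1.0, right_hip = 1.0,
  left_knee = 1.5, right_knee = 1.5,
  left_ankle = 2.0, right_ankle = 2.0,
  left_foot = 2.0, right_foot = 2.0)

#' Cohort specification for the synthetic generator
#'
#' Defaults reproduce the study geometry: 20 risk / 31 control children
#' aged 48-60 months, 180-s sessions at 30 fps (5,400 frames), sexes
#' assigned per arm at the observed 14/6 (risk) and 15/16 (control)
#' boy/girl proportions.
#'
#' @param n_risk,n_control Arm sizes.
#' @param fps Frames per second.
#' @param duration_s Session length in seconds; `fps * duration_s` must
#'   be an integer.
#' @param base_pose 33 x 3 matrix of landmark positions (normalized
#'   image units) for the seated template.
#' @param region_amplitude Named vector, per-region OU innovation scale
#'   (normalized units/frame) for the control arm.
#' @param risk_multiplier Named vector of risk-arm amplitude multipliers.
#' @param ou_theta Mean-reversion rate of the region displacement
#'   process (1/frame).
#' @param chain_coupling Fraction of a parent segment's displacement
#'   inherited by its distal children (kinematic chain coherence).
#' @param jitter_sd Per-frame, per-landmark Gaussian noise (normalized
#'   units), emulating pose-estimator jitter.
#' @param z_amplitude OU innovation scale of the depth coordinate; the
#'   same for both arms, so z carries no group signal.
#' @param dropout_rate Expected confidence-dropout bursts per landmark
#'   per minute.
#' @param dropout_length_p Geometric parameter for burst length in
#'   frames (mean length `1/dropout_length_p`).
#' @param activity_sdlog Between-child log-sd of the latent activity
#'   factor multiplying all region amplitudes.
#' @param conners_intercept,conners_slope,conners_noise_sd Teacher
#'   hyperactivity score model: `score = intercept + slope * latent
#'   activity + noise`, clipped to \[0, 30\] and rounded.
#' @param age_range_months Two-element integer range for uniform ages.
#' @param sex_proportion_boys Named vector, probability of `boy` per arm.
#' @param drift Optional named list mapping a region name to a
#'   deterministic per-frame velocity `c(vx, vy)` added as a linear ramp
#'   (used for closed-form checks).
#' @param seed Integer random seed; identical specs give bit-identical
#'   cohorts.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_risk = 20L, n_control = 31L,
                        fps = 30, duration_s = 180,
                        base_pose = base_pose_default,
                        region_amplitude = region_amplitude_default,
                        risk_multiplier = risk_multiplier_default,
                        ou_theta = 0.05, chain_coupling = 0.5,
                        jitter_sd = 0.001, z_amplitude = 0.0008,
                        dropout_rate = 0.5, dropout_length_p = 0.2,
                        activity_sdlog = 0.45,
                        conners_intercept = -14, conners_slope = 12,
                        conners_noise_sd = 2.5,
                        age_range_months = c(48L, 60L),
                        sex_proportion_boys = c(risk = 14 / 20, control = 15 / 31),
                        drift = list(),
                        seed = 1L) {
  spec <- as.list(environment())
  n_fr <- fps * duration_s
  if (n_risk < 0 || n_control < 0) stop("arm sizes must be non-negative")
  if (abs(n_fr - round(n_fr)) > 1e-9 || n_fr < 1)
    stop("fps * duration_s must be a positive integer frame count")
  missing_regions <- setdiff(regions_all, names(region_amplitude))
  if (length(missing_regions))
    stop("region_amplitude missing segments: ",
         paste(missing_regions, collapse = ", "))
  missing_mult <- setdiff(regions_all, names(risk_multiplier))
  if (length(missing_mult))
    stop("risk_multiplier missing segments: ",
         paste(missing_mult, collapse = ", "))
  stopifnot(all(region_amplitude >= 0), all(risk_multiplier >= 0),
            ou_theta > 0, ou_theta < 1, jitter_sd >= 0,
            dropout_rate >= 0, dropout_length_p > 0, dropout_length_p <= 1)
  spec$n_risk <- as.integer(n_risk)
  spec$n_control <- as.integer(n_control)
  spec$seed <- as.integer(seed)
  class(spec) <- "cohort_spec"
  spec
}

# Realized per-region amplitudes for one participant.
participant_amplitudes <- function(spec, group, activity_factor) {
  amp <- spec$region_amplitude[regions_all]
  if (group == "risk") amp <- amp * spec$risk_multiplier[regions_all]
  amp * activity_factor
}

#' Generate one synthetic session
#'
#' Simulates the landmark trajectory of a single seated child. Each of
#' the 17 body regions follows an AR(1) mean-reverting displacement
#' process around the base pose; wrists/hands inherit part of the elbow
#' displacement and ankles/feet part of the knee displacement; Gaussian
#' jitter is added independently per landmark and frame; confidence is
#' 1.0 outside dropout bursts and uniform in \[0, 0.5) inside them.
#'
#' @param spec A [cohort_spec()].
#' @param group `"risk"` or `"control"`.
#' @param participant_seed Integer seed for this session.
#' @param participant_id Identifier stored in the session.
#' @param activity_factor Latent activity multiplier on all region
#'   amplitudes (1 = arm average).
#' @return A `session_recording` with `fps * duration_s` frames.
#' @export
generate_session <- function(spec, group, participant_seed,
                             participant_id = "synthetic",
                             activity_factor = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!group %in% c("risk", "control")) stop("group must be 'risk' or 'control'")
  tf <- as.integer(round(spec$fps * spec$duration_s))
  if (tf < 1L) stop("non-positive frame count")
  amp <- participant_amplitudes(spec, group, activity_factor)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(participant_seed))

  nr <- length(regions_all)
  phi <- 1 - spec$ou_theta
  # Region displacement processes: AR(1) per region and axis (x, y own
  # amplitude; z a common amplitude with no group dependence).
  ar1 <- function(sd_innov, n, k) {
    eps <- matrix(stats::rnorm(n * k, sd = 1), n, k)
    apply(eps, 2, function(e) stats::filter(e, phi, method = "recursive")) *
      rep(sd_innov, each = n)
  }
  disp_x <- ar1(amp, tf, nr)
  disp_y <- ar1(amp, tf, nr)
  disp_z <- ar1(rep(spec$z_amplitude, nr), tf, nr)
  colnames(disp_x) <- colnames(disp_y) <- colnames(disp_z) <- regions_all

  # kinematic chain coherence: distal regions inherit part of the
  # parent's displacement
  for (child in names(region_parent)) {
    parent <- region_parent[[child]]
    disp_x[, child] <- disp_x[, child] + spec$chain_coupling * disp_x[, parent]
    disp_y[, child] <- disp_y[, child] + spec$chain_coupling * disp_y[, parent]
    disp_z[, child] <- disp_z[, child] + spec$chain_coupling * disp_z[, parent]
  }

  # deterministic linear drift overrides (for closed-form checks)
  if (length(spec$drift)) {
    ramp <- seq_len(tf) - 1
    for (rg in names(spec$drift)) {
      v <- spec$drift[[rg]]
      disp_x[, rg] <- disp_x[, rg] + v[1] * ramp
      disp_y[, rg] <- disp_y[, rg] + v[2] * ramp
    }
  }

  reg_of <- landmark_region
  x <- matrix(rep(spec$base_pose[, "x"], each = tf), tf, N_LANDMARKS) +
    disp_x[, reg_of]
  y <- matrix(rep(spec$base_pose[, "y"], each = tf), tf, N_LANDMARKS) +
    disp_y[, reg_of]
  z <- matrix(rep(spec$base_pose[, "z"], each = tf), tf, N_LANDMARKS) +
    disp_z[, reg_of]
  if (spec$jitter_sd > 0) {
    x <- x + matrix(stats::rnorm(tf * N_LANDMARKS, sd = spec$jitter_sd), tf)
    y <- y + matrix(stats::rnorm(tf * N_LANDMARKS, sd = spec$jitter_sd), tf)
    z <- z + matrix(stats::rnorm(tf * N_LANDMARKS, sd = spec$jitter_sd), tf)
  }

  dimnames(x) <- dimnames(y) <- dimnames(z) <- NULL

  # confidence dropouts in bursts: burst starts are Bernoulli per frame
  # at rate dropout_rate / (60 * fps); lengths geometric
  conf <- matrix(1, tf, N_LANDMARKS)
  if (spec$dropout_rate > 0) {
    p_start <- spec$dropout_rate / (60 * spec$fps)
    for (lm in seq_len(N_LANDMARKS)) {
      starts <- which(stats::runif(tf) < p_start)
      if (!length(starts)) next
      lens <- stats::rgeom(length(starts), spec$dropout_length_p) + 1L
      for (k in seq_along(starts)) {
        idx <- starts[k]:min(tf, starts[k] + lens[k] - 1L)
        conf[idx, lm] <- stats::runif(length(idx), 0, 0.5 - 1e-9)
      }
    }
  }
  session_recording(participant_id, spec$fps, x, y, z, conf)
}

#' Generate a full synthetic cohort
#'
#' Draws per-participant seeds, latent activity factors, ages, sexes and
#' teacher hyperactivity scores, then simulates each session with
#' [generate_session()]. The teacher score is `intercept + slope *
#' latent` where `latent` is the participant's activity factor times the
#' arm's mean amplitude multiplier, plus Gaussian noise, clipped to
#' \[0, 30\] and rounded — the simplest model consistent with a positive
#' rating-movement coupling.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `sessions` (list of `session_recording`) and
#'   `metadata` (data frame; see [read_metadata()] for the schema, plus
#'   a `latent_activity` column).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_risk + spec$n_control
  groups <- rep(c("risk", "control"), c(spec$n_risk, spec$n_control))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(spec$seed))
  participant_seeds <- sample.int(2147483646L, n)
  activity <- stats::rlnorm(n, meanlog = 0, sdlog = spec$activity_sdlog)
  ages <- sample(seq(spec$age_range_months[1], spec$age_range_months[2]),
                 n, replace = TRUE)
  p_boy <- spec$sex_proportion_boys[groups]
  sexes <- ifelse(stats::runif(n) < p_boy, "boy", "girl")
  mean_mult <- ifelse(groups == "risk",
                      mean(spec$risk_multiplier[regions_all]), 1)
  latent <- activity * mean_mult
  raw_score <- spec$conners_intercept + spec$conners_slope * latent +
    stats::rnorm(n, sd = spec$conners_noise_sd)
  conners <- as.integer(round(pmin(30, pmax(0, raw_score))))

  ids <- sprintf("P%03d", seq_len(n))
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    sessions[[i]] <- generate_session(
      spec, groups[i], participant_seeds[i], participant_id = ids[i],
      activity_factor = activity[i])
  }
  metadata <- data.frame(
    participant_id = ids, group = groups, age_months = as.integer(ages),
    sex = sexes, conners_score = conners, latent_activity = latent,
    stringsAsFactors = FALSE)
  list(sessions = sessions, metadata = metadata)
}

#' Read a cohort specification from a YAML file
#'
#' Accepts any subset of [cohort_spec()] arguments as top-level keys;
#' `region_amplitude` and `risk_multiplier` may be given as maps from
#' region name to value.
#'
#' @param path YAML file.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(formals(cohort_spec)))
  if (length(unknown))
    stop("unknown cohort spec keys: ", paste(unknown, collapse = ", "))
  for (nm in c("region_amplitude", "risk_multiplier"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(cohort_spec, raw)
}
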