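# Landmark layout constants for the 33-keypoint pose model and the
# composite body regions derived from it.

#' Landmark index map for the 33-keypoint pose layout
#'
#' Named 0-based indices into the standard 33-keypoint whole-body pose
#' layout: facial keypoints 0-10, upper body 11-24, lower body 25-32.
#' Left/right follow the subject's own left and right.
#'
#' @format A named integer vector of length 33.
#' @export
landmark_index <- c(
  nose = 0L,
  left_eye_inner = 1L, left_eye = 2L, left_eye_outer = 3L,
  right_eye_inner = 4L, right_eye = 5L, right_eye_outer = 6L,
  left_ear = 7L, right_ear = 8L,
  mouth_left = 9L, mouth_right = 10L,
  left_shoulder = 11L, right_shoulder = 12L,
  left_elbow = 13L, right_elbow = 14L,
  left_wrist = 15L, right_wrist = 16L,
  left_pinky = 17L, right_pinky = 18L,
  left_index = 19L, right_index = 20L,
  left_thumb = 21L, right_thumb = 22L,
  left_hip = 23L, right_hip = 24L,
  left_knee = 25L, right_knee = 26L,
  left_ankle = 27L, right_ankle = 28L,
  left_heel = 29L, right_heel = 30L,
  left_foot_index = 31L, right_foot_index = 32L
)

N_LANDMARKS <- 33L

#' Composite body regions
#'
#' The 17 analysis regions and their member landmarks (0-based indices).
#' Composites are unweighted centroids of their members: the head is the
#' centroid of the 11 facial landmarks, each hand the centroid of thumb,
#' index and pinky, each foot the centroid of heel and foot-index; all
#' other regions are single joints.
#'
#' @format A named list of integer vectors.
#' @export
region_members <- list(
  head = 0:10,
  left_shoulder = 11L, right_shoulder = 12L,
  left_elbow = 13L, right_elbow = 14L,
  left_wrist = 15L, right_wrist = 16L,
  left_hand = c(21L, 19L, 17L),   # thumb, index, pinky
  right_hand = c(22L, 20L, 18L),
  left_hip = 23L, right_hip = 24L,
  left_knee = 25L, right_knee = 26L,
  left_ankle = 27L, right_ankle = 28L,
  left_foot = c(29L, 31L),        # heel, foot-index
  right_foot = c(30L, 32L)
)

#' Region name sets used downstream
#'
#' `regions_all` are the 17 composite regions in canonical order.
#' `regions_analysis` are the 15 regions entering group statistics and
#' the classifier feature set: hips are dropped because motion is
#' expressed in a pelvis-rooted frame, which makes hip indices
#' near-degenerate.
#'
#' @rdname region_sets
#' @export
regions_all <- names(region_members)

#' @rdname region_sets
#' @export
regions_analysis <- setdiff(regions_all, c("left_hip", "right_hip"))

#' Anatomical domains for family-wise error control
#'
#' Five a priori domains used for domain-wise Bonferroni correction:
#' the head (one outcome, no correction) and four limb domains of four
#' outcomes each, so the limb-domain threshold is 0.05/4 = 0.0125.
#'
#' @format A named list of character vectors of region names.
#' @export
region_domains <- list(
  head = "head",
  right_upper_limb = c("right_shoulder", "right_elbow", "right_wrist", "right_hand"),
  left_upper_limb = c("left_shoulder", "left_elbow", "left_wrist", "left_hand"),
  right_lower_limb = c("right_hip", "right_knee", "right_ankle", "right_foot"),
  left_lower_limb = c("left_hip", "left_knee", "left_ankle", "left_foot")
)

# Parent region whose displacement a distal region partially inherits in
# the synthetic motion model (kinematic chain coherence).
region_parent <- c(
  left_wrist = "left_elbow", right_wrist = "right_elbow",
  left_hand = "left_elbow", right_hand = "right_elbow",
  left_ankle = "left_knee", right_ankle = "right_knee",
  left_foot = "left_knee", right_foot = "right_knee"
)

# Map each landmark (0-based index) to the region whose rigid displacement
# it follows in the synthetic generator.
landmark_region <- local({
  out <- character(N_LANDMARKS)
  for (rg in names(region_members)) out[region_members[[rg]] + 1L] <- rg
  out
})
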