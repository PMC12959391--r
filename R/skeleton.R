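#' Body configuration
#'
#' Proportions and meshing parameters for the procedural capsule body. All
#' lengths are in meters, the frame is right-handed and Y-up, and the skeleton
#' is posed in a T-pose at rest (arms straight out along X).
#'
#' @param pelvis_height Height of the pelvis joint above the ground plane.
#' @param shoulder_halfwidth Lateral offset of each shoulder from the upper back.
#' @param upper_arm,forearm Arm segment lengths.
#' @param thigh,shank Leg segment lengths.
#' @param hip_halfwidth Lateral offset of each hip joint from the pelvis.
#' @param spine_segment Length of each of the three spine segments
#'   (pelvis to lower back, lower back to trunk, trunk to upper back).
#' @param neck,head Neck segment length and head height above the neck joint.
#' @param radii Named list of surface radii used by the mesher: `torso`,
#'   `waist`, `neck_r`, `head_r`, `upper_arm_r`, `forearm_r`, `wrist_r`,
#'   `thigh_r`, `knee_r`, `ankle_r`.
#' @param resolution Number of segments around each tube circumference
#'   (minimum 8). Axial sampling scales with it so that doubling `resolution`
#'   roughly quadruples the face count.
#' @param blend_radius Falloff length of the distance-based skinning weights.
#'
#' @return A list of class `body_config`.
#' @export
body_config <- function(pelvis_height = 0.95,
                        shoulder_halfwidth = 0.20,
                        upper_arm = 0.28,
                        forearm = 0.26,
                        thigh = 0.42,
                        shank = 0.42,
                        hip_halfwidth = 0.10,
                        spine_segment = 0.12,
                        neck = 0.10,
                        head = 0.20,
                        radii = list(),
                        resolution = 10,
                        blend_radius = 0.06) {
  r <- utils::modifyList(list(
    torso = 0.13, waist = 0.115, neck_r = 0.055, head_r = 0.085,
    upper_arm_r = 0.05, forearm_r = 0.04, wrist_r = 0.032,
    thigh_r = 0.075, knee_r = 0.055, ankle_r = 0.042
  ), radii)
  cfg <- list(
    pelvis_height = pelvis_height, shoulder_halfwidth = shoulder_halfwidth,
    upper_arm = upper_arm, forearm = forearm, thigh = thigh, shank = shank,
    hip_halfwidth = hip_halfwidth, spine_segment = spine_segment,
    neck = neck, head = head, radii = r,
    resolution = resolution, blend_radius = blend_radius
  )
  dims <- c(unlist(cfg[c("pelvis_height", "shoulder_halfwidth", "upper_arm",
                         "forearm", "thigh", "shank", "hip_halfwidth",
                         "spine_segment", "neck", "head", "blend_radius")]),
            unlist(r))
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("body_config: all dimensions must be positive and finite", call. = FALSE)
  }
  if (resolution < 8) {
    stop("body_config: resolution must be at least 8 segments", call. = FALSE)
  }
  structure(cfg, class = "body_config")
}

# The 11 optically tracked joints, in the protocol order, plus pelvis (PV)
# and neck (NK) to complete the 13-joint, 39-DoF skeleton.
MOCAP_JOINT_ORDER <- c("LE", "LS", "RE", "RS", "UB", "LB", "T", "LT", "RT", "LK", "RK")

#' Build the articulated skeleton
#'
#' Thirteen joints in a tree rooted at the pelvis, each with three rotational
#' degrees of freedom (intrinsic X-Y-Z Euler, degrees), for 39 DoF in total.
#' The joint set contains the 11 optically tracked joints (`LE`, `LS`, `RE`,
#' `RS`, `UB`, `LB`, `T`, `LT`, `RT`, `LK`, `RK`) plus the pelvis root `PV`
#' and the neck `NK`.
#'
#' @param config A [body_config()].
#' @return A list of class `skeleton` with fields `joints`, `parent`,
#'   `rest_offset`, `rest_pos`, `dof` (39 DoF names, `<joint>_<axis>`),
#'   `bones` (per-joint list of distal segment endpoints, rest frame) and
#'   `end_sites`.
#' @export
build_skeleton <- function(config = body_config()) {
  cfg <- config
  joints <- c("PV", "LB", "T", "UB", "NK", "LS", "LE", "RS", "RE",
              "LT", "LK", "RT", "RK")
  parent <- c(0L, 1L, 2L, 3L, 4L, 4L, 6L, 4L, 8L, 1L, 10L, 1L, 12L)
  s <- cfg$spine_segment
  off <- rbind(
    PV = c(0, cfg$pelvis_height, 0),
    LB = c(0, s, 0),
    T  = c(0, s, 0),
    UB = c(0, s, 0),
    NK = c(0, cfg$neck, 0),
    LS = c(-cfg$shoulder_halfwidth, 0.04, 0),
    LE = c(-cfg$upper_arm, 0, 0),
    RS = c(cfg$shoulder_halfwidth, 0.04, 0),
    RE = c(cfg$upper_arm, 0, 0),
    LT = c(-cfg$hip_halfwidth, -0.04, 0),
    LK = c(0, -cfg$thigh, 0),
    RT = c(cfg$hip_halfwidth, -0.04, 0),
    RK = c(0, -cfg$shank, 0)
  )
  rest_pos <- off
  for (j in seq_along(joints)) {
    if (parent[j] > 0L) rest_pos[j, ] <- rest_pos[parent[j], ] + off[j, ]
  }
  end_sites <- list(
    NK = rest_pos["NK", ] + c(0, cfg$head, 0),
    LE = rest_pos["LE", ] + c(-cfg$forearm, 0, 0),
    RE = rest_pos["RE", ] + c(cfg$forearm, 0, 0),
    LK = rest_pos["LK", ] + c(0, -cfg$shank, 0),
    RK = rest_pos["RK", ] + c(0, -cfg$shank, 0)
  )
  # each joint owns the bone segments from itself to its children / end sites;
  # these segments are what the skinning weights measure distance to
  bones <- stats::setNames(vector("list", length(joints)), joints)
  for (j in seq_along(joints)) {
    kids <- which(parent == j)
    segs <- lapply(kids, function(k) rest_pos[k, ])
    if (joints[j] %in% names(end_sites)) {
      segs <- c(segs, list(end_sites[[joints[j]]]))
    }
    bones[[j]] <- segs
  }
  dof <- as.vector(t(outer(joints, c("X", "Y", "Z"), paste, sep = "_")))
  structure(list(
    joints = joints, parent = parent, rest_offset = off,
    rest_pos = rest_pos, end_sites = end_sites, bones = bones,
    dof = dof, config = cfg
  ), class = "skeleton")
}

#' Zero (rest) pose
#'
#' @param skeleton A [build_skeleton()] result.
#' @return Named numeric vector of 39 zeros, one per DoF.
#' @export
rest_pose <- function(skeleton) {
  stats::setNames(numeric(length(skeleton$dof)), skeleton$dof)
}

#' Flatten / unflatten a pose
#'
#' A pose is a named numeric vector over the skeleton's 39 DoF (degrees).
#' `as_pose()` coerces a vector, one-row data frame, or per-joint list into
#' that canonical ordering; `pose_matrix()` lays a pose out joint-by-axis.
#' The round trip is lossless.
#'
#' @param skeleton A skeleton.
#' @param x Pose values: a numeric vector (named or in DoF order), or a
#'   one-row data frame with DoF-named columns.
#' @return `as_pose()`: named numeric of length 39. `pose_matrix()`: a
#'   13 x 3 matrix with joint rows and X/Y/Z columns.
#' @export
as_pose <- function(skeleton, x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- unlist(x[intersect(names(x), skeleton$dof)])
  }
  p <- rest_pose(skeleton)
  if (!is.null(names(x)) && any(names(x) %in% skeleton$dof)) {
    keep <- intersect(names(x), skeleton$dof)
    p[keep] <- as.numeric(x[keep])
  } else {
    if (length(x) != length(p)) {
      stop("pose length ", length(x), " does not match ", length(p), " DoF",
           call. = FALSE)
    }
    p[] <- as.numeric(x)
  }
  if (any(!is.finite(p)) || any(abs(p) > 180)) {
    stop("pose angles must be finite and within [-180, 180] degrees", call. = FALSE)
  }
  p
}

#' @rdname as_pose
#' @export
pose_matrix <- function(skeleton, x) {
  p <- as_pose(skeleton, x)
  matrix(p, ncol = 3, byrow = TRUE,
         dimnames = list(skeleton$joints, c("X", "Y", "Z")))
}

# Intrinsic X->Y->Z rotation, angles in degrees, vectorized over frames.
# Returns a T x 9 matrix in column-major element order (r11, r21, r31, r12, ...).
rot_xyz_batch <- function(ax, ay, az) {
  a <- ax * pi / 180; b <- ay * pi / 180; c <- az * pi / 180
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b); cc <- cos(c); sc <- sin(c)
  cbind(
    cb * cc,                      # r11
    ca * sc + sa * sb * cc,       # r21
    sa * sc - ca * sb * cc,       # r31
    -cb * sc,                     # r12
    ca * cc - sa * sb * sc,       # r22
    sa * cc + ca * sb * sc,       # r32
    sb,                           # r13
    -sa * cb,                     # r23
    ca * cb                       # r33
  )
}

# C = A %*% B per frame for T x 9 column-major rotation stacks.
rot_mult_batch <- function(A, B) {
  idx <- function(i, j) (j - 1L) * 3L + i
  C <- matrix(0, nrow(A), 9L)
  for (j in 1:3) for (i in 1:3) {
    C[, idx(i, j)] <- A[, idx(i, 1)] * B[, idx(1, j)] +
      A[, idx(i, 2)] * B[, idx(2, j)] +
      A[, idx(i, 3)] * B[, idx(3, j)]
  }
  C
}

# Batched forward kinematics over an angle matrix (frames x 39, degrees).
# Returns per-joint world rotations (T x 9, column-major) and positions (T x 3).
fk_batch <- function(skeleton, angles) {
  angles <- as.matrix(angles)
  if (ncol(angles) != length(skeleton$dof)) {
    stop("angle matrix has ", ncol(angles), " columns; skeleton has ",
         length(skeleton$dof), " DoF", call. = FALSE)
  }
  nT <- nrow(angles)
  nj <- length(skeleton$joints)
  R <- vector("list", nj)
  P <- vector("list", nj)
  for (j in seq_len(nj)) {
    cols <- (j - 1L) * 3L + 1:3
    Rloc <- rot_xyz_batch(angles[, cols[1]], angles[, cols[2]], angles[, cols[3]])
    pj <- skeleton$parent[j]
    off <- skeleton$rest_offset[j, ]
    if (pj == 0L) {
      R[[j]] <- Rloc
      P[[j]] <- matrix(rep(off, each = nT), nT, 3)
    } else {
      Rp <- R[[pj]]
      R[[j]] <- rot_mult_batch(Rp, Rloc)
      P[[j]] <- P[[pj]] + cbind(
        Rp[, 1] * off[1] + Rp[, 4] * off[2] + Rp[, 7] * off[3],
        Rp[, 2] * off[1] + Rp[, 5] * off[2] + Rp[, 8] * off[3],
        Rp[, 3] * off[1] + Rp[, 6] * off[2] + Rp[, 9] * off[3]
      )
    }
  }
  list(R = R, P = P)
}

#' Forward kinematics
#'
#' World-frame rigid transform of every joint for one pose. The child
#' transform is the parent transform composed with the rest-offset
#' translation and the joint's local intrinsic X-Y-Z rotation.
#'
#' @param skeleton A skeleton.
#' @param pose A pose accepted by [as_pose()].
#' @return A list with `transforms` (named list of 4x4 matrices) and
#'   `positions` (13 x 3 matrix of joint world positions).
#' @export
forward_kinematics <- function(skeleton, pose) {
  p <- as_pose(skeleton, pose)
  fk <- fk_batch(skeleton, matrix(p, nrow = 1))
  tf <- lapply(seq_along(skeleton$joints), function(j) {
    m <- diag(4)
    m[1:3, 1:3] <- matrix(fk$R[[j]][1, ], 3, 3)
    m[1:3, 4] <- fk$P[[j]][1, ]
    m
  })
  names(tf) <- skeleton$joints
  pos <- do.call(rbind, lapply(fk$P, function(p) p[1, ]))
  rownames(pos) <- skeleton$joints
  list(transforms = tf, positions = pos)
}
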