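#' Minimal two-bone hinge body
#'
#' A single tube over two collinear bones meeting at one hinge joint — the
#' smallest articulated body with a nondegenerate cross-joint geodesic.
#' Useful for worked examples and for verifying the placement optimizer
#' against brute force: the best sensor for the hinge must cross it, aligned
#' with the limb axis.
#'
#' The skeleton has two joints: `base` (root, at the origin) and `hinge`
#' (at height `bone_length`), each with X/Y/Z DoF (6 in total); the distal
#' bone extends to an end site at `2 * bone_length`.
#'
#' @param bone_length Length of each bone (m).
#' @param radius Tube radius (m).
#' @param resolution Segments around the circumference.
#' @param blend_radius Skinning falloff length (m).
#' @return A `body` (skeleton + skinned mesh), like [build_capsule_body()].
#' @export
build_hinge_body <- function(bone_length = 0.3, radius = 0.05,
                             resolution = 10, blend_radius = 0.05) {
  stopifnot(bone_length > 0, radius > 0, resolution >= 8, blend_radius > 0)
  joints <- c("base", "hinge")
  parent <- c(0L, 1L)
  off <- rbind(base = c(0, 0, 0), hinge = c(0, bone_length, 0))
  rest_pos <- off
  rest_pos["hinge", ] <- rest_pos["base", ] + off["hinge", ]
  end_sites <- list(hinge = rest_pos["hinge", ] + c(0, bone_length, 0))
  bones <- list(base = list(rest_pos["hinge", ]),
                hinge = list(end_sites$hinge))
  dof <- as.vector(t(outer(joints, c("X", "Y", "Z"), paste, sep = "_")))
  skeleton <- structure(list(
    joints = joints, parent = parent, rest_offset = off,
    rest_pos = rest_pos, end_sites = end_sites, bones = bones,
    dof = dof, config = NULL
  ), class = "skeleton")
  acc <- list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3),
              cap_ids = c())
  line <- rbind(rest_pos["base", ], rest_pos["hinge", ], end_sites$hinge)
  ds <- 2 * pi * radius / resolution
  acc <- add_tube(acc, line, rep(radius, 3), resolution, ds)
  weights <- skin_weights(acc$vertices, skeleton, blend_radius)
  mesh <- structure(list(vertices = acc$vertices,
                         faces = matrix(as.integer(acc$faces),
                                        nrow(acc$faces), 3),
                         weights = weights),
                    class = "skinned_mesh")
  structure(list(skeleton = skeleton, mesh = mesh, config = NULL),
            class = "body")
}

#' Joint ranges for the hinge body
#'
#' @param flexion Hinge X-axis range (degrees).
#' @return A `joint_ranges` tibble covering both joints.
#' @export
hinge_joint_ranges <- function(flexion = c(0, 90)) {
  tibble::tibble(
    dof = c("base_X", "base_Y", "base_Z", "hinge_X", "hinge_Y", "hinge_Z"),
    joint = rep(c("base", "hinge"), each = 3),
    axis = rep(c("X", "Y", "Z"), 2),
    lo = c(0, 0, 0, flexion[1], -5, -5),
    hi = c(0, 0, 0, flexion[2], 5, 5)
  ) -> out
  class(out) <- c("joint_ranges", class(out))
  out
}
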