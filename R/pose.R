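#' Weak-perspective camera pose
#'
#' A weak-perspective (scaled orthographic) camera: rotate the 3D shape,
#' drop depth, scale by `f` pixels per model unit and translate in the
#' image plane.  Only the 2D image-plane translation is identifiable under
#' orthographic projection (the depth component of a 3D translation is
#' projected away), so the pose stores `translation = f * P %*% R %*% t3d`
#' directly; [translation_from_3d()] performs that reduction.
#'
#' Image coordinates follow the landmark-file convention: origin top-left,
#' u to the right, v down, in pixels.
#'
#' @param scale positive scaling factor `f` (pixels per model unit).
#' @param pitch,yaw,roll Euler angles in radians about the x, y and z axes;
#'   the rotation is composed as `R = Rz(roll) %*% Ry(yaw) %*% Rx(pitch)`
#'   with right-handed axes.
#' @param translation length-2 image-plane offset (pixels).
#' @return An object of class `face_pose`.
#' @export
face_pose <- function(scale = 1, pitch = 0, yaw = 0, roll = 0,
                      translation = c(0, 0)) {
  check_finite(c(scale, pitch, yaw, roll), "pose angles/scale")
  check_finite(translation, "translation")
  if (length(translation) != 2L) stopf("'translation' must have length 2")
  if (scale <= 0) stopf("'scale' must be positive, got %g", scale)
  structure(list(scale = scale, pitch = pitch, yaw = yaw, roll = roll,
                 translation = as.numeric(translation)),
            class = "face_pose")
}

#' @export
print.face_pose <- function(x, ...) {
  cat(sprintf("Weak-perspective pose: f = %.6g, (pitch, yaw, roll) = (%.4g, %.4g, %.4g) rad, t = (%.6g, %.6g) px\n",
              x$scale, x$pitch, x$yaw, x$roll, x$translation[1L], x$translation[2L]))
  if (!is.null(attr(x, "residual")))
    cat(sprintf("  alignment residual (RMS px): %.6g\n", attr(x, "residual")))
  invisible(x)
}

#' Rotation matrix from Euler angles
#'
#' Composition order is fixed as `R = Rz(roll) %*% Ry(yaw) %*% Rx(pitch)`
#' (right-handed axes); the result is always a proper rotation.
#'
#' @param pitch,yaw,roll angles in radians.
#' @return A `3 x 3` rotation matrix with `t(R) %*% R = I`, `det(R) = 1`.
#' @export
rotation_from_euler <- function(pitch, yaw, roll) {
  check_finite(c(pitch, yaw, roll), "Euler angles")
  ca <- cos(pitch); sa <- sin(pitch)
  cb <- cos(yaw);   sb <- sin(yaw)
  cg <- cos(roll);  sg <- sin(roll)
  rx <- matrix(c(1, 0, 0,  0, ca, sa,  0, -sa, ca), 3L, 3L)
  ry <- matrix(c(cb, 0, -sb,  0, 1, 0,  sb, 0, cb), 3L, 3L)
  rz <- matrix(c(cg, sg, 0,  -sg, cg, 0,  0, 0, 1), 3L, 3L)
  rz %*% ry %*% rx
}

#' Euler angles from a rotation matrix
#'
#' Inverts [rotation_from_euler()] under the documented composition order.
#' At gimbal lock (`|cos(yaw)| < 1e-9`) pitch and roll are not separately
#' identifiable; the branch is resolved deterministically by setting
#' `roll = 0`.
#'
#' @param R a `3 x 3` rotation matrix.
#' @return Named numeric vector `c(pitch, yaw, roll)` in radians.
#' @export
euler_from_rotation <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  dimnames(R) <- NULL
  sy <- -R[3L, 1L]
  sy <- max(-1, min(1, sy))  # clamp fp drift
  yaw <- asin(sy)
  if (abs(cos(yaw)) < 1e-9) {
    roll <- 0
    # with roll = 0 and sin(yaw) = +/-1: R[1,2] = sin(pitch)*sin(yaw),
    # R[1,3] = cos(pitch)*sin(yaw)
    pitch <- atan2(R[1L, 2L] * sign(sy), R[1L, 3L] * sign(sy))
  } else {
    pitch <- atan2(R[3L, 2L], R[3L, 3L])
    roll <- atan2(R[2L, 1L], R[1L, 1L])
  }
  c(pitch = pitch, yaw = yaw, roll = roll)
}

#' Project 3D points onto the image plane
#'
#' Applies the weak-perspective camera `s2d = f * P %*% R %*% X + t`
#' columnwise, where `P = rbind(c(1,0,0), c(0,1,0))` is the orthographic
#' projection matrix.
#'
#' @param points3d `3 x n` matrix of 3D coordinates (model units).
#' @param pose a [face_pose()].
#' @return `n x 2` matrix of pixel coordinates (columns u, v).
#' @export
project_points <- function(points3d, pose) {
  stopifnot(inherits(pose, "face_pose"))
  points3d <- as.matrix(points3d)
  if (nrow(points3d) != 3L) stopf("'points3d' must be a 3 x n matrix")
  if (ncol(points3d) < 1L) stopf("'points3d' must contain at least one point")
  check_finite(points3d, "points3d")
  R <- rotation_from_euler(pose$pitch, pose$yaw, pose$roll)
  s <- pose$scale * (R[1:2, , drop = FALSE] %*% points3d)  # P %*% R = first two rows of R
  cbind(u = s[1L, ] + pose$translation[1L],
        v = s[2L, ] + pose$translation[2L])
}

#' Image-plane translation equivalent to a 3D translation
#'
#' Under orthographic projection only `f * P %*% R %*% t3d` is observable;
#' this helper converts a pre-rotation 3D offset to the identifiable 2D
#' translation stored in [face_pose()].
#'
#' @param t3d length-3 numeric translation in model units.
#' @param pose a [face_pose()] supplying `f` and the rotation.
#' @return Length-2 pixel translation.
#' @export
translation_from_3d <- function(t3d, pose) {
  check_finite(t3d, "t3d")
  if (length(t3d) != 3L) stopf("'t3d' must have length 3")
  R <- rotation_from_euler(pose$pitch, pose$yaw, pose$roll)
  as.numeric(pose$scale * (R[1:2, , drop = FALSE] %*% t3d))
}

#' Closed-form weak-perspective pose from 2D-3D correspondences
#'
#' Least-squares scaled-orthographic alignment: centroids are removed, the
#' unconstrained `2 x 3` linear map from centred 3D to centred 2D points is
#' solved by least squares, and its SVD gives the nearest scaled
#' row-orthonormal factorisation — scale as the mean singular value and the
#' first two rotation rows as `U %*% t(V)`.  The third rotation row is the
#' cross product of the first two, so the recovered rotation is always
#' proper (`det = +1`), even for mirror-flipped observations.  On noiseless
#' weak-perspective data the generating pose is recovered exactly (up to
#' floating point).
#'
#' @param points3d `3 x n` matrix, `n >= 3`, not collinear.
#' @param points2d `n x 2` matrix of observed pixel coordinates.
#' @return A [face_pose()] with attribute `residual` (RMS reprojection
#'   error in pixels).
#' @export
estimate_pose <- function(points3d, points2d) {
  points3d <- as.matrix(points3d)
  points2d <- landmark_points(points2d)
  if (nrow(points3d) != 3L) stopf("'points3d' must be a 3 x n matrix")
  n <- ncol(points3d)
  if (nrow(points2d) != n)
    stopf("point counts differ: %d 3D vs %d 2D", n, nrow(points2d))
  if (n < 3L) stopf("pose estimation needs at least 3 correspondences, got %d", n)
  check_finite(points3d, "points3d"); check_finite(points2d, "points2d")

  cx <- rowMeans(points3d)
  cu <- colMeans(points2d)
  Xc <- points3d - cx
  Uc <- t(points2d) - cu  # 2 x n

  sx <- svd(Xc, nu = 3L, nv = 0L)
  rank <- sum(sx$d > max(sx$d) * 1e-10)
  if (rank < 2L)
    stopf("degenerate 3D points (collinear or coincident): rank %d < 2", rank)
  # pseudo-inverse solve of M %*% Xc = Uc for the unconstrained 2 x 3 map
  dinv <- ifelse(sx$d > max(sx$d) * 1e-10, 1 / sx$d, 0)
  M <- Uc %*% t(Xc) %*% (sx$u %*% (dinv^2 * t(sx$u)))

  sm <- svd(M)
  f <- mean(sm$d)
  if (f <= 0) stopf("degenerate 2D observations: estimated scale is not positive")
  R12 <- sm$u %*% t(sm$v)           # 2 x 3, orthonormal rows
  r3 <- c(R12[1L, 2L] * R12[2L, 3L] - R12[1L, 3L] * R12[2L, 2L],
          R12[1L, 3L] * R12[2L, 1L] - R12[1L, 1L] * R12[2L, 3L],
          R12[1L, 1L] * R12[2L, 2L] - R12[1L, 2L] * R12[2L, 1L])
  R <- rbind(R12, r3, deparse.level = 0L)
  ang <- euler_from_rotation(R)
  t2 <- cu - as.numeric(f * (R12 %*% cx))
  pose <- face_pose(scale = f, pitch = ang[["pitch"]], yaw = ang[["yaw"]],
                    roll = ang[["roll"]], translation = t2)
  pred <- project_points(points3d, pose)
  attr(pose, "residual") <- sqrt(mean(rowSums((points2d - pred)^2)))
  pose
}

# Accept an n x 2 matrix/data.frame or a landmark_set; return n x 2 matrix.
#' @noRd
landmark_points <- function(x) {
  if (inherits(x, "landmark_set")) return(x$points)
  x <- as.matrix(x)
  if (ncol(x) != 2L) stopf("2D points must have two columns (u, v)")
  storage.mode(x) <- "double"
  x
}
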