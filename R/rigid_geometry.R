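# ---- rotation helpers -------------------------------------------------------

#' Test whether a matrix is a proper rotation
#'
#' A proper rotation is orthonormal with determinant +1.
#'
#' @param R A 3x3 numeric matrix.
#' @param tol Numeric tolerance on orthonormality and determinant.
#' @return Logical scalar.
#' @export
is_rotation <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || any(dim(R) != c(3L, 3L)) || !all(is.finite(R))) {
    return(FALSE)
  }
  max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

assert_rotation <- function(R, tol = 1e-6) {
  if (!is_rotation(R, tol)) {
    stop("input is not a proper rotation matrix (orthonormal, det = +1)",
         call. = FALSE)
  }
  invisible(R)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Length-3 numeric translation, Angstrom.
#' @return A `rigid_transform` object (list with `rotation`, `translation`).
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  assert_rotation(rotation)
  stopifnot(length(translation) == 3L, all(is.finite(translation)))
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform A `rigid_transform`.
#' @param xyz An n x 3 coordinate matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, xyz) {
  xyz <- as_xyz_matrix(xyz)
  sweep(xyz %*% t(transform$rotation), 2, transform$translation, "+")
}

as_xyz_matrix <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("coordinates must be an n x 3 matrix", call. = FALSE)
  storage.mode(xyz) <- "double"
  xyz
}

# ---- superposition ----------------------------------------------------------

#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimising the RMSD of `mobile`
#' onto `target`. Reflections are excluded: the determinant of the rotation is
#' forced to +1 by flipping the smallest singular direction if necessary.
#'
#' @param mobile,target Equal-length n x 3 coordinate matrices, n >= 3.
#' @return A `superposition_result`: list with `transform` (a
#'   [rigid_transform()]), `rmsd` (Angstrom) and `n_atoms`.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as_xyz_matrix(mobile)
  target <- as_xyz_matrix(target)
  if (nrow(mobile) != nrow(target)) {
    stop("coordinate sets have different lengths", call. = FALSE)
  }
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 atom pairs for superposition", call. = FALSE)
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(target, 2, ct)
  # collinear point sets leave the rotation about the line undetermined
  if (svd(P, nu = 0, nv = 0)$d[2] < 1e-8 * max(1, svd(P, nu = 0, nv = 0)$d[1])) {
    stop("degenerate geometry: point set is (near-)collinear", call. = FALSE)
  }
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  translation <- ct - as.numeric(R %*% cm)
  tr <- rigid_transform(R, translation)
  moved <- apply_transform(tr, mobile)
  structure(list(transform = tr,
                 rmsd = sqrt(mean(rowSums((moved - target)^2))),
                 n_atoms = n),
            class = "superposition_result")
}

#' Root-mean-square deviation between paired coordinate sets
#'
#' @param a,b Equal-length n x 3 coordinate matrices.
#' @param superpose If `TRUE`, the minimal RMSD after least-squares
#'   superposition is returned; otherwise the plain paired RMSD.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, superpose = FALSE) {
  a <- as_xyz_matrix(a)
  b <- as_xyz_matrix(b)
  if (nrow(a) != nrow(b)) stop("coordinate sets have different lengths", call. = FALSE)
  if (nrow(a) < 1L) stop("empty coordinate sets", call. = FALSE)
  if (superpose) {
    kabsch_superpose(a, b)$rmsd
  } else {
    sqrt(mean(rowSums((a - b)^2)))
  }
}

# ---- principal axes ---------------------------------------------------------

#' Principal axes of a point cloud
#'
#' Eigen-decomposition of the positional covariance about the centroid.
#' Columns of `$axes` are unit eigenvectors ordered by decreasing variance.
#' Eigenvector signs are fixed deterministically: each axis is oriented to
#' have a positive projection onto `orient` (when supplied and non-orthogonal),
#' falling back to a positive component on the file-frame axis of matching
#' index; the basis is then forced right-handed (det = +1) by flipping the
#' third axis if needed.
#'
#' @param points n x 3 coordinate matrix, n >= 3, non-collinear.
#' @param orient Optional length-3 vector used to orient axis signs (e.g. the
#'   vector from the core centroid to the cap centroid).
#' @return List with `axes` (3x3, columns = axes), `variances` (length 3,
#'   decreasing) and `centroid`.
#' @export
principal_axes <- function(points, orient = NULL) {
  points <- as_xyz_matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 points", call. = FALSE)
  centroid <- colMeans(points)
  X <- sweep(points, 2, centroid)
  covm <- crossprod(X) / (nrow(X) - 1)
  e <- eigen(covm, symmetric = TRUE)
  lam <- e$values
  if (lam[2] < 1e-12 * max(lam[1], 1)) {
    stop("degenerate geometry: point set is (near-)collinear", call. = FALSE)
  }
  if (min(abs(diff(lam))) < 1e-12 * max(lam[1], 1)) {
    warning("principal variances (near-)degenerate; axis order tie-broken by index")
  }
  axes <- e$vectors
  for (k in 1:3) {
    p <- if (!is.null(orient)) sum(axes[, k] * orient) else 0
    if (abs(p) < 1e-10) p <- axes[k, k]  # fall back to +x/+y/+z of file frame
    if (p < 0) axes[, k] <- -axes[, k]
  }
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  list(axes = axes, variances = lam, centroid = centroid)
}

# ---- rotation angle and Euler decomposition ---------------------------------

#' Total rotation angle of a rotation matrix
#'
#' The axis-angle magnitude, `acos((trace(R) - 1)/2)`, in degrees. Used as the
#' interdomain hinge-closure angle of a cap/core rotation.
#'
#' @param R 3x3 proper rotation matrix.
#' @return Angle in degrees, in \[0, 180\].
#' @export
rotation_angle <- function(R) {
  assert_rotation(R)
  rad2deg(acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))))
}

euler_conventions <- c("xyz", "zyx")

#' Intrinsic Euler (Tait-Bryan) angles of a rotation
#'
#' Decomposes a rotation into intrinsic pitch/roll/yaw. Roll is the rotation
#' about the x axis, pitch about y, yaw about z of the frame in which the
#' rotation is expressed; in the canonical cap frame these are the cap's
#' principal axes in decreasing-variance order, so pitch reads as a cap-core
#' closing angle, roll as a twisting motion and yaw as a left-to-right lateral
#' rotation. The default convention `"xyz"` applies roll, then pitch, then yaw
#' as intrinsic rotations (matrix product `Rx(roll) Ry(pitch) Rz(yaw)`);
#' `"zyx"` applies yaw, then pitch, then roll.
#'
#' Near gimbal lock (|pitch| within `lock_tol` of 90 degrees) roll and yaw are
#' not separable; roll is set to 0, yaw absorbs the free angle, and a warning
#' is issued.
#'
#' @param R 3x3 proper rotation matrix.
#' @param convention `"xyz"` (default) or `"zyx"`.
#' @param lock_tol Gimbal-lock tolerance on |cos(pitch)|.
#' @return An `euler_angles` object: list with `pitch`, `roll`, `yaw`
#'   (degrees, each in (-180, 180\]) and `convention`.
#' @export
euler_from_rotation <- function(R, convention = "xyz", lock_tol = 1e-6) {
  assert_rotation(R)
  convention <- match.arg(convention, euler_conventions)
  clamp <- function(x) max(-1, min(1, x))
  if (convention == "xyz") {
    sp <- clamp(R[1, 3])
    if (abs(abs(sp) - 1) < lock_tol) {
      warning("gimbal lock: |pitch| ~ 90 degrees; roll set to 0")
      pitch <- rad2deg(asin(sp))
      roll <- 0
      yaw <- rad2deg(atan2(R[2, 1], R[2, 2]))
    } else {
      pitch <- rad2deg(asin(sp))
      roll <- rad2deg(atan2(-R[2, 3], R[3, 3]))
      yaw <- rad2deg(atan2(-R[1, 2], R[1, 1]))
    }
  } else { # zyx
    sp <- clamp(-R[3, 1])
    if (abs(abs(sp) - 1) < lock_tol) {
      warning("gimbal lock: |pitch| ~ 90 degrees; roll set to 0")
      pitch <- rad2deg(asin(sp))
      roll <- 0
      yaw <- rad2deg(atan2(-R[1, 2], R[2, 2]))
    } else {
      pitch <- rad2deg(asin(sp))
      roll <- rad2deg(atan2(R[3, 2], R[3, 3]))
      yaw <- rad2deg(atan2(R[2, 1], R[1, 1]))
    }
  }
  euler_angles(pitch, roll, yaw, convention)
}

#' Construct an Euler-angle object
#'
#' @param pitch,roll,yaw Angles in degrees, each in (-180, 180\].
#' @param convention Convention tag, see [euler_from_rotation()].
#' @return An `euler_angles` object.
#' @export
euler_angles <- function(pitch, roll, yaw, convention = "xyz") {
  convention <- match.arg(convention, euler_conventions)
  ang <- c(pitch = pitch, roll = roll, yaw = yaw)
  if (!all(is.finite(ang))) stop("angles must be finite", call. = FALSE)
  if (any(ang <= -180 | ang > 180)) {
    stop("angles must lie in (-180, 180] degrees", call. = FALSE)
  }
  structure(list(pitch = pitch, roll = roll, yaw = yaw,
                 convention = convention),
            class = "euler_angles")
}

elementary_rotation <- function(axis, angle_deg) {
  a <- deg2rad(angle_deg)
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
         y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
         z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

#' Rotation matrix from intrinsic Euler angles
#'
#' Exact inverse of [euler_from_rotation()] away from gimbal lock.
#'
#' @param angles An `euler_angles` object, or a list with `pitch`, `roll`,
#'   `yaw` (degrees) and optionally `convention`.
#' @return 3x3 proper rotation matrix.
#' @export
rotation_from_euler <- function(angles) {
  if (!is.list(angles)) stop("angles must be an euler_angles object or list", call. = FALSE)
  conv <- angles$convention %||% "xyz"
  conv <- match.arg(conv, euler_conventions)
  Rx <- elementary_rotation("x", angles$roll)
  Ry <- elementary_rotation("y", angles$pitch)
  Rz <- elementary_rotation("z", angles$yaw)
  if (conv == "xyz") Rx %*% Ry %*% Rz else Rz %*% Ry %*% Rx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.euler_angles <- function(x, ...) {
  cat(sprintf("Euler angles (%s): pitch %.3f, roll %.3f, yaw %.3f degrees\n",
              x$convention, x$pitch, x$roll, x$yaw))
  invisible(x)
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("Superposition of %d atoms: RMSD %.4f A, rotation %.3f degrees\n",
              x$n_atoms, x$rmsd, rotation_angle(x$transform$rotation)))
  invisible(x)
}
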