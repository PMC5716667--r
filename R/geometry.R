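# Rigid-transform algebra, Euler conventions and spherical seeding.
#
# Euler convention used throughout the package: ZXZ with angles
# (phi, psi, theta) and composition
#
#     R = Rz(psi) %*% Rx(theta) %*% Rz(phi)
#
# phi is the in-plane rotation about the reference z-axis; psi and theta
# jointly encode the out-of-plane orientation (theta is the tilt of the
# local z-axis away from the reference z-axis). At the gimbal degeneracy
# (theta = 0 or 180) psi is reported as 0 and the full in-plane rotation
# assigned to phi. Angles are stored in degrees, phi/psi in [0, 360) and
# theta in [0, 180].

Rz <- function(a) {
  a <- deg2rad(a)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

Rx <- function(a) {
  a <- deg2rad(a)
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' Convert ZXZ Euler angles to a rotation matrix
#'
#' @param angles numeric length-3 vector `c(phi, psi, theta)` in degrees.
#' @return 3x3 orthonormal rotation matrix with determinant +1.
#' @details The convention is `R = Rz(psi) %*% Rx(theta) %*% Rz(phi)`:
#'   an in-plane rotation `phi` about z, followed by the out-of-plane
#'   tilt `theta` about x and the azimuth `psi` about z.
#' @examples
#' euler_to_matrix(c(0, 0, 0))       # identity
#' euler_to_matrix(c(90, 0, 0))      # maps +x to +y
#' @export
euler_to_matrix <- function(angles) {
  assert_finite(angles, "angles")
  if (length(angles) != 3L) stopf("angles must have length 3 (phi, psi, theta)")
  Rz(angles[2]) %*% Rx(angles[3]) %*% Rz(angles[1])
}

#' Recover ZXZ Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_matrix()]. At the gimbal degeneracy
#' (`theta` near 0 or 180) `psi` is set to 0 and the whole in-plane
#' rotation is carried by `phi`.
#'
#' @param rotation 3x3 orthonormal matrix, det +1 (checked to 1e-6).
#' @return named numeric vector `c(phi, psi, theta)` in degrees.
#' @export
matrix_to_euler <- function(rotation) {
  check_rotation(rotation)
  R <- rotation
  st <- sqrt(R[3, 1]^2 + R[3, 2]^2)
  theta <- rad2deg(atan2(st, R[3, 3]))
  if (st < 1e-9) {
    ## Rz(psi) Rz(+-phi): assign everything to phi
    if (R[3, 3] > 0) {
      phi <- rad2deg(atan2(R[2, 1], R[1, 1]))
    } else {
      phi <- rad2deg(atan2(-R[1, 2], R[1, 1]))
    }
    psi <- 0
  } else {
    phi <- rad2deg(atan2(R[3, 1], R[3, 2]))
    psi <- rad2deg(atan2(R[1, 3], -R[2, 3]))
  }
  c(phi = posmod(phi, 360), psi = posmod(psi, 360),
    theta = clamp(theta, 0, 180))
}

check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != c(3L, 3L)) || any(!is.finite(R)))
    stopf("rotation must be a finite 3x3 matrix")
  err <- max(abs(crossprod(R) - diag(3)))
  if (err > tol) stopf("rotation matrix is not orthonormal (error %.2e)", err)
  if (det(R) < 0) stopf("rotation matrix has determinant -1 (improper rotation)")
  invisible(R)
}

#' Construct a rigid transform
#'
#' @param rotation 3x3 orthonormal matrix (det +1).
#' @param translation length-3 numeric vector.
#' @param unit unit of the translation, `"voxel"` or `"angstrom"`.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            unit = "voxel") {
  check_rotation(rotation)
  assert_finite(translation, "translation")
  if (length(translation) != 3L) stopf("translation must have length 3")
  unit <- match.arg(unit, c("voxel", "angstrom"))
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 unit = unit),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  e <- matrix_to_euler(x$rotation)
  cat(sprintf(
    "rigid_transform: euler (phi %.2f, psi %.2f, theta %.2f) deg, t = (%.3f, %.3f, %.3f) %s\n",
    e[1], e[2], e[3], x$translation[1], x$translation[2], x$translation[3],
    x$unit))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` is the transform "apply b, then a":
#' rotation `Ra Rb`, translation `Ra tb + ta`.
#'
#' @param a,b `rigid_transform` objects in the same unit.
#' @return `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  check_same_unit(a, b)
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation,
                  unit = a$unit)
}

#' Invert a rigid transform
#' @param a `rigid_transform`.
#' @return `rigid_transform`.
#' @export
invert_transform <- function(a) {
  Rt <- t(a$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% a$translation), unit = a$unit)
}

check_same_unit <- function(a, b) {
  if (!inherits(a, "rigid_transform") || !inherits(b, "rigid_transform"))
    stopf("inputs must be rigid_transform objects")
  if (!identical(a$unit, b$unit))
    stopf("unit mismatch: '%s' vs '%s'", a$unit, b$unit)
  invisible(TRUE)
}

#' Relative transform of b in the local frame of a
#'
#' Returns the transform of pose `b` expressed in the local coordinate
#' frame of pose `a`: rotation `t(Ra) Rb`, translation `t(Ra) (tb - ta)`.
#' `relative_transform(a, a)` is the identity and
#' `relative_transform(a, b)` is the inverse of `relative_transform(b, a)`.
#'
#' @param a,b `rigid_transform` poses in the same global frame and unit.
#' @return `rigid_transform`.
#' @export
relative_transform <- function(a, b) {
  check_same_unit(a, b)
  Rt <- t(a$rotation)
  rigid_transform(Rt %*% b$rotation,
                  as.numeric(Rt %*% (b$translation - a$translation)),
                  unit = a$unit)
}

#' Rotation about an arbitrary axis
#'
#' @param axis length-3 direction vector (normalized internally).
#' @param angle rotation angle in degrees.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @export
rotation_about_axis <- function(axis, angle) {
  assert_finite(axis, "axis")
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stopf("axis must be non-zero")
  u <- axis / n
  a <- deg2rad(angle)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Geodesic angle of a rotation
#'
#' The angle (degrees, in [0, 180]) of the rotation `R`, or of the
#' residual rotation `t(R1) R2` when two matrices are given.
#'
#' @param R rotation matrix, or the first of two.
#' @param R2 optional second rotation matrix.
#' @return angle in degrees.
#' @export
rotation_angle <- function(R, R2 = NULL) {
  if (!is.null(R2)) R <- t(R) %*% R2
  ct <- (sum(diag(R)) - 1) / 2
  rad2deg(acos(clamp(ct, -1, 1)))
}

#' Deterministic Fibonacci lattice on the unit sphere
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors, approximately evenly spaced.
#' @details Uses the golden-angle spiral: point i (0-based) has
#'   `z = 1 - 2 (i + 0.5) / n` and azimuth `i * 2 pi / golden^2`.
#' @export
fibonacci_sphere <- function(n) {
  if (n < 1) stopf("n must be >= 1")
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  az <- i * ga
  cbind(x = r * cos(az), y = r * sin(az), z = z)
}

#' Euler angles whose local z-axis equals a given direction
#'
#' Returns a ZXZ triplet such that `euler_to_matrix(result) %*% c(0,0,1)`
#' equals `normal`. The in-plane angle phi is drawn uniformly at random
#' from the seeded generator (it is unconstrained by the normal).
#'
#' @param normal unit 3-vector (checked to 1e-6).
#' @param rng_seed integer seed for the random phi, or `NULL` with `phi`
#'   given explicitly.
#' @param phi optional explicit in-plane angle in degrees (overrides the
#'   random draw).
#' @return named numeric `c(phi, psi, theta)` in degrees.
#' @export
normal_to_euler <- function(normal, rng_seed = NULL, phi = NULL) {
  assert_finite(normal, "normal")
  n <- sqrt(sum(normal^2))
  if (abs(n - 1) > 1e-6) stopf("normal must be a unit vector (|n| = %.6f)", n)
  v <- normal / n
  theta <- rad2deg(atan2(sqrt(v[1]^2 + v[2]^2), v[3]))
  ## R z = (sin(psi) sin(theta), -cos(psi) sin(theta), cos(theta))
  psi <- if (sqrt(v[1]^2 + v[2]^2) < 1e-9) 0 else rad2deg(atan2(v[1], -v[2]))
  if (is.null(phi)) {
    if (is.null(rng_seed)) stopf("either rng_seed or phi must be given")
    phi <- with_seed(rng_seed, stats::runif(1, 0, 360))
  }
  c(phi = posmod(phi, 360), psi = posmod(psi, 360), theta = clamp(theta, 0, 180))
}

#' Evenly spaced, surface-normal-oriented seed points on a sphere
#'
#' Places `round(4 pi (d/2)^2 / spacing^2)` points on the sphere surface
#' using a deterministic Fibonacci lattice. The out-of-plane orientation
#' of every seed is the outward surface normal; in-plane angles phi are
#' drawn uniformly at random from the seeded generator. This reproduces
#' the standard initialisation for averaging coat proteins on annotated
#' spherical vesicles (10 nm spacing by default).
#'
#' @param center vesicle center, length-3, voxels.
#' @param diameter sphere diameter in nm.
#' @param spacing target point spacing in nm (default 10).
#' @param voxel_size voxel size in Angstrom.
#' @param rng_seed integer seed for the random phi angles.
#' @param vesicle_id identifier copied into the output.
#' @return data.frame with columns `vesicle_id, x, y, z` (voxels),
#'   `phi, psi, theta` (degrees).
#' @export
sphere_seed_points <- function(center, diameter, spacing = 10, voxel_size,
                               rng_seed, vesicle_id = 1L) {
  assert_finite(center, "center")
  if (diameter <= 0) stopf("diameter must be > 0")
  if (spacing <= 0) stopf("spacing must be > 0")
  if (spacing >= pi * diameter / 2)
    stopf("spacing %.1f nm is too coarse for a %.1f nm sphere", spacing, diameter)
  r_nm <- diameter / 2
  n <- max(1L, as.integer(round(4 * pi * r_nm^2 / spacing^2)))
  dirs <- fibonacci_sphere(n)
  r_vox <- r_nm * 10 / voxel_size
  pos <- sweep(dirs * r_vox, 2, center, "+")
  phis <- with_seed(rng_seed, stats::runif(n, 0, 360))
  ang <- t(vapply(seq_len(n),
                  function(i) normal_to_euler(dirs[i, ], phi = phis[i]),
                  numeric(3)))
  data.frame(vesicle_id = vesicle_id,
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             phi = ang[, 1], psi = ang[, 2], theta = ang[, 3])
}
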