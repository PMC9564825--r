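# Small numerical helpers shared across modules.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about z
#' @param theta angle in degrees
#' @return 3x3 rotation matrix
#' @keywords internal
rot_z <- function(theta) {
  t <- .deg2rad(theta)
  matrix(c(cos(t), sin(t), 0,
           -sin(t), cos(t), 0,
           0, 0, 1), 3, 3)
}

#' Rotation matrix about y
#' @param theta angle in degrees
#' @keywords internal
rot_y <- function(theta) {
  t <- .deg2rad(theta)
  matrix(c(cos(t), 0, -sin(t),
           0, 1, 0,
           sin(t), 0, cos(t)), 3, 3)
}

#' Rotation about an arbitrary axis (Rodrigues)
#' @param axis 3-vector, need not be unit length
#' @param theta angle in degrees
#' @keywords internal
rot_about_axis <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  t <- .deg2rad(theta)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

#' Rotation angle of a rotation matrix, in degrees
#' @param R 3x3 proper rotation matrix
#' @keywords internal
rotation_angle_deg <- function(R) {
  tr <- sum(diag(R))
  .rad2deg(acos(min(1, max(-1, (tr - 1) / 2))))
}

# Principal axes of a point cloud: eigenvectors of the covariance, ordered by
# decreasing variance. Returns list(values, vectors, center).
principal_axes <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3) stop("principal_axes: need at least 3 points")
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  e <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, center = ctr)
}

# Angle between two vectors in degrees, in [0, 180].
angle_between_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  .rad2deg(acos(min(1, max(-1, ca))))
}

.unit <- function(v) v / sqrt(sum(v^2))

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Standard atomic masses (u) for mass-weighted centers.
.ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, MG = 24.305, ZN = 65.38,
  CA = 40.078, "NA" = 22.990, K = 39.098, CL = 35.45, MN = 54.938
)

element_mass <- function(element) {
  m <- .ATOMIC_MASSES[toupper(element)]
  if (anyNA(m)) {
    warning("unknown element(s) ", paste(unique(element[is.na(m)]), collapse = ", "),
            "; using carbon mass")
    m[is.na(m)] <- .ATOMIC_MASSES[["C"]]
  }
  unname(m)
}

# van der Waals radii (Angstrom) used by the SASA kernel.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

element_vdw_radius <- function(element, default = 1.70) {
  r <- .VDW_RADII[toupper(element)]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(element[is.na(r)]), collapse = ", "),
            "; using default vdW radius ", default, " A")
    r[is.na(r)] <- default
  }
  unname(r)
}

# Quasi-uniform points on the unit sphere (Fibonacci / golden-section spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
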