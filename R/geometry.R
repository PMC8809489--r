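# Small 3D geometry kernel: torsions, internal-coordinate atom placement and
# least-squares (Kabsch) superposition.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a^2))

#' Signed torsion angle of four points
#'
#' Standard atan2 torsion from the two plane normals, in degrees in
#' `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 Cartesian 3-vectors.
#' @return Signed dihedral angle in degrees.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    ps_value_error("three consecutive points are collinear; torsion undefined")
  }
  m1 <- vcross(n1, b2 / vnorm(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Place an atom X bonded to p3 with |X - p3| = r, angle(p2, p3, X) = ang
# (degrees) and torsion(p1, p2, p3, X) = dih (degrees). NeRF construction.
place_atom <- function(p1, p2, p3, r, ang, dih) {
  a <- ang * pi / 180
  d <- dih * pi / 180
  b1 <- p2 - p1
  b2 <- p3 - p2
  u <- b2 / vnorm(b2)
  nv <- vcross(b1, b2)
  if (vnorm(nv) < 1e-10) ps_value_error("reference points are collinear")
  nv <- nv / vnorm(nv)
  m <- vcross(nv, u)
  p3 + r * (-cos(a) * u + sin(a) * (cos(d) * m + sin(d) * nv))
}

#' Optimal least-squares superposition of two point sets
#'
#' Kabsch algorithm: finds the proper rotation `R` and translation `t`
#' minimising the RMSD of `Q %*% t(R) + t` onto `P` (rows are points).
#'
#' @param p,q n x 3 matrices of matched points (`q` is moved onto `p`).
#' @param allow_inversion also consider an improper (mirror) transform and
#'   keep it if it fits better.
#' @return List with `rotation` (3x3), `translation` (length 3), `rmsd`, and
#'   `inverted` (logical; only possible when `allow_inversion = TRUE`).
#' @export
kabsch <- function(p, q, allow_inversion = FALSE) {
  stopifnot(is.matrix(p), is.matrix(q), nrow(p) == nrow(q), ncol(p) == 3)
  fit1 <- .kabsch_proper(p, q)
  if (!allow_inversion) return(c(fit1, list(inverted = FALSE)))
  fit2 <- .kabsch_proper(p, -q)
  if (fit2$rmsd < fit1$rmsd) {
    # net transform is x -> R(-x) + t; report as improper rotation -R
    c(list(rotation = -fit2$rotation, translation = fit2$translation,
           rmsd = fit2$rmsd), list(inverted = TRUE))
  } else {
    c(fit1, list(inverted = FALSE))
  }
}

.kabsch_proper <- function(p, q) {
  pc <- colMeans(p)
  qc <- colMeans(q)
  p0 <- sweep(p, 2, pc)
  q0 <- sweep(q, 2, qc)
  h <- t(q0) %*% p0
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  dd <- diag(c(1, 1, d))
  rot <- sv$v %*% dd %*% t(sv$u)
  moved <- q0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((p0 - moved)^2)))
  list(rotation = rot, translation = as.numeric(pc - rot %*% qc), rmsd = rmsd)
}

apply_rigid <- function(coords, rotation, translation) {
  sweep(coords %*% t(rotation), 2, translation, `+`)
}

random_rotation_matrix <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
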