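# Small 3D geometry kernel shared by the metrics, the hydrogen-bond
# detector and the fixture generator. Coordinates are N x 3 matrices in
# Angstrom throughout.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalise a zero-length vector")
  v / n
}

# Angle at vertex b of the triangle a-b-c, in degrees.
angle_deg <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Rodrigues rotation matrix: angle (degrees) about unit axis.
rotation_about_axis <- function(axis, angle_deg) {
  k <- unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Place atom D from reference atoms A, B, C given the internal
# coordinates bond = |C-D|, angle = B-C-D (deg), dihedral = A-B-C-D
# (deg). Standard natural-extension-reference-frame construction.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  d2 <- c(
    -bond * cos(th),
    bond * sin(th) * cos(ph),
    bond * sin(th) * sin(ph)
  )
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- cbind(bc, pracma_cross(n, bc), n)
  as.numeric(m %*% d2 + c)
}

pracma_cross <- function(u, v) {
  c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `mobile` onto `target` by singular value decomposition of the
#' cross-covariance matrix. Reflections are never returned: if the best
#' orthogonal map is improper the smallest singular direction is
#' flipped, giving the best proper rotation.
#'
#' @param mobile,target Numeric N x 3 coordinate matrices with equal
#'   dimensions, N >= 3.
#' @return An object of class `pepqa_transform`: a list with `rotation`
#'   (3 x 3, det +1), `translation` (length-3) and `rmsd`, the minimal
#'   RMSD in Angstrom. Apply it with [apply_transform()]; the convention
#'   is `x %*% t(rotation) + translation`.
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' fit <- kabsch(x, x)
#' fit$rmsd
#' @export
kabsch <- function(mobile, target) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3) {
    abort("`mobile` and `target` must be N x 3 matrices of equal size")
  }
  if (nrow(mobile) < 3) abort("superposition needs at least 3 atom pairs")
  if (anyNA(mobile) || anyNA(target)) abort("coordinates contain NA")

  mc <- colMeans(mobile)
  tc <- colMeans(target)
  p <- sweep(mobile, 2, mc)
  q <- sweep(target, 2, tc)
  h <- crossprod(p, q)
  sv <- svd(h)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    warn("near-degenerate (collinear) coordinates; superposition is ill-conditioned")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  s <- diag(c(1, 1, d))
  r <- sv$v %*% s %*% t(sv$u)
  trans <- tc - as.numeric(r %*% mc)
  rmsd <- sqrt(sum((p %*% t(r) - q)^2) / nrow(mobile))
  structure(
    list(rotation = r, translation = as.numeric(trans), rmsd = rmsd),
    class = "pepqa_transform"
  )
}

#' Apply a rigid transform to coordinates
#'
#' @param coords Numeric N x 3 matrix.
#' @param transform A `pepqa_transform` from [kabsch()], or any list
#'   with `rotation` and `translation`.
#' @return Transformed N x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2,
        transform$translation, "+")
}

#' @export
print.pepqa_transform <- function(x, ...) {
  cat("Rigid transform (Kabsch fit), rmsd =", format(x$rmsd, digits = 6), "A\n")
  invisible(x)
}

rmsd_between <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  sqrt(sum((a - b)^2) / nrow(a))
}
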