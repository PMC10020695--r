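#' Euclidean distance between two points
#'
#' Plain Euclidean norm of the difference of two 3-vectors, in the units of
#' the input coordinates (angstroms throughout this package).
#'
#' @param p,q Numeric 3-vectors (x, y, z) in angstroms.
#' @return Non-negative distance in angstroms.
#' @examples
#' atom_distance(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
atom_distance <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  stopifnot(length(p) == 3L, length(q) == 3L)
  if (!all(is.finite(p)) || !all(is.finite(q)))
    stop("atom_distance: coordinates must be finite")
  sqrt(sum((p - q)^2))
}

#' Signed dihedral angle of four points
#'
#' Torsion about the p2-p3 axis under the IUPAC sign convention: 0 degrees
#' for the cis (eclipsed) arrangement, 180 for trans. The value is identical
#' when the four points are taken in reversed order and changes sign under
#' mirror reflection.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors in angstroms.
#' @return Angle in degrees in (-180, 180].
#' @examples
#' dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)) # 180 (trans)
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  pts <- lapply(list(p1, p2, p3, p4), as.numeric)
  if (!all(vapply(pts, function(p) length(p) == 3L && all(is.finite(p)), logical(1))))
    stop("dihedral_angle: need four finite 3-vectors")
  b1 <- pts[[2]] - pts[[1]]
  b2 <- pts[[3]] - pts[[2]]
  b3 <- pts[[4]] - pts[[3]]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9)
    stop("degenerate dihedral: collinear points")
  b2u <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross3(b2u, n1) * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# map any angle in degrees to (-180, 180]
wrap_angle <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  # %% can leave exactly -180 as 180; keep 180 representative
  y[y <= -180] <- y[y <= -180] + 360
  y
}

# smallest absolute separation of two angles on the circle, degrees
angle_sep <- function(a, b) {
  abs(wrap_angle(a - b))
}
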