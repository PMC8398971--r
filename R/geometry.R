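# Low-level geometry: vector helpers, rigid superposition, plane fitting and
# exact convex polygon clipping used for base-stacking overlap areas.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.norm3 <- function(a) sqrt(sum(a * a))

.unit3 <- function(a) {
  n <- .norm3(a)
  if (n < 1e-14) stop("cannot normalize a zero vector")
  a / n
}

#' Rigid-body superposition by the Kabsch algorithm
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' point sets with positional correspondence (row i of `P` corresponds to row
#' i of `Q`).  The transform maps `P` onto `Q` as
#' `sweep(P %*% rotation, 2, translation, "+")`.
#'
#' @param P,Q Numeric matrices of identical dimension n x 3 (n >= 3),
#'   coordinates in Angstrom.
#' @return List with `rotation` (3 x 3 proper orthogonal, applied on the
#'   right of row-vector coordinates), `translation` (length-3), and `rmsd`
#'   (Angstrom).
#' @export
#' @examples
#' P <- matrix(rnorm(15), 5, 3)
#' kabsch_superpose(P, P)$rmsd   # 0
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L)
    stop("P and Q must be n x 3 matrices of identical dimension")
  if (nrow(P) < 3L) stop("at least 3 corresponding points are required")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  if (s$d[2] < 1e-10 * max(s$d[1], 1e-300))
    stop("degenerate (collinear) point set: superposition is ill-defined")
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  resid <- Pc %*% R - Qc
  list(rotation = R,
       translation = as.numeric(cq - cp %*% R),
       rmsd = sqrt(sum(resid^2) / nrow(P)))
}

#' Least-squares mean plane of a base
#'
#' Fits the mean plane of the ring (plus exocyclic) atoms of a chromophore
#' site by singular value decomposition of the centered coordinates.  The
#' normal sign is fixed deterministically: the component of largest magnitude
#' is made positive (ties broken towards +z, then +y, then +x), so congruent
#' inputs give reproducible normals.
#'
#' @param site A `chromophore_site` (or a plain n x 3 coordinate matrix).
#' @return List with `normal` (unit 3-vector) and `point` (centroid).
#' @export
base_plane <- function(site) {
  xyz <- if (is.matrix(site)) site else site_coords(site, site$ring_atoms)
  if (nrow(xyz) < 3L) stop("need at least 3 ring atoms to fit a plane")
  ctr <- colMeans(xyz)
  Xc <- sweep(xyz, 2, ctr)
  s <- svd(Xc)
  if (s$d[2] < 1e-10 * max(s$d[1], 1e-300))
    stop("degenerate geometry: ring atoms are collinear")
  n <- s$v[, 3]
  k <- which.max(abs(n) + c(1e-12, 2e-12, 3e-12))  # tie-break x<y<z
  if (n[k] < 0) n <- -n
  list(normal = as.numeric(n), point = as.numeric(ctr))
}

# Orthonormal in-plane basis (e1, e2) completing a plane normal.
.plane_basis <- function(normal) {
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit3(.cross3(normal, a))
  e2 <- .cross3(normal, e1)
  cbind(e1, e2)
}

# Signed area of a 2D polygon (shoelace); vertices as n x 2 matrix.
.poly_area_signed <- function(v) {
  n <- nrow(v)
  if (is.null(n) || n < 3L) return(0)
  x <- v[, 1]; y <- v[, 2]
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

.poly_area <- function(v) abs(.poly_area_signed(v))

# Counter-clockwise convex hull of 2D points, as vertex matrix.
.convex_hull2d <- function(pts) {
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  v <- pts[idx, , drop = FALSE]
  if (.poly_area_signed(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  v
}

# Sutherland-Hodgman clipping of polygon `subj` by convex polygon `clip`
# (both CCW n x 2 matrices).  Exact up to floating point.
.clip_convex <- function(subj, clip) {
  out <- subj
  nc <- nrow(clip)
  for (k in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0L) return(NULL)
    a <- clip[k, ]; b <- clip[if (k == nc) 1L else k + 1L, ]
    ed <- b - a
    inside <- function(p) ed[1] * (p[2] - a[2]) - ed[2] * (p[1] - a[1]) >= -1e-12
    inter <- function(p, q) {
      d <- q - p
      denom <- ed[1] * d[2] - ed[2] * d[1]
      t <- (ed[1] * (a[2] - p[2]) - ed[2] * (a[1] - p[1])) / denom
      p + t * d
    }
    inp <- out; out <- NULL
    m <- nrow(inp)
    for (i in seq_len(m)) {
      p <- inp[i, ]; q <- inp[if (i == m) 1L else i + 1L, ]
      pin <- inside(p); qin <- inside(q)
      if (pin) {
        out <- rbind(out, p)
        if (!qin) out <- rbind(out, inter(p, q))
      } else if (qin) {
        out <- rbind(out, inter(p, q))
      }
    }
  }
  out
}

# Intersection area of the convex hulls of two 2D point sets.
.hull_intersection_area <- function(pts_i, pts_j) {
  hi <- .convex_hull2d(pts_i)
  hj <- .convex_hull2d(pts_j)
  if (nrow(hi) < 3L || nrow(hj) < 3L) stop("degenerate polygon")
  inter <- .clip_convex(hi, hj)
  if (is.null(inter) || nrow(inter) < 3L) 0 else .poly_area(inter)
}
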