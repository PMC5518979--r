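#' Signed area of a closed polygon
#'
#' @param poly two-column matrix of vertices (m), implicitly closed.
#' @return signed area (m^2); positive for counterclockwise orientation.
#' @keywords internal
polygonSignedArea <- function(poly) {
  poly <- as.matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' Pairwise segment-intersection test over all non-adjacent edge pairs.
#'
#' @param poly two-column vertex matrix, implicitly closed.
#' @return logical.
#' @export
polygonIsSimple <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  p1 <- poly
  p2 <- poly[c(2:n, 1), , drop = FALSE]
  segInt <- function(a1, a2, b1, b2) {
    d1 <- a2 - a1; d2 <- b2 - b1
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-300) return(FALSE)
    r <- b1 - a1
    t <- (r[1] * d2[2] - r[2] * d2[1]) / den
    u <- (r[1] * d1[2] - r[2] * d1[1]) / den
    t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    js <- seq(i + 2, jmax)
    for (j in js) {
      if (segInt(p1[i, ], p2[i, ], p1[j, ], p2[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Area, centroid and second/product moments of a polygon
#'
#' Exact Green's-theorem formulas for a simple closed polygon. Results are
#' orientation-independent (the sign is normalised) and the moments are
#' reported about the centroidal axes.
#'
#' @param poly two-column matrix of vertices (m), implicitly closed.
#' @param check if `TRUE` (default) verify the polygon is simple.
#' @return list with `A` (m^2), `centroid` (length-2, m), `Ix`, `Iy`, `Ixy`
#'   (m^4, centroidal).
#' @export
polygonSectionProperties <- function(poly, check = TRUE) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3) stop("polygon needs at least 3 vertices")
  if (check && !polygonIsSimple(poly)) stop("polygon is self-intersecting")
  if (polygonSignedArea(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-300) stop("degenerate polygon (area is zero)")
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  Ix0 <- sum((y^2 + y * yn + yn^2) * cr) / 12
  Iy0 <- sum((x^2 + x * xn + xn^2) * cr) / 12
  Ixy0 <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  list(A = A,
       centroid = c(cx, cy),
       Ix = Ix0 - A * cy^2,
       Iy = Iy0 - A * cx^2,
       Ixy = Ixy0 - A * cx * cy)
}

#' Raw (origin-referenced) polygon moments
#'
#' Like [polygonSectionProperties()] but moments are about the coordinate
#' origin, which makes hollow-section composition by subtraction exact.
#' @keywords internal
polygonRawMoments <- function(poly) {
  poly <- as.matrix(poly)
  if (polygonSignedArea(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  list(A = A,
       Sx = sum((y + yn) * cr) / 6,          # integral of y dA
       Sy = sum((x + xn) * cr) / 6,          # integral of x dA
       Ix0 = sum((y^2 + y * yn + yn^2) * cr) / 12,
       Iy0 = sum((x^2 + x * xn + xn^2) * cr) / 12,
       Ixy0 = sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24)
}

#' Clip a polygon by a half-plane
#'
#' Sutherland-Hodgman clipping of `poly` against the half-plane
#' `dot(n, p) <= d`.
#' @keywords internal
polygonClipHalfplane <- function(poly, n, d) {
  poly <- as.matrix(poly)
  if (polygonSignedArea(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  np <- nrow(poly)
  out <- matrix(0, nrow = 2 * np, ncol = 2)
  m <- 0
  sv <- poly %*% n - d
  for (i in seq_len(np)) {
    j <- if (i == np) 1 else i + 1
    pi <- poly[i, ]; pj <- poly[j, ]
    si <- sv[i]; sj <- sv[j]
    if (si <= 0) { m <- m + 1; out[m, ] <- pi }
    if ((si <= 0) != (sj <= 0)) {
      t <- si / (si - sj)
      m <- m + 1
      out[m, ] <- pi + t * (pj - pi)
    }
  }
  if (m < 3) return(NULL)
  out[seq_len(m), , drop = FALSE]
}

#' Regular n-gon approximation of a circle
#'
#' @param radius circle radius (m).
#' @param n number of vertices.
#' @param centre length-2 centre.
#' @return two-column vertex matrix (counterclockwise).
#' @export
circleOutline <- function(radius, n = 256L, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(centre[1] + radius * cos(th), centre[2] + radius * sin(th))
}

#' Inward offset of a closed outline
#'
#' Moves every vertex inward by `t` along its (angle-bisector) vertex normal;
#' vertices whose offset collapses past the local radius are dropped.
#' @keywords internal
polygonInwardOffset <- function(poly, t) {
  poly <- as.matrix(poly)
  if (polygonSignedArea(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  n <- nrow(poly)
  prev <- poly[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- poly[c(2:n, 1), , drop = FALSE]
  e1 <- poly - prev
  e2 <- nxt - poly
  norm1 <- sqrt(rowSums(e1^2)); norm2 <- sqrt(rowSums(e2^2))
  e1 <- e1 / pmax(norm1, 1e-300); e2 <- e2 / pmax(norm2, 1e-300)
  # outward normals of a CCW polygon point right of the edge direction
  n1 <- cbind(e1[, 2], -e1[, 1])
  n2 <- cbind(e2[, 2], -e2[, 1])
  nv <- n1 + n2
  nn <- sqrt(rowSums(nv^2))
  nv <- nv / pmax(nn, 1e-300)
  # miter scale so the offset distance to both edges is t
  scale <- 1 / pmax(rowSums(nv * n1), 0.1)
  inner <- poly - t * scale * nv
  ctr <- colMeans(poly)
  r0 <- sqrt(rowSums(sweep(poly, 2, ctr)^2))
  r1v <- sweep(inner, 2, ctr)
  r1 <- sqrt(rowSums(r1v^2))
  keep <- r1 > 1e-9 & r1 < r0
  inner <- inner[keep, , drop = FALSE]
  if (nrow(inner) < 3) return(NULL)
  if (polygonSignedArea(inner) <= 0) return(NULL)
  inner
}
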