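## Convex-hull depth geometry.

# exact distance from point p to triangle (a, b, c) in 3D (Ericson's
# region-based closest-point-on-triangle construction)
point_triangle_distance <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum((p - a)^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum((p - b)^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + v * ab))^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum((p - c)^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + w * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + w * (c - b)))^2)))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  sqrt(sum((p - (a + v * ab + w * ac))^2))
}

# enumerate hull facets by brute force: a triplet is a facet when every other
# point lies on one side of its plane (within tol)
hull_facets <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  if (n < 4) abort("need at least 4 hull points")
  facets <- list()
  combs <- utils::combn(n, 3)
  ctr <- colMeans(pts)
  for (j in seq_len(ncol(combs))) {
    i <- combs[, j]
    a <- pts[i[1], ]; b <- pts[i[2], ]; c <- pts[i[3], ]
    nv <- c(
      (b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
      (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
      (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    nn <- sqrt(sum(nv^2))
    if (nn < tol) next  # degenerate (collinear) triplet
    nv <- nv / nn
    s <- as.vector((pts - matrix(a, n, 3, byrow = TRUE)) %*% nv)
    if (all(s <= tol) || all(s >= -tol)) {
      facets[[length(facets) + 1L]] <- i
    }
  }
  if (!length(facets)) abort("degenerate hull: no facets found (coplanar points?)")
  facets
}

#' Depth of points below a convex hull surface
#'
#' Builds the convex hull of `hull_points` (>= 4 non-coplanar 3D points) and
#' returns the Euclidean distance from each row of `points` to the closest
#' point on the hull surface — the "depth" of an electrode site beneath the
#' cortical convexity when the hull is built from the brain surface.
#'
#' @param points n-by-3 matrix of query points (mm).
#' @param hull_points m-by-3 matrix of surface points.
#' @return numeric vector of depths (mm); points on the hull return 0.
#' @export
depth_from_hull <- function(points, hull_points) {
  points <- as.matrix(points); hull_points <- as.matrix(hull_points)
  if (ncol(points) != 3 || ncol(hull_points) != 3) abort("points must be 3D")
  if (nrow(hull_points) < 4) abort("need at least 4 hull points")
  sv <- svd(sweep(hull_points, 2, colMeans(hull_points)))$d
  if (sv[3] < 1e-9 * sv[1]) abort("degenerate hull: hull points are coplanar")
  facets <- hull_facets(hull_points)
  apply(points, 1, function(p) {
    min(vapply(facets, function(i) {
      point_triangle_distance(p, hull_points[i[1], ], hull_points[i[2], ],
                              hull_points[i[3], ])
    }, numeric(1)))
  })
}
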