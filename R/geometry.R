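# Planar geometry primitives used throughout the package.
#
# Polygons are n x 2 numeric matrices of vertices in order, closed implicitly
# (first vertex is not repeated). Polylines are open n x 2 matrices.
# All boolean-area operations (union of PM contours, clipping to the CTI
# boundary) are computed by an exact vertical slab sweep rather than a general
# polygon-clipping library: between any two consecutive "break" abscissae
# (vertex x's and pairwise edge-crossing x's) the cross-sectional union length
# is a linear function of x, so the midpoint rule integrates it exactly.

as_xy <- function(p) {
  m <- matrix(as.numeric(unlist(p)), ncol = 2, byrow = !is.matrix(p))
  if (is.matrix(p)) m <- matrix(as.numeric(p), ncol = 2)
  m
}

#' Signed shoelace area of a polygon
#' @param xy n x 2 vertex matrix (closed implicitly)
#' @return signed area; use [poly_area()] for the unsigned value
#' @keywords internal
poly_area_signed <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]) / 2
}

#' Unsigned polygon area
#'
#' Area by the shoelace formula, |signed area|, independent of winding.
#' @param xy n x 2 vertex matrix (closed implicitly, first vertex not repeated)
#' @return area (mm^2 when vertices are in mm)
#' @export
poly_area <- function(xy) abs(poly_area_signed(as_xy(xy)))

#' Polygon perimeter
#' @param xy n x 2 vertex matrix (closed implicitly)
#' @return perimeter of the closed vertex cycle
#' @export
poly_perimeter <- function(xy) {
  xy <- as_xy(xy)
  j <- c(2:nrow(xy), 1L)
  sum(sqrt((xy[j, 1] - xy[, 1])^2 + (xy[j, 2] - xy[, 2])^2))
}

#' Arc length of an open polyline
#'
#' Sum of Euclidean inter-vertex distances. Used for the isthmus lengths
#' ILI_L, CI_L and PSI_L.
#' @param xy n x 2 vertex matrix (open), n >= 2
#' @return length (mm)
#' @export
polyline_length <- function(xy) {
  xy <- as_xy(xy)
  if (nrow(xy) < 2) stop("polyline needs at least 2 vertices")
  d <- diff(xy)
  sum(sqrt(rowSums(d^2)))
}

# Do segments p1-p2 and p3-p4 properly intersect (interior crossing)?
segments_cross <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
  d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
  d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
  (d1 * d2 < -eps) && (d3 * d4 < -eps)
}

#' Is a polygon simple (non-self-intersecting)?
#'
#' Checks all non-adjacent edge pairs for proper crossings. O(n^2); the
#' annotation contours are small so this is never a bottleneck.
#' @param xy n x 2 vertex matrix
#' @return logical
#' @export
poly_is_simple <- function(xy) {
  xy <- as_xy(xy)
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  j <- c(2:n, 1L)
  for (a in 1:(n - 1)) {
    for (b in (a + 1):n) {
      # skip adjacent edges (share a vertex)
      if (b == a || j[a] == b || j[b] == a) next
      if (segments_cross(xy[a, ], xy[j[a], ], xy[b, ], xy[j[b], ])) return(FALSE)
    }
  }
  TRUE
}

# Convexity of a quadrilateral given as 4 x 2 matrix in order.
quad_is_convex <- function(xy, eps = 1e-12) {
  xy <- as_xy(xy)
  if (nrow(xy) != 4) return(FALSE)
  j <- c(2:4, 1L)
  k <- c(3:4, 1L, 2L)
  cr <- (xy[j, 1] - xy[, 1]) * (xy[k, 2] - xy[j, 2]) -
        (xy[j, 2] - xy[, 2]) * (xy[k, 1] - xy[j, 1])
  scale <- max(abs(xy)) + 1
  if (any(abs(cr) < eps * scale^2)) return(FALSE)
  all(cr > 0) || all(cr < 0)
}

#' Even-odd point-in-polygon test
#' @param px,py point coordinates (vectorized)
#' @param xy polygon vertex matrix
#' @return logical vector
#' @export
point_in_poly <- function(px, py, xy) {
  xy <- as_xy(xy)
  n <- nrow(xy)
  j <- c(2:n, 1L)
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    crossing <- (xy[, 2] > y) != (xy[j, 2] > y)
    if (!any(crossing)) return(FALSE)
    xs <- xy[crossing, 1] + (y - xy[crossing, 2]) *
      (xy[j, 1][crossing] - xy[crossing, 1]) / (xy[j, 2][crossing] - xy[crossing, 2])
    sum(xs > x) %% 2 == 1
  }, logical(1))
}

# y-intervals of a simple polygon's cross-section at vertical line x = x0.
# x0 must avoid vertex abscissae (guaranteed at slab midpoints).
cross_section <- function(xy, x0) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  x1 <- xy[, 1]; x2 <- xy[j, 1]
  span <- (x1 - x0) * (x2 - x0) < 0
  if (!any(span)) return(matrix(numeric(0), ncol = 2))
  y <- xy[span, 2] + (x0 - x1[span]) * (xy[j, 2][span] - xy[span, 2]) / (x2[span] - x1[span])
  y <- sort(y)
  matrix(y, ncol = 2, byrow = TRUE)
}

# total measure of a union of intervals given as k x 2 matrix
interval_union_measure <- function(iv) {
  if (nrow(iv) == 0) return(0)
  o <- order(iv[, 1])
  a <- iv[o, 1]; b <- iv[o, 2]
  tot <- 0; lo <- a[1]; hi <- b[1]
  for (i in seq_along(a)[-1]) {
    if (a[i] > hi) { tot <- tot + hi - lo; lo <- a[i]; hi <- b[i] }
    else hi <- max(hi, b[i])
  }
  tot + hi - lo
}

# measure of (union of iv) intersected with (union of clip_iv)
interval_intersect_measure <- function(iv, clip_iv) {
  if (nrow(iv) == 0 || nrow(clip_iv) == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(iv))) {
    lo <- pmax(iv[i, 1], clip_iv[, 1])
    hi <- pmin(iv[i, 2], clip_iv[, 2])
    tot <- tot + sum(pmax(hi - lo, 0))
  }
  tot
}

edges_of <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  cbind(xy[, 1], xy[, 2], xy[j, 1], xy[j, 2])
}

#' Area of the union of polygons, optionally clipped
#'
#' Computes |(P1 U P2 U ...) ∩ clip| exactly by a vertical slab sweep.
#' Break abscissae are all vertex x's plus all pairwise edge-crossing x's;
#' within each slab the union cross-section length is linear in x, so the
#' midpoint rule is exact. Self-overlaps are counted once, which is the
#' "coverage" semantics needed for the muscular CTI area.
#'
#' @param polys list of n x 2 vertex matrices (each a simple polygon)
#' @param clip optional clipping polygon (n x 2 matrix); `NULL` for none
#' @return area
#' @export
poly_union_area <- function(polys, clip = NULL) {
  polys <- lapply(polys, as_xy)
  polys <- Filter(function(p) nrow(p) >= 3, polys)
  if (length(polys) == 0) return(0)
  if (!is.null(clip)) clip <- as_xy(clip)
  ed <- do.call(rbind, lapply(polys, edges_of))
  if (!is.null(clip)) ed <- rbind(ed, edges_of(clip))
  xs <- c(ed[, 1], ed[, 3])
  # pairwise line-crossing abscissae within both edges' x-extents
  m <- nrow(ed)
  if (m >= 2) {
    i <- rep(seq_len(m - 1), times = (m - 1):1)
    k <- unlist(lapply(seq_len(m - 1), function(a) (a + 1):m))
    dx1 <- ed[i, 3] - ed[i, 1]; dy1 <- ed[i, 4] - ed[i, 2]
    dx2 <- ed[k, 3] - ed[k, 1]; dy2 <- ed[k, 4] - ed[k, 2]
    den <- dx1 * dy2 - dy1 * dx2
    ok <- abs(den) > 1e-14
    if (any(ok)) {
      i <- i[ok]; k <- k[ok]
      t <- ((ed[k, 1] - ed[i, 1]) * dy2[ok] - (ed[k, 2] - ed[i, 2]) * dx2[ok]) / den[ok]
      xc <- ed[i, 1] + t * dx1[ok]
      inx <- xc >= pmin(ed[i, 1], ed[i, 3]) & xc <= pmax(ed[i, 1], ed[i, 3]) &
             xc >= pmin(ed[k, 1], ed[k, 3]) & xc <= pmax(ed[k, 1], ed[k, 3])
      xs <- c(xs, xc[inx])
    }
  }
  xs <- sort(unique(xs))
  if (length(xs) < 2) return(0)
  area <- 0
  for (s in seq_len(length(xs) - 1)) {
    w <- xs[s + 1] - xs[s]
    if (w < 1e-13) next
    xm <- (xs[s] + xs[s + 1]) / 2
    iv <- do.call(rbind, lapply(polys, cross_section, x0 = xm))
    if (nrow(iv) == 0) next
    if (is.null(clip)) {
      area <- area + w * interval_union_measure(iv)
    } else {
      civ <- cross_section(clip, xm)
      # merge iv into disjoint intervals first so overlaps count once
      merged <- merge_intervals(iv)
      area <- area + w * interval_intersect_measure(merged, civ)
    }
  }
  area
}

# collapse overlapping intervals into a disjoint set
merge_intervals <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  o <- order(iv[, 1])
  a <- iv[o, 1]; b <- iv[o, 2]
  res_a <- a[1]; res_b <- b[1]
  for (i in seq_along(a)[-1]) {
    last <- length(res_a)
    if (a[i] > res_b[last]) { res_a <- c(res_a, a[i]); res_b <- c(res_b, b[i]) }
    else res_b[last] <- max(res_b[last], b[i])
  }
  cbind(res_a, res_b)
}

#' Area of intersection of two polygons
#' @param a,b simple polygons (n x 2 matrices)
#' @return area of a ∩ b
#' @export
poly_intersect_area <- function(a, b) poly_union_area(list(a), clip = b)

# apply rotation theta then translation (tx, ty) to an n x 2 matrix
rigid_transform <- function(xy, theta = 0, tx = 0, ty = 0) {
  xy <- as_xy(xy)
  ct <- cos(theta); st <- sin(theta)
  cbind(ct * xy[, 1] - st * xy[, 2] + tx,
        st * xy[, 1] + ct * xy[, 2] + ty)
}
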