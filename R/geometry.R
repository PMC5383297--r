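# Planar geometry primitives. All coordinates are projected metres; every
# polygon handled here is simple and convex (hulls, rectangles), stored as an
# n x 2 matrix of vertices in counter-clockwise order without a repeated
# closing vertex. Regions (possibly non-convex, possibly disconnected) are
# represented as lists of such convex polygons whose union is the region;
# exact areas of overlays come from the slab-decomposition engine in src/.

#' Convex hull of a planar point set (monotone chain)
#'
#' Computes the smallest convex polygon containing all points using Andrew's
#' monotone-chain construction. Collinear boundary points are dropped, so the
#' vertex set consists of extreme points only, returned in counter-clockwise
#' order. Degenerate inputs (fewer than 3 distinct points, or all points
#' collinear) yield a zero-area polygon flagged `degenerate`.
#'
#' @param points two-column matrix or data frame of x/y coordinates (metres).
#' @return list with `vertices` (m x 2 matrix, CCW), `area` (m^2) and
#'   `degenerate` (logical).
#' @examples
#' convex_hull(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))$area
#' @export
convex_hull <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (anyNA(pts) || any(!is.finite(pts))) {
    stop("convex_hull: coordinates must be finite", call. = FALSE)
  }
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) {
    return(list(vertices = pts, area = 0, degenerate = TRUE))
  }
  ord <- order(pts[, 1], pts[, 2])
  p <- pts[ord, , drop = FALSE]
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    hull <- integer(0)
    for (i in idx) {
      while (length(hull) >= 2 &&
             cross(p[hull[length(hull) - 1], ],
                   p[hull[length(hull)], ], p[i, ]) <= 0) {
        hull <- hull[-length(hull)]
      }
      hull <- c(hull, i)
    }
    hull
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  verts <- p[c(lower[-length(lower)], upper[-length(upper)]), , drop = FALSE]
  a <- polygon_area(verts)
  if (nrow(verts) < 3 || a <= 0) {
    return(list(vertices = verts, area = 0, degenerate = TRUE))
  }
  list(vertices = verts, area = a, degenerate = FALSE)
}

#' Signed-free area of a simple polygon (shoelace formula)
#'
#' @param verts n x 2 vertex matrix (no repeated closing vertex).
#' @return area in squared input units.
#' @export
polygon_area <- function(verts) {
  v <- as.matrix(verts)
  n <- nrow(v)
  if (is.null(n) || n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2])) / 2
}

# orient a convex polygon counter-clockwise
orient_ccw <- function(verts) {
  v <- as.matrix(verts)
  n <- nrow(v)
  i2 <- c(2:n, 1)
  s <- sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2])
  if (s < 0) v[rev(seq_len(n)), , drop = FALSE] else v
}

# axis-aligned rectangle as a CCW polygon matrix
rect_poly <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

as_region <- function(polys) {
  if (is.matrix(polys) || is.data.frame(polys)) polys <- list(polys)
  lapply(polys, function(p) {
    m <- as.matrix(p)[, 1:2, drop = FALSE]
    storage.mode(m) <- "double"
    orient_ccw(m)
  })
}

drop_degenerate <- function(region) {
  region[vapply(region, function(p) nrow(p) >= 3 && polygon_area(p) > 0,
                logical(1))]
}

#' Exact area of a boolean overlay of polygon regions
#'
#' A region is a list of convex polygons whose union defines it. With one
#' region the result is the area of its union (overlaps counted once); with
#' several, the area of the intersection of the unions. Computed exactly by
#' vertical slab decomposition with two-point Gauss quadrature per slab.
#'
#' @param ... one or more regions (each a list of n x 2 vertex matrices, or a
#'   single matrix).
#' @return area in squared input units.
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' region_area(list(sq, sq + 0.5)) # union of two overlapping unit squares
#' @export
region_area <- function(...) {
  region_moments(...)$area
}

#' Area and centroid of a boolean overlay of polygon regions
#'
#' @inheritParams region_area
#' @return list with `area` and centroid coordinates `cx`, `cy` (`NA` for an
#'   empty or zero-area overlay).
#' @export
region_moments <- function(...) {
  regions <- lapply(list(...), as_region)
  regions <- lapply(regions, drop_degenerate)
  if (any(vapply(regions, length, integer(1)) == 0)) {
    return(list(area = 0, cx = NA_real_, cy = NA_real_))
  }
  polys <- do.call(c, regions)
  group <- rep(seq_along(regions) - 1L,
               vapply(regions, length, integer(1)))
  res <- .region_overlay_cpp(polys, as.integer(group), length(regions))
  if (res$area <= 0) {
    return(list(area = 0, cx = NA_real_, cy = NA_real_))
  }
  list(area = res$area, cx = res$mx / res$area, cy = res$my / res$area)
}

#' Test points for membership in a polygon region
#'
#' Boundary-inclusive point-in-region test against the union of a list of
#' convex polygons.
#'
#' @param points n x 2 matrix of coordinates.
#' @param region list of convex polygon vertex matrices (or one matrix).
#' @return logical vector of length n.
#' @export
points_in_region <- function(points, region) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  reg <- as_region(region)
  if (length(reg) == 0 || nrow(pts) == 0) {
    return(rep(FALSE, nrow(pts)))
  }
  .points_in_region_cpp(pts, reg)
}

# Clip a segment (p1, p2) to a convex polygon (Cyrus-Beck): returns the
# parameter interval [t0, t1] of the inside part, or NULL.
clip_segment_convex <- function(p1, p2, poly) {
  v <- orient_ccw(poly)
  n <- nrow(v)
  i2 <- c(2:n, 1)
  ex <- v[i2, 1] - v[, 1]
  ey <- v[i2, 2] - v[, 2]
  # inward normals for CCW polygon
  nx <- -ey
  ny <- ex
  dx <- p2[1] - p1[1]
  dy <- p2[2] - p1[2]
  t0 <- 0
  t1 <- 1
  for (i in seq_len(n)) {
    denom <- nx[i] * dx + ny[i] * dy
    num <- nx[i] * (p1[1] - v[i, 1]) + ny[i] * (p1[2] - v[i, 2])
    if (denom == 0) {
      if (num < 0) return(NULL)
    } else {
      t <- -num / denom
      if (denom > 0) t0 <- max(t0, t) else t1 <- min(t1, t)
      if (t0 > t1) return(NULL)
    }
  }
  c(t0, t1)
}

# Total length of the part of segment (p1, p2) inside a region (union of
# convex polygons): union of per-polygon parameter intervals.
segment_length_in_region <- function(p1, p2, region) {
  reg <- drop_degenerate(as_region(region))
  len <- sqrt(sum((p2 - p1)^2))
  if (len == 0 || length(reg) == 0) return(0)
  ints <- list()
  for (poly in reg) {
    tt <- clip_segment_convex(p1, p2, poly)
    if (!is.null(tt) && tt[2] > tt[1]) ints[[length(ints) + 1]] <- tt
  }
  if (length(ints) == 0) return(0)
  m <- do.call(rbind, ints)
  m <- m[order(m[, 1]), , drop = FALSE]
  tot <- 0
  lo <- m[1, 1]; hi <- m[1, 2]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= hi) {
      hi <- max(hi, m[i, 2])
    } else {
      tot <- tot + (hi - lo)
      lo <- m[i, 1]; hi <- m[i, 2]
    }
  }
  tot <- tot + (hi - lo)
  tot * len
}
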