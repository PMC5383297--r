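# Landscape composition of home ranges: land-class proportions by exact
# polygon intersection, mean elevation by zonal statistics (grid) or by
# contour-length weighting, centroid latitude, and vegetation-zone
# assignment. Where agriculture and settlement would overlap, settlement
# takes precedence: agriculture is only counted outside settlement.

hr_region <- function(home_range) {
  if (inherits(home_range, "home_range")) home_range$polygons
  else as_region(home_range)
}

# class polygons prefiltered to the home range's bounding box
class_polys_near <- function(layers, class_name, region) {
  polys <- layers$classes[[class_name]]
  if (is.null(polys)) {
    stop("proportion_in_class: unknown class '", class_name, "'",
         call. = FALSE)
  }
  if (!length(polys)) return(list())
  bb <- layers$class_bbox[[class_name]]
  xs <- unlist(lapply(region, function(p) range(p[, 1])))
  ys <- unlist(lapply(region, function(p) range(p[, 2])))
  keep <- bb[, 3] >= min(xs) & bb[, 1] <= max(xs) &
    bb[, 4] >= min(ys) & bb[, 2] <= max(ys)
  polys[keep]
}

#' Proportion of a home range covered by a land class
#'
#' Exact area of the intersection between the home-range region and the
#' class's polygons, divided by the home-range area. For agriculture, any
#' part also covered by settlement is excluded (settlement precedence).
#'
#' @param home_range a `home_range` object (or a region: list of convex
#'   polygon matrices).
#' @param layers a `landscape_layers` object (see [build_landscape()]), or
#'   any list with `classes$agriculture` / `classes$settlement` regions.
#' @param class_name `"agriculture"` or `"settlement"`.
#' @return fraction in `[0, 1]`.
#' @export
proportion_in_class <- function(home_range, layers, class_name) {
  region <- hr_region(home_range)
  hr_area <- region_area(region)
  if (hr_area <= 0) {
    stop("proportion_in_class: zero-area home range, proportion undefined",
         call. = FALSE)
  }
  if (is.null(layers$class_bbox)) {
    layers$class_bbox <- lapply(layers$classes, function(lst) {
      if (!length(lst)) return(matrix(numeric(0), ncol = 4))
      t(vapply(lst, function(p) {
        c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))
      }, numeric(4)))
    })
  }
  cls <- class_polys_near(layers, class_name, region)
  if (!length(cls)) return(0)
  a <- region_area(region, cls)
  if (class_name == "agriculture") {
    settl <- class_polys_near(layers, "settlement", region)
    if (length(settl)) a <- a - region_area(region, cls, settl)
  }
  max(0, min(1, a / hr_area))
}

#' Mean elevation of a home range by zonal statistics
#'
#' Mean of the elevation grid values whose cell centres fall inside the
#' home-range region (boundary-inclusive), the common GIS zonal-statistics
#' rule.
#'
#' @param home_range a `home_range` object or region.
#' @param grid elevation grid: list with `xll`, `yll`, `cellsize`, `nrow`,
#'   `ncol` and `values` (matrix, rows north to south).
#' @return mean elevation in metres.
#' @export
mean_elevation_zonal <- function(home_range, grid) {
  region <- hr_region(home_range)
  xs <- unlist(lapply(region, function(p) range(p[, 1])))
  ys <- unlist(lapply(region, function(p) range(p[, 2])))
  cs <- grid$cellsize
  xc <- grid$xll + (seq_len(grid$ncol) - 0.5) * cs
  yc <- grid$yll + (grid$nrow - seq_len(grid$nrow) + 0.5) * cs # row 1 = north
  ci <- which(xc >= min(xs) - cs & xc <= max(xs) + cs)
  ri <- which(yc >= min(ys) - cs & yc <= max(ys) + cs)
  if (!length(ci) || !length(ri)) {
    stop("mean_elevation_zonal: home range outside the elevation grid",
         call. = FALSE)
  }
  pts <- cbind(rep(xc[ci], each = length(ri)), rep(yc[ri], length(ci)))
  inside <- points_in_region(pts, region)
  if (!any(inside)) {
    stop("mean_elevation_zonal: no cell centre inside the home range; use ",
         "a finer grid or the contour method", call. = FALSE)
  }
  vals <- grid$values[ri, ci, drop = FALSE]
  mean(as.vector(vals)[inside])
}

#' Mean elevation of a home range from elevation contours
#'
#' Length-weighted mean of contour elevations over the parts of each contour
#' polyline falling inside the home-range region (the contour-intersection
#' procedure used where no elevation raster is available).
#'
#' @param home_range a `home_range` object or region.
#' @param contours list of contours, each a list with `elevation` (m) and
#'   `coords` (n x 2 polyline matrix).
#' @return length-weighted mean elevation in metres.
#' @export
mean_elevation_contours <- function(home_range, contours) {
  region <- hr_region(home_range)
  len <- vapply(contours, function(ct) {
    m <- as.matrix(ct$coords)
    if (nrow(m) < 2) return(0)
    sum(vapply(seq_len(nrow(m) - 1), function(i) {
      segment_length_in_region(m[i, ], m[i + 1, ], region)
    }, numeric(1)))
  }, numeric(1))
  elev <- vapply(contours, function(ct) ct$elevation, numeric(1))
  if (sum(len) <= 0) {
    stop("mean_elevation_contours: no contour intersects the home range",
         call. = FALSE)
  }
  sum(len * elev) / sum(len)
}

#' Latitude of a home range centroid
#'
#' Area-weighted centroid of the (possibly multi-part) home-range region,
#' mapped through the affine latitude map `lat = lat0 + y / m_per_deg`.
#'
#' @param home_range a `home_range` object or region.
#' @param latitude_map list with `lat0` (degrees) and `m_per_deg`.
#' @return latitude in degrees.
#' @export
centroid_latitude <- function(home_range,
                              latitude_map = list(lat0 = 50,
                                                  m_per_deg = 111320)) {
  region <- hr_region(home_range)
  mom <- region_moments(region)
  if (mom$area <= 0) {
    stop("centroid_latitude: degenerate home range", call. = FALSE)
  }
  latitude_map$lat0 + mom$cy / latitude_map$m_per_deg
}

#' Vegetation zone containing a point
#'
#' Returns the zone whose polygon contains the point; on a shared boundary
#' the southernmost zone wins (zones are checked in south-to-north order).
#'
#' @param point length-2 numeric (x, y) in metres.
#' @param zone_polygons named list of zone polygons in south-to-north order.
#' @return zone name.
#' @export
assign_zone <- function(point, zone_polygons) {
  pt <- matrix(as.numeric(point[1:2]), ncol = 2)
  for (z in names(zone_polygons)) {
    if (points_in_region(pt, zone_polygons[[z]])) return(z)
  }
  stop("assign_zone: point lies in no vegetation zone", call. = FALSE)
}

#' Landscape composition of one home range
#'
#' Convenience wrapper computing the full composition record: land-class
#' proportions, zonal mean elevation, centroid latitude and vegetation zone.
#'
#' @param home_range a `home_range` object.
#' @param layers a `landscape_layers` object.
#' @return one-row data frame (animal_id, prop_agriculture, prop_settlement,
#'   mean_elevation_m, centroid_latitude, zone).
#' @export
composition_record <- function(home_range, layers) {
  region <- hr_region(home_range)
  mom <- region_moments(region)
  if (mom$area <= 0) {
    stop("composition_record: degenerate home range", call. = FALSE)
  }
  zone <- assign_zone(c(mom$cx, mom$cy), layers$zones)
  data.frame(
    animal_id = home_range$animal_id,
    prop_agriculture = proportion_in_class(home_range, layers, "agriculture"),
    prop_settlement = proportion_in_class(home_range, layers, "settlement"),
    mean_elevation_m = mean_elevation_zonal(home_range, layers$elevation),
    centroid_latitude = centroid_latitude(home_range, layers$latitude_map),
    zone = zone,
    stringsAsFactors = FALSE
  )
}
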