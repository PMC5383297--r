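# Home-range estimation: percent minimum convex polygon (MCP) and
# k-nearest-neighbour local convex hulls (LoCoH-k) with isopleths, plus
# area-observation curves for judging monitoring-duration adequacy.

new_home_range <- function(animal_id, estimator, level, k, polygons,
                           area_m2, degenerate = FALSE) {
  structure(
    list(animal_id = animal_id, estimator = estimator, level = level,
         k = k, polygons = polygons, area_km2 = area_m2 / 1e6,
         degenerate = degenerate),
    class = "home_range"
  )
}

#' @export
print.home_range <- function(x, ...) {
  cat("<home_range>", x$estimator,
      sprintf("%d%%", round(100 * x$level)),
      if (!is.na(x$k)) paste0("k=", x$k) else "",
      sprintf("area=%.4g km^2", x$area_km2),
      if (x$degenerate) "(degenerate)" else "", "\n")
  invisible(x)
}

#' Percent minimum convex polygon home range
#'
#' Retains the `ceiling(level * n)` fixes nearest the arithmetic-mean
#' centroid of all fixes (fixed centroid, single peel; distance ties broken
#' by earlier fix order) and returns their convex hull. This is the classical
#' percent-MCP of telemetry analysis.
#'
#' @param points n x 2 matrix of projected fix coordinates (metres), in
#'   time order.
#' @param level isopleth level in (0, 1]; 1 uses every fix.
#' @param animal_id optional identifier carried into the result.
#' @return a `home_range` object (`area_km2`, hull `polygons`).
#' @export
mcp <- function(points, level = 1, animal_id = NA_character_) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (!(level > 0 && level <= 1)) {
    stop("mcp: level must be in (0, 1]", call. = FALSE)
  }
  n <- nrow(pts)
  m <- ceiling(level * n)
  if (n < 3 || m < 3) {
    return(new_home_range(animal_id, "MCP", level, NA_integer_,
                          list(pts), 0, degenerate = TRUE))
  }
  ctr <- colMeans(pts)
  d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  keep <- order(d, seq_len(n))[seq_len(m)]
  h <- convex_hull(pts[keep, , drop = FALSE])
  new_home_range(animal_id, "MCP", level, NA_integer_,
                 list(h$vertices), h$area, degenerate = h$degenerate)
}

#' Number of nearest neighbours for LoCoH-k
#'
#' The per-animal k is the square root of the number of fixes, rounded half
#' up and floored at 3 (a local hull needs 3 points for positive area).
#'
#' @param n_fixes number of fixes (must be at least 9).
#' @return integer k.
#' @examples
#' choose_k(540) # 23
#' @export
choose_k <- function(n_fixes) {
  if (n_fixes < 9) {
    stop("choose_k: need at least 9 fixes (k would fall below 3)",
         call. = FALSE)
  }
  max(3L, as.integer(floor(sqrt(n_fixes) + 0.5)))
}

#' LoCoH-k home range
#'
#' Builds, for every fix (the root), the convex hull of the root and its
#' k - 1 nearest neighbours (Euclidean distance, ties by fix index), sorts
#' the local hulls by ascending area (ties by root index), and unions them in
#' that order until the union contains at least `ceiling(level * n)` of the
#' fixes (boundary-inclusive). The returned area is the exact area of the
#' union.
#'
#' @param points n x 2 matrix of projected fix coordinates (metres).
#' @param k number of points per local hull (root included), `3 <= k <= n`.
#' @param level isopleth level in (0, 1].
#' @param animal_id optional identifier carried into the result.
#' @return a `home_range` object whose `polygons` are the unioned local
#'   hulls.
#' @export
locoh_k <- function(points, k, level = 1, animal_id = NA_character_) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (k < 3 || k > n) stop("locoh_k: need 3 <= k <= n", call. = FALSE)
  if (!(level > 0 && level <= 1)) {
    stop("locoh_k: level must be in (0, 1]", call. = FALSE)
  }
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  hulls <- vector("list", n)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ], seq_len(n))[seq_len(k)]
    h <- convex_hull(pts[nb, , drop = FALSE])
    hulls[[i]] <- h$vertices
    areas[i] <- h$area
  }
  ord <- order(areas, seq_len(n))
  hulls <- hulls[ord]
  usable <- vapply(hulls, function(v) nrow(v) >= 3, logical(1))
  target <- ceiling(level * n)
  if (!any(usable)) {
    warning("locoh_k: all local hulls degenerate; zero-area home range",
            call. = FALSE)
    return(new_home_range(animal_id, "LoCoH-k", level, as.integer(k),
                          hulls[1], 0, degenerate = TRUE))
  }
  counts <- .locoh_cover_counts_cpp(pts, hulls)
  m <- which(counts >= target)
  m <- if (length(m)) m[1] else length(hulls)
  used <- hulls[seq_len(m)]
  area <- region_area(used)
  new_home_range(animal_id, "LoCoH-k", level, as.integer(k), used, area,
                 degenerate = area <= 0)
}

#' Area-observation curve
#'
#' 100% MCP area of all fixes within the first d days of monitoring, for
#' d = increment, 2 * increment, ... up to the monitoring duration. Because
#' the point sets are nested, the curve is non-decreasing; it is used to
#' judge whether monitoring lasted long enough for the home-range estimate
#' to approach an asymptote.
#'
#' @param traj a [trajectory()].
#' @param increment_days grid spacing in days (default 30).
#' @return data frame of class `area_observation_curve` with `duration`
#'   (days), `area_km2`, `n_fixes` and `degenerate` (window had < 3 fixes).
#' @export
area_observation_curve <- function(traj, increment_days = 30) {
  dur <- monitoring_duration(traj)
  if (dur < increment_days) {
    stop("area_observation_curve: duration shorter than one increment",
         call. = FALSE)
  }
  f <- traj$fixes
  t_days <- as.numeric(difftime(f$timestamp, f$timestamp[1], units = "days"))
  grid <- seq(increment_days, dur, by = increment_days)
  rows <- lapply(grid, function(d) {
    sel <- t_days <= d
    hr <- mcp(cbind(f$x[sel], f$y[sel]), level = 1,
              animal_id = traj$animal_id)
    data.frame(duration = d, area_km2 = hr$area_km2, n_fixes = sum(sel),
               degenerate = hr$degenerate)
  })
  out <- do.call(rbind, rows)
  attr(out, "animal_id") <- traj$animal_id
  class(out) <- c("area_observation_curve", "data.frame")
  out
}

#' Fraction of the reference-day area reached at a given day
#'
#' @param curve an [area_observation_curve()].
#' @param at_day,ref_day durations on the curve grid (days).
#' @return `area(at_day) / area(ref_day)`.
#' @export
asymptote_fraction <- function(curve, at_day, ref_day) {
  a1 <- curve$area_km2[match(at_day, curve$duration)]
  a2 <- curve$area_km2[match(ref_day, curve$duration)]
  if (is.na(a1) || is.na(a2)) {
    stop("asymptote_fraction: day not on the curve grid", call. = FALSE)
  }
  if (a2 <= 0) {
    stop("asymptote_fraction: zero reference area, ratio undefined",
         call. = FALSE)
  }
  a1 / a2
}
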