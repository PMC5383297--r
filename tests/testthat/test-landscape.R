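# Landscape composition: class proportions by exact intersection, the two
# elevation methods, centroid latitude and zone assignment.

unit_hr <- function() {
  # a 1 km^2 square home range as a home_range-like region
  list(rect_poly(0, 0, 1000, 1000))
}

test_that("proportion_in_class computes exact intersection fractions", {
  layers <- list(classes = list(
    agriculture = list(rect_poly(500, -10000, 50000, 10000)),
    settlement = list()
  ))
  expect_equal(proportion_in_class(unit_hr(), layers, "agriculture"), 0.5)
  # fully inside one polygon
  layers2 <- list(classes = list(
    agriculture = list(rect_poly(-1e4, -1e4, 1e4, 1e4)),
    settlement = list()
  ))
  expect_equal(proportion_in_class(unit_hr(), layers2, "agriculture"), 1)
  # no class polygons at all
  expect_equal(proportion_in_class(unit_hr(), layers, "settlement"), 0)
})

test_that("settlement takes precedence over overlapping agriculture", {
  layers <- list(classes = list(
    agriculture = list(rect_poly(0, 0, 1000, 1000)),
    settlement = list(rect_poly(0, 0, 250, 1000))
  ))
  expect_equal(proportion_in_class(unit_hr(), layers, "agriculture"), 0.75)
  expect_equal(proportion_in_class(unit_hr(), layers, "settlement"), 0.25)
})

test_that("zero-area home ranges are rejected", {
  layers <- list(classes = list(agriculture = list(), settlement = list()))
  degen <- list(cbind(c(0, 1, 2), c(0, 1, 2)))
  expect_error(proportion_in_class(degen, layers, "agriculture"),
               "zero-area")
})

test_that("zonal mean of a constant field is the constant", {
  grid <- list(xll = 0, yll = 0, cellsize = 50, nrow = 40, ncol = 40,
               values = matrix(100, 40, 40))
  tri <- list(cbind(c(100, 1900, 300), c(200, 400, 1800)))
  expect_equal(mean_elevation_zonal(tri, grid), 100)
})

test_that("zonal mean of a plane converges to the centroid value", {
  mk_grid <- function(cs) {
    nc <- ceiling(1000 / cs)
    xc <- (seq_len(nc) - 0.5) * cs
    list(xll = 0, yll = 0, cellsize = cs, nrow = nc, ncol = nc,
         values = matrix(xc, nrow = nc, ncol = nc, byrow = TRUE))
  }
  # polygon symmetric about x = 500
  hr <- list(rect_poly(200, 100, 800, 900))
  e50 <- mean_elevation_zonal(hr, mk_grid(50))
  e10 <- mean_elevation_zonal(hr, mk_grid(10))
  expect_lt(abs(e10 - 500), abs(e50 - 500) + 1e-9)
  expect_lt(abs(e10 - 500), 2)
})

test_that("zonal statistics reject polygons off the grid", {
  grid <- list(xll = 0, yll = 0, cellsize = 100, nrow = 10, ncol = 10,
               values = matrix(1, 10, 10))
  far <- list(rect_poly(5000, 5000, 6000, 6000))
  expect_error(mean_elevation_zonal(far, grid), "")
})

test_that("contour method length-weights the clipped elevations", {
  hr <- list(rect_poly(0, 0, 3000, 1000))
  contours <- list(
    list(elevation = 400, coords = rbind(c(-500, 200), c(1500, 200))),
    list(elevation = 600, coords = rbind(c(0, 800), c(1000, 800)))
  )
  # clipped lengths 1500 and 1000: (400*1.5 + 600*1) / 2.5 = 480
  expect_equal(mean_elevation_contours(hr, contours), 480)
  one <- list(list(elevation = 600,
                   coords = rbind(c(100, 500), c(900, 500))))
  expect_equal(mean_elevation_contours(hr, one), 600)
  none <- list(list(elevation = 500,
                    coords = rbind(c(0, 5000), c(1000, 5000))))
  expect_error(mean_elevation_contours(hr, none), "no contour")
})

test_that("the two elevation methods agree on smooth planar terrain", {
  # terrain z = 0.1 x over a convex home range; contours are vertical lines
  set.seed(41)
  hull <- convex_hull(cbind(runif(40, 0, 2000), runif(40, 0, 2000)))
  hr <- list(hull$vertices)
  cs <- 20
  nc <- 2000 / cs
  xc <- (seq_len(nc) - 0.5) * cs
  grid <- list(xll = 0, yll = 0, cellsize = cs, nrow = nc, ncol = nc,
               values = matrix(0.1 * xc, nrow = nc, ncol = nc, byrow = TRUE))
  contours <- lapply(seq(0, 2000, by = 20), function(x0) {
    list(elevation = 0.1 * x0,
         coords = rbind(c(x0, -100), c(x0, 2100)))
  })
  ez <- mean_elevation_zonal(hr, grid)
  ec <- mean_elevation_contours(hr, contours)
  expect_lt(abs(ez - ec) / ez, 0.05)
})

test_that("centroid latitude follows the affine map", {
  lm <- list(lat0 = 60, m_per_deg = 111320)
  sq <- list(rect_poly(0, 0, 1, 1))
  expect_equal(centroid_latitude(sq, lm), 60 + 0.5 / 111320)
  north <- list(rect_poly(0, 111320, 1, 111321))
  expect_equal(centroid_latitude(north, lm),
               centroid_latitude(sq, lm) + 1)
  # multi-part region: centroid of the union, not of one part
  two <- list(rect_poly(0, 0, 1, 1), rect_poly(0, 111320, 1, 111321))
  expect_equal(centroid_latitude(two, lm), 60.5 + 0.5 / 111320)
})

test_that("zone assignment is boundary-south inclusive", {
  zones <- list(BN = rect_poly(0, 0, 100, 10),
                SB = rect_poly(0, 10, 100, 20),
                NB = rect_poly(0, 20, 100, 30))
  expect_equal(assign_zone(c(50, 25), zones), "NB")
  expect_equal(assign_zone(c(50, 10), zones), "BN") # shared border
  expect_error(assign_zone(c(50, 99), zones), "no vegetation zone")
})

test_that("all default synthetic foxes land in their designed zones", {
  study <- simulate_study(small_config(seed = 55))
  zones <- vapply(seq_len(nrow(study$foxes)), function(i) {
    assign_zone(c(study$foxes$cx[i], study$foxes$cy[i]),
                study$landscape$zones)
  }, character(1))
  expect_equal(zones, study$foxes$zone)
})

test_that("composition proportions are rigid-motion invariant", {
  hr <- list(rect_poly(100, 100, 1100, 1100))
  cls <- list(rect_poly(600, -1000, 4000, 4000))
  base <- region_area(hr, cls) / region_area(hr)
  sh <- function(p, dx, dy) cbind(p[, 1] + dx, p[, 2] + dy)
  shifted <- region_area(list(sh(hr[[1]], 5e4, -3e4)),
                         list(sh(cls[[1]], 5e4, -3e4))) /
    region_area(list(sh(hr[[1]], 5e4, -3e4)))
  expect_equal(shifted, base, tolerance = 1e-12)
})
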