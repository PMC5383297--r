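# Shared fixtures, built in code. The small study keeps module tests fast;
# acceptance checks use the full default design.

small_config <- function(seed = 1, ...) {
  generator_config(
    n_foxes = 13L, n_males = 8L,
    zone_allocation = c(BN = 7L, SB = 4L, NB = 2L),
    duration_mean = 110, duration_sd = 20,
    duration_min = 95, duration_max = 150,
    include_short_females = FALSE,
    elev_cellsize = 500, seed = seed, ...
  )
}

# brute-force convex hull vertex set: a point is a hull vertex iff some
# directed edge through it has every other point strictly to its left
# (points in general position)
brute_hull_vertices <- function(pts) {
  n <- nrow(pts)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- pts[j, ] - pts[i, ]
      others <- setdiff(seq_len(n), c(i, j))
      cr <- d[1] * (pts[others, 2] - pts[i, 2]) -
        d[2] * (pts[others, 1] - pts[i, 1])
      if (all(cr > 0)) {
        on_hull[i] <- TRUE
        on_hull[j] <- TRUE
      }
    }
  }
  pts[on_hull, , drop = FALSE]
}

# grid-counting area oracle for a region (union of convex polygons)
grid_area_oracle <- function(region, n = 400) {
  xs <- unlist(lapply(region, function(p) range(p[, 1])))
  ys <- unlist(lapply(region, function(p) range(p[, 2])))
  gx <- seq(min(xs), max(xs), length.out = n)
  gy <- seq(min(ys), max(ys), length.out = n)
  pts <- cbind(rep(gx, each = n), rep(gy, n))
  cell <- (gx[2] - gx[1]) * (gy[2] - gy[1])
  sum(points_in_region(pts, region)) * cell
}

# sort polygon vertex rows for order-independent comparison
sort_rows <- function(m) {
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# one reduced study + pipeline result shared across test files
.fixture_cache <- new.env(parent = emptyenv())
shared_small_run <- function() {
  if (!exists("run", envir = .fixture_cache)) {
    study <- simulate_study(small_config(seed = 42))
    res <- run_pipeline(study, pipeline_config())
    assign("run", list(study = study, result = res),
           envir = .fixture_cache)
  }
  get("run", envir = .fixture_cache)
}

make_stationary_traj <- function(seed, s = 500, days = 60, rate = 3,
                                 id = "X1") {
  set.seed(seed)
  truth <- data.frame(animal_id = id, zone = "BN", sex = "F",
                      age_class = "adult", ou_position_sd = s,
                      movement_class = "stationary",
                      duration_days = days, cx = 0, cy = 0)
  simulate_trajectory(truth, generator_config(fix_rate = rate))
}
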