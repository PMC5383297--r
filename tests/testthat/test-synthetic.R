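# The synthetic study generator: design counts, covariate distributions,
# response calibration, movement-scale calibration, trajectory contracts,
# landscape construction, determinism.

test_that("default cohort matches the study design counts", {
  fox <- sample_fox_covariates(generator_config(seed = 2))
  expect_equal(nrow(fox), 52)
  expect_equal(sum(fox$sex == "M"), 33)
  expect_equal(unname(table(fox$zone)[c("BN", "SB", "NB")]),
               c(30L, 14L, 8L), ignore_attr = TRUE)
  expect_true(all(fox$agriculture >= 0 & fox$agriculture <= 1))
  expect_true(all(fox$settlement >= 0 & fox$settlement <= 1))
  expect_true(all(fox$agriculture + fox$settlement <= 1))
  expect_true(all(fox$elevation >= 0))
  expect_true(all(fox$duration_days >= 84 & fox$duration_days <= 270))
})

test_that("infeasible allocations are rejected", {
  expect_error(generator_config(zone_allocation = c(BN = 40, SB = 14,
                                                    NB = 8)),
               "sum")
  expect_error(generator_config(n_males = 60), "n_males")
  expect_error(generator_config(r2_target = 0), "r2_target")
  expect_error(generator_config(fix_rate = 4), "fix_rate")
})

test_that("r2_target = 1 gives noise-free responses", {
  cfg <- generator_config(r2_target = 1, seed = 4)
  fox <- sample_fox_covariates(cfg)
  b <- cfg$betas
  b0 <- attr(fox, "intercept")
  xb <- b0 + b[["elevation"]] * fox$elevation +
    b[["agriculture"]] * fox$agriculture +
    b[["sex_male"]] * (fox$sex == "M")
  expect_equal(fox$true_log_area, xb, tolerance = 1e-12)
})

test_that("zone covariate draws follow the configured normals", {
  # Monte-Carlo check of the boreonemoral elevation distribution
  set.seed(10)
  d <- zone_design()
  draws <- foxhr:::rtrunc_norm(10000, d$elevation_mean[1],
                               d$elevation_sd[1], lo = 0)
  expect_lt(abs(mean(draws) - 54), 1)
  expect_lt(abs(sd(draws) - 22), 1)
})

test_that("derive_position_sd inverts the normal-ellipse area formula", {
  expect_equal(derive_position_sd(pi * qchisq(0.9, 2), 0.9), 1000)
  expect_equal(derive_position_sd(1, 0.9), sqrt(1e6 / (pi * qchisq(0.9, 2))),
               tolerance = 1e-12)
  expect_equal(derive_position_sd(1, 0.9), 262.907, tolerance = 1e-4)
  # limit: s -> 0 with area
  expect_lt(derive_position_sd(1e-12, 0.9), 1e-3)
  expect_error(derive_position_sd(0), "positive")
  expect_error(derive_position_sd(1, 0), "level")
})

test_that("zero movement scale collapses fixes onto the centre", {
  truth <- data.frame(animal_id = "z", zone = "BN", sex = "F",
                      age_class = "adult", ou_position_sd = 0,
                      movement_class = "stationary", duration_days = 40,
                      cx = 123, cy = 456)
  tr <- simulate_trajectory(truth, generator_config())
  expect_true(all(tr$fixes$x == 123 & tr$fixes$y == 456))
  expect_true(mcp(cbind(tr$fixes$x, tr$fixes$y), 1)$degenerate)
})

test_that("trajectories have the scheduled fix count and increasing time", {
  cfg <- generator_config(seed = 12)
  fox <- sample_fox_covariates(cfg)
  tr <- simulate_trajectory(fox[3, ], cfg)
  expect_equal(nrow(tr$fixes), fox$duration_days[3] * 3)
  expect_true(all(diff(as.numeric(tr$fixes$timestamp)) > 0))
  expect_equal(monitoring_duration(tr), fox$duration_days[3] - 1 / 3,
               tolerance = 1e-6)
  expect_error(simulate_trajectory(transform(fox[3, ], duration_days = 0),
                                   cfg),
               "duration")
})

test_that("the OU stationary spread matches its target", {
  set.seed(30)
  s_target <- 600
  rel <- vapply(1:50, function(i) {
    tr <- make_stationary_traj(300 + i, s = s_target, days = 180)
    (sd(tr$fixes$x) + sd(tr$fixes$y)) / 2
  }, numeric(1))
  expect_lt(abs(mean(rel) - s_target) / s_target, 0.1)
})

test_that("disperser displacement clears the designed separation", {
  cfg <- generator_config(n_dispersers = 2L, seed = 9)
  fox <- sample_fox_covariates(cfg)
  for (i in which(fox$movement_class == "disperser")) {
    nsd <- compute_nsd(simulate_trajectory(fox[i, ], cfg))
    expect_gt(max(nsd$nsd), 25 * fox$ou_position_sd[i]^2)
  }
})

test_that("landscape patches respect drawn proportions near each centre", {
  cfg <- small_config(seed = 14)
  study <- simulate_study(cfg)
  fox <- study$foxes
  for (i in c(1, 4, 8)) {
    r <- fox$window_r[i] / 2
    disc <- rect_poly(fox$cx[i] - r, fox$cy[i] - r,
                      fox$cx[i] + r, fox$cy[i] + r)
    near <- foxhr:::class_polys_near(study$landscape, "agriculture",
                                     list(disc))
    measured <- if (length(near)) {
      region_area(list(disc), near) / (2 * r)^2
    } else 0
    expect_lt(abs(measured - fox$agriculture[i]), 0.02)
  }
})

test_that("zero-proportion foxes have no agriculture near the centre", {
  cfg <- small_config(seed = 23)
  fox <- sample_fox_covariates(cfg)
  fox$agriculture <- 0
  fox$settlement[1] <- 0.1 # keep some settlement to exercise the writer
  land <- build_landscape(fox, zone_design(), cellsize = 500)
  for (i in seq_len(nrow(fox))) {
    s3 <- 3 * fox$ou_position_sd[i]
    disc <- rect_poly(fox$cx[i] - s3, fox$cy[i] - s3,
                      fox$cx[i] + s3, fox$cy[i] + s3)
    near <- foxhr:::class_polys_near(land, "agriculture", list(disc))
    if (length(near)) {
      expect_equal(region_area(list(disc), near), 0)
    } else {
      succeed()
    }
  }
})

test_that("agriculture and settlement patches never overlap", {
  cfg <- small_config(seed = 31)
  study <- simulate_study(cfg)
  ag <- study$landscape$classes$agriculture
  st <- study$landscape$classes$settlement
  if (length(ag) && length(st)) {
    expect_equal(region_area(ag, st), 0)
  }
})

test_that("elevation plateaus drive zonal means at fox centres", {
  cfg <- small_config(seed = 19)
  study <- simulate_study(cfg)
  fox <- study$foxes
  for (i in c(2, 9)) {
    r <- fox$window_r[i] / 3
    sqr <- rect_poly(fox$cx[i] - r, fox$cy[i] - r,
                     fox$cx[i] + r, fox$cy[i] + r)
    m <- mean_elevation_zonal(list(sqr), study$landscape$elevation)
    expect_lt(abs(m - fox$elevation[i]), 2.5) # ripple amplitude bound
  }
})

test_that("latitude-elevation correlation sits near its calibration", {
  rs <- vapply(1:8, function(s) {
    fox <- sample_fox_covariates(generator_config(seed = s))
    cor(fox$latitude, fox$elevation)
  }, numeric(1))
  expect_true(all(rs > 0.84 & rs < 0.94))
})

test_that("the generator is deterministic in its seed", {
  s1 <- simulate_study(small_config(seed = 99))
  s2 <- simulate_study(small_config(seed = 99))
  expect_identical(s1$foxes, s2$foxes)
  expect_identical(lapply(s1$trajectories, function(z) z$fixes),
                   lapply(s2$trajectories, function(z) z$fixes))
  expect_identical(s1$landscape$elevation$values,
                   s2$landscape$elevation$values)
  s3 <- simulate_study(small_config(seed = 100))
  expect_false(identical(s1$foxes$true_log_area, s3$foxes$true_log_area))
})

test_that("truth-table regression recovers the configured coefficients", {
  set.seed(202)
  nrep <- 60
  est <- matrix(NA_real_, nrep, 4)
  for (i in seq_len(nrep)) {
    fox <- sample_fox_covariates(generator_config(), seed = NULL)
    rows <- data.frame(log_area = fox$true_log_area,
                       elevation = fox$elevation,
                       agriculture = fox$agriculture,
                       sex = as.integer(fox$sex == "M"))
    f <- fit_ols(rows, c("elevation", "agriculture", "sex"))
    est[i, ] <- c(f$betas[-1], f$R2)
  }
  truth <- c(0.003, -1.37, 0.34)
  mc_se <- apply(est[, 1:3], 2, sd) / sqrt(nrep)
  expect_true(all(abs(colMeans(est[, 1:3]) - truth) < 2 * mc_se))
  expect_lt(abs(mean(est[, 4]) - 0.5), 0.05)
})
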