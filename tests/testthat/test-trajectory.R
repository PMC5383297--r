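# NSD computation, movement-strategy classification and the cohort filter.

test_that("compute_nsd matches hand geometry", {
  t0 <- as.POSIXct("2015-01-01", tz = "UTC")
  tr <- trajectory("a", t0 + c(0, 3600), x = c(0, 3), y = c(0, 4))
  expect_equal(compute_nsd(tr)$nsd, c(0, 25))

  tr2 <- trajectory("b", t0 + (0:5) * 3600, x = rep(1, 6), y = rep(2, 6))
  expect_equal(compute_nsd(tr2)$nsd, rep(0, 6))

  # straight walk of 1 m per step: nsd_i = i^2
  tr3 <- trajectory("c", t0 + (0:9) * 3600, x = 0:9, y = rep(0, 10))
  expect_equal(compute_nsd(tr3)$nsd, (0:9)^2)
})

test_that("compute_nsd is invariant to translation and rotation", {
  t0 <- as.POSIXct("2015-01-01", tz = "UTC")
  set.seed(8)
  x <- rnorm(25)
  y <- rnorm(25)
  base <- compute_nsd(trajectory("a", t0 + (0:24) * 3600, x, y))$nsd
  th <- 1.1
  xr <- cos(th) * x - sin(th) * y + 50
  yr <- sin(th) * x + cos(th) * y - 20
  rot <- compute_nsd(trajectory("a", t0 + (0:24) * 3600, xr, yr))$nsd
  expect_equal(rot, base, tolerance = 1e-10)
})

test_that("trajectory constructor enforces its invariants", {
  t0 <- as.POSIXct("2015-01-01", tz = "UTC")
  expect_error(trajectory("a", t0, 1, 1), "at least 2")
  expect_error(trajectory("a", c(t0, t0), c(1, 2), c(1, 2)), "duplicate")
  expect_error(trajectory("a", t0 + c(0, 1), c(1, Inf), c(1, 2)),
               "non-finite")
})

test_that("monitoring_duration returns elapsed days", {
  t0 <- as.POSIXct("2015-01-01 00:00:00", tz = "UTC")
  tr <- trajectory("a", c(t0, as.POSIXct("2015-04-01", tz = "UTC")),
                   c(0, 1), c(0, 1))
  expect_equal(monitoring_duration(tr), 90)
  tr2 <- trajectory("a", t0 + c(0, 12 * 3600), c(0, 1), c(0, 1))
  expect_equal(monitoring_duration(tr2), 0.5)
})

test_that("noiseless generating forms classify as themselves", {
  t <- seq(0, 120, by = 1)
  expect_equal(classify_movement(
    data.frame(t = t, nsd = rep(4e5, length(t))))$label, "stationary")
  lin <- classify_movement(data.frame(t = t, nsd = 1000 * t))
  expect_equal(lin$label, "transient")
  sig <- classify_movement(
    data.frame(t = t, nsd = 1e6 / (1 + exp((60 - t) / 5))))
  expect_equal(sig$label, "disperser")
  pars <- sig$fits$parameters[[which(sig$fits$form == "disperser")]]
  expect_equal(unname(pars["delta"]), 1e6, tolerance = 0.01)
})

test_that("classification refuses series shorter than 30 days", {
  expect_error(classify_movement(data.frame(t = 0:20, nsd = rnorm(21)^2)),
               "30 days")
})

test_that("synthetic stationary foxes are recognized as residents", {
  lab <- vapply(1:50, function(s) {
    cfg <- generator_config(seed = s)
    fox <- sample_fox_covariates(cfg)
    tr <- simulate_trajectory(fox[1, ], cfg)
    suppressWarnings(classify_movement(compute_nsd(tr))$label)
  }, character(1))
  expect_gte(sum(lab == "stationary"), 45)
})

test_that("synthetic dispersers are recognized and far-displaced", {
  cfg <- generator_config(n_dispersers = 3L, seed = 11)
  fox <- sample_fox_covariates(cfg)
  for (i in which(fox$movement_class == "disperser")) {
    tr <- simulate_trajectory(fox[i, ], cfg)
    nsd <- compute_nsd(tr)
    expect_gt(max(nsd$nsd), 25 * fox$ou_position_sd[i]^2)
    expect_equal(suppressWarnings(classify_movement(nsd)$label), "disperser")
  }
})

test_that("filter applies the duration rule with overrides", {
  t0 <- as.POSIXct("2015-01-01", tz = "UTC")
  mk <- function(id, days) {
    trajectory(id, t0 + c(0, days * 86400), c(0, 1), c(0, 1))
  }
  trajs <- list(mk("a", 100), mk("b", 89), mk("c", 84))
  cls <- rep("stationary", 3)
  res <- filter_study_animals(trajs, cls, overrides = "c")
  kept <- vapply(res$cohort, function(z) z$animal_id, character(1))
  expect_setequal(kept, c("a", "c"))
  expect_equal(res$excluded$animal_id, "b")
  expect_equal(res$excluded$reason, "duration")
})

test_that("non-residents are excluded regardless of duration", {
  t0 <- as.POSIXct("2015-01-01", tz = "UTC")
  tr <- trajectory("d", t0 + c(0, 200 * 86400), c(0, 1), c(0, 1))
  res <- filter_study_animals(list(tr), "disperser")
  expect_length(res$cohort, 0)
  expect_equal(res$excluded$reason, "movement_class")
})

test_that("filter partitions the input without duplication", {
  cfg <- small_config(seed = 3)
  study <- simulate_study(cfg)
  cls <- study$foxes$movement_class # supplied labels: tests the rule itself
  res <- filter_study_animals(study$trajectories, cls)
  kept <- vapply(res$cohort, function(z) z$animal_id, character(1))
  expect_equal(sort(unname(c(kept, res$excluded$animal_id))),
               sort(study$foxes$animal_id))
  expect_false(anyDuplicated(c(kept, res$excluded$animal_id)) > 0)
})

test_that("default-design cohort with supplied labels keeps all 52", {
  cfg <- generator_config(seed = 6)
  fox <- sample_fox_covariates(cfg)
  t0 <- as.POSIXct("2015-01-01", tz = "UTC")
  trajs <- lapply(seq_len(nrow(fox)), function(i) {
    trajectory(fox$animal_id[i],
               t0 + c(0, fox$duration_days[i] * 86400), c(0, 1), c(0, 1))
  })
  res <- filter_study_animals(trajs, fox$movement_class,
                              overrides = attr(fox, "override_ids"))
  expect_length(res$cohort, 52)
})
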