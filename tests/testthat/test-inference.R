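# Paired t-tests, the collinearity screen, candidate enumeration, OLS with
# the ML likelihood conventions, AICc and Akaike weights, cohort summaries.

test_that("paired_t matches hand-computed statistics", {
  a <- c(2, 4, 6)
  b <- c(1, 2, 3)
  res <- paired_t(a, b) # d = (1, 2, 3): mean 2, sd 1
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$df, 2)

  sym <- paired_t(c(1, 0), c(0, 1)) # d = (1, -1)
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)

  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "zero difference")
})

test_that("paired_t is invariant to adding a constant to both samples", {
  set.seed(61)
  a <- rnorm(20)
  b <- rnorm(20)
  r1 <- paired_t(a, b)
  r2 <- paired_t(a + 100, b + 100)
  expect_equal(r1$t, r2$t, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
})

test_that("a t of 3.13 on 51 df has the reported two-sided p", {
  expect_equal(round(2 * pt(-3.13, 51), 3), 0.003)
})

test_that("collinearity screen drops one member of a correlated pair", {
  set.seed(71)
  n <- 52
  x <- rnorm(n)
  rows <- data.frame(log_area = rnorm(n), a = x, b = x, c = rnorm(n))
  res <- collinearity_screen(rows, c("a", "b", "c"))
  expect_length(intersect(res$retained, c("a", "b")), 1)
  expect_true("c" %in% res$retained)
  # orthogonal covariates are all retained
  rows2 <- data.frame(log_area = rnorm(n), a = rnorm(n), b = rnorm(n))
  expect_setequal(collinearity_screen(rows2, c("a", "b"))$retained,
                  c("a", "b"))
})

test_that("screen flags the latitude-elevation confound on synthetic data", {
  fox <- sample_fox_covariates(generator_config(seed = 13))
  rows <- data.frame(log_area = fox$true_log_area,
                     latitude = fox$latitude, elevation = fox$elevation,
                     agriculture = fox$agriculture,
                     settlement = fox$settlement,
                     sex = as.integer(fox$sex == "M"),
                     age = as.integer(fox$age_class == "adult"))
  res <- collinearity_screen(rows, c("latitude", "elevation", "agriculture",
                                     "settlement", "sex", "age"))
  expect_gte(abs(res$r_matrix["latitude", "elevation"]), 0.6)
  expect_equal(res$dropped$variable, "latitude")
  expect_setequal(res$retained, c("elevation", "agriculture", "settlement",
                                  "sex", "age"))
})

test_that("constant covariates are excluded with a warning", {
  rows <- data.frame(log_area = rnorm(20), a = rnorm(20), b = rep(1, 20))
  expect_warning(res <- collinearity_screen(rows, c("a", "b")), "constant")
  expect_equal(res$retained, "a")
})

test_that("candidate enumeration counts additive subsets", {
  c5 <- enumerate_candidates(letters[1:5])
  expect_length(c5, 32) # 31 models + the appended null
  expect_equal(sum(lengths(c5) == 0), 1)
  expect_false(anyDuplicated(vapply(c5, paste, character(1),
                                    collapse = "+")) > 0)
  expect_length(enumerate_candidates("a"), 2)
  c2 <- enumerate_candidates(c("a", "b"))
  expect_length(c2, 4)
  expect_error(enumerate_candidates(character(0)), "covariates")
})

test_that("fit_ols matches the normal-equation oracle", {
  rows <- data.frame(log_area = c(0, 1, 1), x = c(0, 1, 2))
  f <- fit_ols(rows, "x")
  expect_equal(unname(f$betas), c(1 / 6, 1 / 2), tolerance = 1e-12)
  expect_equal(f$R2, 0.75, tolerance = 1e-12)
  expect_equal(f$K, 3L)

  set.seed(81)
  n <- 40
  rows2 <- data.frame(log_area = rnorm(n), u = rnorm(n), v = rnorm(n),
                      w = rnorm(n))
  f2 <- fit_ols(rows2, c("u", "v", "w"))
  X <- cbind(1, rows2$u, rows2$v, rows2$w)
  beta_hat <- solve(t(X) %*% X, t(X) %*% rows2$log_area)
  expect_equal(unname(f2$betas), drop(beta_hat), tolerance = 1e-8)
  rss <- sum((rows2$log_area - X %*% beta_hat)^2)
  expect_equal(f2$logLik, -(n / 2) * (log(2 * pi * rss / n) + 1),
               tolerance = 1e-8)
})

test_that("degenerate designs raise informative errors", {
  rows <- data.frame(log_area = c(0, 1, 2, 3), x = c(0, 1, 2, 3),
                     y = c(0, 2, 4, 6))
  expect_error(fit_ols(rows, c("x", "y")), "aliased")
  expect_error(fit_ols(rows, "x"), "zero residual") # exact fit
  expect_error(fit_ols(rows[1:3, ], c("x", "y")), "too few")
})

test_that("aicc reproduces the printed model-selection table", {
  # printed (logLik, df) pairs with n = 52 reproduce the printed AICc
  expect_lt(abs(aicc(-52.28, 5, 52) - 115.87), 0.01)
  expect_lt(abs(aicc(-53.67, 4, 52) - 116.20), 0.01)
  expect_lt(abs(aicc(-71.86, 2, 52) - 147.96), 0.01)
  expect_equal(aicc(0, 1, 3), 6)
  expect_error(aicc(0, 5, 6), "n > K")
})

test_that("aicc exceeds aic and converges to it as n grows", {
  ll <- -50
  K <- 4
  aic <- -2 * ll + 2 * K
  expect_gt(aicc(ll, K, 20), aic)
  expect_gt(aicc(ll, K, 200), aic)
  expect_lt(aicc(ll, K, 2000) - aic, aicc(ll, K, 20) - aic)
  expect_lt(aicc(ll, K, 1e6) - aic, 1e-4)
})

test_that("rank_models computes deltas, weights and the equivalence set", {
  mk <- function(ll, k, terms) {
    list(terms = terms, logLik = ll, K = as.integer(k), n = 52, R2 = 0.5,
         betas = c(0), se = c(0))
  }
  # two models with equal AICc split the weight
  r <- rank_models(list(mk(-50, 3, "a"), mk(-50, 3, "b")))
  expect_equal(r$weight, c(0.5, 0.5))
  expect_true(all(r$equivalent))
  expect_equal(r$delta[1], 0)
  # delta (0, 2) -> weights 1/(1+e^-1), closed form
  f2 <- list(mk(-50, 3, "a"), mk(-51, 3, "b"))
  r2 <- rank_models(f2)
  expect_equal(r2$delta, c(0, 2), tolerance = 1e-12)
  expect_equal(r2$weight, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(sum(r2$weight), 1)
})

test_that("summarize_cohort produces the standard summary arithmetic", {
  areas <- data.frame(animal_id = c("a", "b", "c"), sex = c("F", "M", "M"),
                      estimator = "LoCoH-k", level = 0.9,
                      area_km2 = c(2, 4, 6))
  s <- summarize_cohort(areas)$by_estimator
  all_row <- s[s$sex == "All", ]
  expect_equal(all_row$mean, 4)
  expect_equal(all_row$sd, 2)
  expect_equal(all_row$se, 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(c(all_row$min, all_row$max), c(2, 6))
  # single-animal group reports NA dispersion
  f_row <- s[s$sex == "F", ]
  expect_true(is.na(f_row$sd) && is.na(f_row$se))
})

test_that("model selection recovers the generating structure", {
  # simulation-oracle rates at the design size (n = 52, weak sex effect):
  # the exact three-term model reaches the top two in ~46% of replicates
  # and the 2-AICc equivalence set in ~60%; elevation, the dominant
  # effect, is in the best model essentially always
  set.seed(91)
  nrep <- 40
  top2 <- 0
  eq2 <- 0
  has_elev <- 0
  for (i in seq_len(nrep)) {
    fox <- sample_fox_covariates(generator_config(), seed = NULL)
    rows <- data.frame(log_area = fox$true_log_area,
                       elevation = fox$elevation,
                       agriculture = fox$agriculture,
                       settlement = fox$settlement,
                       sex = as.integer(fox$sex == "M"),
                       age = as.integer(fox$age_class == "adult"))
    cands <- enumerate_candidates(c("elevation", "agriculture", "settlement",
                                    "sex", "age"))
    fits <- lapply(cands, function(tm) fit_ols(rows, tm))
    rk <- rank_models(fits)
    pos <- which(rk$model == "elevation + agriculture + sex")
    if (pos <= 2) top2 <- top2 + 1
    if (rk$delta[pos] <= 2) eq2 <- eq2 + 1
    if (grepl("elevation", rk$model[1], fixed = TRUE)) {
      has_elev <- has_elev + 1
    }
  }
  expect_gte(has_elev / nrep, 0.95)
  expect_gte(top2 / nrep, 0.3)
  expect_gte(eq2 / nrep, 0.45)
})
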