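# Statistical analysis: estimator comparison by paired t-tests, collinearity
# screening with AICc arbitration, exhaustive additive candidate models over
# the retained covariates, OLS fits with exact (ML) Gaussian log-likelihood,
# AICc ranking with Akaike weights, and Table-style cohort summaries.

#' Paired t-test between matched per-animal areas
#'
#' Two-sided paired Student's t-test (via [stats::t.test()]) on matched
#' vectors, e.g. MCP versus LoCoH-k areas of the same animals at the same
#' isopleth level.
#'
#' @param a,b numeric vectors of equal length, matched by animal.
#' @return list with `t`, `df` (= n - 1) and two-sided `p`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (sd(d) == 0) {
    stop("paired_t: zero difference variance, statistic undefined",
         call. = FALSE)
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Collinearity screen with AICc arbitration
#'
#' Computes all pairwise Pearson correlations among candidate covariates.
#' For every pair at or above `r_limit` in absolute value, the two full
#' models that each exclude one member of the pair are fitted and the member
#' whose exclusion gives the lower-AICc full model is dropped. Pairs are
#' arbitrated in descending |r| order; a pair is skipped if one member was
#' already dropped. Constant covariates (undefined correlation) are dropped
#' with a warning.
#'
#' @param rows data frame with a `log_area` response column and the
#'   covariate columns.
#' @param covariates character vector of covariate column names.
#' @param r_limit absolute-correlation threshold (default 0.6).
#' @return list with `retained` (character), `dropped` (data frame: variable,
#'   partner, r, delta_aicc) and `r_matrix`.
#' @export
collinearity_screen <- function(rows, covariates, r_limit = 0.6) {
  stopifnot(length(covariates) >= 2)
  keep <- covariates
  const <- vapply(covariates, function(v) sd(rows[[v]]) == 0, logical(1))
  if (any(const)) {
    warning("collinearity_screen: constant covariate(s) excluded: ",
            paste(covariates[const], collapse = ", "), call. = FALSE)
    keep <- covariates[!const]
  }
  r_mat <- cor(rows[keep])
  pairs <- which(upper.tri(r_mat) & abs(r_mat) >= r_limit, arr.ind = TRUE)
  dropped <- data.frame(variable = character(0), partner = character(0),
                        r = numeric(0), delta_aicc = numeric(0))
  if (nrow(pairs)) {
    ord <- order(-abs(r_mat[pairs]))
    pairs <- pairs[ord, , drop = FALSE]
    for (p in seq_len(nrow(pairs))) {
      v1 <- rownames(r_mat)[pairs[p, 1]]
      v2 <- colnames(r_mat)[pairs[p, 2]]
      if (!(v1 %in% keep) || !(v2 %in% keep)) next
      f1 <- fit_ols(rows, setdiff(keep, v1)) # full model without v1
      f2 <- fit_ols(rows, setdiff(keep, v2)) # full model without v2
      a1 <- aicc(f1$logLik, f1$K, nrow(rows))
      a2 <- aicc(f2$logLik, f2$K, nrow(rows))
      drop_var <- if (a1 <= a2) v1 else v2
      dropped <- rbind(dropped, data.frame(
        variable = drop_var, partner = if (drop_var == v1) v2 else v1,
        r = r_mat[pairs[p, 1], pairs[p, 2]], delta_aicc = abs(a1 - a2)
      ))
      keep <- setdiff(keep, drop_var)
    }
  }
  list(retained = keep, dropped = dropped, r_matrix = r_mat)
}

#' Enumerate additive candidate models
#'
#' All non-empty subsets of the covariates (2^p - 1 additive models), with
#' the intercept-only null model appended last for reference.
#'
#' @param covariates character vector (1 to 10 names).
#' @return list of character vectors of terms; the null model is
#'   `character(0)`.
#' @examples
#' length(enumerate_candidates(letters[1:5])) # 31 + null
#' @export
enumerate_candidates <- function(covariates) {
  p <- length(covariates)
  if (p < 1 || p > 10) {
    stop("enumerate_candidates: need 1-10 covariates", call. = FALSE)
  }
  subsets <- lapply(seq_len(2^p - 1), function(m) {
    covariates[bitwAnd(m, 2^(seq_len(p) - 1)) > 0]
  })
  # order by size then lexicographic position, for a stable report
  subsets <- subsets[order(lengths(subsets))]
  c(subsets, list(character(0)))
}

#' Ordinary least squares fit with ML log-likelihood
#'
#' Fits `log_area ~ terms` by OLS (via [stats::lm()]) and returns the
#' conventions used for AICc model selection: the maximum-likelihood error
#' variance `RSS / n`, `logLik = -(n/2) (log(2 pi RSS/n) + 1)` and
#' `K = |terms| + 2` (slopes + intercept + residual variance). An empty term
#' set fits the intercept-only null model.
#'
#' @param rows data frame with `log_area` and covariate columns.
#' @param terms character vector of covariate names (possibly empty).
#' @return list with `terms`, `betas`, `se`, `R2`, `RSS`, `logLik`, `K`,
#'   `n` and the underlying `lm` fit.
#' @export
fit_ols <- function(rows, terms) {
  n <- nrow(rows)
  if (n <= length(terms) + 1) {
    stop("fit_ols: too few rows for ", length(terms), " terms", call. = FALSE)
  }
  fml <- if (length(terms)) {
    stats::reformulate(terms, response = "log_area")
  } else {
    log_area ~ 1
  }
  fit <- lm(fml, data = rows)
  if (anyNA(coef(fit))) {
    stop("fit_ols: rank-deficient design, aliased term(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  rss <- sum(residuals(fit)^2)
  tss <- sum((rows$log_area - mean(rows$log_area))^2)
  if (rss <= 1e-12 * max(tss, 1)) {
    stop("fit_ols: zero residual sum of squares, likelihood unbounded",
         call. = FALSE)
  }
  s2 <- rss / n
  ll <- -(n / 2) * (log(2 * pi * s2) + 1)
  sm <- summary(fit)
  list(terms = terms, betas = coef(fit), se = sm$coefficients[, "Std. Error"],
       R2 = if (tss > 0) 1 - rss / tss else NA_real_,
       RSS = rss, logLik = ll, K = length(terms) + 2L, n = n, fit = fit)
}

#' Akaike's information criterion with small-sample correction
#'
#' `AICc = -2 logLik + 2K + 2K(K+1) / (n - K - 1)`.
#'
#' @param logLik maximized log-likelihood.
#' @param K number of estimated parameters (including the residual
#'   variance).
#' @param n sample size; must exceed `K + 1`.
#' @return AICc value.
#' @examples
#' aicc(-52.28, 5, 52)
#' @export
aicc <- function(logLik, K, n) {
  if (n <= K + 1) stop("aicc: need n > K + 1", call. = FALSE)
  -2 * logLik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Rank candidate model fits by AICc
#'
#' Sorts fits by ascending AICc, computes delta AICc and Akaike weights
#' `exp(-delta/2) / sum(exp(-delta/2))`, and flags the models within two
#' AICc units of the best (the conventional equivalence set).
#'
#' @param fits list of [fit_ols()] results.
#' @return data frame with `model`, `df`, `logLik`, `AICc`, `delta`,
#'   `weight`, `R2`, `equivalent`; attribute `fits` keeps the ranked fit
#'   objects.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  n <- fits[[1]]$n
  a <- vapply(fits, function(f) aicc(f$logLik, f$K, n), numeric(1))
  ord <- order(a)
  a <- a[ord]
  fits <- fits[ord]
  delta <- a - a[1]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(
    model = vapply(fits, function(f) {
      if (length(f$terms)) paste(f$terms, collapse = " + ") else "(null)"
    }, character(1)),
    df = vapply(fits, function(f) f$K, integer(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AICc = a, delta = delta, weight = w,
    R2 = vapply(fits, function(f) f$R2, numeric(1)),
    equivalent = delta <= 2
  )
  attr(out, "fits") <- fits
  out
}

#' Cohort summary tables
#'
#' Means, SD, SE (= SD / sqrt(n)) and range of home-range area by estimator,
#' isopleth level and sex, and zone-level summaries of area and landscape
#' covariates by sex, mirroring the usual telemetry-paper layout. Groups of
#' a single animal report `NA` for SD/SE.
#'
#' @param areas data frame with columns `animal_id`, `estimator`, `level`,
#'   `area_km2`, `sex`.
#' @param compositions optional data frame with `animal_id`, `zone`,
#'   `prop_agriculture`, `prop_settlement`, `mean_elevation_m`, `sex` and
#'   `area_km2` (the analysis-level area).
#' @return list with `by_estimator` and (if compositions given) `by_zone`.
#' @export
summarize_cohort <- function(areas, compositions = NULL) {
  smr <- function(x) {
    c(n = length(x), mean = mean(x),
      sd = if (length(x) > 1) sd(x) else NA_real_,
      se = if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_,
      min = min(x), max = max(x))
  }
  grp <- function(df, value, by) {
    res <- aggregate(df[[value]], df[by], smr)
    cbind(res[by], as.data.frame(res$x))
  }
  a_all <- grp(transform(areas, sex = "All"), "area_km2",
               c("estimator", "level", "sex"))
  a_sex <- grp(areas, "area_km2", c("estimator", "level", "sex"))
  by_est <- rbind(a_all, a_sex)
  by_est <- by_est[order(by_est$estimator, by_est$level, by_est$sex), ]
  rownames(by_est) <- NULL
  out <- list(by_estimator = by_est)
  if (!is.null(compositions)) {
    vars <- intersect(c("area_km2", "prop_settlement", "prop_agriculture",
                        "mean_elevation_m"), names(compositions))
    z_all <- do.call(rbind, lapply(vars, function(v) {
      cbind(variable = v, grp(transform(compositions, sex = "All"), v,
                              c("zone", "sex")))
    }))
    z_sex <- do.call(rbind, lapply(vars, function(v) {
      cbind(variable = v, grp(compositions, v, c("zone", "sex")))
    }))
    by_zone <- rbind(z_all, z_sex)
    by_zone <- by_zone[order(by_zone$zone, by_zone$variable, by_zone$sex), ]
    rownames(by_zone) <- NULL
    out$by_zone <- by_zone
  }
  out
}
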