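# End-to-end orchestration: residency classification -> cohort filter ->
# home-range estimation -> area-observation curves -> landscape composition
# -> model selection, with CSV outputs and a reproducibility manifest.

#' Pipeline configuration
#'
#' @param levels isopleth levels for both estimators (ascending, in (0, 1]).
#' @param analysis_level the LoCoH level used for composition and modelling
#'   (the conservative 90% isopleth by default).
#' @param min_days minimum monitoring duration for cohort inclusion.
#' @param overrides animal ids kept despite shorter monitoring.
#' @param r_limit collinearity threshold for the correlation screen.
#' @param covariates candidate covariates offered to the screen.
#' @param aoc_min_days monitoring duration (days) a fox must reach to enter
#'   the area-observation summary (the "followed for six months" subset).
#' @param out_dir output directory for CSV artifacts (`NULL` = no files).
#' @param verbose print stage progress.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(levels = c(0.90, 0.95, 1.00),
                            analysis_level = 0.90, min_days = 90,
                            overrides = NULL, r_limit = 0.6,
                            covariates = c("latitude", "elevation",
                                           "agriculture", "settlement",
                                           "sex", "age"),
                            aoc_min_days = 180, out_dir = NULL,
                            verbose = FALSE) {
  stopifnot(all(levels > 0), all(levels <= 1), !is.unsorted(levels),
            analysis_level %in% levels)
  structure(
    list(levels = levels, analysis_level = analysis_level,
         min_days = min_days, overrides = overrides, r_limit = r_limit,
         covariates = covariates, aoc_min_days = aoc_min_days,
         out_dir = out_dir, verbose = verbose),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes, on a synthetic study or on trajectories plus landscape layers:
#' NSD movement classification, the resident/duration cohort filter,
#' MCP and LoCoH-k home ranges at the configured isopleth levels
#' (per-animal k from [choose_k()]), area-observation curves for the
#' long-monitored subset, landscape composition of the analysis-level LoCoH
#' ranges, paired t-tests comparing estimators, the collinearity screen,
#' exhaustive additive model enumeration and AICc ranking, and Table-style
#' cohort summaries. Optionally writes all tables plus a run manifest.
#'
#' @param study a `synthetic_study`, or a list with `trajectories` (list of
#'   [trajectory()]) and `landscape` (`landscape_layers`).
#' @param config a [pipeline_config()].
#' @return list of class `fox_pipeline_result` with elements
#'   `classification`, `exclusions`, `areas`, `home_ranges`, `aoc`,
#'   `composition`, `analysis_rows`, `paired_tests`, `screen`, `models`,
#'   `best_fit`, `summaries`, `manifest`.
#' @export
run_pipeline <- function(study, config = pipeline_config()) {
  trajs <- study$trajectories
  layers <- study$landscape
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  t_start <- Sys.time()

  # 1. residency classification
  say("classifying movement (", length(trajs), " animals)")
  cls <- lapply(trajs, function(tr) classify_movement(compute_nsd(tr)))
  classification <- data.frame(
    animal_id = vapply(trajs, function(z) as.character(z$animal_id),
                       character(1)),
    label = vapply(cls, function(z) z$label, character(1)),
    duration_days = vapply(trajs, monitoring_duration, numeric(1)),
    n_fixes = vapply(trajs, function(z) nrow(z$fixes), integer(1)),
    row.names = NULL
  )

  # 2. cohort filter
  overrides <- config$overrides
  if (is.null(overrides) && !is.null(study$override_ids)) {
    overrides <- study$override_ids
  }
  flt <- filter_study_animals(trajs, cls, min_days = config$min_days,
                              overrides = overrides)
  cohort <- flt$cohort
  if (!length(cohort)) {
    stop("run_pipeline: no resident animals after filtering", call. = FALSE)
  }
  say("cohort: ", length(cohort), " residents (",
      nrow(flt$excluded), " excluded)")

  # 3. home ranges at all levels, both estimators
  home_ranges <- list()
  areas <- list()
  for (tr in cohort) {
    pts <- cbind(tr$fixes$x, tr$fixes$y)
    k <- choose_k(nrow(pts))
    for (lv in config$levels) {
      hr_m <- mcp(pts, lv, animal_id = tr$animal_id)
      hr_l <- locoh_k(pts, k, lv, animal_id = tr$animal_id)
      home_ranges <- c(home_ranges, list(hr_m, hr_l))
      areas[[length(areas) + 1]] <- data.frame(
        animal_id = tr$animal_id, sex = tr$sex, estimator = c("MCP", "LoCoH-k"),
        level = lv, k = c(NA_integer_, k),
        area_km2 = c(hr_m$area_km2, hr_l$area_km2)
      )
    }
  }
  areas <- do.call(rbind, areas)
  say("home ranges done (", length(home_ranges), " polygons)")

  # 4. area-observation curves for the long-monitored subset
  long <- Filter(function(tr) {
    monitoring_duration(tr) >= config$aoc_min_days
  }, cohort)
  aoc <- lapply(long, area_observation_curve)
  names(aoc) <- vapply(long, function(z) as.character(z$animal_id),
                       character(1))
  aoc_frac <- vapply(aoc, function(cv) {
    ref <- max(cv$duration[cv$duration <= config$aoc_min_days])
    asymptote_fraction(cv, 90, ref)
  }, numeric(1))

  # 5. composition of the analysis-level LoCoH ranges
  say("landscape composition")
  lhr <- Filter(function(h) {
    h$estimator == "LoCoH-k" && h$level == config$analysis_level
  }, home_ranges)
  composition <- do.call(rbind, lapply(lhr, composition_record, layers))

  # 6. analysis table
  idx <- match(composition$animal_id, vapply(cohort, function(z) {
    as.character(z$animal_id)
  }, character(1)))
  lv_areas <- areas[areas$estimator == "LoCoH-k" &
                      areas$level == config$analysis_level, ]
  area_vec <- lv_areas$area_km2[match(composition$animal_id,
                                      lv_areas$animal_id)]
  analysis_rows <- data.frame(
    animal_id = composition$animal_id,
    log_area = log(area_vec),
    latitude = composition$centroid_latitude,
    elevation = composition$mean_elevation_m,
    agriculture = composition$prop_agriculture,
    settlement = composition$prop_settlement,
    sex = as.integer(vapply(cohort[idx], function(z) z$sex,
                            character(1)) == "M"),
    age = as.integer(vapply(cohort[idx], function(z) z$age_class,
                            character(1)) == "adult"),
    zone = composition$zone
  )

  # 7. estimator comparison
  paired_tests <- do.call(rbind, lapply(config$levels, function(lv) {
    a <- areas[areas$estimator == "MCP" & areas$level == lv, ]
    b <- areas[areas$estimator == "LoCoH-k" & areas$level == lv, ]
    b <- b[match(a$animal_id, b$animal_id), ]
    pt <- paired_t(a$area_km2, b$area_km2)
    data.frame(level = lv, t = pt$t, df = pt$df, p = pt$p)
  }))

  # 8. model selection
  say("model selection")
  screen <- collinearity_screen(analysis_rows, config$covariates,
                                r_limit = config$r_limit)
  cands <- enumerate_candidates(screen$retained)
  fits <- lapply(cands, function(terms) fit_ols(analysis_rows, terms))
  models <- rank_models(fits)
  best_fit <- attr(models, "fits")[[1]]

  # 9. summaries
  comp_sum <- merge(composition,
                    data.frame(animal_id = lv_areas$animal_id,
                               area_km2 = lv_areas$area_km2,
                               sex = lv_areas$sex))
  summaries <- summarize_cohort(areas, comp_sum)

  manifest <- list(
    n_input_animals = length(trajs),
    n_residents = length(cohort),
    n_excluded = nrow(flt$excluded),
    n_home_ranges = length(home_ranges),
    n_composition = nrow(composition),
    n_candidate_models = length(cands) - 1L, # null reported separately
    levels = config$levels,
    analysis_level = config$analysis_level,
    min_days = config$min_days,
    overrides = overrides,
    aoc_mean_fraction_90d = if (length(aoc_frac)) mean(aoc_frac) else NA,
    seed = study$config$seed,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )

  result <- structure(
    list(classification = classification, exclusions = flt$excluded,
         areas = areas, home_ranges = home_ranges, aoc = aoc,
         aoc_fraction_90d = aoc_frac, composition = composition,
         analysis_rows = analysis_rows, paired_tests = paired_tests,
         screen = screen, models = models, best_fit = best_fit,
         summaries = summaries, manifest = manifest),
    class = "fox_pipeline_result"
  )
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(result, study, config$out_dir)
  }
  result
}

#' @export
print.fox_pipeline_result <- function(x, ...) {
  cat("<fox_pipeline_result>", x$manifest$n_residents, "residents;",
      "best model:", x$models$model[1],
      sprintf("(AICc %.2f, R2 %.2f)\n", x$models$AICc[1], x$models$R2[1]))
  invisible(x)
}

write_pipeline_outputs <- function(result, study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write.csv(result$classification, p("classification.csv"),
            row.names = FALSE)
  write.csv(result$exclusions, p("exclusions.csv"), row.names = FALSE)
  write.csv(result$areas, p("areas.csv"), row.names = FALSE)
  write.csv(result$composition, p("composition.csv"), row.names = FALSE)
  write.csv(result$analysis_rows, p("analysis_rows.csv"), row.names = FALSE)
  write.csv(result$paired_tests, p("paired_tests.csv"), row.names = FALSE)
  write.csv(result$models, p("model_selection.csv"), row.names = FALSE)
  coefs <- data.frame(term = names(result$best_fit$betas),
                      estimate = result$best_fit$betas,
                      se = result$best_fit$se)
  write.csv(coefs, p("best_model_coefficients.csv"), row.names = FALSE)
  write.csv(result$summaries$by_estimator, p("summary_by_estimator.csv"),
            row.names = FALSE)
  if (!is.null(result$summaries$by_zone)) {
    write.csv(result$summaries$by_zone, p("summary_by_zone.csv"),
              row.names = FALSE)
  }
  write_home_ranges_geojson(result$home_ranges, p("home_ranges.geojson"))
  files <- list.files(out_dir, full.names = TRUE)
  sums <- tools::md5sum(files)
  manifest <- c(
    result$manifest,
    list(files = data.frame(file = basename(files), md5 = unname(sums)))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(out_dir)
}
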