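# File formats: fix tables and attribute tables as CSV (UTF-8, "." decimal,
# ISO-8601 UTC timestamps with trailing Z), polygon layers and home ranges
# as GeoJSON in planar coordinates, elevation as ESRI ASCII grid.

fmt_iso8601 <- function(ts) {
  format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

# lenient ISO-8601 parser: unparseable entries become NA instead of errors
parse_iso8601 <- function(x) {
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- as.POSIXct(x[miss], tz = "UTC",
                            format = "%Y-%m-%d %H:%M:%S")
  }
  out
}

#' Write a fix table to CSV
#'
#' Columns: `animal_id`, `timestamp` (ISO-8601 UTC), `x_m`, `y_m`, `lon`,
#' `lat`.
#'
#' @param trajs list of [trajectory()] objects (or a `synthetic_study`).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fix_table <- function(trajs, path) {
  if (inherits(trajs, "synthetic_study")) trajs <- trajs$trajectories
  rows <- lapply(trajs, function(tr) {
    data.frame(animal_id = tr$animal_id,
               timestamp = fmt_iso8601(tr$fixes$timestamp),
               x_m = tr$fixes$x, y_m = tr$fixes$y,
               lon = tr$fixes$lon, lat = tr$fixes$lat)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the animal attribute table to CSV
#'
#' @param foxes attribute table (e.g. from [sample_fox_covariates()]); only
#'   `animal_id`, `sex`, `age_class` and `zone` are required.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_attribute_table <- function(foxes, path) {
  cols <- intersect(c("animal_id", "sex", "age_class", "zone"), names(foxes))
  write.csv(foxes[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a fix-table CSV
#'
#' Checks required columns, timestamp parseability, per-animal timestamp
#' uniqueness and monotonicity, and coordinate finiteness; reports per-animal
#' fix counts and a list of violations (with line numbers where applicable).
#'
#' @param path CSV file as written by [write_fix_table()].
#' @return list with `ok` (logical), `errors` (character), `fix_counts`
#'   (data frame).
#' @export
validate_fix_table <- function(path) {
  errors <- character(0)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp", "x_m", "y_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    return(list(ok = FALSE,
                errors = paste("missing column(s):",
                               paste(miss, collapse = ", ")),
                fix_counts = NULL))
  }
  ts <- parse_iso8601(df$timestamp)
  bad_ts <- which(is.na(ts))
  if (length(bad_ts)) {
    errors <- c(errors, paste0("unparseable timestamp at line(s) ",
                               paste(head(bad_ts + 1, 10), collapse = ", ")))
  }
  bad_xy <- which(!is.finite(df$x_m) | !is.finite(df$y_m))
  if (length(bad_xy)) {
    errors <- c(errors, paste0("non-finite coordinates at line(s) ",
                               paste(head(bad_xy + 1, 10), collapse = ", ")))
  }
  for (id in unique(df$animal_id)) {
    tsi <- ts[df$animal_id == id]
    tsi <- tsi[!is.na(tsi)]
    if (anyDuplicated(tsi)) {
      errors <- c(errors, paste0("duplicate timestamp(s) for animal ", id))
    } else if (length(tsi) > 1 && is.unsorted(tsi)) {
      errors <- c(errors, paste0("timestamps not increasing for animal ", id))
    }
  }
  counts <- as.data.frame(table(animal_id = df$animal_id),
                          stringsAsFactors = FALSE)
  names(counts)[2] <- "n_fixes"
  list(ok = length(errors) == 0, errors = errors, fix_counts = counts)
}

#' Read a fix-table CSV into trajectories
#'
#' @param path fix CSV (see [write_fix_table()]).
#' @param attributes optional attribute table (data frame or CSV path) with
#'   `animal_id`, `sex`, `age_class`, `zone`.
#' @return named list of [trajectory()] objects.
#' @export
read_fix_table <- function(path, attributes = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ts <- parse_iso8601(df$timestamp)
  if (is.character(attributes)) attributes <- read.csv(attributes)
  out <- lapply(split(seq_len(nrow(df)), df$animal_id), function(idx) {
    id <- df$animal_id[idx[1]]
    at <- if (!is.null(attributes)) {
      attributes[match(id, attributes$animal_id), ]
    } else NULL
    trajectory(id, ts[idx], df$x_m[idx], df$y_m[idx],
               lon = if ("lon" %in% names(df)) df$lon[idx] else NA,
               lat = if ("lat" %in% names(df)) df$lat[idx] else NA,
               sex = if (!is.null(at)) at$sex else NA_character_,
               age_class = if (!is.null(at)) at$age_class else NA_character_,
               study_area = if (!is.null(at)) at$zone else NA_character_)
  })
  out[order(names(out))]
}

#' Write polygon features as GeoJSON
#'
#' Planar coordinates; each feature is a Polygon (one convex part) or
#' MultiPolygon (a region of several parts) with a `properties` list. The
#' top-level object carries `"crs": "planar-metres"`.
#'
#' @param features list; each element a list with `region` (list of n x 2
#'   matrices) and `properties` (named list).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_geojson_polygons <- function(features, path) {
  close_ring <- function(m) {
    m <- as.matrix(m)
    rbind(m, m[1, , drop = FALSE])
  }
  feats <- lapply(features, function(f) {
    region <- as_region(f$region)
    geom <- if (length(region) == 1) {
      list(type = "Polygon",
           coordinates = list(close_ring(region[[1]])))
    } else {
      list(type = "MultiPolygon",
           coordinates = lapply(region, function(p) list(close_ring(p))))
    }
    list(type = "Feature", properties = f$properties, geometry = geom)
  })
  obj <- list(type = "FeatureCollection", crs = "planar-metres",
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygon features from GeoJSON
#'
#' @param path file written by [write_geojson_polygons()] (Polygon and
#'   MultiPolygon features).
#' @return list of features, each with `region` and `properties`.
#' @export
read_geojson_polygons <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj$features, function(f) {
    open_ring <- function(ring) {
      m <- do.call(rbind, lapply(ring, function(pt) {
        c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
      }))
      m[-nrow(m), , drop = FALSE]
    }
    region <- if (f$geometry$type == "Polygon") {
      list(open_ring(f$geometry$coordinates[[1]]))
    } else {
      lapply(f$geometry$coordinates, function(poly) open_ring(poly[[1]]))
    }
    list(region = region, properties = f$properties)
  })
}

#' Write an elevation grid as an ESRI ASCII grid
#'
#' @param grid list with `xll`, `yll`, `cellsize`, `nrow`, `ncol`, `values`
#'   (matrix, rows north to south).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_esri_ascii <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$ncol),
    paste("nrows", grid$nrow),
    paste("xllcorner", grid$xll),
    paste("yllcorner", grid$yll),
    paste("cellsize", grid$cellsize),
    "NODATA_value -9999"
  ), con)
  apply(grid$values, 1, function(row) {
    writeLines(paste(formatC(row, format = "g", digits = 8),
                     collapse = " "), con)
  })
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file.
#' @return grid list as used by [mean_elevation_zonal()].
#' @export
read_esri_ascii <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, character(1), 1))
  vals <- as.numeric(vapply(kv, `[`, character(1), 2))
  names(vals) <- keys
  nr <- as.integer(vals[["nrows"]])
  nc <- as.integer(vals[["ncols"]])
  body <- scan(path, skip = 6, quiet = TRUE)
  list(xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
       cellsize = vals[["cellsize"]], nrow = nr, ncol = nc,
       values = matrix(body, nrow = nr, ncol = nc, byrow = TRUE))
}

#' Write home ranges as GeoJSON
#'
#' One feature per home range with properties `animal_id`, `estimator`,
#' `level`, `k`, `area_km2`.
#'
#' @param home_ranges list of `home_range` objects.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_home_ranges_geojson <- function(home_ranges, path) {
  feats <- lapply(home_ranges, function(hr) {
    list(region = hr$polygons,
         properties = list(animal_id = hr$animal_id,
                           estimator = hr$estimator, level = hr$level,
                           k = if (is.na(hr$k)) NULL else hr$k,
                           area_km2 = hr$area_km2))
  })
  write_geojson_polygons(feats, path)
}

#' Write landscape layers as GeoJSON
#'
#' One feature per zone polygon (`class = "zone:<name>"`) and one per
#' land-class patch (`class = "agriculture"` / `"settlement"`). The
#' elevation grid is not part of the GeoJSON; write it with
#' [write_esri_ascii()].
#'
#' @param layers a `landscape_layers` object.
#' @param path output file.
#' @param include_patches write the (possibly numerous) class patches.
#' @return the path, invisibly.
#' @export
write_landscape_geojson <- function(layers, path, include_patches = TRUE) {
  feats <- lapply(names(layers$zones), function(z) {
    list(region = list(layers$zones[[z]]),
         properties = list(class = paste0("zone:", z)))
  })
  if (include_patches) {
    for (cl in names(layers$classes)) {
      feats <- c(feats, lapply(layers$classes[[cl]], function(p) {
        list(region = list(p), properties = list(class = cl))
      }))
    }
  }
  write_geojson_polygons(feats, path)
}
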