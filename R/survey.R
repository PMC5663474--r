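#' Aggregate classified recordings into a spatio-temporal survey map
#'
#' Tiles the study area with equirectangular grid cells of fixed metric
#' size (side length computed at the box's mean latitude; over the few-km
#' extents of a field exercise the distortion is negligible), counts
#' classified recordings per cell per species, histograms recording
#' timestamps by hour as a proxy for mosquito activity, and carries
#' zero-encounter reports through as first-class markers.
#'
#' @param results A data.frame with one row per report and columns
#'   \code{species} (predicted species; \code{NA} for zero-encounter
#'   reports), \code{lat}, \code{lon}, \code{timestamp} (optional), and
#'   optionally \code{is_zero_encounter}. Rows lacking coordinates are
#'   excluded with a warning, never an error.
#' @param grid_size_m Cell side length in metres (default 100).
#' @param time_bin_h Width of the temporal bins in hours (default 1).
#' @param area Optional bounding box \code{c(lat_min, lat_max, lon_min,
#'   lon_max)}; default the range of the supplied coordinates.
#' @return An object of class \code{survey_map}: \code{cells} (data.frame
#'   of cell bounds and per-species counts, one row per occupied
#'   cell-species pair), \code{zero_encounters} (lat/lon data.frame),
#'   \code{hourly} (named count vector over time bins), \code{area},
#'   \code{grid_size_m}, \code{n_classified}.
#' @export
aggregate_survey <- function(results, grid_size_m = 100, time_bin_h = 1,
                             area = NULL) {
  stopifnot(is.data.frame(results), grid_size_m > 0, time_bin_h > 0)
  if (!all(c("species", "lat", "lon") %in% names(results)))
    stop("results needs columns species, lat, lon", call. = FALSE)
  if (is.null(results$is_zero_encounter))
    results$is_zero_encounter <- is.na(results$species)
  ok <- is.finite(results$lat) & is.finite(results$lon)
  if (any(!ok)) {
    warning(sum(!ok), " result(s) lacking location excluded from the map")
    results <- results[ok, , drop = FALSE]
  }
  if (nrow(results) == 0L)
    stop("no mappable results", call. = FALSE)
  if (is.null(area))
    area <- c(min(results$lat), max(results$lat),
              min(results$lon), max(results$lon))
  mean_lat <- (area[1] + area[2]) / 2
  dlat <- grid_size_m / 111320
  dlon <- grid_size_m / (111320 * max(0.01, cos(mean_lat * pi / 180)))
  n_lat <- max(1L, ceiling((area[2] - area[1]) / dlat))
  n_lon <- max(1L, ceiling((area[4] - area[3]) / dlon))

  cls <- results[!results$is_zero_encounter, , drop = FALSE]
  zero <- results[results$is_zero_encounter, c("lat", "lon"), drop = FALSE]
  ri <- pmin(n_lat, pmax(1L, 1L + floor((cls$lat - area[1]) / dlat)))
  ci <- pmin(n_lon, pmax(1L, 1L + floor((cls$lon - area[3]) / dlon)))
  if (nrow(cls) > 0L) {
    key <- paste(ri, ci, cls$species, sep = "\t")
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- do.call(rbind, strsplit(as.character(agg$key), "\t",
                                     fixed = TRUE))
    cells <- data.frame(
      row = as.integer(parts[, 1]), col = as.integer(parts[, 2]),
      species = parts[, 3],
      count = agg$Freq, stringsAsFactors = FALSE)
  } else {
    cells <- data.frame(row = integer(), col = integer(),
                        species = character(), count = integer(),
                        stringsAsFactors = FALSE)
  }
  cells$lat_min <- area[1] + (cells$row - 1L) * dlat
  cells$lat_max <- cells$lat_min + dlat
  cells$lon_min <- area[3] + (cells$col - 1L) * dlon
  cells$lon_max <- cells$lon_min + dlon
  cells$cell_id <- sprintf("r%03dc%03d", cells$row, cells$col)

  hourly <- stats::setNames(rep(0L, ceiling(24 / time_bin_h)),
                            sprintf("h%02.0f", seq(0, 24 - time_bin_h,
                                                   by = time_bin_h)))
  if (!is.null(cls$timestamp) && nrow(cls) > 0) {
    hr <- as.numeric(format(as.POSIXct(cls$timestamp, tz = "UTC"), "%H")) +
      as.numeric(format(as.POSIXct(cls$timestamp, tz = "UTC"), "%M")) / 60
    bin <- pmin(length(hourly), 1L + floor(hr / time_bin_h))
    tab <- table(factor(bin, levels = seq_along(hourly)))
    hourly <- stats::setNames(as.integer(tab), names(hourly))
  }
  structure(
    list(cells = cells, zero_encounters = zero, hourly = hourly,
         area = area, grid_size_m = grid_size_m, time_bin_h = time_bin_h,
         n_classified = nrow(cls)),
    class = "survey_map")
}

#' @export
print.survey_map <- function(x, ...) {
  cat(sprintf(
    "<survey_map> %d recordings in %d occupied cell-species pairs, %d zero-encounter sites\n",
    x$n_classified, nrow(x$cells), nrow(x$zero_encounters)))
  invisible(x)
}

#' Export a survey map as GeoJSON and CSV
#'
#' Writes a GeoJSON FeatureCollection (one polygon feature per occupied
#' cell-species pair, with species and count properties, plus point
#' features for zero-encounter sites) and a CSV summary with columns
#' \code{cell_id}, \code{species}, \code{count}.
#'
#' @param map A \code{survey_map}.
#' @param path Output path stem; \code{.geojson} and \code{.csv} are
#'   appended.
#' @return Character vector of the two file paths, invisibly.
#' @export
export_map <- function(map, path) {
  stopifnot(inherits(map, "survey_map"))
  geo <- paste0(path, ".geojson")
  csv <- paste0(path, ".csv")
  features <- lapply(seq_len(nrow(map$cells)), function(i) {
    cl <- map$cells[i, ]
    ring <- list(c(cl$lon_min, cl$lat_min), c(cl$lon_max, cl$lat_min),
                 c(cl$lon_max, cl$lat_max), c(cl$lon_min, cl$lat_max),
                 c(cl$lon_min, cl$lat_min))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(cell_id = cl$cell_id, species = cl$species,
                           count = cl$count))
  })
  zeros <- lapply(seq_len(nrow(map$zero_encounters)), function(i) {
    z <- map$zero_encounters[i, ]
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(z$lon, z$lat)),
         properties = list(zero_encounter = TRUE))
  })
  fc <- list(type = "FeatureCollection", features = c(features, zeros))
  jsonlite::write_json(fc, geo, auto_unbox = TRUE, digits = NA)
  utils::write.csv(map$cells[, c("cell_id", "species", "count")], csv,
                   row.names = FALSE)
  invisible(c(geojson = geo, csv = csv))
}

#' Read a survey map summary CSV back
#'
#' @param path The \code{.csv} written by \code{\link{export_map}}.
#' @return A data.frame with columns \code{cell_id}, \code{species},
#'   \code{count}.
#' @export
read_map_csv <- function(path) utils::read.csv(path)
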