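## Plain-text readers/writers for the pipeline's interchange formats:
## fix tables and weather as CSV, land cover as GeoJSON, ground truth and
## fitted movement parameters as JSON.

#' Write / read a GPS fix table
#'
#' CSV columns `id,timestamp_iso_local,x_m,y_m,nsats,hdop`; timestamps are
#' local CEST in ISO format without a zone suffix.
#'
#' @param fixes Tibble with `id, timestamp, x_m, y_m` and optionally
#'   `nsats, hdop`.
#' @param path File path.
#' @return `read_fixes` returns the fix tibble with POSIXct timestamps.
#' @export
write_fixes <- function(fixes, path) {
  df <- data.frame(
    id = fixes$id,
    timestamp_iso_local = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%S"),
    x_m = fixes$x_m, y_m = fixes$y_m,
    nsats = if ("nsats" %in% names(fixes)) fixes$nsats else NA_integer_,
    hdop = if ("hdop" %in% names(fixes)) fixes$hdop else NA_real_
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixes
#' @export
read_fixes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(
    id = as.character(df$id),
    timestamp = as.POSIXct(df$timestamp_iso_local, format = "%Y-%m-%dT%H:%M:%S",
                           tz = owl_tz()),
    x_m = df$x_m, y_m = df$y_m, nsats = df$nsats, hdop = df$hdop
  )
}

#' Write / read hourly weather
#'
#' CSV columns `night_date,hour,temp_c,precip` with precipitation coded
#' yes/no.
#'
#' @param weather Tibble from [generate_weather()].
#' @param path File path.
#' @export
write_weather <- function(weather, path) {
  df <- data.frame(night_date = as.character(weather$night_date),
                   hour = weather$hour, temp_c = weather$temp_c,
                   precip = ifelse(weather$precip, "yes", "no"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weather
#' @export
read_weather <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(night_date = as.Date(df$night_date), hour = df$hour,
                 temp_c = df$temp_c, precip = df$precip == "yes")
}

#' Write / read a landscape as GeoJSON
#'
#' Fields become Polygon features carrying a `class` property; roads and
#' field edges become LineString features with `kind` "road" or
#' "field_edge". Coordinates are projected metres (no geodesy).
#'
#' @param map A `landcover_map`.
#' @param path File path.
#' @return `read_landcover_geojson` reconstructs the `landcover_map`
#'   (including the grid index) from the rectangle corners.
#' @export
write_landcover_geojson <- function(map, path) {
  poly_feat <- lapply(seq_len(nrow(map$fields)), function(i) {
    f <- map$fields[i, ]
    ring <- list(c(f$xmin, f$ymin), c(f$xmax, f$ymin), c(f$xmax, f$ymax),
                 c(f$xmin, f$ymax), c(f$xmin, f$ymin))
    list(type = "Feature",
         properties = list(id = f$id, class = f$class),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  line_feat <- function(seg, kind) {
    lapply(seq_len(nrow(seg)), function(i) {
      list(type = "Feature", properties = list(kind = kind),
           geometry = list(type = "LineString",
                           coordinates = list(c(seg$x0[i], seg$y0[i]),
                                              c(seg$x1[i], seg$y1[i]))))
    })
  }
  fc <- list(type = "FeatureCollection",
             features = c(poly_feat, line_feat(map$roads, "road"),
                          line_feat(map$edges, "field_edge")))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landcover_geojson
#' @export
read_landcover_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(fc$type, "FeatureCollection"))
  polys <- list(); lines <- list()
  for (ft in fc$features) {
    if (ft$geometry$type == "Polygon") polys[[length(polys) + 1]] <- ft
    else lines[[length(lines) + 1]] <- ft
  }
  rect <- lapply(polys, function(ft) {
    xy <- do.call(rbind, lapply(ft$geometry$coordinates[[1]], unlist))
    data.frame(id = ft$properties$id, class = ft$properties$class,
               xmin = min(xy[, 1]), ymin = min(xy[, 2]),
               xmax = max(xy[, 1]), ymax = max(xy[, 2]))
  })
  fields <- do.call(rbind, rect)
  fields <- fields[order(fields$id), ]
  fields$area_m2 <- (fields$xmax - fields$xmin) * (fields$ymax - fields$ymin)
  seg <- lapply(lines, function(ft) {
    xy <- do.call(rbind, lapply(ft$geometry$coordinates, unlist))
    data.frame(kind = ft$properties$kind, x0 = xy[1, 1], y0 = xy[1, 2],
               x1 = xy[2, 1], y1 = xy[2, 2])
  })
  seg <- do.call(rbind, seg)
  xb <- sort(unique(c(fields$xmin, fields$xmax)))
  yb <- sort(unique(c(fields$ymin, fields$ymax)))
  classes <- landcover_classes()
  cls <- match(fields$class, classes)
  roads <- seg[seg$kind == "road", c("x0", "y0", "x1", "y1")]
  edges <- seg[seg$kind == "field_edge", c("x0", "y0", "x1", "y1")]
  structure(list(fields = tibble::as_tibble(fields[, c("id", "class", "xmin",
                                                       "ymin", "xmax", "ymax",
                                                       "area_m2")]),
                 xb = xb, yb = yb, cell_class = cls,
                 roads = tibble::as_tibble(roads),
                 edges = tibble::as_tibble(edges),
                 extent = c(min(xb), max(xb)), classes = classes),
            class = "landcover_map")
}

#' Write / read ground truth as a JSON sidecar
#'
#' @param truth A [synthetic_truth()].
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  x$selection_coefficients <- as.list(x$selection_coefficients)  # keep names
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_truth(nest_xy = x$nest_xy,
                  selection = unlist(x$selection_coefficients),
                  turn_correlation = x$turn_correlation,
                  step_scale = x$step_scale,
                  attraction_exponent = x$attraction_exponent,
                  home_scale_m = x$home_scale_m, noise_sd = x$noise_sd,
                  bad_fix_rate = x$bad_fix_rate,
                  dropout_rate = x$dropout_rate, seed = x$seed)
}
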