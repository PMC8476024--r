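#' Assign land-cover classes to points
#'
#' Point-in-polygon lookup against the rectangular-field mosaic. Points on
#' a shared border get the class of the first polygon in insertion order
#' (fields are stored row-major from the lower-left, so a boundary point
#' belongs to the lower/left field). Points outside every polygon are
#' flagged unclassified (`NA`); downstream users exclude them and log the
#' count rather than imputing.
#'
#' @param points Tibble with `x_m`, `y_m`.
#' @param map A `landcover_map`.
#' @return `points` with a `land_cover` column (`NA` = unclassified).
#' @export
assign_land_cover <- function(points, map) {
  stopifnot(inherits(map, "landcover_map"))
  points$land_cover <- landcover_at(map, points$x_m, points$y_m)
  points
}

#' Distance from points to the nearest line feature
#'
#' Minimum Euclidean point-to-segment distance over all polylines (roads or
#' field edges).
#'
#' @param points Tibble with `x_m`, `y_m`.
#' @param lines Segment tibble with `x0, y0, x1, y1` (e.g. `map$edges`).
#' @return Numeric vector of distances (m).
#' @export
distance_to_nearest <- function(points, lines) {
  if (is.null(lines) || nrow(lines) == 0) stop("empty line feature set")
  px <- points$x_m; py <- points$y_m
  best <- rep(Inf, length(px))
  for (i in seq_len(nrow(lines))) {
    ax <- lines$x0[i]; ay <- lines$y0[i]
    bx <- lines$x1[i]; by <- lines$y1[i]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    d <- sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
    best <- pmin(best, d)
  }
  best
}

## Exact area of the intersection of the disk of radius r centred at
## (cx, cy) with an axis-aligned rectangle, by integrating the vertical
## chord overlap over x (adaptive quadrature; the integrand is piecewise
## smooth).
disk_rect_area <- function(cx, cy, r, xmin, xmax, ymin, ymax) {
  if (r <= 0) return(0)
  x0 <- xmin - cx; x1 <- xmax - cx
  y0 <- ymin - cy; y1 <- ymax - cy
  ## quick rejects / full containment
  ddx <- pmax(pmax(x0, -x1), 0); ddy <- pmax(pmax(y0, -y1), 0)
  if (ddx^2 + ddy^2 >= r^2) return(0)
  corners <- c(x0^2 + y0^2, x0^2 + y1^2, x1^2 + y0^2, x1^2 + y1^2)
  if (all(corners <= r^2)) return((x1 - x0) * (y1 - y0))
  lo <- max(x0, -r); hi <- min(x1, r)
  if (hi <= lo) return(0)
  f <- function(x) {
    g <- sqrt(pmax(r^2 - x^2, 0))
    pmax(pmin(y1, g) - pmax(y0, -g), 0)
  }
  val <- tryCatch(
    integrate(f, lo, hi, rel.tol = 1e-9, abs.tol = 1e-6,
              subdivisions = 400L)$value,
    error = function(e) NA_real_)
  if (is.na(val)) {
    ## composite Simpson fallback: the integrand has sqrt kinks that the
    ## adaptive rule occasionally refuses; a fine fixed grid is ample here
    n <- 4096L
    xs <- seq(lo, hi, length.out = n + 1L)
    w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
    val <- sum(w * f(xs)) * (hi - lo) / (3 * n)
  }
  val
}

## Clipped area (m^2) of every field inside the disk of radius r around p.
clipped_field_areas <- function(map, nest_xy, r) {
  f <- map$fields
  vapply(seq_len(nrow(f)), function(i)
    disk_rect_area(nest_xy[1], nest_xy[2], r,
                   f$xmin[i], f$xmax[i], f$ymin[i], f$ymax[i]),
    numeric(1))
}

#' Land-cover composition in distance rings around the nest
#'
#' Proportion of each land-cover class's area within concentric annuli
#' around the nest; the study described territories with the six distance
#' classes 0-100, 100-200, 200-300, 300-400, 400-500 and 500-2000 m.
#' Proportions within each ring sum to 1 over the classified area.
#'
#' @param nest_xy Nest coordinates (m); must lie inside the map extent.
#' @param map A `landcover_map`.
#' @param ring_breaks Increasing radii (m) delimiting the annuli.
#' @return Tibble `ring, class, area_m2, proportion`.
#' @export
buffer_composition <- function(nest_xy, map,
                               ring_breaks = c(0, 100, 200, 300, 400, 500, 2000)) {
  stopifnot(inherits(map, "landcover_map"),
            all(diff(ring_breaks) > 0))
  if (is.na(landcover_at(map, nest_xy[1], nest_xy[2]))) {
    stop("nest lies outside the landscape")
  }
  cum <- vapply(ring_breaks, function(r)
    if (r == 0) rep(0, nrow(map$fields)) else clipped_field_areas(map, nest_xy, r),
    numeric(nrow(map$fields)))
  rows <- list()
  for (k in seq_len(length(ring_breaks) - 1)) {
    ring_area <- cum[, k + 1] - cum[, k]
    by_class <- tapply(ring_area, map$fields$class, sum)
    by_class <- by_class[!is.na(by_class)]
    tot <- sum(by_class)
    rows[[k]] <- tibble::tibble(
      ring = paste0(ring_breaks[k], "-", ring_breaks[k + 1]),
      class = names(by_class),
      area_m2 = as.numeric(by_class),
      proportion = if (tot > 0) as.numeric(by_class) / tot else NA_real_)
  }
  do.call(rbind, rows)
}

#' Mean field size around the nest
#'
#' Average full-polygon area (ha) over the fields whose footprint
#' intersects the disc of `radius` metres around the nest. The full area
#' is used for intersecting fields (not the clipped part): the quantity is
#' the average size of the fields a territory touches.
#'
#' @param map A `landcover_map`.
#' @param nest_xy Nest coordinates (m).
#' @param radius Buffer radius (m); the study used 500 m.
#' @return Mean field size in hectares.
#' @export
mean_field_size <- function(map, nest_xy, radius = 500) {
  clip <- clipped_field_areas(map, nest_xy, radius)
  hit <- clip > 0
  if (!any(hit)) stop("no field intersects the buffer")
  mean(map$fields$area_m2[hit]) / 1e4
}

#' Simpson's Index of Diversity of a territory
#'
#' `D = 1 - [sum n(n-1) / N(N-1)]` with `n` the clipped area (m^2) of each
#' land-cover class inside the nest buffer and `N` the total classified
#' area. With areas in square metres the finite-size correction is
#' negligible and D converges to `1 - sum p^2`.
#'
#' @inheritParams mean_field_size
#' @return D in `[0, 1)`.
#' @export
simpson_diversity <- function(map, nest_xy, radius = 500) {
  clip <- clipped_field_areas(map, nest_xy, radius)
  n_k <- tapply(clip, map$fields$class, sum)
  n_k <- n_k[!is.na(n_k) & n_k > 0]
  N <- sum(n_k)
  if (N <= 0) stop("zero classified area within the buffer")
  1 - sum(n_k * (n_k - 1)) / (N * (N - 1))
}

#' Build the used/available table for the resource selection function
#'
#' Stacks observed (used = 1) and availability (used = 0) positions,
#' assigns land cover, and attaches the distance covariates: distance to
#' the nearest field edge, nearest road, and the individual's nest.
#' Unclassified points (outside the mapped extent) are dropped with a
#' logged count.
#'
#' @param used Tibble `id, x_m, y_m` of observed positions.
#' @param available Tibble `id, x_m, y_m` from [generate_availability()].
#' @param map A `landcover_map`.
#' @param nests Named list of nest coordinates per individual id.
#' @return Tibble `id, used, x_m, y_m, land_cover, dist_edge_m,
#'   dist_road_m, dist_nest_m`.
#' @export
used_available_table <- function(used, available, map, nests) {
  pts <- tibble::tibble(
    id = c(used$id, available$id),
    x_m = c(used$x_m, available$x_m),
    y_m = c(used$y_m, available$y_m))
  pts$used <- rep(c(1L, 0L), c(nrow(used), nrow(available)))
  pts <- pts[, c("id", "used", "x_m", "y_m")]
  pts <- assign_land_cover(pts, map)
  n_uncl <- sum(is.na(pts$land_cover))
  if (n_uncl > 0) {
    message(n_uncl, " unclassified point(s) outside the mapped extent dropped")
    pts <- pts[!is.na(pts$land_cover), , drop = FALSE]
  }
  pts$dist_edge_m <- distance_to_nearest(pts, map$edges)
  pts$dist_road_m <- distance_to_nearest(pts, map$roads)
  pts$dist_nest_m <- NA_real_
  for (ind in unique(pts$id)) {
    nest <- nests[[ind]]
    sel <- pts$id == ind
    pts$dist_nest_m[sel] <- dist_to_point(pts$x_m[sel], pts$y_m[sel],
                                          nest[1], nest[2])
  }
  pts
}
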