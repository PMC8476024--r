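#' Per-fix distance from the nest
#'
#' Straight-line (Euclidean) distance of every GPS position from the nest,
#' in the order of the fixes.
#'
#' @param segment A `night_segment` (or any tibble with `x_m`, `y_m`).
#' @param nest_xy Numeric length-2 nest coordinates (m).
#' @return Numeric vector of distances (m).
#' @export
nest_distances <- function(segment, nest_xy) {
  stopifnot(length(nest_xy) == 2, all(is.finite(nest_xy)))
  fx <- if (inherits(segment, "night_segment")) segment$fixes else segment
  dist_to_point(fx$x_m, fx$y_m, nest_xy[1], nest_xy[2])
}

#' Nightly space use: 95% isopleth area of a kernel density estimate
#'
#' Bivariate Gaussian KDE with the reference bandwidth
#' `h_ref = sqrt(0.5 * (var(x) + var(y))) * n^(-1/6)` applied to both
#' coordinates. Density is evaluated on a `grid_cells` x `grid_cells` grid
#' extending at least `3 * h` beyond the fix bounding box; the isopleth
#' area is the summed area of the smallest set of cells whose cumulative
#' density reaches `isopleth` of the total, converted to hectares.
#'
#' Absolute areas are mildly grid-sensitive; the 200-cell default is
#' documented and configurable.
#'
#' @param segment A `night_segment` or tibble with `x_m`, `y_m`.
#' @param grid_cells Grid resolution per axis.
#' @param isopleth Utilisation-distribution quantile (default 0.95).
#' @param extend_h Grid margin beyond the bounding box, in bandwidths.
#' @return Area in hectares.
#' @export
nightly_kde_area <- function(segment, grid_cells = 200, isopleth = 0.95,
                             extend_h = 3) {
  fx <- if (inherits(segment, "night_segment")) segment$fixes else segment
  x <- fx$x_m; y <- fx$y_m
  n <- length(x)
  stopifnot(n >= 2)
  h <- href_bandwidth(x, y)
  if (!is.finite(h) || h <= 0) stop("degenerate segment: zero coordinate variance")
  gx <- seq(min(x) - extend_h * h, max(x) + extend_h * h, length.out = grid_cells)
  gy <- seq(min(y) - extend_h * h, max(y) + extend_h * h, length.out = grid_cells)
  ## separable Gaussian kernel: density = (1/n) * Kx %*% t(Ky) summed over fixes
  kx <- outer(gx, x, function(g, xi) dnorm(g, xi, h))
  ky <- outer(gy, y, function(g, yi) dnorm(g, yi, h))
  dens <- kx %*% t(ky) / n   # rows = gx, cols = gy
  cell_area <- diff(gx[1:2]) * diff(gy[1:2])
  isopleth_area_ha(dens, cell_area, isopleth)
}

## Reference ("ad hoc") bandwidth with a pooled coordinate SD.
href_bandwidth <- function(x, y) {
  n <- length(x)
  sqrt(0.5 * (var(x) + var(y))) * n^(-1 / 6)
}

## Smallest set of grid cells holding `isopleth` of the total density mass.
isopleth_area_ha <- function(dens, cell_area, isopleth) {
  v <- sort(as.numeric(dens), decreasing = TRUE)
  cum <- cumsum(v)
  k <- which(cum >= isopleth * sum(v))[1]
  k * cell_area / 1e4
}

#' Detect foraging trips away from the nest
#'
#' A trip is a maximal excursion containing at least one fix farther than
#' `far_m` from the nest, bounded by the last fix within `home_m` of the
#' nest before it (trip start) and the first fix within `home_m` after it
#' (trip end); duration runs from start to end. Excursions that exceed
#' `far_m` but lack a bounding at-nest fix on either side (recording began
#' or ended mid-trip) are censored: excluded from the trip list and counted
#' in the report.
#'
#' @param segment A `night_segment` or tibble with `timestamp, x_m, y_m`.
#' @param nest_xy Nest coordinates (m).
#' @param far_m Excursion threshold (m); the study used 200 m.
#' @param home_m At-nest threshold (m); the study used 25 m.
#' @return List with `trips` (tibble: individual_id, night_date,
#'   start_time, end_time, duration_min, max_nest_distance_m) and
#'   `n_censored`.
#' @export
detect_trips <- function(segment, nest_xy, far_m = 200, home_m = 25) {
  fx <- if (inherits(segment, "night_segment")) segment$fixes else segment
  ind <- if (inherits(segment, "night_segment")) segment$individual_id else NA_character_
  nd <- if (inherits(segment, "night_segment")) segment$night_date else as.Date(NA)
  d <- dist_to_point(fx$x_m, fx$y_m, nest_xy[1], nest_xy[2])
  n <- length(d)
  home <- which(d <= home_m)
  empty <- tibble::tibble(individual_id = character(), night_date = as.Date(character()),
                          start_time = as.POSIXct(character()),
                          end_time = as.POSIXct(character()),
                          duration_min = numeric(), max_nest_distance_m = numeric())
  if (n == 0) return(list(trips = empty, n_censored = 0L))

  ## candidate excursions: runs of away fixes delimited by home fixes or the
  ## segment boundary
  bounds <- c(0L, home, n + 1L)
  trips <- list(); censored <- 0L
  for (b in seq_len(length(bounds) - 1L)) {
    lo <- bounds[b]; hi <- bounds[b + 1L]
    if (hi - lo <= 1L) next               # no away fixes between these bounds
    seg_idx <- (lo + 1L):(hi - 1L)
    dmax <- max(d[seg_idx])
    if (dmax <= far_m) next               # never beyond the trip threshold
    if (lo == 0L || hi == n + 1L) {       # unbounded at one end: censored
      censored <- censored + 1L
      next
    }
    trips[[length(trips) + 1L]] <- tibble::tibble(
      individual_id = ind, night_date = nd,
      start_time = fx$timestamp[lo], end_time = fx$timestamp[hi],
      duration_min = as.numeric(difftime(fx$timestamp[hi], fx$timestamp[lo],
                                         units = "mins")),
      max_nest_distance_m = dmax)
  }
  list(trips = if (length(trips)) do.call(rbind, trips) else empty,
       n_censored = censored)
}

#' Hourly displacement
#'
#' Sum of straight-line distances between consecutive GPS positions within
#' each clock hour of the night; a step is assigned to the hour of its
#' earlier fix, and steps spanning a recording gap longer than
#' `max_gap_min` minutes are excluded (fix-dropout protection). The number
#' of fixes per hour is reported alongside as a bias covariate.
#'
#' @param segment A `night_segment` or tibble with `timestamp, x_m, y_m`.
#' @param max_gap_min Longest fix interval (minutes) still summed as a step.
#' @return Tibble `hour, displacement_m, n_fixes_hour` (one row per clock
#'   hour holding at least one fix, in night order).
#' @export
hourly_displacement <- function(segment, max_gap_min = 10) {
  fx <- if (inherits(segment, "night_segment")) segment$fixes else segment
  n <- nrow(fx)
  stopifnot(n >= 1)
  hr <- as.integer(format(fx$timestamp, "%H"))
  n_fixes_hour <- table(factor(hr, levels = unique(hr)))
  disp <- setNames(numeric(length(n_fixes_hour)), names(n_fixes_hour))
  if (n >= 2) {
    step <- sqrt(diff(fx$x_m)^2 + diff(fx$y_m)^2)
    gap <- diff(as.numeric(fx$timestamp)) / 60
    ok <- gap <= max_gap_min
    h_step <- as.character(hr[-n])           # earlier fix's hour
    agg <- tapply(step[ok], h_step[ok], sum)
    disp[names(agg)] <- agg
  }
  tibble::tibble(hour = as.integer(names(n_fixes_hour)),
                 displacement_m = as.numeric(disp),
                 n_fixes_hour = as.integer(n_fixes_hour))
}

#' Count nest visits per hour
#'
#' A (presumed) nest visit is one or more consecutive fixes within
#' `near_m` of the nest following a fix farther than `away_m`. Implemented
#' as a state machine starting disarmed: a fix beyond `away_m` arms it; the
#' first subsequent fix within `near_m` while armed scores one visit
#' (assigned to that arrival fix's clock hour) and disarms; consecutive
#' near-nest fixes collapse into the same visit.
#'
#' @param segment A `night_segment` or tibble with `timestamp, x_m, y_m`.
#' @param nest_xy Nest coordinates (m).
#' @param near_m At-nest radius (m); the study used 25 m.
#' @param away_m Arming radius (m); the study used 50 m.
#' @return Tibble `hour, nest_visits` over the hours present in the segment.
#' @export
count_nest_visits <- function(segment, nest_xy, near_m = 25, away_m = 50) {
  fx <- if (inherits(segment, "night_segment")) segment$fixes else segment
  d <- dist_to_point(fx$x_m, fx$y_m, nest_xy[1], nest_xy[2])
  hr <- as.integer(format(fx$timestamp, "%H"))
  visits <- integer(length(d))
  armed <- FALSE
  for (i in seq_along(d)) {
    if (d[i] > away_m) {
      armed <- TRUE
    } else if (armed && d[i] <= near_m) {
      visits[i] <- 1L
      armed <- FALSE
    }
  }
  hours <- unique(hr)
  tibble::tibble(hour = hours,
                 nest_visits = as.integer(tapply(visits, factor(hr, levels = hours),
                                                 sum)))
}

#' Proportion of fixes near the nest
#'
#' Share of a segment's GPS positions within `near_m` of the nest.
#'
#' @inheritParams count_nest_visits
#' @return Proportion in `[0, 1]`.
#' @export
near_nest_proportion <- function(segment, nest_xy, near_m = 25) {
  fx <- if (inherits(segment, "night_segment")) segment$fixes else segment
  if (nrow(fx) == 0) stop("empty segment")
  d <- dist_to_point(fx$x_m, fx$y_m, nest_xy[1], nest_xy[2])
  mean(d <= near_m)
}

#' Nightly metric summary across segments
#'
#' Convenience wrapper producing one row per individual-night with the
#' space-use and movement metrics: 95% KDE area (only for nights in the
#' KDE set), fix count, trip count and mean nest distance.
#'
#' @param segments List of `night_segment`s.
#' @param nests Named list (or two-column matrix rownames = id) of nest
#'   coordinates per individual.
#' @param ... Passed to [nightly_kde_area()] and [detect_trips()].
#' @return Tibble `individual_id, night_date, kde95_area_ha, n_fixes,
#'   n_trips, mean_nest_distance_m`.
#' @export
nightly_metrics <- function(segments, nests, ...) {
  rows <- lapply(segments, function(s) {
    nest <- nests[[s$individual_id]]
    d <- nest_distances(s, nest)
    tibble::tibble(
      individual_id = s$individual_id,
      night_date = s$night_date,
      kde95_area_ha = if (s$include_kde) nightly_kde_area(s) else NA_real_,
      n_fixes = s$n_fixes,
      n_trips = nrow(detect_trips(s, nest)$trips),
      mean_nest_distance_m = mean(d))
  })
  do.call(rbind, rows)
}
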