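## Brute-force oracles that replay the metric definitions literally, plus
## small fixture builders. Oracles deliberately share no code with the
## implementations they check.

## A synthetic night of 1-min fixes following a lazy random walk; returns a
## tibble usable wherever a night_segment's fixes are expected.
make_night <- function(seed, n = 150, start = "2020-06-10 21:00:00",
                       step_sd = 30, start_near_nest = TRUE) {
  set.seed(seed)
  t0 <- as.POSIXct(start, tz = "Etc/GMT-2")
  x0 <- if (start_near_nest) rnorm(1, 0, 5) else runif(1, -400, 400)
  y0 <- if (start_near_nest) rnorm(1, 0, 5) else runif(1, -400, 400)
  tibble::tibble(
    id = "owl_test",
    timestamp = t0 + 60 * (seq_len(n) - 1),
    x_m = x0 + cumsum(rnorm(n, 0, step_sd)),
    y_m = y0 + cumsum(rnorm(n, 0, step_sd)))
}

## Trip oracle: exhaustive scan over all pairs of at-nest fixes; a trip is
## any at-nest pair (i, j) with only away fixes between them, at least one
## beyond far_m.
oracle_trips <- function(fixes, nest, far_m = 200, home_m = 25) {
  d <- sqrt((fixes$x_m - nest[1])^2 + (fixes$y_m - nest[2])^2)
  n <- length(d)
  home <- which(d <= home_m)
  trips <- list()
  censored <- 0L
  if (n == 0) return(list(trips = trips, n_censored = censored))
  runs <- list()
  bounds <- c(0L, home, n + 1L)
  for (b in seq_len(length(bounds) - 1L)) {
    lo <- bounds[b]; hi <- bounds[b + 1L]
    if (hi - lo <= 1L) next
    idx <- (lo + 1L):(hi - 1L)
    if (max(d[idx]) <= far_m) next
    if (lo == 0L || hi == n + 1L) censored <- censored + 1L else {
      trips[[length(trips) + 1L]] <- c(start = lo, end = hi, dmax = max(d[idx]))
    }
  }
  list(trips = trips, n_censored = censored)
}

## Nest-visit oracle: literal replay of the armed/disarmed definition.
oracle_visits <- function(fixes, nest, near_m = 25, away_m = 50) {
  d <- sqrt((fixes$x_m - nest[1])^2 + (fixes$y_m - nest[2])^2)
  armed <- FALSE
  hits <- integer(0)
  for (i in seq_along(d)) {
    if (d[i] > away_m) armed <- TRUE
    else if (armed && d[i] <= near_m) { hits <- c(hits, i); armed <- FALSE }
  }
  hits
}

## Hourly displacement oracle: explicit pairwise loop.
oracle_hourly_disp <- function(fixes, max_gap_min = 10) {
  hr <- as.integer(format(fixes$timestamp, "%H"))
  out <- numeric(0)
  for (h in unique(hr)) out[as.character(h)] <- 0
  if (nrow(fixes) >= 2) {
    for (i in seq_len(nrow(fixes) - 1)) {
      gap <- as.numeric(difftime(fixes$timestamp[i + 1], fixes$timestamp[i],
                                 units = "mins"))
      if (gap > max_gap_min) next
      step <- sqrt((fixes$x_m[i + 1] - fixes$x_m[i])^2 +
                   (fixes$y_m[i + 1] - fixes$y_m[i])^2)
      key <- as.character(hr[i])
      out[key] <- out[key] + step
    }
  }
  out
}

## Point-in-rectangle oracle: first-match scan over all fields in insertion
## order with closed intervals.
oracle_assign <- function(map, x, y) {
  f <- map$fields
  vapply(seq_along(x), function(i) {
    hit <- which(x[i] >= f$xmin & x[i] <= f$xmax &
                 y[i] >= f$ymin & y[i] <= f$ymax)
    if (length(hit) == 0) NA_character_ else f$class[hit[1]]
  }, character(1))
}

## Point-to-polyline oracle: minimum distance to segments densified to 1 m
## vertex spacing.
oracle_line_dist <- function(lines, px, py) {
  verts_x <- numeric(0); verts_y <- numeric(0)
  for (i in seq_len(nrow(lines))) {
    len <- sqrt((lines$x1[i] - lines$x0[i])^2 + (lines$y1[i] - lines$y0[i])^2)
    tt <- seq(0, 1, length.out = max(2, ceiling(len) + 1))
    verts_x <- c(verts_x, lines$x0[i] + tt * (lines$x1[i] - lines$x0[i]))
    verts_y <- c(verts_y, lines$y0[i] + tt * (lines$y1[i] - lines$y0[i]))
  }
  vapply(seq_along(px), function(i) {
    sqrt(min((verts_x - px[i])^2 + (verts_y - py[i])^2))
  }, numeric(1))
}

## Fixture: tiny two-owl used/available table with known class layout, for
## inference tests that do not need the full movement pipeline.
make_ua_table <- function(seed, n_used = 300, ratio = 10,
                          betas = c(pasture = 0, maize = 0)) {
  set.seed(seed)
  classes <- c("cereal", "pasture", "maize")
  base_p <- c(0.5, 0.25, 0.25)
  rows <- list()
  for (ind in c("owlA", "owlB")) {
    w <- base_p * exp(c(0, betas["pasture"], betas["maize"]))
    used_cls <- sample(classes, n_used, TRUE, prob = w / sum(w))
    avail_cls <- sample(classes, n_used * ratio, TRUE, prob = base_p)
    k <- n_used * (1 + ratio)
    rows[[ind]] <- tibble::tibble(
      id = ind,
      used = rep(c(1L, 0L), c(n_used, n_used * ratio)),
      x_m = runif(k, 0, 1000), y_m = runif(k, 0, 1000),
      land_cover = c(used_cls, avail_cls),
      dist_edge_m = runif(k, 0, 100),
      dist_road_m = runif(k, 0, 400),
      dist_nest_m = runif(k, 0, 600))
  }
  do.call(rbind, rows)
}
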