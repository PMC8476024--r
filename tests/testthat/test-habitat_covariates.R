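test_that("land-cover assignment matches a brute-force containment scan", {
  map <- generate_landscape(seed = 31, extent_m = 2000, n_fields = 150)
  set.seed(6)
  pts <- tibble::tibble(x_m = runif(1000, -50, 2050),
                        y_m = runif(1000, -50, 2050))   # some outside
  got <- assign_land_cover(pts, map)$land_cover
  expect_identical(got, oracle_assign(map, pts$x_m, pts$y_m))

  ## interior point and boundary tie rule: a point on a shared vertical
  ## border belongs to the first field in insertion order (the left one)
  bx <- map$xb[3]
  by <- (map$yb[2] + map$yb[3]) / 2
  tie <- assign_land_cover(tibble::tibble(x_m = bx, y_m = by), map)$land_cover
  expect_identical(tie, oracle_assign(map, bx, by))
})

test_that("distance to the nearest line feature is exact and 1-Lipschitz", {
  lines <- tibble::tibble(x0 = c(0, 0), y0 = c(0, 200),
                          x1 = c(100, 100), y1 = c(0, 200))
  ## 30 m perpendicular from a long segment; on-line point gives 0
  d <- distance_to_nearest(tibble::tibble(x_m = c(50, 20), y_m = c(30, 0)),
                           lines)
  expect_equal(d, c(30, 0))

  map <- generate_landscape(seed = 37, extent_m = 1500, n_fields = 60)
  set.seed(8)
  pts <- tibble::tibble(x_m = runif(100, 0, 1500), y_m = runif(100, 0, 1500))
  exact <- distance_to_nearest(pts, map$edges)
  approx <- oracle_line_dist(map$edges, pts$x_m, pts$y_m)
  expect_true(all(abs(exact - approx) <= 0.5))   # 1 m densified oracle

  ## Lipschitz: nudging a point by delta moves its distance by <= delta
  delta <- 3
  nudged <- pts; nudged$x_m <- nudged$x_m + delta
  expect_true(all(abs(distance_to_nearest(nudged, map$edges) - exact) <=
                    delta + 1e-9))

  expect_error(distance_to_nearest(pts, map$edges[0, ]), "empty")
})

test_that("buffer-ring composition integrates the mosaic correctly", {
  ## single-class landscape: every ring is 100% that class
  mono <- generate_landscape(seed = 3, extent_m = 5000, n_fields = 50,
                             class_mix = c(pasture = 1))
  comp <- buffer_composition(c(2500, 2500), mono)
  expect_true(all(comp$proportion[comp$area_m2 > 0] == 1))
  expect_true(all(comp$class[comp$area_m2 > 0] == "pasture"))

  ## half-plane split through the nest: every ring 50/50 (+-1%)
  half <- mono
  half$fields$class <- ifelse((half$fields$xmin + half$fields$xmax) / 2 < 2500,
                              "cereal", "pasture")
  half$cell_class <- match(half$fields$class, half$classes)
  ## force the split exactly through the nest x
  half$xb[which.min(abs(half$xb - 2500))] <- 2500
  half$fields$xmin <- half$xb[rep(seq_len(length(half$xb) - 1),
                                  times = length(half$yb) - 1)]
  half$fields$xmax <- half$xb[rep(seq_len(length(half$xb) - 1) + 1,
                                  times = length(half$yb) - 1)]
  half$fields$class <- ifelse((half$fields$xmin + half$fields$xmax) / 2 < 2500,
                              "cereal", "pasture")
  half$cell_class <- match(half$fields$class, half$classes)
  comp2 <- buffer_composition(c(2500, 2500), half)
  for (ring in unique(comp2$ring)) {
    p <- comp2$proportion[comp2$ring == ring & comp2$class == "cereal"]
    expect_lt(abs(p - 0.5), 0.01)
  }

  ## proportions sum to 1 per ring on a generic mosaic
  map <- generate_landscape(seed = 41, extent_m = 5000, n_fields = 300)
  comp3 <- buffer_composition(c(2500, 2500), map)
  sums <- tapply(comp3$proportion, comp3$ring, sum)
  expect_true(all(abs(sums - 1) < 1e-6))

  expect_error(buffer_composition(c(-10, 0), map), "outside")
})

test_that("mean field size averages the full area of intersecting fields", {
  ## hand-built map: two fields of 2 ha and 6 ha split at x = 100
  fields <- tibble::tibble(id = 1:2, class = c("cereal", "pasture"),
                           xmin = c(0, 100), ymin = 0,
                           xmax = c(100, 400), ymax = 200)
  fields$area_m2 <- (fields$xmax - fields$xmin) * (fields$ymax - fields$ymin)
  map <- structure(list(fields = fields, xb = c(0, 100, 400), yb = c(0, 200),
                        cell_class = match(fields$class, landcover_classes()),
                        roads = fields[0, 3:6], edges = fields[0, 3:6],
                        extent = c(0, 400), classes = landcover_classes()),
                   class = "landcover_map")
  expect_equal(mean_field_size(map, c(100, 100), radius = 50), 4)  # (2+6)/2 ha
  expect_error(mean_field_size(map, c(2000, 2000), radius = 10),
               "no field intersects")

  ## generated mosaic: the intersecting set matches a brute-force
  ## disc-rectangle overlap test
  gm <- generate_landscape(seed = 43, extent_m = 2000, n_fields = 150)
  nest <- c(1000, 1000)
  clip <- vapply(seq_len(nrow(gm$fields)), function(i) {
    f <- gm$fields[i, ]
    ## Monte-Carlo overlap check
    set.seed(i)
    xs <- runif(4000, f$xmin, f$xmax); ys <- runif(4000, f$ymin, f$ymax)
    mean((xs - nest[1])^2 + (ys - nest[2])^2 <= 500^2) > 0
  }, logical(1))
  expect_equal(mean_field_size(gm, nest),
               mean(gm$fields$area_m2[clip]) / 1e4, tolerance = 1e-6)
})

test_that("Simpson's D reproduces its closed-form limits", {
  ## strip map: side-by-side rectangles with prescribed widths
  strip_map <- function(widths, classes, height = 100) {
    xb <- cumsum(c(0, widths))
    n <- length(widths)
    fields <- tibble::tibble(id = seq_len(n), class = classes,
                             xmin = xb[-(n + 1)], ymin = 0,
                             xmax = xb[-1], ymax = height)
    fields$area_m2 <- (fields$xmax - fields$xmin) * height
    structure(list(fields = fields, xb = xb, yb = c(0, height),
                   cell_class = match(classes, landcover_classes()),
                   roads = fields[0, 3:6], edges = fields[0, 3:6],
                   extent = c(0, max(xb)), classes = landcover_classes()),
              class = "landcover_map")
  }

  ## one class only: D = 0
  mono <- generate_landscape(seed = 3, extent_m = 4000, n_fields = 50,
                             class_mix = c(maize = 1))
  expect_equal(simpson_diversity(mono, c(2000, 2000)), 0)

  ## a radius covering the whole strip map turns D into the areal limit
  two <- strip_map(c(50, 50), c("cereal", "pasture"))
  expect_equal(simpson_diversity(two, c(50, 50), radius = 1000), 0.5,
               tolerance = 1e-3)
  three <- strip_map(c(50, 30, 20), c("cereal", "pasture", "maize"))
  expect_equal(simpson_diversity(three, c(50, 50), radius = 1000),
               1 - (0.25 + 0.09 + 0.04), tolerance = 1e-3)

  ## large-N agreement with 1 - sum(p^2) on a generated territory
  hp <- generate_landscape(seed = 5, extent_m = 5000, n_fields = 64,
                           class_mix = c(cereal = 0.5, pasture = 0.5))
  D <- simpson_diversity(hp, c(2500, 2500))
  areas <- tapply(owltrack:::clipped_field_areas(hp, c(2500, 2500), 500),
                  hp$fields$class, sum)
  p <- areas[!is.na(areas) & areas > 0] / sum(areas, na.rm = TRUE)
  expect_lt(abs(D - (1 - sum(p^2))), 1e-6)   # finite-size term vanishes
})

test_that("the used/available table carries classes and distances per owl", {
  map <- generate_landscape(seed = 47, extent_m = 2000, n_fields = 100,
                            nest_xy = rbind(c(600, 600), c(1400, 1400)))
  set.seed(9)
  used <- tibble::tibble(id = rep(c("a", "b"), each = 20),
                         x_m = runif(40, 100, 1900),
                         y_m = runif(40, 100, 1900))
  avail <- tibble::tibble(id = rep(c("a", "b"), each = 200),
                          x_m = runif(400, 100, 1900),
                          y_m = runif(400, 100, 1900))
  tab <- used_available_table(used, avail, map,
                              list(a = c(600, 600), b = c(1400, 1400)))
  expect_equal(sum(tab$used == 0) / sum(tab$used == 1), 10)
  expect_true(all(tab$land_cover %in% landcover_classes()))
  expect_true(all(tab$dist_edge_m >= 0 & tab$dist_road_m >= 0))
  a1 <- tab[tab$id == "a", ]
  expect_equal(a1$dist_nest_m,
               sqrt((a1$x_m - 600)^2 + (a1$y_m - 600)^2))
})
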