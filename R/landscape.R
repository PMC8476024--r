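#' Generate a synthetic agricultural landscape
#'
#' Builds a rectangular-field mosaic tiling a square extent: the extent is
#' partitioned by jittered vertical and horizontal break lines into
#' approximately `n_fields` fields, each assigned one of the nine land-cover
#' classes so that realised areal proportions track `class_mix` (greedy
#' largest-deficit assignment in a seeded random order). Roads run along a
#' subset of interior break lines; every field border is a field edge. Any
#' nest site supplied is guaranteed to sit in a built-up field, emulating
#' owls nesting in farm buildings.
#'
#' @param seed Integer seed; fully determines the map.
#' @param extent_m Side length of the square extent in metres.
#' @param n_fields Target number of fields (the realised count is the
#'   nearest grid `nx * ny >= n_fields`).
#' @param class_mix Named numeric vector of target areal proportions over
#'   the classes of [landcover_classes()]; must sum to 1. Defaults to a
#'   farmland mix dominated by cereal with scattered pasture, rape and
#'   maize.
#' @param nest_xy Optional matrix or data.frame of nest coordinates
#'   (columns x, y) whose containing fields are forced to "built up".
#' @param n_roads Number of interior break lines carrying a road (half
#'   vertical, half horizontal).
#'
#' @return A `landcover_map`: list with `fields` (tibble: id, class, xmin,
#'   ymin, xmax, ymax, area_m2 in row-major order from the lower-left),
#'   `xb`/`yb` break vectors, `cell_class` (integer class index per field),
#'   `roads` and `edges` (segment tibbles x0, y0, x1, y1), `extent`,
#'   `classes`.
#' @export
generate_landscape <- function(seed, extent_m = 3000, n_fields = 200,
                               class_mix = NULL, nest_xy = NULL,
                               n_roads = 4) {
  stopifnot(extent_m > 0, n_fields >= 1)
  classes <- landcover_classes()
  if (is.null(class_mix)) {
    class_mix <- c("built up" = 0.04, "cereal" = 0.30, "fallow" = 0.06,
                   "forest" = 0.07, "maize" = 0.14, "other arable" = 0.06,
                   "pasture" = 0.14, "rape" = 0.14, "road verges" = 0.05)
  }
  stopifnot(!is.null(names(class_mix)), all(names(class_mix) %in% classes))
  mix <- setNames(numeric(length(classes)), classes)
  mix[names(class_mix)] <- class_mix
  if (abs(sum(mix) - 1) > 1e-8) stop("class_mix proportions must sum to 1")
  n_active <- sum(mix > 0)
  if (n_fields < n_active) {
    stop("n_fields (", n_fields, ") is smaller than the number of classes ",
         "with nonzero mix (", n_active, ")")
  }

  set.seed(seed)
  nx <- max(2L, as.integer(round(sqrt(n_fields))))
  ny <- max(2L, as.integer(ceiling(n_fields / nx)))
  ## jittered breaks: gamma weights give irregular but not degenerate fields
  wx <- rgamma(nx, shape = 6); wy <- rgamma(ny, shape = 6)
  xb <- extent_m * cumsum(c(0, wx)) / sum(wx)
  yb <- extent_m * cumsum(c(0, wy)) / sum(wy)
  xb[nx + 1] <- extent_m; yb[ny + 1] <- extent_m

  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  fields <- tibble::tibble(
    id = seq_len(nx * ny),
    xmin = xb[ix], xmax = xb[ix + 1],
    ymin = yb[iy], ymax = yb[iy + 1]
  )
  fields$area_m2 <- (fields$xmax - fields$xmin) * (fields$ymax - fields$ymin)

  ## greedy largest-deficit assignment tracks the target areal mix closely
  total <- sum(fields$area_m2)
  target <- mix * total
  assigned <- setNames(numeric(length(classes)), classes)
  cls <- integer(nrow(fields))
  for (i in sample.int(nrow(fields))) {
    deficit <- target - assigned
    k <- which.max(deficit)
    cls[i] <- k
    assigned[k] <- assigned[k] + fields$area_m2[i]
  }

  if (!is.null(nest_xy)) {
    nest_xy <- as.matrix(nest_xy)
    built <- match("built up", classes)
    for (r in seq_len(nrow(nest_xy))) {
      cell <- cell_index_cpp(nest_xy[r, 1], nest_xy[r, 2], xb, yb)
      if (is.na(cell)) stop("nest site outside the landscape extent")
      cls[cell] <- built
    }
  }
  fields$class <- classes[cls]
  fields <- fields[, c("id", "class", "xmin", "ymin", "xmax", "ymax", "area_m2")]

  ## edges: every grid line (all polygon borders); roads: a seeded subset of
  ## interior lines
  vseg <- tibble::tibble(x0 = xb, y0 = 0, x1 = xb, y1 = extent_m)
  hseg <- tibble::tibble(x0 = 0, y0 = yb, x1 = extent_m, y1 = yb)
  edges <- rbind(vseg, hseg)
  n_rv <- min(ceiling(n_roads / 2), nx - 1)
  n_rh <- min(floor(n_roads / 2), ny - 1)
  road_x <- sample(xb[2:nx], n_rv)
  road_y <- sample(yb[2:ny], n_rh)
  roads <- rbind(
    tibble::tibble(x0 = road_x, y0 = 0, x1 = road_x, y1 = extent_m),
    tibble::tibble(x0 = 0, y0 = road_y, x1 = extent_m, y1 = road_y)
  )

  structure(list(fields = fields, xb = xb, yb = yb, cell_class = cls,
                 roads = roads, edges = edges,
                 extent = c(0, extent_m), classes = classes),
            class = "landcover_map")
}

#' @exportS3Method base::print
print.landcover_map <- function(x, ...) {
  cat("<landcover_map> ", nrow(x$fields), " fields over ",
      diff(x$extent) / 1000, " x ", diff(x$extent) / 1000, " km\n", sep = "")
  tab <- tapply(x$fields$area_m2, x$fields$class, sum)
  prop <- round(tab / sum(tab), 3)
  for (k in names(sort(prop, decreasing = TRUE))) {
    cat(sprintf("  %-13s %5.1f%%\n", k, 100 * prop[[k]]))
  }
  invisible(x)
}

## Land-cover class of each point, NA_character_ outside the extent.
landcover_at <- function(map, x, y) {
  idx <- cell_index_cpp(as.numeric(x), as.numeric(y), map$xb, map$yb)
  out <- rep(NA_character_, length(x))
  ok <- !is.na(idx)
  out[ok] <- map$classes[map$cell_class[idx[ok]]]
  out
}
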