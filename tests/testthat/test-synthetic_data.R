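test_that("landscape generation honours the class mix and is deterministic", {
  m1 <- generate_landscape(seed = 5, extent_m = 2000, n_fields = 200)
  m2 <- generate_landscape(seed = 5, extent_m = 2000, n_fields = 200)
  expect_identical(m1, m2)

  ## areal proportions track a two-class mix within +-5%
  mix <- c(cereal = 0.5, pasture = 0.5)
  m <- generate_landscape(seed = 9, extent_m = 2000, n_fields = 200,
                          class_mix = mix)
  areas <- tapply(m$fields$area_m2, m$fields$class, sum)
  expect_lt(abs(areas[["cereal"]] / sum(areas) - 0.5), 0.05)
  expect_lt(abs(areas[["pasture"]] / sum(areas) - 0.5), 0.05)

  ## a pure mix forces every field to that class
  mono <- generate_landscape(seed = 3, n_fields = 50,
                             class_mix = c(cereal = 1))
  expect_true(all(mono$fields$class == "cereal"))

  ## mosaic tiles the extent: total field area equals the square
  expect_equal(sum(m$fields$area_m2), 2000^2, tolerance = 1e-10)
  expect_error(generate_landscape(seed = 1, n_fields = 3),
               "smaller than the number of classes")

  ## nests are forced into built-up fields
  mn <- generate_landscape(seed = 7, extent_m = 2000, n_fields = 100,
                           nest_xy = rbind(c(500, 500), c(1500, 900)))
  expect_identical(assign_land_cover(
    tibble::tibble(x_m = c(500, 1500), y_m = c(500, 900)), mn)$land_cover,
    c("built up", "built up"))
})

test_that("weather generation matches the requested precipitation rate", {
  nights <- as.Date("2020-06-01") + 0:124   # 125 nights x 8 hours = 1000
  w <- generate_weather(seed = 2, nights, precip_prob = 0.3)
  expect_equal(nrow(w), 1000)
  expect_lt(abs(mean(w$precip) - 0.3), 0.05)
  expect_true(all(w$temp_c >= 8 & w$temp_c <= 20))

  expect_true(all(generate_weather(seed = 1, nights[1:5],
                                   precip_prob = 0)$precip == FALSE))
  expect_equal(nrow(generate_weather(seed = 1, as.Date(character()))), 0)
  expect_identical(generate_weather(seed = 4, nights[1:10]),
                   generate_weather(seed = 4, nights[1:10]))
})

test_that("owl trajectories stay in the window and start/end at the roost", {
  map <- generate_landscape(seed = 11, extent_m = 2000, n_fields = 100,
                            nest_xy = rbind(c(1000, 1000)))
  truth <- synthetic_truth(nest_xy = c(1000, 1000), seed = 21)
  sch <- night_schedule("2020-06-10", 2)
  traj <- simulate_owl_trajectory(truth, map, sch)

  expect_equal(nrow(traj), 2 * 421)   # 1 fix per minute, 21:00-04:00
  tod <- as.numeric(format(traj$timestamp, "%H")) +
    as.numeric(format(traj$timestamp, "%M")) / 60
  expect_true(all(tod >= 21 | tod <= 4))

  d <- nest_distances(traj, truth$nest_xy)
  night_of <- as.Date(format(traj$timestamp, "%Y-%m-%d")) -
    (as.integer(format(traj$timestamp, "%H")) < 12)
  for (nd in unique(night_of)) {
    dn <- d[night_of == nd]
    expect_lte(dn[1], 25)
    expect_lte(dn[length(dn)], 25)
  }

  expect_identical(traj, simulate_owl_trajectory(truth, map, sch))
  expect_error(simulate_owl_trajectory(
    synthetic_truth(nest_xy = c(-50, -50), seed = 1), map, sch),
    "inside the landscape")
})

test_that("with zero selection, thinned class use matches areal availability", {
  ## fine mosaic + 12 owls spread over the extent; fixes thinned to a 10-min
  ## lag before the goodness-of-fit test because consecutive 1-min fixes are
  ## strongly autocorrelated
  set.seed(72)
  ext <- 2500
  nests <- cbind(runif(12, 500, ext - 500), runif(12, 500, ext - 500))
  map <- generate_landscape(seed = 52, extent_m = ext, n_fields = 10000)
  sch <- night_schedule("2020-06-01", 2)
  cls <- character(0)
  for (i in 1:12) {
    truth <- synthetic_truth(nest_xy = nests[i, ], attraction_exponent = 0,
                             seed = 1200 + i)
    traj <- simulate_owl_trajectory(truth, map, sch)
    thin <- traj[seq(1, nrow(traj), by = 10), ]
    cls <- c(cls, assign_land_cover(thin, map)$land_cover)
  }
  obs <- table(factor(cls, levels = landcover_classes()))
  areas <- tapply(map$fields$area_m2,
                  factor(map$fields$class, levels = landcover_classes()), sum)
  chi <- suppressWarnings(chisq.test(as.numeric(obs),
                                     p = as.numeric(areas) / sum(areas)))
  expect_gt(chi$p.value, 0.01)
})

test_that("GPS degradation injects noise, bad fixes and dropout as configured", {
  map <- generate_landscape(seed = 13, extent_m = 2000, n_fields = 100,
                            nest_xy = rbind(c(1000, 1000)))
  sch <- night_schedule("2020-06-10", 12)   # ~5,000 fixes
  base <- synthetic_truth(nest_xy = c(1000, 1000), seed = 31)
  traj <- simulate_owl_trajectory(base, map, sch)

  ## identity when all degradation is off
  clean_truth <- synthetic_truth(nest_xy = c(1000, 1000), noise_sd = 0,
                                 bad_fix_rate = 0, dropout_rate = 0, seed = 31)
  out0 <- degrade_gps(traj, clean_truth)
  expect_equal(out0$x_m, traj$x_m)
  expect_equal(out0$y_m, traj$y_m)
  expect_true(all(out0$nsats >= 4 & out0$hdop <= 5))

  ## flagged-bad fraction ~ bad_fix_rate and noise sd ~ noise_sd
  deg_truth <- synthetic_truth(nest_xy = c(1000, 1000), noise_sd = 3,
                               bad_fix_rate = 0.09, dropout_rate = 0, seed = 31)
  out <- degrade_gps(traj, deg_truth)
  bad_frac <- mean(out$nsats < 4 | out$hdop > 5)
  expect_lt(abs(bad_frac - 0.09), 0.012)
  err <- c(out$x_m - traj$x_m, out$y_m - traj$y_m)
  expect_lt(abs(sd(err) - 3), 0.2)
  expect_lt(abs(mean(err)), 0.1)          # degradation is unbiased

  expect_equal(nrow(degrade_gps(traj[0, ], deg_truth)), 0)
})

test_that("fix, weather, land-cover and truth files round-trip", {
  tmp <- withr::local_tempdir()
  map <- generate_landscape(seed = 17, extent_m = 1500, n_fields = 60,
                            nest_xy = rbind(c(700, 700)))
  truth <- synthetic_truth(nest_xy = c(700, 700),
                           selection = c(pasture = 1.2), seed = 77)
  traj <- simulate_owl_trajectory(truth, map, night_schedule("2020-06-10", 1))
  raw <- degrade_gps(traj, truth)

  f <- file.path(tmp, "fixes.csv")
  write_fixes(raw, f)
  back <- read_fixes(f)
  expect_equal(back$x_m, raw$x_m)
  expect_equal(back$nsats, raw$nsats)
  expect_equal(format(back$timestamp, "%H:%M:%S"),
               format(raw$timestamp, "%H:%M:%S"))

  w <- generate_weather(seed = 3, as.Date("2020-06-10") + 0:2)
  fw <- file.path(tmp, "weather.csv")
  write_weather(w, fw)
  expect_equal(read_weather(fw), w)

  fg <- file.path(tmp, "landcover.geojson")
  write_landcover_geojson(map, fg)
  map2 <- read_landcover_geojson(fg)
  expect_equal(map2$fields$class, map$fields$class)
  expect_equal(map2$fields$area_m2, map$fields$area_m2, tolerance = 1e-9)
  pts <- tibble::tibble(x_m = runif(50, 0, 1500), y_m = runif(50, 0, 1500))
  expect_identical(assign_land_cover(pts, map2)$land_cover,
                   assign_land_cover(pts, map)$land_cover)

  ft <- file.path(tmp, "truth.json")
  write_truth_json(truth, ft)
  truth2 <- read_truth_json(ft)
  expect_equal(truth2$selection_coefficients, truth$selection_coefficients)
  expect_equal(truth2$seed, truth$seed)
})
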