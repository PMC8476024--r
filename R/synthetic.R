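#' Ground truth for a synthetic owl
#'
#' Bundles every parameter governing one simulated individual: per-class
#' log-selection strengths (reference class "cereal" fixed at 0), movement
#' autocorrelation and step scale, central-place attraction, nest location,
#' and the GPS degradation model. The seed fully determines all downstream
#' output.
#'
#' @param nest_xy Numeric length-2 nest coordinates (m, projected).
#' @param selection Named numeric vector of log-selection strengths for a
#'   subset of [landcover_classes()]; unnamed classes default to 0 and
#'   "cereal" (the reference) must be 0 if supplied.
#' @param turn_correlation Directional autocorrelation in `[0, 1)`; mapped
#'   internally to a von Mises concentration.
#' @param step_scale Mean 1-minute step length in metres.
#' @param attraction_exponent Central-place attraction exponent (>= 0); 0
#'   disables homing bias during the night.
#' @param home_scale_m Distance scale (m) of the central-place attraction.
#' @param noise_sd Isotropic GPS noise standard deviation (m).
#' @param bad_fix_rate Probability a fix is degraded to trigger the quality
#'   filter (nsats < 4 or HDOP > 5).
#' @param dropout_rate Probability a fix is lost entirely.
#' @param seed Integer seed.
#'
#' @return Object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(nest_xy, selection = NULL, turn_correlation = 0.7,
                            step_scale = 20, attraction_exponent = 2,
                            home_scale_m = 800, noise_sd = 3,
                            bad_fix_rate = 0.05, dropout_rate = 0.02,
                            seed = 1L) {
  classes <- landcover_classes()
  beta <- setNames(numeric(length(classes)), classes)
  if (!is.null(selection)) {
    stopifnot(!is.null(names(selection)), all(names(selection) %in% classes))
    if ("cereal" %in% names(selection) && selection[["cereal"]] != 0) {
      stop("the reference class 'cereal' must have selection strength 0")
    }
    beta[names(selection)] <- selection
  }
  stopifnot(length(nest_xy) == 2, all(is.finite(nest_xy)),
            turn_correlation >= 0, turn_correlation < 1,
            step_scale > 0, attraction_exponent >= 0, home_scale_m > 0,
            noise_sd >= 0, bad_fix_rate >= 0, bad_fix_rate <= 1,
            dropout_rate >= 0, dropout_rate <= 1)
  structure(list(selection_coefficients = beta,
                 turn_correlation = turn_correlation,
                 step_scale = step_scale,
                 attraction_exponent = attraction_exponent,
                 home_scale_m = home_scale_m,
                 nest_xy = as.numeric(nest_xy),
                 noise_sd = noise_sd, bad_fix_rate = bad_fix_rate,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Nightly recording schedule
#'
#' One row per night: the window opens at `window[1]` on `night_date` and
#' closes at `window[2]` the next morning. The default 21:00-04:00 window is
#' the main tag programming; 20:00-05:00 matches the first tag batch.
#'
#' @param start_date First night's date (anything `as.Date` accepts).
#' @param n_nights Number of consecutive nights.
#' @param window Character `c(start, end)` clock times, end past midnight.
#' @return Tibble with `night_date`, `start`, `end` (POSIXct, fixed CEST).
#' @export
night_schedule <- function(start_date, n_nights, window = c("21:00", "04:00")) {
  stopifnot(n_nights >= 1)
  d <- as.Date(start_date) + seq_len(n_nights) - 1
  tz <- owl_tz()
  start <- as.POSIXct(paste(d, window[1]), tz = tz)
  end <- as.POSIXct(paste(d + 1, window[2]), tz = tz)
  if (any(end <= start)) stop("window end must fall after the start (next morning)")
  tibble::tibble(night_date = d, start = start, end = end)
}

#' Simulate a habitat-biased central-place owl trajectory
#'
#' One position per minute inside each nightly window. At every step a
#' single candidate displacement is proposed from the correlated-random-walk
#' kernel (von Mises turning, gamma step lengths with mean `step_scale`) and
#' accepted with the Metropolis probability `min(1, exp(beta_new -
#' beta_old))` of the land-cover selection coefficients; on rejection the
#' owl perches in place for that minute. Habitat bias therefore enters
#' through step-level acceptance whose stationary spatial distribution
#' carries the `exp(beta)` tilt over the null walk's availability, while the
#' trajectory keeps its movement autocorrelation; with all coefficients 0
#' the process is exactly a central-place CRW. Central-place behaviour:
#' proposals are re-centred on the nest bearing with probability
#' `min(d / home_scale_m, 1) ^ attraction_exponent`, every night starts at
#' the nest, and steps are forced nest-ward at the end of the night so the
#' owl finishes within 25 m of the nest.
#'
#' @param truth A [synthetic_truth()].
#' @param map A `landcover_map` from [generate_landscape()].
#' @param schedule A [night_schedule()] tibble.
#' @param id Individual identifier stored in the output.
#' @return Tibble `id, timestamp, x_m, y_m` (true positions, no GPS error).
#' @export
simulate_owl_trajectory <- function(truth, map, schedule, id = "owl1") {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(map, "landcover_map"))
  nest <- truth$nest_xy
  if (is.na(landcover_at(map, nest[1], nest[2]))) {
    stop("nest must lie inside the landscape extent")
  }
  kappa <- kappa_from_rho(truth$turn_correlation)
  beta_cell <- truth$selection_coefficients[map$classes[map$cell_class]]
  shape <- 2
  scale_g <- truth$step_scale / shape
  set.seed(truth$seed)
  nights <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    ts <- seq(schedule$start[i], schedule$end[i], by = 60)
    xy <- biased_walk_cpp(length(ts), kappa, truth$attraction_exponent,
                          truth$home_scale_m, shape, scale_g,
                          as.numeric(beta_cell), map$xb, map$yb,
                          nest[1], nest[2], truth$step_scale, 50L)
    nights[[i]] <- tibble::tibble(id = id, timestamp = ts,
                                  x_m = xy[, 1], y_m = xy[, 2])
  }
  do.call(rbind, nights)
}

#' Degrade a true trajectory into a raw GPS fix table
#'
#' Adds isotropic Gaussian position noise, draws nominal quality fields
#' (nsats = 4 + Poisson(2), HDOP log-normal with median 1.5), then with
#' probability `bad_fix_rate` overwrites a fix's quality so it triggers the
#' cleaning filter (nsats < 4 or HDOP > 5, chosen with equal probability),
#' and finally drops fixes independently with probability `dropout_rate`.
#'
#' @param traj Tibble from [simulate_owl_trajectory()].
#' @param truth The matching [synthetic_truth()].
#' @return Tibble `id, timestamp, x_m, y_m, nsats, hdop`.
#' @export
degrade_gps <- function(traj, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- nrow(traj)
  if (n == 0) {
    return(tibble::tibble(id = character(), timestamp = as.POSIXct(character()),
                          x_m = numeric(), y_m = numeric(),
                          nsats = integer(), hdop = numeric()))
  }
  set.seed(child_seed(truth$seed, 9901L))
  out <- traj
  out$x_m <- out$x_m + rnorm(n, 0, truth$noise_sd)
  out$y_m <- out$y_m + rnorm(n, 0, truth$noise_sd)
  out$nsats <- 4L + rpois(n, 2)
  out$hdop <- rlnorm(n, meanlog = log(1.5), sdlog = 0.35)
  bad <- runif(n) < truth$bad_fix_rate
  if (any(bad)) {
    which_sat <- bad & (runif(n) < 0.5)
    which_hdop <- bad & !which_sat
    out$nsats[which_sat] <- sample(0:3, sum(which_sat), replace = TRUE)
    out$hdop[which_hdop] <- 5 + rexp(sum(which_hdop), rate = 0.5)
  }
  keep <- runif(n) >= truth$dropout_rate
  out[keep, , drop = FALSE]
}

#' Generate hourly night-time weather
#'
#' One record per clock hour per night inside the recording window:
#' mean temperature (smooth nightly cooling plus noise, clamped to
#' `temp_range`) and a yes/no precipitation flag drawn independently with
#' probability `precip_prob`.
#'
#' @param seed Integer seed.
#' @param nights Vector of night dates (`Date` or coercible).
#' @param precip_prob Hourly precipitation probability in `[0, 1]`.
#' @param temp_range Numeric `c(min, max)` degrees Celsius.
#' @param window Clock window as in [night_schedule()].
#' @return Tibble `night_date, hour, temp_c, precip`.
#' @export
generate_weather <- function(seed, nights, precip_prob = 0.2,
                             temp_range = c(8, 20),
                             window = c("21:00", "04:00")) {
  stopifnot(precip_prob >= 0, precip_prob <= 1, temp_range[2] >= temp_range[1])
  nights <- as.Date(nights)
  if (length(nights) == 0) {
    return(tibble::tibble(night_date = as.Date(character()), hour = integer(),
                          temp_c = numeric(), precip = logical()))
  }
  h0 <- as.integer(substr(window[1], 1, 2))
  h1 <- as.integer(substr(window[2], 1, 2))
  hours <- c(seq(h0, 23L), seq(0L, h1))
  set.seed(seed)
  recs <- lapply(seq_along(nights), function(i) {
    base <- runif(1, temp_range[1] + 0.6 * diff(temp_range), temp_range[2])
    cool <- cumsum(c(0, runif(length(hours) - 1, 0.1, 0.8)))
    temp <- pmin(pmax(base - cool + rnorm(length(hours), 0, 0.4),
                      temp_range[1]), temp_range[2])
    tibble::tibble(night_date = nights[i], hour = hours,
                   temp_c = round(temp, 1),
                   precip = runif(length(hours)) < precip_prob)
  })
  do.call(rbind, recs)
}
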