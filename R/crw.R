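#' Empirical step-length and turning-angle series of a trajectory
#'
#' Step lengths are consecutive Euclidean distances; headings are the
#' directions of those steps; turning angles are successive heading
#' differences wrapped to `(-pi, pi]`, so there is one fewer turning angle
#' than steps.
#'
#' @param trajectory Tibble with `x_m`, `y_m` (>= 3 fixes).
#' @return List of class `step_series`: `step_lengths_m`,
#'   `turning_angles_rad`, `headings_rad`.
#' @export
empirical_step_stats <- function(trajectory) {
  x <- trajectory$x_m; y <- trajectory$y_m
  if (length(x) < 3) stop("need at least 3 fixes to compute turning angles")
  dx <- diff(x); dy <- diff(y)
  steps <- sqrt(dx^2 + dy^2)
  headings <- atan2(dy, dx)
  turns <- wrap_angle(diff(headings))
  structure(list(step_lengths_m = steps, turning_angles_rad = turns,
                 headings_rad = headings),
            class = "step_series")
}

#' Central-place CRW parameters
#'
#' @param turn_concentration von Mises concentration `kappa >= 0` of the
#'   turning-angle distribution (kappa = 0 is an uncorrelated walk).
#' @param step_pool Observed step lengths (m) resampled with replacement by
#'   the simulator; no parametric fit is made.
#' @param attraction_exponent Nest-ward bias exponent `gamma >= 0`: at
#'   nest distance `d` the heading is redrawn toward the nest with
#'   probability `(d / dmax_m) ^ gamma`.
#' @param dmax_m Maximum observed nest distance (m), the hard movement
#'   boundary of the central place.
#' @param seed Integer seed for the simulation stream.
#' @return Object of class `crw_params`.
#' @export
crw_params <- function(turn_concentration, step_pool, attraction_exponent,
                       dmax_m, seed = 1L) {
  stopifnot(turn_concentration >= 0, is.finite(turn_concentration),
            length(step_pool) >= 1, all(step_pool >= 0),
            attraction_exponent >= 0, dmax_m > 0)
  structure(list(turn_concentration = turn_concentration,
                 step_pool = as.numeric(step_pool),
                 attraction_exponent = attraction_exponent,
                 dmax_m = dmax_m, seed = as.integer(seed)),
            class = "crw_params")
}

#' Simulate a central-place correlated random walk
#'
#' Starts at the nest. Each heading is the previous heading plus a von
#' Mises(0, kappa) turn; with probability `(d/dmax)^gamma` the heading is
#' instead redrawn around the bearing to the nest (concentration
#' `max(kappa, 1)`), giving the smooth movement restriction that grows with
#' nest distance. Step lengths are resampled from the observed pool.
#' Candidate positions beyond `dmax` are rejected and redrawn (up to 50
#' tries, then a nest-ward step is forced), so the walk never leaves the
#' central-place disc.
#'
#' @param params A [crw_params()].
#' @param n_steps Number of positions to return (the first is the nest).
#' @param nest_xy Nest coordinates (m).
#' @return Tibble `x_m, y_m` with exactly `n_steps` rows.
#' @export
simulate_crw <- function(params, n_steps, nest_xy) {
  stopifnot(inherits(params, "crw_params"), n_steps >= 1)
  if (params$dmax_m <= 0) stop("dmax_m must be positive")
  set.seed(params$seed)
  xy <- crw_simulate_cpp(as.integer(n_steps), params$turn_concentration,
                         params$attraction_exponent, params$dmax_m,
                         params$step_pool, nest_xy[1], nest_xy[2], 50L)
  tibble::tibble(x_m = xy[, 1], y_m = xy[, 2])
}

#' Fit CRW parameters to an observed trajectory
#'
#' Grid search over (kappa, gamma) minimising a composite dissimilarity
#' between simulated and observed trajectories, averaged over `n_rep`
#' seeded replicates:
#' `J = KS(nest distances) + KS(step lengths) + (1 - cosine similarity of
#' turning-angle histograms)`. Step lengths are resampled from the observed
#' pool, the maximum observed nest distance sets `dmax`, so the search only
#' has to recover the turning concentration and the nest-ward bias.
#'
#' @param trajectory Tibble with `x_m, y_m` (>= 10 fixes).
#' @param nest_xy Nest coordinates (m).
#' @param kappa_grid,gamma_grid Candidate values searched in the first
#'   (coarse) pass.
#' @param n_rep Seeded simulation replicates per grid point.
#' @param n_sim Steps per fitting simulation (capped at the observed length).
#' @param n_breaks Turning-angle histogram bins over `(-pi, pi]`.
#' @param refine Run a second, local search pass around the coarse optimum
#'   (multiplicative neighbours for kappa, additive for gamma).
#' @param dmax Central-place radius (m) used in the fit. Defaults to the
#'   maximum observed nest distance (the study definition); supply the true
#'   radius in simulation self-consistency checks, where gamma is only
#'   identified jointly with the radius.
#' @param seed Base seed for the replicate streams.
#' @return A [crw_params()] with attributes `objective` (the minimised J)
#'   and `grid` (the full objective table over both passes).
#' @export
fit_crw_params <- function(trajectory, nest_xy,
                           kappa_grid = c(0, 0.5, 1, 2, 4, 8, 16),
                           gamma_grid = c(0, 0.5, 1, 2, 4),
                           n_rep = 5, n_sim = 500, n_breaks = 36,
                           refine = TRUE, dmax = NULL, seed = 1L) {
  if (nrow(trajectory) < 10) stop("need at least 10 fixes to fit CRW parameters")
  obs <- empirical_step_stats(trajectory)
  obs_d <- dist_to_point(trajectory$x_m, trajectory$y_m, nest_xy[1], nest_xy[2])
  if (is.null(dmax)) dmax <- max(obs_d)
  if (dmax <= 0) stop("trajectory never leaves the nest; dmax undefined")
  brk <- seq(-pi, pi, length.out = n_breaks + 1)
  obs_hist <- hist_counts(obs$turning_angles_rad, brk)
  n_sim <- min(n_sim, nrow(trajectory))

  eval_grid <- function(grid, offset) {
    grid$J <- NA_real_
    for (g in seq_len(nrow(grid))) {
      js <- numeric(n_rep)
      for (r in seq_len(n_rep)) {
        p <- crw_params(grid$kappa[g], obs$step_lengths_m, grid$gamma[g],
                        dmax, seed = child_seed(seed, 1000 * (offset + g) + r))
        sim <- simulate_crw(p, n_sim, nest_xy)
        sim_stats <- empirical_step_stats(sim)
        sim_d <- dist_to_point(sim$x_m, sim$y_m, nest_xy[1], nest_xy[2])
        js[r] <- ks_stat(sim_d, obs_d) +
          ks_stat(sim_stats$step_lengths_m, obs$step_lengths_m) +
          (1 - cosine_sim(hist_counts(sim_stats$turning_angles_rad, brk),
                          obs_hist))
      }
      grid$J[g] <- mean(js)
    }
    grid
  }

  grid <- eval_grid(expand.grid(kappa = kappa_grid, gamma = gamma_grid), 0L)
  best <- grid[which.min(grid$J), ]
  if (refine) {
    kb <- best$kappa; gb <- best$gamma
    kloc <- unique(if (kb == 0) c(0, 0.25, 0.5) else kb * c(0.5, 0.75, 1, 1.5))
    gloc <- unique(pmax(0, gb + c(-0.5, -0.25, 0, 0.25, 0.5, 1)))
    local <- expand.grid(kappa = kloc, gamma = gloc)
    ## skip points already evaluated in the coarse pass
    key <- paste(grid$kappa, grid$gamma)
    local <- local[!paste(local$kappa, local$gamma) %in% key, , drop = FALSE]
    if (nrow(local)) {
      local <- eval_grid(local, nrow(grid))
      grid <- rbind(grid, local)
      best <- grid[which.min(grid$J), ]
    }
  }
  out <- crw_params(best$kappa, obs$step_lengths_m, best$gamma,
                    dmax, seed = child_seed(seed, 1L))
  attr(out, "objective") <- best$J
  attr(out, "grid") <- grid
  out
}

hist_counts <- function(x, breaks) {
  x[x <= breaks[1]] <- breaks[1] + 1e-12
  as.numeric(table(cut(x, breaks, include.lowest = TRUE)))
}

#' Generate availability positions for the resource selection function
#'
#' Runs the fitted central-place CRW until it has produced exactly
#' `multiplier` times the number of observed locations, and labels the
#' positions as available (`used = 0`). The study design used 10 random
#' positions per used position.
#'
#' @param trajectory Observed (cleaned) trajectory tibble with `x_m, y_m`
#'   and optionally `id`.
#' @param params A fitted [crw_params()].
#' @param nest_xy Nest coordinates (m).
#' @param multiplier Availability : used ratio (>= 1).
#' @param night_lengths Optional integer vector of per-night fix counts
#'   (summing to `nrow(trajectory)`). When given, `multiplier` replicate
#'   walks are simulated per observed night, each restarting at the nest
#'   with that night's length — matching the nightly start-at-roost
#'   structure of the observed data. Otherwise one walk of
#'   `multiplier * n` steps is run.
#' @return Tibble `id, x_m, y_m, used` with `multiplier * nrow(trajectory)`
#'   rows, all `used = 0`.
#' @export
generate_availability <- function(trajectory, params, nest_xy, multiplier = 10,
                                  night_lengths = NULL) {
  if (multiplier < 1) stop("multiplier must be at least 1")
  n_obs <- nrow(trajectory)
  id <- if ("id" %in% names(trajectory) && n_obs > 0) trajectory$id[1] else NA_character_
  if (is.null(night_lengths)) {
    sim <- simulate_crw(params, as.integer(multiplier * n_obs), nest_xy)
  } else {
    if (sum(night_lengths) != n_obs) {
      stop("night_lengths must sum to the number of observed locations")
    }
    reps <- list()
    k <- 0L
    for (len in night_lengths) {
      for (r in seq_len(multiplier)) {
        k <- k + 1L
        p <- params
        p$seed <- child_seed(params$seed, k)
        reps[[k]] <- simulate_crw(p, as.integer(len), nest_xy)
      }
    }
    sim <- do.call(rbind, reps)
  }
  tibble::tibble(id = id, x_m = sim$x_m, y_m = sim$y_m, used = 0L)
}
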