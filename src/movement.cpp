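#include <Rcpp.h>
using namespace Rcpp;

static inline double dist2d(double dx, double dy) {
  return std::sqrt(dx * dx + dy * dy);
}

// Wrap an angle to (-pi, pi].
static inline double wrap_angle(double a) {
  // manual modulo: keeps the object free of recent libm symbol versions
  a = (a + M_PI) - 2.0 * M_PI * std::floor((a + M_PI) / (2.0 * M_PI));
  double w = a - M_PI;
  if (w <= -M_PI) w = M_PI;  // map -pi to +pi so the interval is half-open
  return w;
}

// von Mises(mu, kappa) draw, Best & Fisher (1979) rejection sampler.
// Uses R's RNG stream so set.seed() on the R side governs determinism.
static double rvonmises(double mu, double kappa) {
  if (kappa < 1e-8) return wrap_angle(R::runif(-M_PI, M_PI) + mu);
  double a = 1.0 + std::sqrt(1.0 + 4.0 * kappa * kappa);
  double b = (a - std::sqrt(2.0 * a)) / (2.0 * kappa);
  double r = (1.0 + b * b) / (2.0 * b);
  for (;;) {
    double u1 = unif_rand(), u2 = unif_rand(), u3 = unif_rand();
    double z = std::cos(M_PI * u1);
    double f = (1.0 + r * z) / (r + z);
    double c = kappa * (r - f);
    if (c * (2.0 - c) - u2 > 0.0 || std::log(c / u2) + 1.0 - c >= 0.0) {
      double theta = (u3 > 0.5 ? 1.0 : -1.0) * std::acos(f);
      return wrap_angle(theta + mu);
    }
  }
}

// [[Rcpp::export]]
NumericVector rvm_cpp(int n, double mu, double kappa) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rvonmises(mu, kappa);
  return out;
}

// Locate the grid cell of (x, y) given sorted break vectors; returns the
// 0-based linear index ix + nx*iy, or -1 when outside the extent. Interior
// boundaries are closed on the low side (cell (b_{i-1}, b_i]) except the
// very first break, matching the first-match scan over rectangles ordered
// row-major from the lower-left corner.
static inline int cell_index(double x, double y,
                             const NumericVector& xb, const NumericVector& yb) {
  int nx = xb.size() - 1, ny = yb.size() - 1;
  if (x < xb[0] || x > xb[nx] || y < yb[0] || y > yb[ny]) return -1;
  int ix = int(std::upper_bound(xb.begin(), xb.end(), x) - xb.begin()) - 1;
  if (ix >= nx) ix = nx - 1;
  if (ix < 0) ix = 0;
  int iy = int(std::upper_bound(yb.begin(), yb.end(), y) - yb.begin()) - 1;
  if (iy >= ny) iy = ny - 1;
  if (iy < 0) iy = 0;
  return ix + nx * iy;
}

// [[Rcpp::export]]
IntegerVector cell_index_cpp(NumericVector x, NumericVector y,
                             NumericVector xb, NumericVector yb) {
  int n = x.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int c = cell_index(x[i], y[i], xb, yb);
    out[i] = (c < 0) ? NA_INTEGER : (c + 1);  // 1-based for R
  }
  return out;
}

// Central-place correlated random walk used to build availability data.
//
// Starts at the nest; heading evolves by von Mises turns with concentration
// kappa; with probability (d/dmax)^gamma the heading is redrawn around the
// nest bearing (concentration max(kappa, 1)); step lengths are resampled
// with replacement from the supplied pool; candidates beyond dmax are
// rejected and redrawn up to max_tries, then a nest-ward step is forced.
// Returns n_steps positions, the first being the nest.
// [[Rcpp::export]]
NumericMatrix crw_simulate_cpp(int n_steps, double kappa, double gamma,
                               double dmax, NumericVector step_pool,
                               double nest_x, double nest_y,
                               int max_tries) {
  NumericMatrix out(n_steps, 2);
  int npool = step_pool.size();
  double kappa_home = std::max(kappa, 1.0);
  double x = nest_x, y = nest_y;
  double heading = R::runif(-M_PI, M_PI);
  out(0, 0) = x; out(0, 1) = y;
  for (int t = 1; t < n_steps; ++t) {
    double d = dist2d(x - nest_x, y - nest_y);
    double base = wrap_angle(heading + rvonmises(0.0, kappa));
    if (gamma > 0.0 && d > 0.0 && dmax > 0.0) {
      double p = std::pow(std::min(d / dmax, 1.0), gamma);
      if (unif_rand() < p) {
        double to_nest = std::atan2(nest_y - y, nest_x - x);
        base = rvonmises(to_nest, kappa_home);
      }
    }
    double h = base, L = step_pool[int(unif_rand() * npool) % npool];
    double cx = x + L * std::cos(h), cy = y + L * std::sin(h);
    int tries = 0;
    while (dist2d(cx - nest_x, cy - nest_y) > dmax && tries < max_tries) {
      h = rvonmises(base, kappa);
      L = step_pool[int(unif_rand() * npool) % npool];
      cx = x + L * std::cos(h);
      cy = y + L * std::sin(h);
      ++tries;
    }
    if (dist2d(cx - nest_x, cy - nest_y) > dmax) {
      // forced nest-ward move
      h = std::atan2(nest_y - y, nest_x - x);
      L = std::min(L, d);
      cx = x + L * std::cos(h);
      cy = y + L * std::sin(h);
    }
    x = cx; y = cy; heading = h;
    out(t, 0) = x; out(t, 1) = y;
  }
  return out;
}

// Habitat-biased central-place walk generating ground-truth owl fixes.
//
// At each 1-minute step one candidate displacement is proposed from the
// CRW kernel (von Mises turn around the current heading, gamma-distributed
// step length) and accepted with the Metropolis probability
// min(1, exp(beta[cand] - beta[current])); on rejection the owl perches in
// place. For zero selection every proposal is accepted and the process is a
// plain central-place CRW; otherwise the stationary spatial distribution
// carries the exp(beta) tilt over that null walk's availability.
// Central-place behaviour: with probability min(d/home_scale, 1)^attraction
// the proposal heading is re-centred on the nest bearing, and near the end
// of the night steps are forced nest-ward so the owl roosts at the nest.
// Proposals falling outside the landscape extent are redrawn (<= max_tries,
// then a forced nest-ward move). Returns n_steps positions starting at the
// nest.
// [[Rcpp::export]]
NumericMatrix biased_walk_cpp(int n_steps, double kappa, double attraction,
                              double home_scale, double step_shape,
                              double step_scale_gamma, NumericVector beta_cell,
                              NumericVector xb, NumericVector yb,
                              double nest_x, double nest_y,
                              double mean_step, int max_tries) {
  NumericMatrix out(n_steps, 2);
  double x = nest_x, y = nest_y;
  double heading = R::runif(-M_PI, M_PI);
  out(0, 0) = x; out(0, 1) = y;
  for (int t = 1; t < n_steps; ++t) {
    double d = dist2d(x - nest_x, y - nest_y);
    int remaining = n_steps - t;  // steps still to be taken, incl. this one
    if (d > 0.7 * mean_step * remaining) {
      // forced return so the night ends at the roost
      double L = std::max(R::rgamma(step_shape, step_scale_gamma), mean_step);
      L = std::min(L, d);
      double h = std::atan2(nest_y - y, nest_x - x);
      x += L * std::cos(h); y += L * std::sin(h);
      heading = h;
      out(t, 0) = x; out(t, 1) = y;
      continue;
    }
    double base = heading;
    if (attraction > 0.0 && d > 0.0) {
      double p = std::pow(std::min(d / home_scale, 1.0), attraction);
      if (unif_rand() < p) base = std::atan2(nest_y - y, nest_x - x);
    }
    // propose one CRW step inside the extent
    double cx = 0.0, cy = 0.0, h = base;
    int cell = -1;
    for (int tries = 0; tries < max_tries && cell < 0; ++tries) {
      h = rvonmises(base, kappa);
      double L = R::rgamma(step_shape, step_scale_gamma);
      cx = x + L * std::cos(h);
      cy = y + L * std::sin(h);
      cell = cell_index(cx, cy, xb, yb);
    }
    if (cell < 0) {
      // all proposals left the extent: forced nest-ward move
      double L = std::min(R::rgamma(step_shape, step_scale_gamma), d);
      h = std::atan2(nest_y - y, nest_x - x);
      x += L * std::cos(h); y += L * std::sin(h);
      heading = h;
      out(t, 0) = x; out(t, 1) = y;
      continue;
    }
    int cur = cell_index(x, y, xb, yb);
    double log_ratio = beta_cell[cell] - (cur < 0 ? 0.0 : beta_cell[cur]);
    if (log_ratio >= 0.0 || unif_rand() < std::exp(log_ratio)) {
      x = cx; y = cy; heading = h;   // accept the step
    } else {
      // perch in place and reverse the heading: with persistent headings a
      // position-only Metropolis rule needs the momentum flip on rejection
      // to preserve the exp(beta)-tilted stationary distribution
      heading = wrap_angle(heading + M_PI);
    }
    out(t, 0) = x; out(t, 1) = y;
  }
  return out;
}
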