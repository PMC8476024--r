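## Internal numeric helpers shared across modules.

## Wrap angles to (-pi, pi].
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi)
  w <- w - pi
  w[w <= -pi] <- pi
  w
}

## Convert a circular correlation rho = E[cos(turn)] in [0, 1) to the von
## Mises concentration kappa with A(kappa) = I1/I0 = rho, using Fisher's
## (1993) piecewise approximation of A^{-1}.
kappa_from_rho <- function(rho) {
  stopifnot(rho >= 0, rho < 1)
  if (rho < 1e-8) return(0)
  if (rho < 0.53) {
    2 * rho + rho^3 + 5 * rho^5 / 6
  } else if (rho < 0.85) {
    -0.4 + 1.39 * rho + 0.43 / (1 - rho)
  } else {
    1 / (rho^3 - 4 * rho^2 + 3 * rho)
  }
}

## Mean resultant length A(kappa) = I1(kappa)/I0(kappa).
rho_from_kappa <- function(kappa) {
  if (kappa < 1e-12) return(0)
  besselI(kappa, 1) / besselI(kappa, 0)
}

## Euclidean distance from points (x, y) to a single point.
dist_to_point <- function(x, y, px, py) sqrt((x - px)^2 + (y - py)^2)

## Two-sample Kolmogorov-Smirnov statistic (sup distance between ECDFs),
## computed directly so ties do not emit warnings inside fitting loops.
ks_stat <- function(a, b) {
  a <- sort(a); b <- sort(b)
  grid <- sort(c(a, b))
  fa <- findInterval(grid, a) / length(a)
  fb <- findInterval(grid, b) / length(b)
  max(abs(fa - fb))
}

## Cosine similarity between two non-negative histograms.
cosine_sim <- function(p, q) {
  np <- sqrt(sum(p^2)); nq <- sqrt(sum(q^2))
  if (np == 0 || nq == 0) return(0)
  sum(p * q) / (np * nq)
}

## Derive a child seed from a base seed, kept inside the 32-bit range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% .Machine$integer.max)
}
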