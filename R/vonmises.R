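# von Mises density, sampling, and concentration ML helpers.
# Angles at the interface are azimuths in degrees; internals use radians.

log_bessel_i0 <- function(kappa) {
  kappa + log(besselI(kappa, 0, expon.scaled = TRUE))
}

# A1(kappa) = I1(kappa) / I0(kappa), the mean resultant length of a
# von Mises distribution with concentration kappa
a1 <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

# inverse of A1 by series/continued-fraction start + Newton refinement
# (maximum-likelihood concentration for resultant length r)
a1_inv <- function(r, kappa_max = 500) {
  vapply(r, function(ri) {
    if (!is.finite(ri) || ri <= 0) return(0)
    if (ri >= 1) return(kappa_max)
    k <- if (ri < 0.53) {
      2 * ri + ri^3 + 5 * ri^5 / 6
    } else if (ri < 0.85) {
      -0.4 + 1.39 * ri + 0.43 / (1 - ri)
    } else {
      1 / (ri^3 - 4 * ri^2 + 3 * ri)
    }
    k <- min(max(k, 1e-8), kappa_max)
    for (it in 1:8) {
      a <- a1(k)
      da <- 1 - a^2 - a / k
      if (!is.finite(da) || da <= 0) break
      knew <- k - (a - ri) / da
      if (!is.finite(knew)) break
      k <- min(max(knew, 1e-8), kappa_max)
    }
    k
  }, numeric(1))
}

#' von Mises density on azimuths
#'
#' Density of the von Mises distribution — the circular analogue of the
#' normal distribution — parameterized by mean direction `mu` (azimuth
#' degrees) and concentration `kappa`. The density is per *radian* on the
#' circle, so it integrates to 1 over any 2*pi interval.
#'
#' @param theta Azimuths in degrees.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration (>= 0); 0 is the circular uniform.
#' @param log Return log density?
#' @return Numeric vector of densities.
#' @export
dvonmises <- function(theta, mu, kappa, log = FALSE) {
  stopifnot(kappa >= 0)
  ld <- kappa * cos((theta - mu) * pi / 180) - log(2 * pi) -
    log_bessel_i0(kappa)
  if (log) ld else exp(ld)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher wrapped-Cauchy envelope rejection sampling. Draws depend on
#' the R random number generator state, so wrap calls in
#' [withr::with_seed()] or `set.seed()` for reproducibility.
#'
#' @param n Number of draws.
#' @param mu Mean direction in azimuth degrees.
#' @param kappa Concentration (>= 0).
#' @return Azimuths in degrees in `[0, 360)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    u1 <- runif(m)
    u2 <- runif(m)
    u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[keep] - 0.5) * acos(f[keep])
    out <- c(out, th)
  }
  az_norm(mu + out[seq_len(n)] * 180 / pi)
}

# closed-form single-component von Mises ML fit
vm_ml <- function(theta, kappa_max = 500) {
  mu <- circular_mean(theta)
  if (is.na(mu)) mu <- 0
  kappa <- a1_inv(resultant_length(theta), kappa_max)
  list(mu = mu, kappa = kappa)
}
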