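#' Normalize angles to azimuth convention
#'
#' Azimuths are measured in degrees clockwise from north and stored in
#' `[0, 360)`. Normalization is idempotent.
#'
#' @param deg Numeric vector of angles in degrees.
#' @return Numeric vector in `[0, 360)`.
#' @examples
#' az_norm(c(-90, 360, 725))
#' @export
az_norm <- function(deg) {
  stopifnot(is.numeric(deg))
  ((deg %% 360) + 360) %% 360
}

#' Absolute angular error between two azimuths
#'
#' The pointing error used throughout the package: the absolute angular
#' difference between a judged direction and the true direction, folded to
#' `[0, 180]` so that wrap-around at north is handled correctly.
#'
#' @param judged,truth Azimuths in degrees (recycled to common length).
#' @return Numeric vector of absolute errors in `[0, 180]` degrees.
#' @examples
#' angular_error(350, 10) # 20, not 340
#' @export
angular_error <- function(judged, truth) {
  d <- abs(az_norm(judged) - az_norm(truth))
  pmin(d, 360 - d)
}

#' Signed smallest rotation from one azimuth to another
#'
#' @param from,to Azimuths in degrees.
#' @return Signed rotation in `(-180, 180]`; positive = clockwise.
#' @export
signed_angle <- function(from, to) {
  d <- az_norm(to - from)
  ifelse(d > 180, d - 360, d)
}

#' Circular mean direction
#'
#' Mean direction of a sample of azimuths, computed from the vector resultant.
#'
#' @param deg Azimuths in degrees.
#' @param w Optional non-negative weights.
#' @return Mean azimuth in `[0, 360)`; `NA` if the resultant is degenerate.
#' @export
circular_mean <- function(deg, w = NULL) {
  rad <- deg * pi / 180
  if (is.null(w)) w <- rep(1, length(rad))
  s <- sum(w * sin(rad))
  c <- sum(w * cos(rad))
  if (sqrt(s^2 + c^2) < 1e-12 * max(sum(w), 1)) {
    return(NA_real_)
  }
  az_norm(atan2(s, c) * 180 / pi)
}

#' Mean resultant length of a circular sample
#'
#' @param deg Azimuths in degrees.
#' @param w Optional non-negative weights.
#' @return Resultant length in `[0, 1]`.
#' @export
resultant_length <- function(deg, w = NULL) {
  rad <- deg * pi / 180
  if (is.null(w)) w <- rep(1, length(rad))
  sqrt(sum(w * sin(rad))^2 + sum(w * cos(rad))^2) / sum(w)
}

# Azimuth of the planar vector (dx east, dy north).
vector_azimuth <- function(dx, dy) {
  az_norm(atan2(dx, dy) * 180 / pi)
}
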