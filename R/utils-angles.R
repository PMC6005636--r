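# Shared angular/thermodynamic helpers. All angles are degrees; the membrane
# normal is +z and in-plane angles increase counterclockwise when the bilayer
# is viewed from the intracellular side.

#' Boltzmann constant in kJ mol^-1 K^-1
#' @keywords internal
.kB <- 0.0083144621

#' Thermal energy kT in kJ/mol
#'
#' @param temperature Temperature in Kelvin (default 310, physiological).
#' @return kT in kJ/mol.
#' @export
kT <- function(temperature = 310) .kB * temperature

#' Reduce angles to \[0, 360)
#' @param x angles in degrees
#' @return wrapped angles
#' @export
wrap_angle <- function(x) x %% 360

#' Signed toroidal difference a - b in (-180, 180]
#' @param a,b angles in degrees
#' @return signed difference
#' @export
ang_diff <- function(a, b = 0) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Toroidal Euclidean distance between points on the (beta, chi) torus
#' @param b1,c1 first point (degrees)
#' @param b2,c2 second point (degrees)
#' @return distance in degrees
#' @export
torus_dist <- function(b1, c1, b2, c2) {
  sqrt(ang_diff(b1, b2)^2 + ang_diff(c1, c2)^2)
}

#' Circular mean of angles
#'
#' Vector-averaging circular mean, reduced to \[0, 360).
#'
#' @param x angles in degrees
#' @param w optional non-negative weights
#' @return mean angle in degrees
#' @export
circular_mean <- function(x, w = NULL) {
  if (length(x) == 0L) stop("circular_mean: empty input")
  r <- x * pi / 180
  if (is.null(w)) w <- rep(1, length(x))
  wrap_angle(atan2(sum(w * sin(r)), sum(w * cos(r))) * 180 / pi)
}

# in-plane angle (degrees) of vectors given by components
.plane_angle <- function(x, y) wrap_angle(atan2(y, x) * 180 / pi)

# minimum-image displacement for a periodic box length L (vectorized)
.min_image <- function(d, L) d - L * round(d / L)

# deterministic per-replicate RNG seed derived from a base seed; kept within
# the 32-bit integer range R requires
.replicate_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(r) * 104729) %% 2147483647)
}
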