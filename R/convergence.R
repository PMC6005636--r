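# Ensemble convergence diagnostics: vigintile (5%-quantile) bands of the
# protomer-protomer interaction energy over time, plateau detection, and
# the dimerized-fraction time course.

#' Vigintile bands of an interaction-energy ensemble
#'
#' At every time point, the 21 five-percent quantile levels (0, 5, ..., 100
#' percent; linear interpolation between order statistics, quantile type 7)
#' of the per-replicate energies, plus the ensemble mean.
#'
#' @param energies either an energy table (data.frame with replicate,
#'   time_us, E_interaction_kJmol) or a matrix (times x replicates) with a
#'   `times` attribute/argument
#' @param times time grid (required for matrix input without attribute)
#' @return a `quantile_bands` data.frame: time, q0 ... q100, mean
#' @export
vigintile_bands <- function(energies, times = NULL) {
  if (is.data.frame(energies)) {
    tt <- sort(unique(energies$time_us))
    reps <- sort(unique(energies$replicate))
    E <- matrix(NA_real_, length(tt), length(reps))
    E[cbind(match(energies$time_us, tt), match(energies$replicate, reps))] <-
      energies$E_interaction_kJmol
    times <- tt
  } else {
    E <- as.matrix(energies)
    if (is.null(times)) times <- attr(energies, "times")
    if (is.null(times)) times <- seq_len(nrow(E))
  }
  if (ncol(E) < 21L)
    stop("vigintile_bands: need at least 21 replicates for vigintiles")
  probs <- seq(0, 1, by = 0.05)
  Q <- t(apply(E, 1, stats::quantile, probs = probs, type = 7, na.rm = TRUE))
  out <- data.frame(time = times, Q, mean = rowMeans(E, na.rm = TRUE))
  names(out) <- c("time", paste0("q", probs * 100), "mean")
  class(out) <- c("quantile_bands", class(out))
  out
}

#' Plateau check on the ensemble-mean energy
#'
#' Least-squares slope of the mean band over the trailing `tail_fraction`
#' of the time course; the ensemble is "leveled" when |slope| is below
#' `slope_tol` (default: 1% of the mean-energy range per tail duration).
#'
#' @param bands a `quantile_bands`
#' @param tail_fraction trailing fraction of time points (default 0.25)
#' @param slope_tol kJ/mol per us; default as above
#' @return list(leveled, slope, slope_tol)
#' @export
plateau_check <- function(bands, tail_fraction = 0.25, slope_tol = NULL) {
  n <- nrow(bands)
  i0 <- max(1L, n - ceiling(n * tail_fraction) + 1L)
  if (n - i0 + 1L < 4L) stop("plateau_check: need >= 4 time points in the tail")
  tail_df <- bands[i0:n, ]
  if (is.null(slope_tol)) {
    rng <- diff(range(bands$mean))
    dur <- max(diff(range(tail_df$time)), .Machine$double.eps)
    slope_tol <- 0.01 * rng / dur
    if (slope_tol == 0) slope_tol <- .Machine$double.eps
  }
  slope <- unname(stats::coef(stats::lm(mean ~ time, data = tail_df))[2])
  if (is.na(slope)) slope <- 0
  list(leveled = abs(slope) < slope_tol, slope = slope, slope_tol = slope_tol)
}

#' Fraction of replicates dimerized at a time point
#'
#' @param frames orientation-frame data.frame (see [orientation_frames()])
#' @param dimer_cutoff nm on the minimum bead distance
#' @param at_time us
#' @return fraction in \[0, 1\]
#' @export
dimer_fraction <- function(frames, dimer_cutoff = 0.6, at_time) {
  tt <- unique(frames$time)
  i <- which.min(abs(tt - at_time))
  if (abs(tt[i] - at_time) > 1e-6)
    stop(sprintf("dimer_fraction: no frames at t = %g us", at_time))
  fr <- frames[abs(frames$time - tt[i]) < 1e-9, ]
  mean(fr$min_bead_distance < dimer_cutoff)
}
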