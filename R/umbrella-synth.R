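# Analytic 1-D potentials and biased (umbrella) sampling from them - the
# ground truth used to validate the WHAM machinery.

#' Analytic reference potential for WHAM testing
#'
#' @param form one of "harmonic_well", "gaussian_well_plus_wall", "flat"
#' @param depth well depth in kJ/mol (ignored for "flat")
#' @param width nm. For the harmonic well the stiffness is chosen so that
#'   U(minimum +/- width) = depth; for the Gaussian well it is the Gaussian
#'   sigma.
#' @param minimum position of the well minimum (nm)
#' @param temperature K
#' @return an `analytic_pmf`
#' @export
analytic_pmf <- function(form = c("harmonic_well", "gaussian_well_plus_wall", "flat"),
                         depth = 60, width = 0.3, minimum = 4.5,
                         temperature = 310) {
  form <- match.arg(form)
  if (form != "flat" && depth <= 0) stop("analytic_pmf: depth must be > 0")
  structure(list(form = form, depth = depth, width = width, minimum = minimum,
                 temperature = temperature),
            class = "analytic_pmf")
}

#' Evaluate an analytic reference potential
#'
#' The free energy is defined up to a constant; the convention here fixes
#' the flat baseline (full separation) to zero.
#'
#' @param truth an `analytic_pmf`
#' @param xi separation values (nm)
#' @return U(xi) in kJ/mol
#' @export
pmf_truth_energy <- function(truth, xi) {
  switch(truth$form,
    flat = rep(0, length(xi)),
    harmonic_well = {
      # parabolic well of the stated depth, rejoining the zero baseline at
      # minimum +/- width
      kappa <- 2 * truth$depth / truth$width^2
      pmin(0.5 * kappa * (xi - truth$minimum)^2 - truth$depth, 0)
    },
    gaussian_well_plus_wall = {
      wall0 <- truth$minimum - 1.5 * truth$width
      -truth$depth * exp(-(xi - truth$minimum)^2 / (2 * truth$width^2)) +
        ifelse(xi < wall0, 0.5 * 800 * (wall0 - xi)^2, 0)
    })
}

#' Draw umbrella-window samples from an analytic potential
#'
#' Metropolis sampling from the biased density
#' p_i(xi) proportional to exp(-\[U(xi) + k/2 (xi - c_i)^2\]/kT), run as one
#' chain per window (vectorized across windows), thinned and burned in.
#' Warns when adjacent windows' sample ranges fail to overlap at the
#' requested force constant.
#'
#' @param truth an `analytic_pmf`
#' @param centers window centers (nm), ascending
#' @param k_bias force constant (kJ/mol/nm^2, > 0); scalar or per-window
#' @param n_samples samples kept per window
#' @param seed RNG seed
#' @param thin Metropolis steps per kept sample
#' @param burn burn-in steps
#' @return list of `umbrella_window`s
#' @export
generate_umbrella_samples <- function(truth, centers, k_bias = 1000,
                                      n_samples = 1000L, seed = 1L,
                                      thin = 4L, burn = 200L) {
  if (is.unsorted(centers)) stop("generate_umbrella_samples: centers must ascend")
  if (any(k_bias <= 0)) stop("generate_umbrella_samples: k_bias must be > 0")
  nw <- length(centers)
  kvec <- rep_len(k_bias, nw)
  kt <- kT(truth$temperature)
  windows <- lapply(seq_len(nw), function(i)
    umbrella_window(centers[i], kvec[i], numeric(0)))
  if (n_samples < 1L) return(windows)
  set.seed(seed)
  x <- centers
  prop_sd <- pmax(sqrt(kt / kvec), 1e-3)
  logp <- function(x) -(pmf_truth_energy(truth, x) + 0.5 * kvec * (x - centers)^2) / kt
  lp <- logp(x)
  keep <- matrix(NA_real_, n_samples, nw)
  ki <- 0L
  total <- burn + n_samples * thin
  for (s in seq_len(total)) {
    xp <- x + stats::rnorm(nw, 0, prop_sd)
    lpp <- logp(xp)
    acc <- log(stats::runif(nw)) < (lpp - lp)
    x[acc] <- xp[acc]; lp[acc] <- lpp[acc]
    if (s > burn && (s - burn) %% thin == 0L) {
      ki <- ki + 1L
      keep[ki, ] <- x
    }
  }
  for (i in seq_len(nw)) {
    windows[[i]]$xi <- keep[, i]
    windows[[i]]$time <- seq_len(n_samples)
  }
  # overlap diagnostics
  for (i in seq_len(nw - 1L)) {
    r1 <- range(windows[[i]]$xi); r2 <- range(windows[[i + 1L]]$xi)
    if (r1[2] < r2[1] || r2[2] < r1[1])
      warning(sprintf(paste0("generate_umbrella_samples: no sample overlap ",
                             "between windows at %.3f and %.3f nm at ",
                             "k = %g kJ/mol/nm^2"),
                      centers[i], centers[i + 1L], kvec[i]))
  }
  windows
}
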