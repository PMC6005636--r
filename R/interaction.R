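# Orientation-dependent pair interaction between two rigid protomers.
# The potential is a set of Gaussian wells on the (beta, chi) torus, each
# multiplied by a smooth distance switching function, plus a weak isotropic
# contact attraction (membrane-mediated) and a harmonic core repulsion.

#' Construct an interaction map
#'
#' Off-diagonal attractors (beta != chi) are stored once; the symmetry
#' partner (chi, beta) that label-swap invariance of a homodimer requires is
#' generated implicitly wherever the potential is evaluated.
#'
#' @param attractors data.frame with columns `beta`, `chi` (deg), `depth`
#'   (kJ/mol, > 0), `width` (deg, Gaussian sigma), `distance_min` (nm, the
#'   COM distance below which the well is fully switched on).
#' @param repulsion_core nm; COM distances below this are harmonically
#'   penalized.
#' @param encounter_distance nm; the attraction is fully switched off beyond
#'   this COM distance.
#' @param nonspecific_depth kJ/mol; orientation-independent contact
#'   attraction standing in for generic membrane-mediated forces.
#' @param repulsion_k kJ/mol/nm^2 for the core repulsion.
#' @param bundle_penalty kJ/mol; soft positive ridge applied in contact when
#'   either protomer faces its partner with the bundle-domain sector of its
#'   surface, emulating the membrane-mediated force that opposes dimer
#'   formation at the bundle surface. Zero disables it.
#' @param bundle_center,bundle_width deg; face angle of the bundle-sector
#'   center and the Gaussian width of the ridge.
#' @return an `interaction_map` object.
#' @export
interaction_map <- function(attractors,
                            repulsion_core = 4.1,
                            encounter_distance = 6.0,
                            nonspecific_depth = 3.0,
                            repulsion_k = 200,
                            bundle_penalty = 8.0,
                            bundle_center = 112.5,
                            bundle_width = 40) {
  attractors <- as.data.frame(attractors)
  need <- c("beta", "chi", "depth", "width", "distance_min")
  if (nrow(attractors) && !all(need %in% names(attractors)))
    stop("interaction_map: attractors need columns ", paste(need, collapse = ", "))
  if (nrow(attractors)) {
    if (any(attractors$depth <= 0)) stop("interaction_map: depths must be > 0")
    if (any(attractors$distance_min < repulsion_core))
      stop("interaction_map: distance_min must be >= repulsion_core")
    attractors$beta <- wrap_angle(attractors$beta)
    attractors$chi <- wrap_angle(attractors$chi)
    # keep each off-diagonal attractor only once
    key <- apply(attractors, 1, function(r) {
      b <- round(as.numeric(r[["beta"]]), 6); c <- round(as.numeric(r[["chi"]]), 6)
      paste(sort(c(b, c)), collapse = "_")
    })
    attractors <- attractors[!duplicated(key), , drop = FALSE]
  }
  structure(list(attractors = attractors,
                 repulsion_core = repulsion_core,
                 encounter_distance = encounter_distance,
                 nonspecific_depth = nonspecific_depth,
                 repulsion_k = repulsion_k,
                 bundle_penalty = bundle_penalty,
                 bundle_center = bundle_center,
                 bundle_width = bundle_width),
            class = "interaction_map")
}

#' Default eight-cluster interaction map
#'
#' Four symmetric (diagonal) and four asymmetric (off-diagonal, each with an
#' implicit symmetry partner) orientation attractors, all placed outside the
#' bundle-domain sector of the default template so that the bundle surface
#' stays out of stable interfaces. Depths (45-55 kJ/mol, i.e. 17-21 kT at
#' 310 K) sit inside the 30-90 kJ/mol range of stable-dimer free-energy
#' profiles and are kept near-equal so that no attractor's capture basin is
#' swallowed by a deeper neighbour; all are deep enough not to leak on the
#' 2 us simulation scale.
#'
#' @return an `interaction_map`
#' @export
default_interaction_map <- function() {
  interaction_map(data.frame(
    beta  = c(220, 320, 270,   5, 215, 215, 265, 315),
    chi   = c(220, 320, 270,   5, 305,   5, 355,   8),
    depth = c( 55,  50,  50,  50,  45,  55,  45,  50),
    width = c( 12,  14,  15,  12,  12,  12,  14,  12),
    distance_min = rep(4.15, 8)
  ))
}

# attractor table with implicit symmetry partners materialized
expand_attractors <- function(imap) {
  a <- imap$attractors
  if (!nrow(a)) return(a)
  off <- abs(ang_diff(a$beta, a$chi)) > 1e-9
  if (any(off)) {
    sw <- a[off, , drop = FALSE]
    tmp <- sw$beta; sw$beta <- sw$chi; sw$chi <- tmp
    a <- rbind(a, sw)
  }
  rownames(a) <- NULL
  a
}

# smoothstep switching: 1 at d <= d0, 0 at d >= d1
.switch_fun <- function(d, d0, d1) {
  t <- pmin(pmax((d - d0) / (d1 - d0), 0), 1)
  1 - t * t * (3 - 2 * t)
}
.switch_deriv <- function(d, d0, d1) {
  t <- pmin(pmax((d - d0) / (d1 - d0), 0), 1)
  (-6 * t + 6 * t * t) / (d1 - d0)
}

#' Interaction energy at given relative coordinates
#'
#' @param imap an `interaction_map`
#' @param beta,chi relative orientation angles (deg), vectorized
#' @param d COM distance (nm), vectorized
#' @return energy in kJ/mol
#' @export
imap_potential <- function(imap, beta, chi, d) {
  n <- max(length(beta), length(chi), length(d))
  beta <- rep_len(beta, n); chi <- rep_len(chi, n); d <- rep_len(d, n)
  U <- numeric(n)
  a <- expand_attractors(imap)
  if (nrow(a)) {
    for (k in seq_len(nrow(a))) {
      db <- ang_diff(beta, a$beta[k]); dc <- ang_diff(chi, a$chi[k])
      g <- exp(-(db^2 + dc^2) / (2 * a$width[k]^2))
      U <- U - a$depth[k] * g * .switch_fun(d, a$distance_min[k], imap$encounter_distance)
    }
  }
  if (imap$nonspecific_depth > 0)
    U <- U - imap$nonspecific_depth *
      .switch_fun(d, imap$repulsion_core, imap$encounter_distance)
  if (!is.null(imap$bundle_penalty) && imap$bundle_penalty > 0) {
    gb <- exp(-ang_diff(beta, imap$bundle_center)^2 / (2 * imap$bundle_width^2))
    gc <- exp(-ang_diff(chi, imap$bundle_center)^2 / (2 * imap$bundle_width^2))
    U <- U + imap$bundle_penalty * (gb + gc) *
      .switch_fun(d, imap$repulsion_core, imap$encounter_distance)
  }
  core <- d < imap$repulsion_core
  if (any(core))
    U[core] <- U[core] + 0.5 * imap$repulsion_k * (imap$repulsion_core - d[core])^2
  U
}

# analytic gradients dU/dbeta, dU/dchi (kJ/mol/deg) and dU/dd (kJ/mol/nm)
imap_gradients <- function(imap, beta, chi, d) {
  n <- max(length(beta), length(chi), length(d))
  beta <- rep_len(beta, n); chi <- rep_len(chi, n); d <- rep_len(d, n)
  gB <- numeric(n); gC <- numeric(n); gD <- numeric(n)
  a <- expand_attractors(imap)
  if (nrow(a)) {
    for (k in seq_len(nrow(a))) {
      db <- ang_diff(beta, a$beta[k]); dc <- ang_diff(chi, a$chi[k])
      g <- exp(-(db^2 + dc^2) / (2 * a$width[k]^2))
      s <- .switch_fun(d, a$distance_min[k], imap$encounter_distance)
      ds <- .switch_deriv(d, a$distance_min[k], imap$encounter_distance)
      gB <- gB + a$depth[k] * g * s * db / a$width[k]^2
      gC <- gC + a$depth[k] * g * s * dc / a$width[k]^2
      gD <- gD - a$depth[k] * g * ds
    }
  }
  if (imap$nonspecific_depth > 0)
    gD <- gD - imap$nonspecific_depth *
      .switch_deriv(d, imap$repulsion_core, imap$encounter_distance)
  if (!is.null(imap$bundle_penalty) && imap$bundle_penalty > 0) {
    db <- ang_diff(beta, imap$bundle_center)
    dc <- ang_diff(chi, imap$bundle_center)
    gb <- exp(-db^2 / (2 * imap$bundle_width^2))
    gc <- exp(-dc^2 / (2 * imap$bundle_width^2))
    s0 <- .switch_fun(d, imap$repulsion_core, imap$encounter_distance)
    ds0 <- .switch_deriv(d, imap$repulsion_core, imap$encounter_distance)
    gB <- gB - imap$bundle_penalty * s0 * gb * db / imap$bundle_width^2
    gC <- gC - imap$bundle_penalty * s0 * gc * dc / imap$bundle_width^2
    gD <- gD + imap$bundle_penalty * (gb + gc) * ds0
  }
  core <- d < imap$repulsion_core
  if (any(core))
    gD[core] <- gD[core] - imap$repulsion_k * (imap$repulsion_core - d[core])
  list(dbeta = gB, dchi = gC, dd = gD)
}

#' @export
print.interaction_map <- function(x, ...) {
  cat("interaction_map:", nrow(x$attractors), "stored attractors",
      sprintf("(core %.2f nm, encounter %.2f nm, nonspecific %.1f kJ/mol)\n",
              x$repulsion_core, x$encounter_distance, x$nonspecific_depth))
  if (nrow(x$attractors)) print(x$attractors)
  invisible(x)
}
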