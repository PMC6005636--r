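# DAFT-like synthetic ensembles: many independent replicates of two rigid
# protomers performing overdamped in-plane Brownian dynamics (translation +
# rotation about the membrane normal) under an orientation-dependent pair
# potential, in a periodic box.

#' Ensemble generator configuration
#'
#' Defaults mirror the reference docking-assay protocol: 512 replicates of
#' 2 us each, started at 8.4 nm COM separation with uniformly random
#' in-plane orientations.
#'
#' @param n_replicates number of independent replicates (>= 1).
#' @param duration trajectory length in us-equivalents.
#' @param timestep integration step (us).
#' @param stride store every `stride`-th step (frame spacing =
#'   `stride * timestep` us; default 0.02 us).
#' @param D_trans translational diffusion coefficient (nm^2/us) per protomer.
#' @param D_rot rotational diffusion coefficient (deg^2/us) per protomer.
#' @param box periodic box lengths (nm, length 2).
#' @param start_com_separation initial COM distance (nm).
#' @param min_start_clearance nm; initial placements with a smaller minimum
#'   bead distance are retried (up to 100 times) with a new orientation.
#' @param temperature K.
#' @param seed integer master seed; replicate r is reproducible from
#'   (seed, r) alone.
#' @return an `ensemble_config`
#' @export
ensemble_config <- function(n_replicates = 512L, duration = 2.0,
                            timestep = 2e-4, stride = 100L,
                            D_trans = 4.0, D_rot = 15000,
                            box = c(18, 18), start_com_separation = 8.4,
                            min_start_clearance = 2.0,
                            temperature = 310, seed = 1L) {
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L)
    stop("ensemble_config: n_replicates must be >= 1")
  if (duration < 0) stop("ensemble_config: duration must be >= 0")
  if (timestep <= 0 || stride < 1L) stop("ensemble_config: bad timestep/stride")
  if (length(box) != 2L || any(box <= 0)) stop("ensemble_config: bad box")
  if (start_com_separation > sqrt(sum((box / 2)^2)))
    stop("ensemble_config: start_com_separation does not fit in the box")
  structure(list(n_replicates = n_replicates, duration = duration,
                 timestep = timestep, stride = as.integer(stride),
                 D_trans = D_trans, D_rot = D_rot, box = box,
                 start_com_separation = start_com_separation,
                 min_start_clearance = min_start_clearance,
                 temperature = temperature, seed = as.integer(seed)),
            class = "ensemble_config")
}

# lab-frame bead coordinates for a pose (x, y, phi in deg)
beads_lab <- function(template, x, y, phi) {
  r <- phi * pi / 180
  cs <- cos(r); sn <- sin(r)
  b <- template$bead_positions
  cbind(x + cs * b[, 1] - sn * b[, 2],
        y + sn * b[, 1] + cs * b[, 2],
        b[, 3])
}

# exact minimum bead-bead distance between two posed protomers (min-image)
min_bead_distance_pose <- function(template, poseA, poseB, box) {
  A <- beads_lab(template, poseA[1], poseA[2], poseA[3])
  B <- beads_lab(template, poseB[1], poseB[2], poseB[3])
  dx <- .min_image(outer(B[, 1], A[, 1], "-"), box[1])
  dy <- .min_image(outer(B[, 2], A[, 2], "-"), box[2])
  dz <- outer(B[, 3], A[, 3], "-")
  sqrt(min(dx * dx + dy * dy + dz * dz))
}

#' Generate a DAFT-like two-protomer ensemble
#'
#' Runs overdamped rigid-body Brownian dynamics for every replicate. Each
#' replicate has its own random-number stream derived from `(seed, r)`, so
#' single replicates are reproducible independently of the ensemble size.
#' Initial relative orientations are uniform on the torus; the initial COM
#' separation is fixed. Placements whose minimum bead distance is <= 2 nm
#' are retried with a new random orientation (at most 100 attempts).
#'
#' @param template a `protomer_template`
#' @param imap an `interaction_map`
#' @param cfg an `ensemble_config`
#' @param membrane optional `membrane_model`, carried through for membrane
#'   analyses (does not act on the protein dynamics).
#' @return a `daft_ensemble`: frame times, per-frame pose/orientation/energy
#'   matrices (frames x replicates) and the inputs used.
#' @export
generate_daft_ensemble <- function(template, imap = default_interaction_map(),
                                   cfg = ensemble_config(), membrane = NULL) {
  stopifnot(inherits(template, "protomer_template"),
            inherits(imap, "interaction_map"),
            inherits(cfg, "ensemble_config"))
  nrep <- cfg$n_replicates
  n_steps <- round(cfg$duration / cfg$timestep)
  store_at <- if (n_steps > 0) seq(0L, n_steps, by = cfg$stride) else 0L
  n_frames <- length(store_at)
  times <- store_at * cfg$timestep
  L <- cfg$box
  kt <- kT(cfg$temperature)
  ct <- cfg$D_trans * cfg$timestep / kt      # mobility * dt (translation)
  cr <- cfg$D_rot * cfg$timestep / kt        # mobility * dt (rotation)
  st <- sqrt(2 * cfg$D_trans * cfg$timestep) # noise amplitudes
  sr <- sqrt(2 * cfg$D_rot * cfg$timestep)
  alpha0 <- .plane_angle(body_reference_vector(template)[1],
                         body_reference_vector(template)[2])

  ## initial placement, one RNG stream per replicate --------------------------
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  states <- vector("list", nrep)
  xA <- rep(L[1] / 2, nrep); yA <- rep(L[2] / 2, nrep)
  phiA <- numeric(nrep); phiB <- numeric(nrep)
  xB <- numeric(nrep); yB <- numeric(nrep)
  clearance <- cfg$min_start_clearance
  clear_bound <- cfg$start_com_separation - 2 * template$max_radius
  for (r in seq_len(nrep)) {
    set.seed(.replicate_seed(cfg$seed, r))
    ok <- FALSE
    for (attempt in seq_len(100L)) {
      pA <- stats::runif(1, 0, 360); pB <- stats::runif(1, 0, 360)
      psi0 <- stats::runif(1, 0, 360)
      bx <- xA[r] + cfg$start_com_separation * cos(psi0 * pi / 180)
      by <- yA[r] + cfg$start_com_separation * sin(psi0 * pi / 180)
      if (clear_bound > clearance ||
          min_bead_distance_pose(template, c(xA[r], yA[r], pA),
                                 c(bx, by, pB), L) > clearance) {
        ok <- TRUE; break
      }
      message(sprintf("replicate %d: overlapping start, retrying (%d)", r, attempt))
    }
    if (!ok) stop(sprintf("replicate %d: no non-overlapping start in 100 attempts", r))
    phiA[r] <- pA; phiB[r] <- pB
    xB[r] <- bx %% L[1]; yB[r] <- by %% L[2]
    states[[r]] <- get(".Random.seed", .GlobalEnv)
  }

  pose <- array(NA_real_, c(n_frames, nrep, 6L),
                dimnames = list(NULL, NULL, c("xA", "yA", "phiA", "xB", "yB", "phiB")))
  beta_m <- matrix(NA_real_, n_frames, nrep)
  chi_m <- matrix(NA_real_, n_frames, nrep)
  dist_m <- matrix(NA_real_, n_frames, nrep)

  rel_state <- function() {
    dx <- .min_image(xB - xA, L[1]); dy <- .min_image(yB - yA, L[2])
    d <- sqrt(dx^2 + dy^2)
    psi <- .plane_angle(dx, dy)
    list(dx = dx, dy = dy, d = d, psi = psi,
         beta = wrap_angle(psi - phiA - alpha0),
         chi = wrap_angle(psi + 180 - phiB - alpha0))
  }
  record <- function(fi) {
    s <- rel_state()
    pose[fi, , ] <<- cbind(xA, yA, phiA, xB, yB, phiB)
    beta_m[fi, ] <<- s$beta; chi_m[fi, ] <<- s$chi; dist_m[fi, ] <<- s$d
  }
  record(1L)

  ## chunked Brownian dynamics ------------------------------------------------
  if (n_steps > 0) {
    chunk <- 500L
    fi <- 1L
    step0 <- 0L
    while (step0 < n_steps) {
      nc <- min(chunk, n_steps - step0)
      noise <- array(NA_real_, c(nc, 6L, nrep))
      for (r in seq_len(nrep)) {
        assign(".Random.seed", states[[r]], .GlobalEnv)
        noise[, , r] <- matrix(stats::rnorm(6L * nc), nc, 6L)
        states[[r]] <- get(".Random.seed", .GlobalEnv)
      }
      for (s in seq_len(nc)) {
        rs <- rel_state()
        g <- imap_gradients(imap, rs$beta, rs$chi, rs$d)
        dpsi <- (g$dbeta + g$dchi) * 180 / pi      # dU/dpsi_rad
        ex <- rs$dx / rs$d; ey <- rs$dy / rs$d
        # force on B (A feels the opposite); grad_B psi = perp(e)/d with
        # perp(e) = (-ey, ex)
        fBx <- -g$dd * ex - dpsi / rs$d * (-ey)
        fBy <- -g$dd * ey - dpsi / rs$d * ( ex)
        nz <- matrix(noise[s, , ], 6L, nrep)
        xA <- (xA + ct * (-fBx) + st * nz[1, ]) %% L[1]
        yA <- (yA + ct * (-fBy) + st * nz[2, ]) %% L[2]
        xB <- (xB + ct * ( fBx) + st * nz[4, ]) %% L[1]
        yB <- (yB + ct * ( fBy) + st * nz[5, ]) %% L[2]
        phiA <- wrap_angle(phiA + cr * g$dbeta + sr * nz[3, ])
        phiB <- wrap_angle(phiB + cr * g$dchi + sr * nz[6, ])
        stepno <- step0 + s
        if (stepno %% cfg$stride == 0L) {
          fi <- fi + 1L
          record(fi)
        }
      }
      step0 <- step0 + nc
    }
  }

  energy <- matrix(imap_potential(imap, as.vector(beta_m), as.vector(chi_m),
                                  as.vector(dist_m)), n_frames, nrep)
  structure(list(template = template, imap = imap, config = cfg,
                 membrane = membrane, times = times, pose = pose,
                 beta = beta_m, chi = chi_m, com_distance = dist_m,
                 energy = energy),
            class = "daft_ensemble")
}

#' @export
print.daft_ensemble <- function(x, ...) {
  cat("daft_ensemble:", x$config$n_replicates, "replicates,",
      length(x$times), "frames over", x$config$duration, "us\n")
  invisible(x)
}

# index of the stored frame closest to a requested time
.frame_index <- function(ens, at_time, tol = NULL) {
  if (is.null(tol)) tol <- ens$config$timestep * ens$config$stride / 2 + 1e-12
  i <- which.min(abs(ens$times - at_time))
  if (abs(ens$times[i] - at_time) > tol)
    stop(sprintf("no stored frame within %.3g us of t = %g us", tol, at_time))
  i
}

#' Per-frame orientation table of an ensemble
#'
#' Builds the `(replicate, time, beta, chi, com_distance, min_bead_distance)`
#' table consumed by the orientation and convergence analyses. The minimum
#' bead-bead distance is computed exactly whenever the protomers could be
#' within `exact_below` nm of each other (i.e. `com_distance - 2 * max_radius
#' < exact_below`); far frames report the rigorous lower bound
#' `com_distance - 2 * max_radius`, which is all any dimer cutoff below
#' `exact_below` can ever query.
#'
#' @param ens a `daft_ensemble`
#' @param times frame times to extract (default: all stored frames)
#' @param exact_below exactness threshold for the bead-distance shortcut (nm)
#' @return data.frame of orientation frames
#' @export
orientation_frames <- function(ens, times = NULL, exact_below = 1.0) {
  stopifnot(inherits(ens, "daft_ensemble"))
  if (is.null(times)) times <- ens$times
  idx <- vapply(times, function(t) .frame_index(ens, t), integer(1))
  tpl <- ens$template
  L <- ens$config$box
  out <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    fi <- idx[j]
    d <- ens$com_distance[fi, ]
    bound <- d - 2 * tpl$max_radius
    mbd <- bound
    near <- which(bound < exact_below)
    for (r in near) {
      mbd[r] <- min_bead_distance_pose(tpl,
        ens$pose[fi, r, c("xA", "yA", "phiA")],
        ens$pose[fi, r, c("xB", "yB", "phiB")], L)
    }
    out[[j]] <- data.frame(replicate = seq_len(ncol(ens$beta)),
                           time = ens$times[fi],
                           beta = ens$beta[fi, ], chi = ens$chi[fi, ],
                           com_distance = d, min_bead_distance = mbd)
  }
  do.call(rbind, out)
}

#' Per-frame interaction-energy table
#'
#' One row per (replicate, frame); the energy is exactly the interaction-map
#' potential evaluated at that frame's (beta, chi, COM distance).
#'
#' @param ens a `daft_ensemble`
#' @return data.frame with columns replicate, time_us, E_interaction_kJmol
#' @export
energy_table <- function(ens) {
  stopifnot(inherits(ens, "daft_ensemble"))
  nf <- length(ens$times); nr <- ncol(ens$energy)
  data.frame(replicate = rep(seq_len(nr), each = nf),
             time_us = rep(ens$times, nr),
             E_interaction_kJmol = as.vector(ens$energy))
}
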