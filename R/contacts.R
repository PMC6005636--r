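# Residue-residue interface contact maps, helix-pairing geometry, interface
# periodicity, and the bundle-domain exclusion screen.

# logical residue-contact matrix (A rows x B cols) for one posed frame;
# returns NULL when the protomers cannot be within the cutoff
.frame_contacts <- function(template, poseA, poseB, box, cutoff) {
  A <- beads_lab(template, poseA[1], poseA[2], poseA[3])
  B <- beads_lab(template, poseB[1], poseB[2], poseB[3])
  dx <- .min_image(outer(A[, 1], B[, 1], "-"), box[1])
  dy <- .min_image(outer(A[, 2], B[, 2], "-"), box[2])
  dz <- outer(A[, 3], B[, 3], "-")
  (dx * dx + dy * dy + dz * dz) < cutoff^2
}

#' Minimum inter-protomer bead distance over a replicate trajectory
#'
#' @param ens a `daft_ensemble` (or a list of bead data.frames with columns
#'   chain, x, y, z — one element per frame — for file-based input)
#' @param replicate replicate index (for ensemble input)
#' @param box periodic box, only needed for data-frame input
#' @param times optional vector of frame times (data-frame input)
#' @return data.frame time, min_distance (nm)
#' @export
min_distance_series <- function(ens, replicate = 1L, box = NULL, times = NULL) {
  if (inherits(ens, "daft_ensemble")) {
    L <- ens$config$box
    md <- vapply(seq_along(ens$times), function(fi) {
      min_bead_distance_pose(ens$template,
                             ens$pose[fi, replicate, c("xA", "yA", "phiA")],
                             ens$pose[fi, replicate, c("xB", "yB", "phiB")], L)
    }, numeric(1))
    return(data.frame(time = ens$times, min_distance = md))
  }
  # list-of-frames path (structures read from files)
  stopifnot(is.list(ens), length(ens) > 0)
  md <- vapply(seq_along(ens), function(fi) {
    df <- ens[[fi]]
    ch <- unique(df$chain[df$chain %in% c("A", "B")])
    if (length(ch) < 2L) stop("min_distance_series: need two protein chains")
    A <- as.matrix(df[df$chain == "A", c("x", "y", "z")])
    B <- as.matrix(df[df$chain == "B", c("x", "y", "z")])
    dx <- outer(A[, 1], B[, 1], "-"); dy <- outer(A[, 2], B[, 2], "-")
    dz <- outer(A[, 3], B[, 3], "-")
    if (!is.null(box)) { dx <- .min_image(dx, box[1]); dy <- .min_image(dy, box[2]) }
    sqrt(min(dx * dx + dy * dy + dz * dz))
  }, numeric(1))
  data.frame(time = if (is.null(times)) seq_along(ens) else times,
             min_distance = md)
}

#' Ensemble residue-residue contact map
#'
#' A residue pair (i on protomer A, j on protomer B) counts once per frame
#' when any bead of i is within `cutoff` of any bead of j. Counts are summed
#' over `n_frames` frames sampled at (approximately) equal spacing within
#' the final `window` us-equivalents of every replicate, and over all
#' replicates; both labelings (i, j) and (j, i) are accumulated, so the
#' ensemble homodimer map is exactly symmetric.
#'
#' @param ens a `daft_ensemble`
#' @param cutoff contact cutoff in nm (default 0.5)
#' @param n_frames frames per replicate (default 5)
#' @param window length of the terminal time window in us (default 0.1,
#'   i.e. the last 100 ns-equivalents)
#' @param replicates optional subset of replicate indices
#' @return a `contact_map`: square count matrix with residue dimnames plus
#'   frame-budget attributes
#' @export
residue_contact_map <- function(ens, cutoff = 0.5, n_frames = 5L,
                                window = 0.1, replicates = NULL) {
  stopifnot(inherits(ens, "daft_ensemble"))
  tpl <- ens$template
  t_end <- max(ens$times)
  if (t_end - window < min(ens$times) - 1e-9)
    stop("residue_contact_map: window extends beyond the trajectory")
  want <- seq(t_end - window, t_end, length.out = n_frames)
  fidx <- unique(vapply(want, function(t) which.min(abs(ens$times - t)), integer(1)))
  if (length(fidx) < n_frames)
    stop(sprintf("residue_contact_map: replicate frames too sparse for %d frames in %g us",
                 n_frames, window))
  res <- tpl$residue_index
  nres <- length(res)
  M <- matrix(0, nres, nres, dimnames = list(res, res))
  L <- ens$config$box
  reps <- if (is.null(replicates)) seq_len(dim(ens$pose)[2]) else replicates
  reach <- 2 * tpl$max_radius + cutoff
  for (r in reps) {
    for (fi in fidx) {
      if (ens$com_distance[fi, r] > reach) next
      cm <- .frame_contacts(tpl, ens$pose[fi, r, c("xA", "yA", "phiA")],
                            ens$pose[fi, r, c("xB", "yB", "phiB")], L, cutoff)
      if (any(cm)) M <- M + cm + t(cm)
    }
  }
  structure(M, class = c("contact_map", "matrix"),
            cutoff = cutoff, n_frames = n_frames, window = window,
            template = tpl)
}

#' Interface composition summary of a contact map
#'
#' @param map a `contact_map`
#' @param template the `protomer_template` (defaults to the one attached to
#'   the map)
#' @return list with `helix_pair_totals` (block sums partitioning the map
#'   total), `per_helix` totals, `bundle_fraction` (fraction of contacts
#'   with a bundle-domain residue on either side) and the interface helix
#'   list (helices with nonzero contacts)
#' @export
interface_summary <- function(map, template = attr(map, "template")) {
  res <- as.integer(rownames(map))
  hx <- unname(template$helix_of_residue[as.character(res)])
  labs <- unique(hx)
  block <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (a in labs) for (b in labs)
    block[a, b] <- sum(map[hx == a, hx == b, drop = FALSE])
  per_helix <- rowSums(block)
  bundle_labs <- names(template$domain_of_helix)[template$domain_of_helix == "bundle"]
  inb <- hx %in% bundle_labs
  total <- sum(map)
  bf <- if (total > 0) sum(map[inb, ] ) / total +
    sum(map[!inb, inb, drop = FALSE]) / total else 0
  list(helix_pair_totals = block,
       per_helix = per_helix,
       bundle_fraction = bf,
       interface_helices = names(per_helix)[per_helix > 0],
       total = total)
}

#' Filter a contact map to its significant sparse contacts
#'
#' Retains residue pairs observed strictly more than `min_count` times,
#' sorted by decreasing count.
#'
#' @param map a `contact_map` (or plain matrix with residue dimnames)
#' @param min_count threshold (default 5; strict inequality)
#' @return data.frame res_i, res_j, count
#' @export
filter_contacts <- function(map, min_count = 5) {
  idx <- which(map > min_count, arr.ind = TRUE)
  out <- data.frame(res_i = as.integer(rownames(map)[idx[, 1]]),
                    res_j = as.integer(colnames(map)[idx[, 2]]),
                    count = map[idx])
  out[order(-out$count, out$res_i, out$res_j), , drop = FALSE]
}

#' Helix-pairing orientation from a contact-map block
#'
#' Fits the principal axis of the above-threshold cells of the submatrix for
#' one helix pair. A positive slope in (i, j) space indicates parallel
#' helix packing, a negative slope antiparallel; isotropic scatter
#' (principal-axis anisotropy below `min_anisotropy`) gives "none".
#'
#' @param map a `contact_map`
#' @param helix_pair character length 2, e.g. c("TMH9", "TMH9")
#' @param template template with helix residue ranges
#' @param threshold count threshold for cells entering the fit
#' @param min_anisotropy eigenvalue ratio required to call a direction
#' @return list(orientation = "parallel"|"antiparallel"|"none",
#'   extent = strand length in residues)
#' @export
helix_pairing_orientation <- function(map, helix_pair,
                                      template = attr(map, "template"),
                                      threshold = 0, min_anisotropy = 2) {
  ri <- helix_residues(template, helix_pair[1])
  rj <- helix_residues(template, helix_pair[2])
  sub <- map[as.character(ri), as.character(rj), drop = FALSE]
  idx <- which(sub > threshold, arr.ind = TRUE)
  if (nrow(idx) < 3L) return(list(orientation = "none", extent = 0L))
  pts <- cbind(i = idx[, 1], j = idx[, 2])
  cc <- stats::cov(pts)
  eg <- eigen(cc, symmetric = TRUE)
  if (eg$values[1] <= 1e-12 ||
      eg$values[1] / max(eg$values[2], 1e-12) < min_anisotropy)
    return(list(orientation = "none", extent = 0L))
  v <- eg$vectors[, 1]
  ori <- if (v[1] * v[2] > 0) "parallel" else "antiparallel"
  proj <- pts %*% v
  list(orientation = ori, extent = as.integer(round(diff(range(proj)))))
}

#' Dominant interface periodicity along a helix
#'
#' Computes the periodogram of the interfacial-residue indicator along the
#' helix sequence and returns the period (in residues) maximizing spectral
#' power within `period_range`. A coiled-coil-like heptad repeat appears as
#' a period near 3.5.
#'
#' @param contacts sparse contact data.frame from [filter_contacts()]
#' @param helix helix label, e.g. "TMH9"
#' @param template template with helix residue ranges
#' @param period_range residues (default c(3, 4.5))
#' @return list(period, power, flagged, indicator); `flagged` is TRUE when
#'   there are < 6 interfacial residues or the indicator carries no contrast
#' @export
interface_periodicity <- function(contacts, helix, template,
                                  period_range = c(3, 4.5)) {
  res <- helix_residues(template, helix)
  inter <- res %in% unique(c(contacts$res_i, contacts$res_j))
  x <- as.numeric(inter)
  if (sum(inter) < 6L)
    return(list(period = NA_real_, power = NA_real_, flagged = TRUE,
                indicator = x))
  xc <- x - mean(x)
  if (all(abs(xc) < 1e-12))
    return(list(period = NA_real_, power = 0, flagged = TRUE, indicator = x))
  Tgrid <- seq(period_range[1], period_range[2], by = 0.01)
  j <- seq_along(xc)
  P <- vapply(Tgrid, function(Tp) {
    Mod(sum(xc * exp(2i * pi * j / Tp)))^2
  }, numeric(1))
  k <- which.max(P)
  list(period = Tgrid[k], power = P[k], flagged = FALSE, indicator = x)
}

#' Screen an ensemble for bundle-domain-centered dimers
#'
#' A replicate is flagged when, for at least `persistence` consecutive
#' stored contact frames, the fraction of its interfacial residue contacts
#' involving a bundle-domain residue (either protomer) reaches
#' `bundle_fraction_threshold`. First-contact time, separation time and
#' lifetime are reported per replicate.
#'
#' @param ens a `daft_ensemble`
#' @param template template (defaults to the ensemble's)
#' @param bundle_fraction_threshold fraction in \[0, 1\] (default 0.5)
#' @param persistence consecutive stored frames required (default 2)
#' @param cutoff contact cutoff in nm
#' @return a `bundle_screen_result`: per-replicate data.frame plus `count`
#'   and `percentage` attributes
#' @export
bundle_screen <- function(ens, template = ens$template,
                          bundle_fraction_threshold = 0.5, persistence = 2L,
                          cutoff = 0.5) {
  stopifnot(inherits(ens, "daft_ensemble"))
  nrep <- dim(ens$pose)[2]
  L <- ens$config$box
  reach <- 2 * template$max_radius + cutoff
  bundle_res <- domain_residues(template, "bundle")
  res <- template$residue_index
  inb <- res %in% bundle_res
  out <- data.frame(replicate = seq_len(nrep), flagged = FALSE,
                    first_contact = NA_real_, separation = NA_real_,
                    lifetime = NA_real_)
  for (r in seq_len(nrep)) {
    run <- 0L; flagged <- FALSE
    first_contact <- NA_real_; separation <- NA_real_
    in_contact_prev <- FALSE
    for (fi in seq_along(ens$times)) {
      contact <- FALSE; bf <- 0
      if (ens$com_distance[fi, r] <= reach) {
        cm <- .frame_contacts(template, ens$pose[fi, r, c("xA", "yA", "phiA")],
                              ens$pose[fi, r, c("xB", "yB", "phiB")], L, cutoff)
        ncon <- sum(cm)
        if (ncon > 0) {
          contact <- TRUE
          nb <- sum(cm[inb, ]) + sum(cm[!inb, inb, drop = FALSE])
          bf <- nb / ncon
        }
      }
      if (contact) {
        if (!flagged && is.na(first_contact)) first_contact <- ens$times[fi]
        run <- if (bf >= bundle_fraction_threshold) run + 1L else 0L
        if (run >= persistence) flagged <- TRUE
      } else {
        if (flagged && is.na(separation) && in_contact_prev)
          separation <- ens$times[fi]
        if (!flagged) first_contact <- NA_real_
        run <- 0L
      }
      in_contact_prev <- contact
    }
    if (flagged) {
      if (is.na(separation)) separation <- max(ens$times)
      out$flagged[r] <- TRUE
      out$first_contact[r] <- first_contact
      out$separation[r] <- separation
      out$lifetime[r] <- separation - first_contact
    }
  }
  structure(out, class = c("bundle_screen_result", "data.frame"),
            count = sum(out$flagged),
            percentage = bundle_screen_percentage(sum(out$flagged), nrep))
}

#' Bundle-screen percentage
#'
#' @param count flagged replicates
#' @param n_replicates ensemble size
#' @param digits decimals (default 1, as conventionally reported)
#' @return percentage, rounded
#' @export
bundle_screen_percentage <- function(count, n_replicates, digits = 1) {
  round(100 * count / n_replicates, digits)
}

#' Expected number of random bundle-surface encounters
#'
#' Closed-form expectation n * p * f for `n` replicates, per-replicate
#' encounter probability `p` and bundle angular surface fraction `f`.
#' When an attractor-free ensemble is supplied, `p` is estimated from it as
#' the fraction of replicates that ever reach bead contact.
#'
#' @param n_replicates ensemble size
#' @param encounter_probability probability in \[0, 1\] (ignored when
#'   `ensemble` is given)
#' @param angular_fraction bundle fraction of the lateral surface in \[0, 1\]
#' @param ensemble optional attractor-free `daft_ensemble` for a Monte-Carlo
#'   estimate of the encounter probability
#' @param contact_cutoff nm, used with `ensemble`
#' @return expected count
#' @export
expected_random_encounters <- function(n_replicates, encounter_probability,
                                       angular_fraction, ensemble = NULL,
                                       contact_cutoff = 0.6) {
  if (!is.null(ensemble)) {
    fr <- orientation_frames(ensemble)
    hit <- tapply(fr$min_bead_distance < contact_cutoff, fr$replicate, any)
    encounter_probability <- mean(hit)
  }
  if (encounter_probability < 0 || encounter_probability > 1 ||
      angular_fraction < 0 || angular_fraction > 1)
    stop("expected_random_encounters: probability and fraction must be in [0, 1]")
  n_replicates * encounter_probability * angular_fraction
}
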