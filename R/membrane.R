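# Model bilayers, lipid second-rank order parameter, thickness maps,
# annular-shell statistics and the interface thickness-mismatch score.

#' Model membrane description
#'
#' @param lipids_per_leaflet lipids per leaflet (default 180; the reference
#'   systems carried 172-190)
#' @param bulk_thickness head-to-head bilayer thickness (nm; POPC-like 4.0)
#' @param tail_beads_per_lipid tail beads per lipid (>= 3; 4 for a
#'   Martini-like phosphatidylcholine tail)
#' @param bulk_order bulk second-rank tail order parameter
#' @param area_per_lipid nm^2 (POPC-like 0.65); sets the patch size
#' @param protein_thickness_perturbation data.frame(angle, delta) of signed
#'   thickness changes (nm) induced in the annulus facing each protomer
#'   surface sector (angles in the protomer body frame, deg)
#' @param protein_order_perturbation numeric per annular shell (added to the
#'   bulk order parameter in shells 1, 2, ...; zero beyond)
#' @param annulus_radius nm; perturbations decay to zero beyond this
#'   distance from the protein surface
#' @param protein_radius nm footprint radius of one protomer
#' @return a `membrane_model`
#' @export
membrane_model <- function(lipids_per_leaflet = 180L, bulk_thickness = 4.0,
                           tail_beads_per_lipid = 4L, bulk_order = 0.35,
                           area_per_lipid = 0.65,
                           protein_thickness_perturbation =
                             data.frame(angle = c(112.5, 292.5), delta = c(-0.3, 0.2)),
                           protein_order_perturbation = c(0.15, 0.05),
                           annulus_radius = 2.5, protein_radius = 2.0) {
  if (tail_beads_per_lipid < 3L)
    stop("membrane_model: need >= 3 tail beads per lipid")
  structure(list(lipids_per_leaflet = as.integer(lipids_per_leaflet),
                 bulk_thickness = bulk_thickness,
                 tail_beads_per_lipid = as.integer(tail_beads_per_lipid),
                 bulk_order = bulk_order, area_per_lipid = area_per_lipid,
                 protein_thickness_perturbation = protein_thickness_perturbation,
                 protein_order_perturbation = protein_order_perturbation,
                 annulus_radius = annulus_radius,
                 protein_radius = protein_radius),
            class = "membrane_model")
}

# local signed thickness deviation (nm) at in-plane points, given protein
# poses (data.frame x, y, phi)
.thickness_deviation_field <- function(model, x, y, proteins) {
  dev <- numeric(length(x))
  if (is.null(proteins) || !nrow(model$protein_thickness_perturbation)) return(dev)
  sig_r <- model$annulus_radius / 2.5
  sig_a <- 30
  for (p in seq_len(nrow(proteins))) {
    dx <- x - proteins$x[p]; dy <- y - proteins$y[p]
    dist_edge <- pmax(sqrt(dx^2 + dy^2) - model$protein_radius, 0)
    ang <- wrap_angle(.plane_angle(dx, dy) - proteins$phi[p])
    for (s in seq_len(nrow(model$protein_thickness_perturbation))) {
      a0 <- model$protein_thickness_perturbation$angle[s]
      d0 <- model$protein_thickness_perturbation$delta[s]
      dev <- dev + d0 * exp(-dist_edge^2 / (2 * sig_r^2)) *
        exp(-ang_diff(ang, a0)^2 / (2 * sig_a^2))
    }
  }
  dev
}

# local target order parameter at in-plane points
.order_field <- function(model, x, y, proteins) {
  S <- rep(model$bulk_order, length(x))
  if (is.null(proteins) || !length(model$protein_order_perturbation)) return(S)
  shell_w <- 0.5
  for (p in seq_len(nrow(proteins))) {
    dist_edge <- pmax(sqrt((x - proteins$x[p])^2 + (y - proteins$y[p])^2) -
                        model$protein_radius, 0)
    shell <- floor(dist_edge / shell_w) + 1L
    hit <- shell <= length(model$protein_order_perturbation)
    S[hit] <- S[hit] + model$protein_order_perturbation[shell[hit]]
  }
  pmin(pmax(S, -0.5), 1)
}

#' Simulate lipid frames of a model bilayer
#'
#' Places jittered-grid lipids in two mirrored leaflets around z = 0,
#' excluding protein footprints, with headgroup z displaced by half the
#' local thickness deviation and tail bonds tilted so the local target
#' order parameter is met (exactly when `tilt_sd = 0` and no perturbation
#' noise, in expectation otherwise). A fixed uniform tilt can be imposed
#' with `tilt_deg`.
#'
#' @param model a `membrane_model`
#' @param n_frames number of frames
#' @param proteins optional data.frame(x, y, phi) of protomer poses
#' @param seed RNG seed
#' @param tilt_deg optional fixed tail tilt (overrides the order field)
#' @param tilt_sd degrees of frame-to-frame tilt noise (default 0)
#' @param jitter nm of in-plane lipid jitter per frame
#' @return a `lipid_frames` list; each frame is a data.frame with columns
#'   lipid, leaflet, bead (0 = headgroup, 1..n tail), x, y, z
#' @export
simulate_membrane_frames <- function(model, n_frames = 5L, proteins = NULL,
                                     seed = 1L, tilt_deg = NULL, tilt_sd = 0,
                                     jitter = 0.05) {
  set.seed(seed)
  L <- sqrt(model$lipids_per_leaflet * model$area_per_lipid)
  ngrid <- ceiling(sqrt(model$lipids_per_leaflet))
  g <- (seq_len(ngrid) - 0.5) * (L / ngrid)
  xy0 <- expand.grid(x = g, y = g)[seq_len(model$lipids_per_leaflet), ]
  bond <- (model$bulk_thickness / 2 - 0.2) / model$tail_beads_per_lipid
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    per_leaflet <- lapply(c(upper = 1, lower = -1), function(sgn) {
      x <- xy0$x + stats::rnorm(nrow(xy0), 0, jitter)
      y <- xy0$y + stats::rnorm(nrow(xy0), 0, jitter)
      if (!is.null(proteins)) {
        keep <- rep(TRUE, length(x))
        for (p in seq_len(nrow(proteins)))
          keep <- keep & sqrt((x - proteins$x[p])^2 + (y - proteins$y[p])^2) >
            model$protein_radius
        x <- x[keep]; y <- y[keep]
      }
      n <- length(x)
      zhead <- sgn * (model$bulk_thickness / 2 +
                        .thickness_deviation_field(model, x, y, proteins) / 2)
      if (is.null(tilt_deg)) {
        Sloc <- .order_field(model, x, y, proteins)
        # S = (3<cos^2 theta> - 1)/2  =>  cos theta = sqrt((2S+1)/3)
        th <- acos(sqrt(pmin(pmax((2 * Sloc + 1) / 3, 0), 1))) * 180 / pi
      } else th <- rep(tilt_deg, n)
      th <- pmin(pmax(th + stats::rnorm(n, 0, tilt_sd), 0), 90) * pi / 180
      az <- stats::runif(n, 0, 2 * pi)
      ux <- sin(th) * cos(az); uy <- sin(th) * sin(az); uz <- -sgn * cos(th)
      nb <- model$tail_beads_per_lipid
      rows <- lapply(0:nb, function(b) {
        data.frame(lipid = seq_len(n),
                   leaflet = if (sgn > 0) "upper" else "lower",
                   bead = b,
                   x = x + b * bond * ux, y = y + b * bond * uy,
                   z = zhead + b * bond * uz)
      })
      do.call(rbind, rows)
    })
    fr <- do.call(rbind, per_leaflet)
    fr$lipid <- fr$lipid + ifelse(fr$leaflet == "lower", model$lipids_per_leaflet, 0L)
    rownames(fr) <- NULL
    frames[[f]] <- fr
  }
  structure(frames, class = "lipid_frames", box = c(L, L),
            bulk_thickness = model$bulk_thickness)
}

#' Tail-bond angles of a lipid frame
#'
#' @param frame one lipid-frame data.frame
#' @return data.frame lipid, leaflet, x, y (headgroup position), theta (deg,
#'   angle between each successive tail bond and the membrane normal)
#' @export
lipid_bond_angles <- function(frame) {
  frame <- frame[order(frame$lipid, frame$bead), ]
  out <- list()
  for (l in unique(frame$lipid)) {
    lf <- frame[frame$lipid == l, ]
    if (nrow(lf) < 3L) stop("lipid_bond_angles: need >= 2 tail beads per lipid")
    v <- diff(as.matrix(lf[, c("x", "y", "z")]))
    theta <- acos(pmin(pmax(abs(v[, 3]) / sqrt(rowSums(v^2)), -1), 1)) * 180 / pi
    out[[length(out) + 1L]] <- data.frame(lipid = l, leaflet = lf$leaflet[1],
                                          x = lf$x[1], y = lf$y[1],
                                          theta = theta)
  }
  do.call(rbind, out)
}

#' Second-rank lipid order parameter
#'
#' S = (3 <cos^2 theta> - 1) / 2, with the ensemble average taken inside
#' cos^2 over all supplied bond angles. S = 1 for bonds parallel to the
#' membrane normal, -0.5 for bonds in the membrane plane, 0 for isotropic
#' orientations.
#'
#' @param theta bond angles versus the membrane normal, degrees
#' @return S in \[-0.5, 1\]
#' @export
order_parameter <- function(theta) {
  if (!length(theta)) stop("order_parameter: empty angle list")
  (3 * mean(cos(theta * pi / 180)^2) - 1) / 2
}

# shared 2-D binning helper
.grid_index <- function(x, y, origin, cell, nx, ny) {
  ix <- pmin(pmax(floor((x - origin[1]) / cell) + 1L, 1L), nx)
  iy <- pmin(pmax(floor((y - origin[2]) / cell) + 1L, 1L), ny)
  cbind(ix, iy)
}

#' Gridded order-parameter map
#'
#' Bonds are pooled per grid cell by the in-plane headgroup position of
#' their lipid, over the trailing `window` fraction of the frames, and the
#' order parameter is evaluated per cell. Cells without samples are NA
#' (flagged), never zero-filled.
#'
#' @param frames a `lipid_frames` list
#' @param cell grid cell size (nm, default 0.4)
#' @param window trailing fraction of frames averaged (default 0.5)
#' @return an `order_map`: list(S, counts, origin, cell)
#' @export
order_map <- function(frames, cell = 0.4, window = 0.5) {
  use <- frames[seq.int(floor(length(frames) * (1 - window)) + 1L, length(frames))]
  if (!length(use)) stop("order_map: empty frame window")
  ang <- do.call(rbind, lapply(use, lipid_bond_angles))
  box <- attr(frames, "box")
  origin <- c(0, 0)
  nx <- max(1L, ceiling(box[1] / cell)); ny <- max(1L, ceiling(box[2] / cell))
  idx <- .grid_index(ang$x, ang$y, origin, cell, nx, ny)
  Ssum <- matrix(0, nx, ny); cnt <- matrix(0L, nx, ny)
  c2 <- cos(ang$theta * pi / 180)^2
  for (k in seq_len(nrow(ang))) {
    Ssum[idx[k, 1], idx[k, 2]] <- Ssum[idx[k, 1], idx[k, 2]] + c2[k]
    cnt[idx[k, 1], idx[k, 2]] <- cnt[idx[k, 1], idx[k, 2]] + 1L
  }
  S <- ifelse(cnt > 0, (3 * Ssum / pmax(cnt, 1L) - 1) / 2, NA_real_)
  structure(list(S = S, counts = cnt, origin = origin, cell = cell),
            class = "order_map")
}

#' Gridded bilayer thickness map
#'
#' Per cell, the upper-leaflet headgroup surface minus the lower-leaflet
#' surface, each interpolated by inverse-distance weighting within the cell
#' and its 8 neighbours when the cell itself is empty. Cells where a leaflet
#' is absent from the whole neighbourhood stay NA (flagged).
#'
#' @param frames a `lipid_frames` list
#' @param cell nm (default 0.4)
#' @param window trailing fraction of frames (default 0.5)
#' @param bulk reference thickness for the deviation map (default: the
#'   generating model's bulk thickness when attached, else the median cell
#'   thickness)
#' @return a `thickness_map`: list(thickness, deviation, counts, origin,
#'   cell, bulk)
#' @export
thickness_map <- function(frames, cell = 0.4, window = 0.5, bulk = NULL) {
  use <- frames[seq.int(floor(length(frames) * (1 - window)) + 1L, length(frames))]
  if (!length(use)) stop("thickness_map: empty frame window")
  heads <- do.call(rbind, lapply(use, function(f) f[f$bead == 0L, ]))
  box <- attr(frames, "box")
  origin <- c(0, 0)
  nx <- max(1L, ceiling(box[1] / cell)); ny <- max(1L, ceiling(box[2] / cell))
  surf <- function(df) {
    idx <- .grid_index(df$x, df$y, origin, cell, nx, ny)
    zs <- matrix(0, nx, ny); cnt <- matrix(0L, nx, ny)
    for (k in seq_len(nrow(df))) {
      zs[idx[k, 1], idx[k, 2]] <- zs[idx[k, 1], idx[k, 2]] + df$z[k]
      cnt[idx[k, 1], idx[k, 2]] <- cnt[idx[k, 1], idx[k, 2]] + 1L
    }
    zm <- ifelse(cnt > 0, zs / pmax(cnt, 1L), NA_real_)
    # neighbour fill (inverse-distance over the 3x3 neighbourhood)
    filled <- zm
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
      if (!is.na(zm[i, j])) next
      zsum <- 0; wsum <- 0
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || jj < 1 || ii > nx || jj > ny) next
        if (is.na(zm[ii, jj])) next
        w <- 1 / sqrt(di^2 + dj^2)
        zsum <- zsum + w * zm[ii, jj]; wsum <- wsum + w
      }
      if (wsum > 0) filled[i, j] <- zsum / wsum
    }
    list(z = filled, counts = cnt)
  }
  up <- surf(heads[heads$leaflet == "upper", ])
  lo <- surf(heads[heads$leaflet == "lower", ])
  th <- up$z - lo$z
  if (is.null(bulk)) {
    bulk <- attr(frames, "bulk_thickness")
    if (is.null(bulk)) bulk <- stats::median(th, na.rm = TRUE)
  }
  structure(list(thickness = th, deviation = th - bulk,
                 counts = up$counts + lo$counts,
                 origin = origin, cell = cell, bulk = bulk),
            class = "thickness_map")
}

# cell-center coordinates of a gridded map
.map_cell_centers <- function(map) {
  m <- if (!is.null(map$S)) map$S else map$thickness
  nx <- nrow(m); ny <- ncol(m)
  list(x = map$origin[1] + (seq_len(nx) - 0.5) * map$cell,
       y = map$origin[2] + (seq_len(ny) - 0.5) * map$cell)
}

#' Annular-shell averages around a protein footprint
#'
#' Grid cells are partitioned by their distance to the nearest footprint
#' edge into shells of width `shell_width`; per-shell means (of S or of the
#' thickness deviation) are returned with counts. Cells inside a footprint
#' are excluded.
#'
#' @param map an `order_map` or `thickness_map`
#' @param footprint data.frame(x, y, radius) of protomer footprints
#' @param shell_width nm (default 0.5)
#' @param what "auto" (S for order maps, deviation for thickness maps),
#'   "S", "thickness", or "deviation"
#' @return data.frame shell, distance (inner edge), mean, n
#' @export
annular_shells <- function(map, footprint, shell_width = 0.5, what = "auto") {
  vals <- switch(what,
                 auto = if (!is.null(map$S)) map$S else map$deviation,
                 S = map$S, thickness = map$thickness, deviation = map$deviation)
  cc <- .map_cell_centers(map)
  gx <- matrix(cc$x, length(cc$x), length(cc$y))
  gy <- matrix(cc$y, length(cc$x), length(cc$y), byrow = TRUE)
  dmin <- matrix(Inf, nrow(vals), ncol(vals))
  inside <- matrix(FALSE, nrow(vals), ncol(vals))
  for (p in seq_len(nrow(footprint))) {
    d <- sqrt((gx - footprint$x[p])^2 + (gy - footprint$y[p])^2) - footprint$radius[p]
    inside <- inside | d < 0
    dmin <- pmin(dmin, d)
  }
  ok <- !inside & !is.na(vals)
  shell <- floor(dmin[ok] / shell_width) + 1L
  agg <- tapply(vals[ok], shell, mean)
  cnt <- tapply(vals[ok], shell, length)
  data.frame(shell = as.integer(names(agg)),
             distance = (as.integer(names(agg)) - 1L) * shell_width,
             mean = as.numeric(agg), n = as.integer(cnt))
}

#' Thickness-mismatch score across a dimer interface
#'
#' Averages the thickness deviation over the half-annulus of each protomer
#' facing its partner and returns `-(mean_A * mean_B)`: positive when the
#' deviations have opposite signs across the interface (the transient-dimer
#' signature), negative when they match (stable dimers).
#'
#' @param map a `thickness_map`
#' @param com_A,com_B protomer centers, numeric c(x, y)
#' @param r_in,r_out annulus radii around each protomer (nm)
#' @return list(score, mean_A, mean_B); score is NA when a sector is
#'   unsampled
#' @export
interface_mismatch <- function(map, com_A, com_B, r_in = 2.0, r_out = 3.5) {
  cc <- .map_cell_centers(map)
  gx <- matrix(cc$x, length(cc$x), length(cc$y))
  gy <- matrix(cc$y, length(cc$x), length(cc$y), byrow = TRUE)
  u <- c(com_B[1] - com_A[1], com_B[2] - com_A[2])
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) stop("interface_mismatch: coincident protomer centers")
  u <- u / nu
  sector_mean <- function(com, dir) {
    d <- sqrt((gx - com[1])^2 + (gy - com[2])^2)
    facing <- ((gx - com[1]) * dir[1] + (gy - com[2]) * dir[2]) > 0
    sel <- d >= r_in & d <= r_out & facing & !is.na(map$deviation)
    if (!any(sel)) return(NA_real_)
    mean(map$deviation[sel])
  }
  mA <- sector_mean(com_A, u)
  mB <- sector_mean(com_B, -u)
  list(score = if (is.na(mA) || is.na(mB)) NA_real_ else -(mA * mB),
       mean_A = mA, mean_B = mB)
}
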