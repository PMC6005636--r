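# Relative-orientation (beta, chi) coordinates, toroidal density maps,
# cluster detection and symmetry-based convergence measures.
#
# beta: signed CCW angle (viewed from the intracellular side) from protomer
# A's reference vector to the A->B COM direction; chi: same for protomer B
# and the B->A direction. Swapping the protomer labels maps (beta, chi) to
# (chi, beta), which is what makes the orientation plot of a homodimer
# mirror-symmetric about its diagonal at convergence.

#' Lab-frame reference vector of a posed protomer
#'
#' @param template a `protomer_template`
#' @param pose numeric c(x, y, phi) with phi in degrees (CCW, intracellular
#'   view)
#' @return in-plane unit vector (length 2)
#' @export
reference_vector <- function(template, pose) {
  v <- body_reference_vector(template)  # errors when degenerate
  r <- unname(pose[3]) * pi / 180
  unname(c(cos(r) * v[1] - sin(r) * v[2], sin(r) * v[1] + cos(r) * v[2]))
}

#' Relative orientation angles of a two-protomer pose
#'
#' @param template a `protomer_template` (shared by both protomers)
#' @param pose_A,pose_B numeric c(x, y, phi_deg)
#' @param box optional periodic box (length 2, nm) for minimum-image COM
#'   displacement
#' @return named numeric c(beta, chi) in \[0, 360)
#' @export
beta_chi <- function(template, pose_A, pose_B, box = NULL) {
  dx <- pose_B[1] - pose_A[1]; dy <- pose_B[2] - pose_A[2]
  if (!is.null(box)) { dx <- .min_image(dx, box[1]); dy <- .min_image(dy, box[2]) }
  if (sqrt(dx^2 + dy^2) < 1e-9)
    stop("beta_chi: coincident centers of mass, direction undefined")
  vA <- reference_vector(template, pose_A)
  vB <- reference_vector(template, pose_B)
  psiAB <- .plane_angle(dx, dy)
  psiBA <- wrap_angle(psiAB + 180)
  c(beta = as.numeric(wrap_angle(psiAB - .plane_angle(vA[1], vA[2]))),
    chi = as.numeric(wrap_angle(psiBA - .plane_angle(vB[1], vB[2]))))
}

#' Toroidal orientation density at one time slice
#'
#' Bins the (beta, chi) angles of all replicates that are dimeric at the
#' requested time (minimum bead distance below `dimer_cutoff`) on an
#' n x n wrap-around grid, and normalizes cell counts by the uniform
#' expectation to give an enrichment map. Optionally also computes a
#' periodic-Gaussian smoothed density.
#'
#' @param frames orientation-frame data.frame (see [orientation_frames()])
#' @param at_time time slice (us); must match a frame time
#' @param dimer_cutoff nm; inclusion cutoff on the minimum bead distance
#' @param grid_n cells per axis (default 72, i.e. 5 degree cells)
#' @param bandwidth optional smoothing bandwidth in degrees
#' @return an `orientation_density` object
#' @export
orientation_density <- function(frames, at_time, dimer_cutoff = 0.6,
                                grid_n = 72L, bandwidth = NULL) {
  if (dimer_cutoff <= 0) stop("orientation_density: dimer_cutoff must be > 0")
  tt <- unique(frames$time)
  i <- which.min(abs(tt - at_time))
  if (abs(tt[i] - at_time) > 1e-6)
    stop(sprintf("orientation_density: no frames at t = %g us", at_time))
  sel <- frames[abs(frames$time - tt[i]) < 1e-9 &
                  frames$min_bead_distance < dimer_cutoff, , drop = FALSE]
  cell <- 360 / grid_n
  counts <- matrix(0, grid_n, grid_n)
  if (nrow(sel)) {
    ib <- pmin(floor(wrap_angle(sel$beta) / cell) + 1L, grid_n)
    ic <- pmin(floor(wrap_angle(sel$chi) / cell) + 1L, grid_n)
    for (k in seq_len(nrow(sel))) counts[ib[k], ic[k]] <- counts[ib[k], ic[k]] + 1
  }
  total <- sum(counts)
  enrich <- if (total > 0) counts * (grid_n^2 / total) else counts
  smoothed <- NULL
  if (!is.null(bandwidth) && total > 0)
    smoothed <- .smooth_torus(enrich, bandwidth / cell)
  structure(list(grid_n = grid_n, cell = cell,
                 centers = (seq_len(grid_n) - 0.5) * cell,
                 counts = counts, enrichment = enrich, smoothed = smoothed,
                 members = sel, time = tt[i], n_dimers = total,
                 empty = total == 0),
            class = "orientation_density")
}

# periodic Gaussian smoothing of a toroidal grid (sigma in cells)
.smooth_torus <- function(m, sigma_cells) {
  n <- nrow(m)
  rad <- min(max(1L, ceiling(3 * sigma_cells)), floor(n / 2))
  off <- -rad:rad
  w1 <- exp(-off^2 / (2 * sigma_cells^2))
  w <- outer(w1, w1); w <- w / sum(w)
  out <- matrix(0, n, n)
  for (a in seq_along(off)) for (b in seq_along(off)) {
    ia <- ((seq_len(n) - 1 + off[a]) %% n) + 1L
    ib <- ((seq_len(n) - 1 + off[b]) %% n) + 1L
    out <- out + w[a, b] * m[ia, ib]
  }
  out
}

#' @export
print.orientation_density <- function(x, ...) {
  cat(sprintf("orientation_density: %dx%d grid, %d dimer frames at t = %g us%s\n",
              x$grid_n, x$grid_n, x$n_dimers, x$time,
              if (x$empty) " [EMPTY]" else ""))
  invisible(x)
}

#' Detect orientation clusters in a density map
#'
#' Thresholds the (smoothed, if available) enrichment map and labels every
#' above-threshold cell by steepest ascent to its local density maximum
#' under toroidal 8-neighbour adjacency (a watershed-by-ascent, so that
#' nearby peaks connected by an above-threshold bridge are still resolved);
#' maxima closer than `merge_tol` are merged. Each cluster is summarized by
#' the circular mean of its member frames' angles. Clusters on the diagonal
#' (|beta - chi| <= `diag_tol`, toroidally) are classified symmetric; every
#' other cluster is asymmetric and is paired with the cluster whose center
#' is the label-swapped twin within `pair_tol`.
#'
#' @param density an `orientation_density`
#' @param min_enrichment cells below this enrichment are background
#' @param min_population minimum number of member replicates per cluster
#' @param diag_tol,pair_tol degrees
#' @param merge_tol degrees; density maxima closer than this are one peak
#' @return a `cluster_set` data.frame: id, center_beta, center_chi,
#'   population, n_frames, symmetry_class, partner
#' @export
detect_clusters <- function(density, min_enrichment = 2, min_population = 3,
                            diag_tol = 15, pair_tol = 20, merge_tol = 12) {
  stopifnot(inherits(density, "orientation_density"))
  field <- if (!is.null(density$smoothed)) density$smoothed else density$enrichment
  n <- density$grid_n
  above <- field >= min_enrichment
  lab <- matrix(0L, n, n)
  comp <- 0L
  idx_above <- which(above)
  if (length(idx_above)) {
    # steepest-ascent pointer for every above-threshold cell (linear index);
    # ascent is restricted to above-threshold cells
    nxt <- integer(n * n)
    for (idx in idx_above) {
      i <- ((idx - 1L) %% n) + 1L; j <- ((idx - 1L) %/% n) + 1L
      best <- idx; bestv <- field[idx]
      for (di in -1:1) for (dj in -1:1) {
        ii <- ((i - 1L + di) %% n) + 1L; jj <- ((j - 1L + dj) %% n) + 1L
        k <- (jj - 1L) * n + ii
        if (above[k] && field[k] > bestv) { best <- k; bestv <- field[k] }
      }
      nxt[idx] <- best
    }
    # path compression to the fixed point (local maxima map to themselves)
    root <- nxt
    repeat {
      root2 <- root
      root2[idx_above] <- root[root[idx_above]]
      if (identical(root2, root)) break
      root <- root2
    }
    maxima <- unique(root[idx_above])
    # merge maxima closer than merge_tol (single linkage on the torus)
    cell <- density$cell
    mi <- ((maxima - 1L) %% n) + 1L; mj <- ((maxima - 1L) %/% n) + 1L
    mb <- (mi - 0.5) * cell; mc <- (mj - 0.5) * cell
    group <- seq_along(maxima)
    repeat {
      changed <- FALSE
      for (a in seq_along(maxima)) for (b in seq_along(maxima)) {
        if (group[a] != group[b] &&
            torus_dist(mb[a], mc[a], mb[b], mc[b]) <= merge_tol) {
          group[group == group[b]] <- group[a]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    gid <- match(group, unique(group))
    comp <- max(gid)
    lab[idx_above] <- gid[match(root[idx_above], maxima)]
  }
  rows <- list()
  mem <- density$members
  if (comp > 0L && nrow(mem)) {
    cell <- density$cell
    ib <- pmin(floor(wrap_angle(mem$beta) / cell) + 1L, n)
    ic <- pmin(floor(wrap_angle(mem$chi) / cell) + 1L, n)
    mcomp <- lab[cbind(ib, ic)]
    for (k in seq_len(comp)) {
      mk <- mem[mcomp == k, , drop = FALSE]
      if (length(unique(mk$replicate)) < min_population) next
      rows[[length(rows) + 1L]] <- data.frame(
        center_beta = circular_mean(mk$beta),
        center_chi = circular_mean(mk$chi),
        population = length(unique(mk$replicate)),
        n_frames = nrow(mk))
    }
  }
  if (!length(rows)) {
    out <- data.frame(id = integer(0), center_beta = numeric(0),
                      center_chi = numeric(0), population = integer(0),
                      n_frames = integer(0), symmetry_class = character(0),
                      partner = integer(0))
    class(out) <- c("cluster_set", class(out))
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$population), , drop = FALSE]
  out$id <- seq_len(nrow(out))
  out$symmetry_class <- ifelse(
    abs(ang_diff(out$center_beta, out$center_chi)) <= diag_tol,
    "symmetric", "asymmetric")
  out$partner <- NA_integer_
  asym <- which(out$symmetry_class == "asymmetric")
  for (i in asym) {
    if (!is.na(out$partner[i])) next
    d <- torus_dist(out$center_beta[asym], out$center_chi[asym],
                    out$center_chi[i], out$center_beta[i])
    d[asym == i] <- Inf
    j <- asym[which.min(d)]
    if (length(j) && min(d) <= pair_tol && is.na(out$partner[j])) {
      out$partner[i] <- out$id[j]; out$partner[j] <- out$id[i]
    }
  }
  rownames(out) <- NULL
  out <- out[, c("id", "center_beta", "center_chi", "population", "n_frames",
                 "symmetry_class", "partner")]
  class(out) <- c("cluster_set", class(out))
  out
}

#' Count clusters after merging symmetry-related pairs
#'
#' Each asymmetric cluster and its label-swap partner describe the same
#' dimer conformation and are counted once; unpaired clusters count singly.
#'
#' @param clusters a `cluster_set`
#' @return integer cluster count
#' @export
count_merged_clusters <- function(clusters) {
  if (!nrow(clusters)) return(0L)
  n_sym <- sum(clusters$symmetry_class == "symmetric")
  asym <- clusters[clusters$symmetry_class == "asymmetric", , drop = FALSE]
  paired <- sum(!is.na(asym$partner))
  n_sym + as.integer(paired / 2) + sum(is.na(asym$partner))
}

#' Above/below-diagonal symmetry ratio of the asymmetric clusters
#'
#' The number of replicates in off-diagonal clusters above the diagonal
#' (chi > beta, toroidally signed) divided by the number below. At full
#' convergence of a homodimer ensemble the ratio tends to 1.
#'
#' @param clusters a `cluster_set`
#' @return ratio (>= 0); `Inf` with a warning when no members lie below
#' @export
symmetry_ratio <- function(clusters) {
  asym <- clusters[clusters$symmetry_class == "asymmetric", , drop = FALSE]
  if (!nrow(asym)) stop("symmetry_ratio: no off-diagonal clusters")
  side <- sign(ang_diff(asym$center_chi, asym$center_beta))
  n_above <- sum(asym$population[side > 0])
  n_below <- sum(asym$population[side < 0])
  if (n_below == 0) {
    warning("symmetry_ratio: no members below the diagonal; returning Inf")
    return(Inf)
  }
  n_above / n_below
}

#' Assign replicates to detected clusters
#'
#' A replicate that is dimeric at the requested time (minimum bead distance
#' below `dimer_cutoff`) is assigned to the nearest cluster center under the
#' toroidal metric, provided it lies within `angular_radius`; ties break to
#' the lower cluster id. Monomeric replicates stay unassigned.
#'
#' @param clusters a `cluster_set`
#' @param frames orientation-frame data.frame
#' @param at_time time slice (us)
#' @param angular_radius degrees
#' @param dimer_cutoff nm
#' @return data.frame replicate, cluster (NA = unassigned)
#' @export
assign_replicates <- function(clusters, frames, at_time, angular_radius = 20,
                              dimer_cutoff = 0.6) {
  tt <- unique(frames$time)
  i <- which.min(abs(tt - at_time))
  fr <- frames[abs(frames$time - tt[i]) < 1e-9, , drop = FALSE]
  cl <- rep(NA_integer_, nrow(fr))
  if (nrow(clusters)) {
    for (k in seq_len(nrow(fr))) {
      if (fr$min_bead_distance[k] >= dimer_cutoff) next
      d <- torus_dist(clusters$center_beta, clusters$center_chi,
                      fr$beta[k], fr$chi[k])
      ok <- which(d <= angular_radius)
      if (length(ok)) {
        best <- ok[d[ok] == min(d[ok])]
        cl[k] <- clusters$id[min(best)]
      }
    }
  }
  data.frame(replicate = fr$replicate, cluster = cl)
}
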