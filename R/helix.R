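# Ideal alpha-helix construction and per-residue radial directions.
# Used to rationalize the alternating (heptad-like) pattern of interfacial
# residues: consecutive residues of a canonical alpha-helix rotate ~100
# degrees about the helix axis.

# place atom D given positions A, B, C, the C-D bond length, the B-C-D bond
# angle (deg) and the A-B-C-D dihedral (deg) - standard internal-coordinate
# chain extension
.nerf_place <- function(A, B, C, bond, angle, dihedral) {
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal alpha-helix
#'
#' Either from canonical backbone dihedrals (default phi = -57, psi = -47,
#' omega = 180, with standard bond geometry; the C-alpha trace is returned
#' in nm) or from an explicit parametric `residues_per_turn` description.
#' For every residue the unit vector from the helix axis to the residue,
#' projected normal to the axis, is returned together with the successive
#' angular offsets of these radial directions about the axis. Canonical
#' alpha-helical geometry gives a mean successive offset of ~100 degrees.
#'
#' @param n_residues number of residues (>= 4; the axis is undefined below)
#' @param rise_per_residue nm, used only on the parametric path
#'   (default 0.15)
#' @param residues_per_turn if given, build a parametric helix with this
#'   periodicity instead of the dihedral-based backbone
#' @param canonical_dihedrals numeric c(phi, psi) in degrees for the
#'   backbone path
#' @param radius parametric helix radius (nm)
#' @return list with `coords` (C-alpha positions, nm), `axis` (unit vector),
#'   `radial` (n x 3 unit radial directions), `offsets` (n-1 successive
#'   angular offsets about the axis, deg) and `mean_offset` (deg)
#' @export
build_ideal_helix <- function(n_residues, rise_per_residue = 0.15,
                              residues_per_turn = NULL,
                              canonical_dihedrals = c(phi = -57, psi = -47),
                              radius = 0.23) {
  if (n_residues < 4L)
    stop("build_ideal_helix: need n_residues >= 4 (axis undefined)")
  if (!is.null(residues_per_turn)) {
    twist <- 360 / residues_per_turn
    th <- (seq_len(n_residues) - 1) * twist * pi / 180
    ca <- cbind(radius * cos(th), radius * sin(th),
                (seq_len(n_residues) - 1) * rise_per_residue)
  } else {
    # NeRF chain with standard backbone geometry (lengths in Angstrom)
    bl <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329)
    ba <- c(N_CA_C = 111.2, CA_C_N = 116.2, C_N_CA = 121.7)
    phi <- canonical_dihedrals[[1]]; psi <- canonical_dihedrals[[2]]
    atoms <- matrix(NA_real_, 3 * n_residues, 3)
    atoms[1, ] <- c(0, 0, 0)
    atoms[2, ] <- c(bl["N_CA"], 0, 0)
    a <- ba["N_CA_C"] * pi / 180
    atoms[3, ] <- atoms[2, ] + bl["CA_C"] * c(-cos(a), sin(a), 0)
    for (i in 2:n_residues) {
      b <- 3 * (i - 1)
      atoms[b + 1, ] <- .nerf_place(atoms[b - 2, ], atoms[b - 1, ], atoms[b, ],
                                    bl["C_N"], ba["CA_C_N"], psi)
      atoms[b + 2, ] <- .nerf_place(atoms[b - 1, ], atoms[b, ], atoms[b + 1, ],
                                    bl["N_CA"], ba["C_N_CA"], 180)
      atoms[b + 3, ] <- .nerf_place(atoms[b, ], atoms[b + 1, ], atoms[b + 2, ],
                                    bl["CA_C"], ba["N_CA_C"], phi)
    }
    ca <- atoms[seq(2, 3 * n_residues, by = 3), , drop = FALSE] / 10  # A -> nm
  }
  if (!is.null(residues_per_turn)) {
    # the parametric helix axis is +z by construction
    ctr <- c(0, 0, mean(ca[, 3]))
    ax <- c(0, 0, 1)
  } else {
    # axis = first principal component of the C-alpha trace, oriented along
    # the chain
    ctr <- colMeans(ca)
    ax <- svd(sweep(ca, 2, ctr), nu = 0, nv = 1)$v[, 1]
    if (sum(ax * (ca[n_residues, ] - ca[1, ])) < 0) ax <- -ax
  }
  cc <- sweep(ca, 2, ctr)
  proj <- cc %*% ax
  radial <- cc - proj %*% t(ax)
  rn <- sqrt(rowSums(radial^2))
  radial <- radial / rn
  # successive signed rotation of the radial direction about the axis
  offsets <- vapply(seq_len(n_residues - 1L), function(i) {
    u <- radial[i, ]; v <- radial[i + 1L, ]
    cr <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    atan2(sum(cr * ax), sum(u * v)) * 180 / pi
  }, numeric(1))
  list(coords = ca, axis = as.vector(ax), radial = radial,
       offsets = offsets, mean_offset = mean(abs(offsets)))
}
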