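# Protomer bead templates: a coarse, rigid, hDAT-like 12-helix body used by
# the ensemble generator and all downstream analyses. One bead per residue.

#' Build a coarse-grained protomer template
#'
#' Constructs an idealized twelve-helix transporter body: transmembrane
#' helices are placed on two concentric rings so that the bundle domain
#' (TMH1, TMH2, TMH6, TMH7) occupies one contiguous angular sector of the
#' lateral surface, with the large extracellular loop (EL2), EL3, the
#' C-terminal helix and generic loops filling the remaining sequence.
#' The reference vector used by the orientation coordinates points from the
#' protomer axis towards TMH4.
#'
#' With the default arguments the residue numbering runs 44..602, mimicking
#' the modeled construct of a human dopamine-transporter-like protein.
#'
#' @param n_helices number of transmembrane helices (>= 4).
#' @param beads_per_helix beads (residues) per helix (>= 4).
#' @param seed integer seed controlling the small loop-bead jitter.
#' @param bundle_helices integer helix indices forming the bundle domain;
#'   defaults to c(1, 2, 6, 7) when at least 7 helices are present.
#' @param first_residue residue number of the first bead.
#' @return an object of class `protomer_template` with fields
#'   `bead_positions` (n x 3 matrix, nm, body frame), `residue_index`,
#'   `helix_of_residue` (named character vector), `domain_of_helix`,
#'   `refvec_beads` (two bead indices whose in-plane difference defines the
#'   reference vector), plus layout metadata (`helix_angles`, `max_radius`).
#' @export
build_protomer_template <- function(n_helices = 12L, beads_per_helix = 25L,
                                    seed = 1L,
                                    bundle_helices = if (n_helices >= 7L) c(1L, 2L, 6L, 7L) else integer(0),
                                    first_residue = if (n_helices == 12L && beads_per_helix == 25L) 44L else 1L) {
  n_helices <- as.integer(n_helices)
  beads_per_helix <- as.integer(beads_per_helix)
  if (is.na(n_helices) || n_helices < 4L)
    stop("build_protomer_template: n_helices must be >= 4")
  if (is.na(beads_per_helix) || beads_per_helix < 4L)
    stop("build_protomer_template: beads_per_helix must be >= 4")
  if (length(bundle_helices) && any(bundle_helices > n_helices))
    stop("build_protomer_template: bundle helix index exceeds n_helices")
  set.seed(seed)

  helix_labels <- paste0("TMH", seq_len(n_helices))
  ref_helix <- min(4L, n_helices)

  ## angular layout ----------------------------------------------------------
  r_outer <- 1.9
  r_inner <- 0.95
  # bundle helices sit slightly recessed behind the loop rim (EL3), which
  # limits how much of their surface can reach a partner protomer
  r_bundle <- 1.4
  if (n_helices == 12L) {
    # outer ring carries the bundle sector plus the main interface helices;
    # TMH4 sits at 0 deg so the reference vector is +x in the body frame
    outer <- c(4L, 7L, 1L, 2L, 6L, 9L, 11L, 12L)
    inner <- c(3L, 5L, 8L, 10L)
    helix_angle <- numeric(12)
    helix_radius <- numeric(12)
    helix_angle[outer] <- (seq_along(outer) - 1) * 45
    helix_radius[outer] <- r_outer
    helix_radius[outer[outer %in% bundle_helices]] <- r_bundle
    helix_angle[inner] <- c(30, 120, 210, 300)
    helix_radius[inner] <- r_inner
  } else {
    # single ring: bundle helices contiguous, reference helix rotated to 0
    ordering <- unique(c(sort(bundle_helices), setdiff(seq_len(n_helices), bundle_helices)))
    slot <- match(seq_len(n_helices), ordering)
    helix_angle <- wrap_angle((slot - slot[ref_helix]) * 360 / n_helices)
    helix_radius <- rep(r_outer, n_helices)
    helix_radius[bundle_helices] <- r_bundle
  }

  ## sequence layout ---------------------------------------------------------
  # segment table in sequence order: loops between helices; EL2 after TMH3,
  # EL3 after TMH5, C-terminal helix after the last TMH (12-helix default)
  segs <- list()
  default_hdat <- (n_helices == 12L && beads_per_helix == 25L)
  gap_sizes <- NULL
  if (default_hdat) {
    # 12*25 helix + EL2 40 + EL3 20 + CTERM 30 + 9 generic gaps = 559 beads
    gap_sizes <- c(rep(19L, 8L), 17L)
  }
  gi <- 0L
  for (h in seq_len(n_helices)) {
    segs[[length(segs) + 1L]] <- list(label = helix_labels[h], n = beads_per_helix)
    if (h < n_helices) {
      if (n_helices == 12L && h == 3L) {
        segs[[length(segs) + 1L]] <- list(label = "EL2", n = if (default_hdat) 40L else 6L)
      } else if (n_helices == 12L && h == 5L) {
        segs[[length(segs) + 1L]] <- list(label = "EL3", n = if (default_hdat) 20L else 4L)
      } else {
        gi <- gi + 1L
        ng <- if (default_hdat) gap_sizes[gi] else 3L
        segs[[length(segs) + 1L]] <- list(label = "LOOP", n = ng)
      }
    }
  }
  if (n_helices == 12L)
    segs[[length(segs) + 1L]] <- list(label = "CTERM", n = if (default_hdat) 30L else 5L)

  ## bead coordinates --------------------------------------------------------
  z_span <- c(-1.5, 1.5)
  twist <- 100          # deg per residue about the helix axis
  helix_bead_radius <- 0.25
  pos <- list(); res_label <- character(0)
  for (s in segs) {
    lab <- s$label; n <- s$n
    if (grepl("^TMH", lab)) {
      h <- as.integer(sub("TMH", "", lab))
      th <- helix_angle[h] * pi / 180
      ax <- helix_radius[h] * c(cos(th), sin(th))
      z <- seq(z_span[1], z_span[2], length.out = n)
      psi <- (helix_angle[h] + twist * (seq_len(n) - 1)) * pi / 180
      pos[[length(pos) + 1L]] <- cbind(ax[1] + helix_bead_radius * cos(psi),
                                       ax[2] + helix_bead_radius * sin(psi), z)
    } else if (lab == "CTERM") {
      # intracellular amphipathic helix trailing the last TMH
      h_last <- n_helices
      th0 <- helix_angle[h_last] + 15
      th <- (th0 + seq(0, 40, length.out = n)) * pi / 180
      pos[[length(pos) + 1L]] <- cbind(1.6 * cos(th), 1.6 * sin(th),
                                       rep(-1.9, n) + stats::rnorm(n, 0, 0.03))
    } else {
      # loops: placed in a second pass once flanking helices are known
      pos[[length(pos) + 1L]] <- matrix(0, n, 3)
    }
    res_label <- c(res_label, rep(lab, n))
  }
  beads <- do.call(rbind, pos)

  # fill loop coordinates properly: for each loop segment locate flanking TMHs
  seg_labels <- vapply(segs, `[[`, "", "label")
  seg_sizes <- vapply(segs, function(s) as.integer(s$n), integer(1))
  seg_end <- cumsum(seg_sizes)
  seg_start <- seg_end - seg_sizes + 1L
  tm_idx <- grep("^TMH", seg_labels)
  for (si in seq_along(segs)) {
    lab <- seg_labels[si]
    if (lab %in% c("EL2", "EL3", "LOOP")) {
      n <- seg_sizes[si]
      h_before <- as.integer(sub("TMH", "", seg_labels[max(tm_idx[tm_idx < si])]))
      h_after <- as.integer(sub("TMH", "", seg_labels[min(tm_idx[tm_idx > si])]))
      extracellular <- (h_before %% 2L) == 1L   # loops after odd helices are extracellular
      zl <- if (extracellular) 1.75 else -1.75
      rl <- if (lab == "LOOP") 0.8 else 1.5     # EL2/EL3 skirt the outer surface
      a0 <- helix_angle[h_before]; a1 <- a0 + ang_diff(helix_angle[h_after], a0)
      th <- (seq(a0, a1, length.out = n + 2L)[-c(1L, n + 2L)]) * pi / 180
      jit <- matrix(stats::rnorm(3L * n, 0, 0.04), n, 3)
      beads[seg_start[si]:seg_end[si], ] <-
        cbind(rl * cos(th), rl * sin(th), rep(zl, n)) + jit
    }
  }

  n_beads <- nrow(beads)
  residue_index <- seq.int(first_residue, length.out = n_beads)
  helix_of_residue <- stats::setNames(res_label, residue_index)

  domain_of_helix <- stats::setNames(rep("scaffold", n_helices), helix_labels)
  if (length(bundle_helices)) domain_of_helix[helix_labels[bundle_helices]] <- "bundle"
  domain_of_helix <- c(domain_of_helix,
                       EL2 = "other", EL3 = "other", CTERM = "other", LOOP = "other")

  ## reference vector beads: two beads of the reference helix whose twist
  ## phases differ by (close to) 180 deg, so their in-plane difference points
  ## along the reference-helix direction (exactly +x in the 12-helix default)
  ref_seg <- which(seg_labels == paste0("TMH", ref_helix))
  ref_beads_all <- seg_start[ref_seg]:seg_end[ref_seg]
  ph <- (twist * (seq_len(beads_per_helix) - 1)) %% 360
  j_in <- which.min(abs(ang_diff(ph, 180)))
  refvec_beads <- c(ref_beads_all[1L], ref_beads_all[j_in])

  out <- structure(list(
    bead_positions = beads,
    residue_index = residue_index,
    helix_of_residue = helix_of_residue,
    domain_of_helix = domain_of_helix,
    refvec_beads = refvec_beads,
    helix_angles = stats::setNames(helix_angle, helix_labels),
    bundle_helices = helix_labels[bundle_helices],
    max_radius = max(sqrt(beads[, 1]^2 + beads[, 2]^2)),
    seed = seed
  ), class = "protomer_template")
  validate_protomer_template(out)
  out
}

#' Validate a protomer template
#' @param x a `protomer_template`
#' @return `x`, invisibly; errors if an invariant is violated
#' @export
validate_protomer_template <- function(x) {
  stopifnot(inherits(x, "protomer_template"))
  if (nrow(x$bead_positions) != length(x$residue_index))
    stop("template: bead/residue length mismatch")
  if (anyDuplicated(x$residue_index))
    stop("template: duplicated residue indices")
  if (!all(x$helix_of_residue %in% names(x$domain_of_helix)))
    stop("template: residue with unknown helix label")
  v <- body_reference_vector(x)  # errors if degenerate
  invisible(x)
}

#' Body-frame reference vector of a template
#'
#' The in-plane difference between the two `refvec_beads`, normalized.
#' Errors if the in-plane projection is (near) zero.
#'
#' @param template a `protomer_template`
#' @return length-2 unit vector (x, y)
#' @export
body_reference_vector <- function(template) {
  b <- template$bead_positions[template$refvec_beads, 1:2, drop = FALSE]
  v <- unname(b[1, ] - b[2, ])
  nv <- sqrt(sum(v^2))
  if (!is.finite(nv) || nv < 1e-6)
    stop("degenerate reference vector: in-plane norm < 1e-6")
  v / nv
}

#' Residues belonging to a helix or loop label
#' @param template a `protomer_template`
#' @param label e.g. "TMH9", "EL2"
#' @return integer residue numbers
#' @export
helix_residues <- function(template, label) {
  as.integer(names(template$helix_of_residue)[template$helix_of_residue == label])
}

#' Residues belonging to a domain
#' @param template a `protomer_template`
#' @param domain one of "bundle", "scaffold", "other"
#' @return integer residue numbers
#' @export
domain_residues <- function(template, domain) {
  labs <- names(template$domain_of_helix)[template$domain_of_helix == domain]
  as.integer(names(template$helix_of_residue)[template$helix_of_residue %in% labs])
}

#' @export
print.protomer_template <- function(x, ...) {
  cat("protomer_template:", nrow(x$bead_positions), "beads, residues",
      min(x$residue_index), "-", max(x$residue_index), "\n")
  cat("  bundle helices:", paste(x$bundle_helices, collapse = " "), "\n")
  cat("  max radius:", round(x$max_radius, 2), "nm\n")
  invisible(x)
}
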