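# helper: a static ensemble (no diffusion, no noise) with the protomers
# planted at a given separation and orientation
static_ensemble <- function(tpl, sep, beta = 200, chi = 200, n_rep = 1L,
                            duration = 0.1) {
  imap <- interaction_map(data.frame(beta = numeric(0), chi = numeric(0),
                                     depth = numeric(0), width = numeric(0),
                                     distance_min = numeric(0)),
                          nonspecific_depth = 0, repulsion_k = 0,
                          bundle_penalty = 0)
  cfg <- ensemble_config(n_replicates = n_rep, duration = duration,
                         D_trans = 0, D_rot = 0, box = c(18, 18),
                         start_com_separation = sep,
                         min_start_clearance = 0, seed = 4L)
  ens <- generate_daft_ensemble(tpl, imap, cfg)
  # place the pose deterministically at the requested orientation: A at the
  # box center, B due +x, body refvec is +x, so phiA = -beta, phiB = 180-chi
  nf <- length(ens$times)
  for (fi in seq_len(nf)) {
    ens$pose[fi, , ] <- matrix(rep(c(9, 9, wrap_angle(-beta),
                                     9 + sep, 9, wrap_angle(180 - chi)),
                                   each = n_rep), n_rep, 6)
    ens$beta[fi, ] <- beta; ens$chi[fi, ] <- chi; ens$com_distance[fi, ] <- sep
  }
  ens
}

test_that("min_distance_series matches a brute-force scan and flags bad input", {
  ens <- ens_mid()
  ms <- min_distance_series(ens, replicate = 3L)
  expect_equal(ms$time, ens$times)
  # oracle: plain double loop over bead pairs on a few frames
  tpl <- ens$template
  L <- ens$config$box
  for (fi in c(1L, 51L, 101L)) {
    A <- beads_lab(tpl, ens$pose[fi, 3, "xA"], ens$pose[fi, 3, "yA"],
                   ens$pose[fi, 3, "phiA"])
    B <- beads_lab(tpl, ens$pose[fi, 3, "xB"], ens$pose[fi, 3, "yB"],
                   ens$pose[fi, 3, "phiB"])
    best <- Inf
    for (i in seq_len(nrow(A))) {
      dx <- B[, 1] - A[i, 1]; dx <- dx - L[1] * round(dx / L[1])
      dy <- B[, 2] - A[i, 2]; dy <- dy - L[2] * round(dy / L[2])
      dz <- B[, 3] - A[i, 3]
      best <- min(best, sqrt(min(dx^2 + dy^2 + dz^2)))
    }
    expect_equal(ms$min_distance[fi], best, tolerance = 1e-12)
  }
  # duration-0 start at 8.4 nm: constant series, above the 2 nm floor
  ens0 <- generate_daft_ensemble(tpl_small(), default_interaction_map(),
                                 ensemble_config(n_replicates = 1L, duration = 0,
                                                 seed = 3L))
  ms0 <- min_distance_series(ens0, 1L)
  expect_true(all(ms0$min_distance > 2.0))
  # data-frame input: overlapping beads give zero; one chain errors
  fr <- list(data.frame(chain = c("A", "B"), x = c(1, 1), y = c(2, 2),
                        z = c(0, 0)))
  expect_equal(min_distance_series(fr)$min_distance, 0)
  expect_error(min_distance_series(list(data.frame(chain = "A", x = 1, y = 1,
                                                   z = 0))),
               "two protein chains")
})

test_that("contact maps are symmetric, linear in frames, and empty when apart", {
  tpl <- tpl_small()
  # far apart -> all-zero map
  far <- static_ensemble(tpl, sep = 8.4)
  m0 <- residue_contact_map(far, n_frames = 3L, window = 0.06)
  expect_true(all(m0 == 0))
  # touching TMH9-TMH9 (helix at 225 deg): strongest block is TMH9-TMH9
  touch <- static_ensemble(tpl, sep = 4.15, beta = 225, chi = 225)
  m1 <- residue_contact_map(touch, n_frames = 3L, window = 0.06)
  expect_true(sum(m1) > 0)
  expect_identical(unclass(m1)[, ], t(unclass(m1))[, ])  # exact symmetry
  smry <- interface_summary(m1, tpl)
  blocks <- smry$helix_pair_totals
  expect_equal(sum(blocks), smry$total)  # partition property
  best <- which(blocks == max(blocks), arr.ind = TRUE)
  expect_true(any(rownames(blocks)[best[, 1]] == "TMH9" &
                    colnames(blocks)[best[, 2]] == "TMH9"))
  expect_equal(smry$bundle_fraction, 0)
  # doubling the frame budget doubles every count on a static dimer
  m2 <- residue_contact_map(touch, n_frames = 6L, window = 0.1)
  m1b <- residue_contact_map(touch, n_frames = 3L, window = 0.1)
  expect_equal(unclass(m2)[, ] / 2, unclass(m1b)[, ] * 1)
  # window outside the trajectory errors
  expect_error(residue_contact_map(touch, window = 5), "window")
})

test_that("filter_contacts applies a strict threshold and respects symmetry", {
  m <- matrix(0, 4, 4, dimnames = list(101:104, 101:104))
  m[1, 2] <- m[2, 1] <- 6
  m[3, 4] <- m[4, 3] <- 5
  m[1, 4] <- m[4, 1] <- 9
  fc <- filter_contacts(m, min_count = 5)
  expect_equal(nrow(fc), 4L)  # both labelings of the two retained pairs
  expect_true(all(fc$count > 5))
  expect_false(any(fc$count == 5))
  expect_equal(fc$count[1], 9)  # sorted descending
  fct <- filter_contacts(t(m), min_count = 5)
  expect_equal(fct[order(fct$res_i, fct$res_j), c("res_i", "res_j", "count")],
               fc[order(fc$res_i, fc$res_j), c("res_i", "res_j", "count")],
               ignore_attr = TRUE)
  expect_equal(nrow(filter_contacts(m, min_count = 10)), 0L)
})

test_that("helix pairing orientation classifies band geometry", {
  tpl <- tpl_small()
  res9 <- helix_residues(tpl, "TMH9")
  res4 <- helix_residues(tpl, "TMH4")
  m <- matrix(0, 138, 138,
              dimnames = list(tpl$residue_index, tpl$residue_index))
  # parallel band: i = j + const
  for (k in seq_along(res9)) m[as.character(res9[k]), as.character(res4[k])] <- 10
  expect_equal(helix_pairing_orientation(m, c("TMH9", "TMH4"), tpl)$orientation,
               "parallel")
  # antiparallel band: i + j = const
  m2 <- m * 0
  for (k in seq_along(res9))
    m2[as.character(res9[k]), as.character(rev(res4)[k])] <- 10
  expect_equal(helix_pairing_orientation(m2, c("TMH9", "TMH4"), tpl)$orientation,
               "antiparallel")
  # random scatter -> no direction
  set.seed(21)
  m3 <- m * 0
  idx <- cbind(sample(match(res9, tpl$residue_index), 20, TRUE),
               sample(match(res4, tpl$residue_index), 20, TRUE))
  m3[idx] <- 5
  expect_equal(helix_pairing_orientation(m3, c("TMH9", "TMH4"), tpl)$orientation,
               "none")
  # fewer than 3 cells -> none
  m4 <- m * 0; m4[as.character(res9[1]), as.character(res4[1])] <- 10
  expect_equal(helix_pairing_orientation(m4, c("TMH9", "TMH4"), tpl)$orientation,
               "none")
})

test_that("interface periodicity finds heptad-like and planted periods", {
  tpl <- tpl_default()
  res <- helix_residues(tpl, "TMH9")
  # heptad: interfacial residues at alternating spacings 3, 4, 3, 4, ...
  pos <- res[1] + cumsum(c(0, rep(c(3, 4), 4)))
  contacts <- data.frame(res_i = pos, res_j = pos, count = 10)
  p <- interface_periodicity(contacts, "TMH9", tpl)
  expect_false(p$flagged)
  expect_equal(p$period, 3.5, tolerance = 0.06)
  # planted period 4
  pos4 <- res[1] + seq(0, 20, by = 4)
  p4 <- interface_periodicity(data.frame(res_i = pos4, res_j = pos4, count = 1),
                              "TMH9", tpl)
  expect_equal(p4$period, 4.0, tolerance = 0.06)
  # every residue interfacial -> no contrast, flagged
  pall <- interface_periodicity(data.frame(res_i = res, res_j = res, count = 1),
                                "TMH9", tpl)
  expect_true(pall$flagged)
  # too few residues -> flagged
  pf <- interface_periodicity(data.frame(res_i = res[1:3], res_j = res[1:3],
                                         count = 1), "TMH9", tpl)
  expect_true(pf$flagged)
})

test_that("bundle screen flags bundle-centered dimers and is monotone", {
  tpl <- tpl_small()
  # bundle-facing contact: TMH2 sits at 135 deg in the body frame; the
  # bundle ring is recessed, so bundle-bundle contact needs a closer
  # separation than the scaffold contact distance
  bundle_touch <- static_ensemble(tpl, sep = 3.5, beta = 135, chi = 135)
  scr <- bundle_screen(bundle_touch)
  expect_true(scr$flagged[1])
  expect_equal(attr(scr, "count"), 1L)
  expect_gte(scr$lifetime[1], 0)
  # scaffold-facing contact is not flagged at the default threshold, but a
  # zero threshold flags every contacting replicate
  scaff_touch <- static_ensemble(tpl, sep = 4.15, beta = 225, chi = 225)
  expect_equal(attr(bundle_screen(scaff_touch), "count"), 0L)
  expect_equal(attr(bundle_screen(scaff_touch, bundle_fraction_threshold = 0),
                    "count"), 1L)
  # monotone in the threshold on the planted ensemble
  ens <- ens_mid()
  counts <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                   function(th) attr(bundle_screen(ens, bundle_fraction_threshold = th),
                                     "count"),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("default planted ensemble leaves bundle helices out of interfaces", {
  ens <- ens_def()
  m <- residue_contact_map(ens)
  smry <- interface_summary(m, ens$template)
  expect_gt(smry$total, 0)
  bundle_rows <- smry$per_helix[c("TMH1", "TMH2", "TMH7")]
  expect_lt(sum(bundle_rows, na.rm = TRUE), 0.01 * smry$total)
  # any flagged bundle-centered dimers are short-lived transients
  scr <- bundle_screen(ens_mid())
  if (attr(scr, "count") > 0)
    expect_true(all(scr$lifetime[scr$flagged] < 0.5))
})

test_that("bundle screen reporting and expected random encounters", {
  expect_identical(bundle_screen_percentage(7, 512), 1.4)
  expect_equal(expected_random_encounters(512, 1.0, 0.0), 0)
  expect_equal(expected_random_encounters(512, 0.625, 0.125), 40)
  expect_error(expected_random_encounters(10, 1.5, 0.5), "probability")
  # Monte-Carlo encounter probability from an attractor-free ensemble is
  # consistent between two disjoint seeds (binomial 3 sigma)
  tpl <- tpl_small()
  imap0 <- interaction_map(data.frame(beta = numeric(0), chi = numeric(0),
                                      depth = numeric(0), width = numeric(0),
                                      distance_min = numeric(0)),
                           nonspecific_depth = 0, bundle_penalty = 0)
  mk <- function(seed) generate_daft_ensemble(
    tpl, imap0, quick_cfg(n_replicates = 32L, duration = 0.3, seed = seed))
  e1 <- expected_random_encounters(32, angular_fraction = 0.125,
                                   ensemble = mk(1001L))
  e2 <- expected_random_encounters(32, angular_fraction = 0.125,
                                   ensemble = mk(2002L))
  p1 <- e1 / (32 * 0.125); p2 <- e2 / (32 * 0.125)
  se <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 32 + 1e-6)
  expect_lt(abs(p1 - p2), 3 * se + 0.1)
})
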