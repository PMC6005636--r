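test_that("order parameter reproduces the closed-form limits", {
  expect_identical(order_parameter(rep(0, 7)), 1)
  expect_identical(order_parameter(rep(90, 5)), -0.5)
  # isotropic limit: <cos^2> = 1/3 -> S = 0
  expect_equal(order_parameter(rep(acos(sqrt(1 / 3)) * 180 / pi, 9)), 0,
               tolerance = 1e-12)
  expect_error(order_parameter(numeric(0)), "empty")
})

test_that("order parameter equals the literal formula and stays in bounds", {
  set.seed(31)
  for (k in 1:20) {
    th <- runif(sample(3:40, 1), 0, 180)
    literal <- 0.5 * (3 * mean(cos(th * pi / 180)^2) - 1)
    S <- order_parameter(th)
    expect_equal(S, literal, tolerance = 1e-14)
    expect_gte(S, -0.5); expect_lte(S, 1)
  }
})

test_that("order maps: uniform tilt, perturbation decay, refinement invariance", {
  model <- membrane_model(lipids_per_leaflet = 144L)
  fr30 <- simulate_membrane_frames(model, n_frames = 4L, tilt_deg = 30,
                                   seed = 5L)
  om <- order_map(fr30, cell = 0.8)
  sampled <- om$S[om$counts > 0]
  expect_equal(unique(round(sampled, 10)), 0.625)  # 1/2 (3 cos^2 30 - 1)
  # unsampled cells are NA, never zero-filled
  expect_true(all(is.na(om$S[om$counts == 0])))
  # protein-induced ordering decays with the annular shell index
  prot <- data.frame(x = 5, y = 5, phi = 0)
  frp <- simulate_membrane_frames(model, n_frames = 4L, proteins = prot,
                                  seed = 6L)
  omp <- order_map(frp, cell = 0.5)
  sh <- annular_shells(omp, data.frame(x = 5, y = 5, radius = 2.0),
                       shell_width = 0.5)
  expect_gt(sh$mean[1], sh$mean[min(5, nrow(sh))])
  expect_equal(sh$mean[1], model$bulk_order + model$protein_order_perturbation[1],
               tolerance = 0.05)
  # grid refinement preserves the count-weighted mean order parameter
  om_f <- order_map(fr30, cell = 0.4)
  wm <- function(m) sum(m$S * m$counts, na.rm = TRUE) / sum(m$counts)
  expect_equal(wm(om), wm(om_f), tolerance = 1e-12)
})

test_that("thickness maps: flat bilayer, planted thinning, zero-sum deviation", {
  flat <- membrane_model(lipids_per_leaflet = 144L,
                         protein_thickness_perturbation =
                           data.frame(angle = numeric(0), delta = numeric(0)))
  fr <- simulate_membrane_frames(flat, n_frames = 4L, seed = 7L, jitter = 0.02)
  tm <- thickness_map(fr, cell = 0.6)
  expect_equal(unique(round(tm$thickness[!is.na(tm$thickness)], 9)), 4.0)
  # planted -0.4 nm thinning sector recovered within 0.05 nm
  thin <- membrane_model(lipids_per_leaflet = 400L,
                         protein_thickness_perturbation =
                           data.frame(angle = 112.5, delta = -0.4))
  prot <- data.frame(x = 8, y = 8, phi = 0)
  frt <- simulate_membrane_frames(thin, n_frames = 6L, proteins = prot,
                                  seed = 8L, jitter = 0.02)
  tmt <- thickness_map(frt, cell = 0.4)
  expect_equal(min(tmt$deviation, na.rm = TRUE), -0.4, tolerance = 0.125)
  expect_lt(abs(min(tmt$deviation, na.rm = TRUE) + 0.4), 0.05)
  # where is the minimum? adjacent to the footprint, in the sector direction
  idx <- which(tmt$deviation == min(tmt$deviation, na.rm = TRUE), arr.ind = TRUE)
  cx <- tmt$origin[1] + (idx[1, 1] - 0.5) * tmt$cell
  cy <- tmt$origin[2] + (idx[1, 2] - 0.5) * tmt$cell
  expect_lt(sqrt((cx - 8)^2 + (cy - 8)^2), 3.5)
  # opposite-sign sectors integrate to ~0 deviation
  bal <- membrane_model(lipids_per_leaflet = 400L,
                        protein_thickness_perturbation =
                          data.frame(angle = c(0, 180), delta = c(0.3, -0.3)))
  frb <- simulate_membrane_frames(bal, n_frames = 4L, proteins = prot,
                                  seed = 9L, jitter = 0.02)
  tmb <- thickness_map(frb, cell = 0.4)
  expect_lt(abs(mean(tmb$deviation, na.rm = TRUE)), 0.02)
})

test_that("annular shells are translation invariant and flag uniform maps", {
  model <- membrane_model(lipids_per_leaflet = 256L)
  prot <- data.frame(x = 6, y = 6, phi = 0)
  fr <- simulate_membrane_frames(model, n_frames = 3L, proteins = prot,
                                 seed = 10L)
  om <- order_map(fr, cell = 0.5)
  sh0 <- annular_shells(om, data.frame(x = 6, y = 6, radius = 2), 0.5)
  # translate everything by one full cell: shell means must be unchanged
  fr2 <- lapply(fr, function(f) { f$x <- f$x + 0.5; f$y <- f$y + 0.5; f })
  attributes(fr2) <- attributes(fr)
  attr(fr2, "box") <- attr(fr, "box") + 0.5
  om2 <- order_map(fr2, cell = 0.5)
  sh2 <- annular_shells(om2, data.frame(x = 6.5, y = 6.5, radius = 2), 0.5)
  m <- min(nrow(sh0), nrow(sh2))
  expect_equal(sh0$mean[1:m], sh2$mean[1:m], tolerance = 0.02)
  # uniform map -> all shells equal
  fru <- simulate_membrane_frames(model, n_frames = 3L, tilt_deg = 25,
                                  seed = 11L)
  omu <- order_map(fru, cell = 0.5)
  shu <- annular_shells(omu, data.frame(x = 6, y = 6, radius = 2), 0.5)
  expect_lt(diff(range(shu$mean)), 1e-9)
})

test_that("interface mismatch scores opposite and matched deviations", {
  # synthetic thickness map: 14 x 8 nm patch, protomers at (3,4) and (11,4)
  nx <- 35L; ny <- 20L; cell <- 0.4
  cx <- (seq_len(nx) - 0.5) * cell; cy <- (seq_len(ny) - 0.5) * cell
  gx <- matrix(cx, nx, ny); gy <- matrix(cy, nx, ny, byrow = TRUE)
  mk_map <- function(devA, devB) {
    dev <- matrix(0, nx, ny)
    dA <- sqrt((gx - 3)^2 + (gy - 4)^2); dB <- sqrt((gx - 11)^2 + (gy - 4)^2)
    dev[dA >= 2 & dA <= 3.5] <- devA
    dev[dB >= 2 & dB <= 3.5] <- devB
    structure(list(thickness = dev + 4, deviation = dev,
                   counts = matrix(1L, nx, ny), origin = c(0, 0),
                   cell = cell, bulk = 4), class = "thickness_map")
  }
  mm <- interface_mismatch(mk_map(0.3, -0.3), c(3, 4), c(11, 4))
  expect_equal(mm$score, 0.09, tolerance = 1e-9)
  expect_equal(interface_mismatch(mk_map(0.3, 0.3), c(3, 4), c(11, 4))$score,
               -0.09, tolerance = 1e-9)
  expect_equal(interface_mismatch(mk_map(0, 0), c(3, 4), c(11, 4))$score, 0)
  expect_error(interface_mismatch(mk_map(0, 0), c(3, 4), c(3, 4)),
               "coincident")
})

test_that("mismatch contrast separates transient from stable dimer geometry", {
  # two protomers in contact; the thinning sector (body angle 112.5) faces
  # the partner on protomer A only -> opposite-sign deviations across the
  # interface (transient signature). Stable geometry: both thinning sectors
  # point away, matched deviations.
  model <- membrane_model(lipids_per_leaflet = 529L, area_per_lipid = 0.65)
  L <- sqrt(529 * 0.65)
  com_A <- c(L / 2 - 3.5, L / 2); com_B <- c(L / 2 + 3.5, L / 2)
  # the model's thinning sector sits at body angle 112.5, thickening at
  # 292.5. phi = -112.5 turns the thinning sector to lab angle 0 (facing B
  # from A; facing away from A when applied to B, whose thickening sector
  # then faces A at 180). Transient geometry: A thins / B thickens across
  # the interface (opposite signs); stable: both thickening sectors face
  # the interface (matched signs).
  transient <- data.frame(x = c(com_A[1], com_B[1]), y = c(com_A[2], com_B[2]),
                          phi = c(-112.5, -112.5))
  stable <- data.frame(x = c(com_A[1], com_B[1]), y = c(com_A[2], com_B[2]),
                       phi = c(67.5, -112.5))
  score_of <- function(prot, seed) {
    fr <- simulate_membrane_frames(model, n_frames = 4L, proteins = prot,
                                   seed = seed, jitter = 0.02)
    tm <- thickness_map(fr, cell = 0.5)
    interface_mismatch(tm, com_A, com_B, r_in = 2, r_out = 3.5)$score
  }
  expect_gt(score_of(transient, 12L), score_of(stable, 12L))
  expect_gt(score_of(transient, 12L), 0)
})
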