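# shared window fixture: umbrella samples from a gaussian well over the
# standard window schedule (coarse 0.1 nm + fine 0.025 nm grids)
pmf_windows <- function(depth = 60, n_samples = 1500L, seed = 3L,
                        form = "gaussian_well_plus_wall") {
  truth <- analytic_pmf(form, depth = depth, width = 0.3, minimum = 4.5)
  cen <- suppressWarnings(plan_windows(origin = 4.2))
  kk <- ifelse(abs(cen - 4.2) <= 0.4 + 1e-9 &
                 (round((cen - 4.2) / 0.025) %% 4 != 0), 5000, 1000)
  list(truth = truth,
       windows = generate_umbrella_samples(truth, cen, k_bias = kk,
                                           n_samples = n_samples, seed = seed))
}

test_that("window planning reproduces the coarse+fine schedule", {
  expect_warning(cen <- plan_windows(origin = 4.2), "32 umbrellas")
  expect_equal(length(cen), 29L)           # 17 coarse + 17 fine - 5 shared
  expect_false(any(duplicated(cen)))
  expect_equal(min(cen), 4.2); expect_equal(max(cen), 5.8)
  expect_equal(sort(unique(round(diff(cen), 9))), c(0.025, 0.1))
  coarse_only <- suppressWarnings(plan_windows(origin = 4.2, fine_extent = 0))
  expect_equal(length(coarse_only), 17L)
  expect_error(plan_windows(coarse_spacing = 0.3), "divide")
  expect_error(umbrella_window(4.2, -1, 1:10), "force constant")
})

test_that("umbrella sampling matches closed-form Gaussian statistics", {
  kt <- kT(310)
  # flat truth, one window: mean = center, variance = kT/k
  flat <- analytic_pmf("flat")
  w <- generate_umbrella_samples(flat, centers = 5.0, k_bias = 1000,
                                 n_samples = 4000L, seed = 8L)
  x <- w[[1]]$xi
  expect_lt(abs(mean(x) - 5.0), 0.01)
  expect_equal(stats::var(x), kt / 1000, tolerance = 0.15)
  # harmonic truth: completing the square gives the biased mean/variance
  D <- 60; wdt <- 0.3; m <- 4.5
  kappa <- 2 * D / wdt^2
  har <- analytic_pmf("harmonic_well", depth = D, width = wdt, minimum = m)
  cen <- 4.55; kb <- 2000
  wh <- generate_umbrella_samples(har, cen, k_bias = kb, n_samples = 6000L,
                                  seed = 9L)
  mu <- (kappa * m + kb * cen) / (kappa + kb)
  v <- kt / (kappa + kb)
  expect_lt(abs(mean(wh[[1]]$xi) - mu), 0.01)
  expect_equal(stats::var(wh[[1]]$xi), v, tolerance = 0.15)
  # empty windows flow through and WHAM refuses them
  w0 <- generate_umbrella_samples(flat, centers = c(4.5, 5.0), n_samples = 0L)
  expect_length(w0[[1]]$xi, 0L)
  expect_error(wham(w0), "samples")
})

test_that("WHAM recovers a gaussian well within bootstrap error", {
  pw <- pmf_windows(depth = 60)
  prof <- bootstrap_errors(pw$windows, n_boot = 12L, seed = 4L)
  df <- prof$profile
  ok <- !is.na(df$G)
  # recovered depth within 2 bootstrap sigma of the planted 60 kJ/mol
  imin <- which.min(df$G)
  expect_lt(abs(-min(df$G, na.rm = TRUE) - 60),
            max(2 * df$err[imin], 2.0))
  # oracle equivalence over the sampled support (3 sigma pointwise, 200 bins)
  tr <- pmf_truth_energy(pw$truth, df$xi)
  tr <- tr - tr[max(which(ok))]
  expect_true(all(abs(df$G - tr)[ok] < pmax(3 * df$err[ok], 1.5)))
  expect_true(prof$converged)
})

test_that("flat truth gives a flat profile within error", {
  pw <- pmf_windows(form = "flat", n_samples = 1200L, seed = 5L)
  prof <- bootstrap_errors(pw$windows, n_boot = 12L, seed = 6L)
  df <- prof$profile
  ok <- !is.na(df$G)
  expect_true(all(abs(df$G[ok]) < pmax(3 * df$err[ok], 1.5)))
})

test_that("WHAM agrees with unbiased Boltzmann inversion on a shallow well", {
  # shallow well (2 kT) so that an unbiased Metropolis chain samples the
  # whole range: the inverted histogram is an independent oracle
  truth <- analytic_pmf("gaussian_well_plus_wall", depth = 5, width = 0.3,
                        minimum = 4.8)
  kt <- kT(310)
  set.seed(42)
  n <- 150000L; x <- numeric(n); cur <- 4.8
  lp <- function(z) ifelse(z < 4.2 | z > 5.8, -Inf,
                           -pmf_truth_energy(truth, z) / kt)
  lcur <- lp(cur)
  for (i in seq_len(n)) {
    prop <- cur + rnorm(1, 0, 0.15)
    lprop <- lp(prop)
    if (log(runif(1)) < lprop - lcur) { cur <- prop; lcur <- lprop }
    x[i] <- cur
  }
  br <- seq(4.2, 5.8, length.out = 65)
  h <- hist(x, breaks = br, plot = FALSE)
  Ginv <- -kt * log(h$counts / sum(h$counts))
  Ginv <- Ginv - Ginv[60]
  # WHAM from umbrella draws of the same truth, on the same bins
  cen <- seq(4.2, 5.8, by = 0.1)
  w <- generate_umbrella_samples(truth, cen, k_bias = 500,
                                 n_samples = 8000L, seed = 7L, thin = 8L)
  prof <- wham(w, breaks = br)
  G <- prof$profile$G - prof$profile$G[60]
  # compare only where the unbiased oracle itself is well sampled
  ok <- h$counts >= 300 & is.finite(Ginv) & !is.na(G)
  expect_gt(sum(ok), 20)
  expect_lt(max(abs(G - Ginv)[ok]), 1.0)
  expect_lt(mean(abs(G - Ginv)[ok]), 0.4)
})

test_that("single-window WHAM reproduces the analytic potential locally", {
  D <- 60; wdt <- 0.3; m <- 4.5
  har <- analytic_pmf("harmonic_well", depth = D, width = wdt, minimum = m)
  w <- generate_umbrella_samples(har, m, k_bias = 1000, n_samples = 20000L,
                                 seed = 10L)
  prof <- wham(w, n_bins = 30L, min_bin_count = 50L)
  df <- prof$profile[!is.na(prof$profile$G), ]
  kappa <- 2 * D / wdt^2
  tru <- 0.5 * kappa * (df$xi - m)^2 - D
  shift <- mean(df$G - tru)
  expect_lt(max(abs(df$G - tru - shift)), 0.8)
})

test_that("WHAM iteration diagnostics behave", {
  pw <- pmf_windows(n_samples = 600L, seed = 12L)
  prof <- wham(pw$windows)
  # residuals essentially non-increasing: the max-norm of a
  # self-consistent iteration may wiggle by a fraction of a percent
  r <- prof$residuals
  expect_true(all(r[-1] <= r[-length(r)] * 1.01 + 1e-12))
  expect_lt(r[length(r)], r[1] * 1e-4)
  # gauge invariance: warm start shifted by a constant -> same profile
  prof2 <- wham(pw$windows, breaks = prof$breaks, f_init = prof$f + 7)
  expect_equal(prof2$profile$G, prof$profile$G, tolerance = 1e-4)
  # missing overlap is reported with the offending gap
  truth <- analytic_pmf("flat")
  expect_warning(
    wgap <- generate_umbrella_samples(truth, c(4.2, 5.6), k_bias = 5000,
                                      n_samples = 400L, seed = 13L),
    "no sample overlap")
  expect_error(wham(wgap), "overlap")
})

test_that("bootstrap errors: degenerate resamples, scaling, metadata", {
  pw <- pmf_windows(n_samples = 800L, seed = 14L)
  expect_error(bootstrap_errors(pw$windows, n_boot = 1L), "n_boot")
  prof <- wham(pw$windows)
  # block length >= series length forces identical resamples -> zero error
  pb <- bootstrap_errors(pw$windows, n_boot = 3L, seed = 2L, profile = prof,
                         block_length = 10000L)
  expect_true(all(pb$profile$err[!is.na(pb$profile$G)] < 1e-10))
  expect_match(pb$error_note, "lower boundaries")
  # errors shrink roughly as 1/sqrt(N): compare N and 4N samples
  pwN <- pmf_windows(n_samples = 500L, seed = 15L)
  pw4N <- pmf_windows(n_samples = 2000L, seed = 15L)
  eN <- bootstrap_errors(pwN$windows, n_boot = 10L, seed = 3L)
  e4N <- bootstrap_errors(pw4N$windows, n_boot = 10L, seed = 3L,
                          breaks = eN$breaks)
  ratio <- mean(eN$profile$err, na.rm = TRUE) /
    mean(e4N$profile$err, na.rm = TRUE)
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.5)
})

test_that("profile integration is exact on simple shapes and additive", {
  # flat zero profile
  flat <- data.frame(xi = seq(4, 6, by = 0.01), G = 0)
  expect_equal(integrate_profile(flat), 0)
  # rectangular well: compare to an independently coded trapezoid
  xi <- seq(4, 6, by = 0.01)
  G <- ifelse(xi >= 4.5 & xi <= 5.0, -40, 0)
  got <- integrate_profile(data.frame(xi = xi, G = G))
  oracle <- sum(diff(xi) * (G[-1] + G[-length(G)]) / 2)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(got, -40 * 0.5, tolerance = 40 * 0.011)  # -D*W within one bin
  # triangular well: -D*W/2 within one bin-width of discretization error
  Gt <- pmax(-40 * (1 - abs(xi - 4.75) / 0.25), -40) * (abs(xi - 4.75) <= 0.25)
  expect_equal(integrate_profile(data.frame(xi = xi, G = Gt)),
               -40 * 0.5 / 2, tolerance = 40 * 0.011)
  # additivity over disjoint sub-ranges
  cut <- xi <= 5
  expect_equal(integrate_profile(data.frame(xi = xi, G = G)),
               integrate_profile(data.frame(xi = xi[cut], G = G[cut])) +
                 integrate_profile(data.frame(xi = xi[!cut], G = G[!cut])) +
                 diff(xi)[1] * (G[sum(cut)] + G[sum(cut) + 1]) / 2,
               tolerance = 1e-9)
})

test_that("restraint diagnostics classify gaussian vs hidden-gradient series", {
  good <- simulate_restraint_series(n_windows = 4L, n = 400L, sd_angle = 0.05,
                                    seed = 6L)
  rg <- restraint_gaussianity(good)
  expect_true(all(rg$verdict == "gaussian-like"))
  expect_true(all(rg$angle_sd < 0.075))
  expect_true(all(rg$angle_ok))
  bad <- simulate_restraint_series(n_windows = 3L, n = 400L, bimodal = TRUE,
                                   seed = 7L)
  rb <- restraint_gaussianity(bad)
  expect_true(all(rb$verdict == "hidden-gradient"))
  short <- simulate_restraint_series(n_windows = 2L, n = 60L, seed = 8L)
  expect_true(all(restraint_gaussianity(short)$verdict == "indeterminate"))
})
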