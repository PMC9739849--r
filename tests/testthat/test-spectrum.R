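test_that("binning collects counts and per-bin dipole means", {
  b <- bin_vertical(rep(0.02, 5), rep(2, 5), bin_width = 1e-3)
  expect_length(b$bin_centers, 1)
  expect_equal(b$counts, 5L)
  expect_equal(b$mean_mu2, 2)
  expect_equal(b$nu_el, b$bin_centers)
  # two equal-count bins, |mu|^2 ratio 2:1 -> maximum at the larger
  nu <- c(rep(0.0205, 4), rep(0.0255, 4))
  mu2 <- c(rep(1, 4), rep(2, 4))
  b2 <- bin_vertical(nu, mu2, bin_width = 1e-3)
  expect_equal(b2$nu_el, 0.0255)
  # counts conserve the frame count for random input
  set.seed(3)
  nu3 <- runif(137, 0.018, 0.03)
  b3 <- bin_vertical(nu3, runif(137), bin_width = 5e-4)
  expect_equal(sum(b3$counts), 137L)
  expect_error(bin_vertical(numeric(0), numeric(0), 1e-3), "empty input")
})

test_that("vertical spectrum area matches the closed-form bin prefactor", {
  sig <- 1e-5
  b <- bin_vertical(rep(0.02, 10), rep(1.5, 10), bin_width = 1e-3,
                    sigma = sig)
  sp <- vertical_spectrum(b)
  area <- spectrum_integral(sp)
  expected <- pmmvib:::spectral_const("absorption") * 1.5 *
    pmmvib:::spectral_freq_factor("absorption", b$bin_centers)
  expect_equal(area, expected, tolerance = 1e-6)
  # linearity: doubling |mu|^2 doubles the intensity everywhere
  b2 <- bin_vertical(rep(0.02, 10), rep(3, 10), bin_width = 1e-3, sigma = sig)
  sp2 <- vertical_spectrum(b2, grid = sp$grid)
  expect_equal(sp2$intensity, 2 * sp$intensity, tolerance = 1e-12)
  expect_error(bin_vertical(0.02, 1, 1e-3, sigma = -1), "sigma")
})

test_that("emission/absorption prefactors differ by the (nu/c)^3 vs h*nu
           factor pair", {
  nu <- c(0.021, 0.024, 0.027); mu2 <- c(1, 2, 0.5)
  ba <- bin_vertical(nu, mu2, 1e-3, "absorption")
  be <- bin_vertical(nu, mu2, 1e-3, "emission")
  grid <- seq(0.018, 0.03, by = 5e-5)
  Ia <- vertical_spectrum(ba, grid)$intensity
  Ie <- vertical_spectrum(be, grid)$intensity
  cst <- pmmvib::au_constants
  ratio_expect <- (8 * pi * cst$h_au / (6 * cst$eps0_au)) *
    (grid / cst$c_au)^3 /
    ((1 / (6 * cst$eps0_au * cst$c_au)) * cst$h_au * grid)
  ok <- Ia > max(Ia) * 1e-8
  expect_equal(Ie[ok] / Ia[ok], ratio_expect[ok], tolerance = 1e-10)
})

test_that("0-0 correction reproduces the reference shifts", {
  shift_ev <- function(calc, expv)
    pmmvib:::freq_au_to_ev(correct_00(energy_ev_to_freq_au(calc),
                                      energy_ev_to_freq_au(expv)))
  expect_equal(shift_ev(4.69, 4.37), -0.32, tolerance = 1e-10)
  expect_equal(shift_ev(5.11, 4.54), -0.57, tolerance = 1e-10)
  expect_equal(correct_00(0.02, 0.02), 0)
})

test_that("sigma conversion to photon energy is linear and matches the
           reference value", {
  expect_equal(round(sigma_to_energy(0.0004), 3), 0.068)
  expect_equal(sigma_to_energy(0), 0)
  x <- 0.00037
  expect_equal(sigma_to_energy(2 * x), 2 * sigma_to_energy(x),
               tolerance = 1e-14)
})

test_that("vibronic construction: 0-0 fixed point, peak placement,
           intensity conservation, rigid translation", {
  set.seed(11)
  nu <- 0.021 + rnorm(60, sd = 4e-4)
  b <- bin_vertical(nu, runif(60, 0.5, 2), 2e-4, "absorption")
  # single 0-0 transition with nu_m0 = nu_el0: identical to the vertical
  t00 <- enumerate_transitions(numeric(0), numeric(0))
  v <- vertical_spectrum(b)
  vb <- vibronic_spectrum(b, t00, nu_el0 = 0.02, nu_00 = 0.02, grid = v$grid)
  expect_equal(vb$intensity, v$intensity, tolerance = 1e-12)
  # progression: integrated ratio equals the captured sum
  S <- c(0.5, 0.9); f <- c(0.002, 0.003)
  ts <- enumerate_transitions(S, f, fc_threshold = 1e-6)
  vb2 <- vibronic_spectrum(b, ts, nu_el0 = 0.02, nu_00 = 0.019)
  expect_equal(spectrum_integral(vb2) / spectrum_integral(v), ts$captured,
               tolerance = 1e-8)
  # unperturbed single frame: peaks at exactly the nu_m0 values
  b1 <- bin_vertical(0.02 + 1e-4, 1, 2e-4, "absorption")  # bin center 0.02?
  b1 <- bin_vertical(rep(b1$nu_el, 3), rep(1, 3), 2e-4, "absorption")
  ts1 <- enumerate_transitions(0.8, 0.004, fc_threshold = 1e-4)
  vb1 <- vibronic_spectrum(b1, ts1, nu_el0 = b1$nu_el, nu_00 = 0.019)
  for (k in 0:2) {
    num <- 0.019 + k * 0.004
    region <- abs(vb1$grid - num) < 2e-4
    pk <- vb1$grid[region][which.max(vb1$intensity[region])]
    expect_equal(pk, num, tolerance = 1.1e-4, label = sprintf("peak k=%d", k))
  }
  # shifting every nu_m0 by delta translates the spectrum rigidly
  delta <- 0.0012
  vb3 <- vibronic_spectrum(b, ts, nu_el0 = 0.02, nu_00 = 0.019 + delta,
                           grid = vb2$grid + delta)
  expect_equal(vb3$intensity, vb2$intensity, tolerance = 1e-12)
  expect_error(vibronic_spectrum(b, structure(list(fc2 = numeric(0)),
                                              class = "transition_set"),
                                 0.02, 0.02), "empty transition set")
})

test_that("combination is linear, grid-aware and validates weights", {
  set.seed(5)
  b <- bin_vertical(0.02 + rnorm(40, sd = 3e-4), runif(40), 2e-4)
  s1 <- vertical_spectrum(b)
  comb1 <- combine_spectra(list(s1), 1)
  expect_equal(comb1$intensity, s1$intensity)
  comb2 <- combine_spectra(list(s1, s1), c(0.5, 0.5))
  expect_equal(comb2$intensity, s1$intensity, tolerance = 1e-12)
  # disjoint bands: integral adds with the weights
  b2 <- bin_vertical(0.04 + rnorm(40, sd = 3e-4), runif(40), 2e-4)
  s2 <- vertical_spectrum(b2)
  tot <- combine_spectra(list(s1, s2), c(0.3, 0.7))
  expect_equal(spectrum_integral(tot),
               0.3 * spectrum_integral(s1) + 0.7 * spectrum_integral(s2),
               tolerance = 1e-6)
  expect_error(combine_spectra(list(s1, s2), 1), "length mismatch")
  # pooled frames equal the count-weighted combination of subset spectra
  nu <- 0.02 + rnorm(60, sd = 3e-4); mu2 <- runif(60)
  grid <- seq(0.015, 0.025, by = 5e-5)
  pooled <- vertical_spectrum(bin_vertical(nu, mu2, 2e-4), grid)
  pa <- vertical_spectrum(bin_vertical(nu[1:20], mu2[1:20], 2e-4), grid)
  pb <- vertical_spectrum(bin_vertical(nu[21:60], mu2[21:60], 2e-4), grid)
  mix <- combine_spectra(list(pa, pb), c(20, 40) / 60)
  expect_equal(mix$intensity, pooled$intensity, tolerance = 1e-10)
})

test_that("peak normalization and its failure modes", {
  b <- bin_vertical(0.02, 1, 2e-4)
  s <- vertical_spectrum(b)
  n1 <- normalize_peak(s)
  expect_equal(max(n1$intensity), 1)
  s3 <- s; s3$intensity <- 3 * s$intensity
  expect_equal(normalize_peak(s3)$intensity, n1$intensity)
  s0 <- s; s0$intensity <- rep(0, length(s$intensity))
  expect_error(normalize_peak(s0), "all-zero")
})

test_that("halving the bin width changes the broadened spectrum by under
           1 percent in L1 norm", {
  set.seed(9)
  nu <- 0.021 + rnorm(400, sd = 6e-4); mu2 <- runif(400, 0.5, 1.5)
  sig <- 4e-4
  grid <- seq(0.017, 0.026, by = sig / 10)
  s1 <- vertical_spectrum(bin_vertical(nu, mu2, sig / 2, sigma = sig), grid)
  s2 <- vertical_spectrum(bin_vertical(nu, mu2, sig / 4, sigma = sig), grid)
  l1 <- sum(abs(s1$intensity - s2$intensity)) / sum(abs(s1$intensity))
  expect_lt(l1, 0.01)
})
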