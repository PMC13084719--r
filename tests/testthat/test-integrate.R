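# Window integration, the noise model and normalization.

make_flat_series <- function(f, temps = c(20, 30, 40), ppm = seq(0, 8, 2e-3)) {
  sp <- tidyr::expand_grid(temperature_C = temps, ppm = ppm)
  sp$intensity <- f(sp$ppm, sp$temperature_C)
  spectrum_series(sp)
}

test_that("noise is estimated robustly, with and without baseline drift", {
  ppm <- seq(0, 8, by = 8 / 511)
  set.seed(11)
  noise <- stats::rnorm(512 * 3)
  flat <- make_flat_series(function(p, t) noise[seq_along(p)], ppm = ppm)
  est <- estimate_noise(flat, c(0, 8))
  expect_true(all(abs(est$sigma_noise - 1) < 0.1))

  # same noise plus a steep linear drift: estimate unchanged
  drift <- make_flat_series(function(p, t) noise[seq_along(p)] + 5 * p,
                            ppm = ppm)
  est2 <- estimate_noise(drift, c(0, 8))
  expect_equal(est2$sigma_noise, est$sigma_noise, tolerance = 1e-6)

  zero <- make_flat_series(function(p, t) 0 * p, ppm = ppm)
  expect_equal(estimate_noise(zero, c(0, 8))$sigma_noise, rep(0, 3))
})

test_that("quiet-region misconfiguration is caught", {
  zero <- make_flat_series(function(p, t) 0 * p)
  expect_error(estimate_noise(zero, c(3.0, 3.01)), "32")
  expect_error(estimate_noise(zero, c(6.0, 6.5), windows = default_windows()),
               "overlaps configured window")
})

test_that("a Lorentzian fully inside its window integrates to its area within 2%", {
  g <- 0.005
  sh <- function(p, t) liquidus:::lorentzian(p, 3.7, g, 1)
  series <- make_flat_series(sh, ppm = seq(0, 8, 5e-4))
  win <- peak_windows(tibble::tibble(
    name = "peak", ppm_lo = 3.35, ppm_hi = 4.05, multiplicity = 1L,
    role = "reference"
  ), quiet_region = c(6, 7))
  for (bl in c("none", "edges")) {
    tr <- integrate_windows(series, win, baseline = bl)
    expect_equal(tr$raw, rep(tr$raw[1], 3))
    expect_lt(abs(tr$raw[1] - 1), 0.02)
    # and against the independent quadrature oracle, tightly
    if (bl == "none") {
      expect_equal(tr$raw[1], oracle_window_mass(3.35, 4.05, 3.7, g, 1),
                   tolerance = 1e-5)
    }
  }
})

test_that("integration is linear and an empty window integrates to zero", {
  g <- 0.005
  s1 <- make_flat_series(function(p, t) liquidus:::lorentzian(p, 3.7, g, 1))
  s2 <- make_flat_series(function(p, t) 3 * liquidus:::lorentzian(p, 3.7, g, 1) +
                           0.5 * liquidus:::lorentzian(p, 3.8, 0.01, 1))
  s3 <- make_flat_series(function(p, t) 0.5 * liquidus:::lorentzian(p, 3.8, 0.01, 1))
  win <- peak_windows(tibble::tibble(
    name = c("peak", "empty"), ppm_lo = c(3.35, 5.0), ppm_hi = c(4.05, 5.7),
    multiplicity = c(1L, 1L), role = c("reference", "solvent")
  ), quiet_region = c(6, 7))
  r1 <- integrate_windows(s1, win)
  r2 <- integrate_windows(s2, win)
  r3 <- integrate_windows(s3, win)
  expect_equal(r2$raw[r2$window == "peak"],
               3 * r1$raw[r1$window == "peak"] + r3$raw[r3$window == "peak"],
               tolerance = 1e-10)
  expect_equal(r1$raw[r1$window == "empty"], rep(0, 3), tolerance = 1e-12)
  expect_error(integrate_windows(s1, peak_windows(tibble::tibble(
    name = "out", ppm_lo = -2, ppm_hi = -1, multiplicity = 1L,
    role = "reference"), quiet_region = c(6, 7))), "outside")
})

test_that("sigma_raw follows the white-noise trapezoid model", {
  zero <- make_flat_series(function(p, t) 0 * p, ppm = seq(0, 8, 1e-3))
  set.seed(5)
  zero$spectra$intensity <- stats::rnorm(nrow(zero$spectra), sd = 2)
  win <- peak_windows(tibble::tibble(
    name = c("narrow", "wide"), ppm_lo = c(1, 3), ppm_hi = c(1.5, 5),
    multiplicity = c(1L, 1L), role = c("reference", "solvent")
  ), quiet_region = c(6, 7))
  tr <- dplyr::filter(integrate_windows(zero, win), temperature_C == 20)
  # sigma scales as sqrt(window width) at fixed point density and noise
  expect_equal(tr$sigma_raw[tr$window == "wide"] /
                 tr$sigma_raw[tr$window == "narrow"],
               sqrt(2001 / 501), tolerance = 1e-6)
  # absolute scale: sigma * dppm * sqrt(n)
  est <- estimate_noise(zero, c(6, 7))$sigma_noise[1]
  expect_equal(tr$sigma_raw[tr$window == "narrow"],
               est * 1e-3 * sqrt(501), tolerance = 0.01)
})

test_that("normalization divides by the normalizer and propagates errors", {
  tab <- tibble::tibble(temperature_C = seq(20, 26, 2),
                        NH = 1, CH2O = 3, vinyl = 2, BTMSA = 0.5)
  tr <- normalize_traces(traces_from_table(tab, default_windows()), "vinyl")
  expect_equal(tr$normalized[tr$window == "NH"], rep(0.5, 4))
  expect_equal(tr$normalized[tr$window == "CH2O"], rep(1.5, 4))
  expect_equal(tr$sigma_norm, rep(0, 16))

  bad <- tab
  bad$vinyl[2] <- 0
  expect_error(normalize_traces(traces_from_table(bad, default_windows()),
                                "vinyl"), "22")
  expect_error(normalize_traces(tr, "nope"), "not present")
})

test_that("noise-free normalized gelator integrals track the true soluble fraction", {
  truth <- synthetic_truth("single", noise = "none")
  series <- generate_series(truth, seed = 1)
  tr <- normalize_traces(integrate_windows(series, default_windows()), "vinyl")
  nh <- dplyr::filter(tr, window == "NH")
  frac <- true_solubility(truth, nh$temperature_C) / truth$W_D
  expect_equal(nh$normalized / max(nh$normalized), frac / max(frac),
               tolerance = 0.02)
})

test_that("swapping the normalizer rescales traces by a single global factor", {
  truth <- synthetic_truth("single", noise = "none")
  series <- generate_series(truth, seed = 1, temperatures = seq(60, 90, 5))
  raw <- integrate_windows(series, default_windows())
  by_vinyl <- normalize_traces(raw, "vinyl")
  by_ref <- normalize_traces(raw, "BTMSA")
  ratio <- by_vinyl$normalized / by_ref$normalized
  ratio <- ratio[is.finite(ratio) & abs(by_ref$normalized) > 1e-6]
  expect_equal(ratio, rep(ratio[1], length(ratio)), tolerance = 1e-9)
})

test_that("the solvent/reference parallel-evolution check flags drift", {
  truth <- synthetic_truth("single")
  series <- generate_series(truth, seed = 21, temperatures = seq(50, 90, 2))
  tr <- integrate_windows(series, default_windows())
  chk <- reference_consistency_check(tr, "vinyl", "BTMSA")
  expect_true(chk$pass)

  drift <- synthetic_truth("single", ref_drift = 0.10)
  series2 <- generate_series(drift, seed = 21, temperatures = seq(50, 90, 2))
  tr2 <- integrate_windows(series2, default_windows())
  chk2 <- reference_consistency_check(tr2, "vinyl", "BTMSA")
  expect_false(chk2$pass)
  # the largest deviation sits at one of the ramp ends
  expect_true(chk2$temperature_C <= 56 || chk2$temperature_C >= 84)

  same <- reference_consistency_check(tr, "vinyl", "vinyl")
  expect_true(same$pass)
  expect_equal(same$max_abs_deviation, 0)
})
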