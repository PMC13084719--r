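# The synthetic experiment generator and schedule arithmetic.

test_that("generation is bit-identical under a fixed seed", {
  truth <- synthetic_truth("single")
  a <- generate_series(truth, seed = 5, temperatures = seq(60, 90, 5))
  b <- generate_series(truth, seed = 5, temperatures = seq(60, 90, 5))
  expect_identical(a$spectra, b$spectra)
  c <- generate_series(truth, seed = 6, temperatures = seq(60, 90, 5))
  expect_false(identical(a$spectra$intensity, c$spectra$intensity))
})

test_that("a written experiment directory is reproducible file-for-file", {
  truth <- synthetic_truth("two_polymorph")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_synthetic_experiment(truth, d1, seed = 4,
                             temperatures = seq(30, 60, 5))
  write_synthetic_experiment(truth, d2, seed = 4,
                             temperatures = seq(30, 60, 5))
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("the true solubility curve is monotone and caps at W", {
  for (type in c("single", "two_polymorph")) {
    truth <- synthetic_truth(type)
    tt <- seq(0, 100, 0.5)
    w <- true_solubility(truth, tt)
    expect_true(all(diff(w) >= -1e-12))
    expect_true(all(w <= truth$W_D + 1e-12))
    expect_equal(w[tt >= truth$T_m_C], rep(truth$W_D, sum(tt >= truth$T_m_C)))
    # inverse consistency below the cap
    ww <- c(0.2, 0.5, 1.5) * truth$W_D / 2
    expect_equal(true_solubility(truth, true_liquidus_temperature(truth, ww)),
                 ww, tolerance = 1e-9)
  }
})

test_that("the two-polymorph truth has a concentration-independent corner", {
  t1 <- synthetic_truth("two_polymorph", W_D = 5)
  t2 <- synthetic_truth("two_polymorph", W_D = 3.5)
  tt <- seq(5, 35, 0.5)
  expect_equal(true_solubility(t1, tt)[tt < 30], true_solubility(t2, tt)[tt < 30])
  expect_equal(t1$T_GG_C, t2$T_GG_C)
  expect_gt(t1$T_m_C, t2$T_m_C)
})

test_that("generated integrals match the closed-form window-mass oracle", {
  truth <- synthetic_truth("single", noise = "none")
  win <- default_windows()
  series <- generate_series(truth, seed = 1, temperatures = seq(70, 90, 5))
  tr <- integrate_windows(series, win)
  w_true <- true_solubility(truth, seq(70, 90, 5))
  gamma <- truth$linewidth_ppm / 2
  for (nm in c("NH", "CH2O")) {
    i <- which(win$name == nm)
    ctr <- (win$ppm_lo[i] + win$ppm_hi[i]) / 2
    expected <- win$multiplicity[i] * (w_true / truth$W_D) *
      oracle_window_mass(win$ppm_lo[i], win$ppm_hi[i], ctr, gamma, 1)
    if (nm == "CH2O") {
      expected <- expected + oracle_window_mass(
        win$ppm_lo[i], win$ppm_hi[i], win$ppm_lo[i] + 0.17,
        truth$satellite_linewidth_ppm / 2, truth$floors[["CH2O"]])
    }
    got <- tr$raw[tr$window == nm]
    expect_equal(got, expected, tolerance = 1e-4)
  }
  # package closed form agrees with the independent quadrature oracle
  expect_equal(lorentzian_window_mass(6.10, 6.80, 6.45, gamma, 1),
               oracle_window_mass(6.10, 6.80, 6.45, gamma, 1),
               tolerance = 1e-8)
})

test_that("truth reports carry T_m, the corner and the table schema", {
  single <- truth_report(synthetic_truth("single"))
  expect_null(attr(single, "T_GG_true"))
  expect_equal(attr(single, "T_m_true"), 80)

  two <- synthetic_truth("two_polymorph")
  rep2 <- truth_report(two)
  expect_equal(attr(rep2, "T_GG_true"), 22)
  expect_equal(rep2$w_wtpct_D[rep2$temperature_C == 22], two$w_corner)

  path <- withr::local_tempfile(fileext = ".csv")
  write_integral_table(rep2, path)
  back <- read_integral_table(path)
  expect_equal(back$w_wtpct_D, rep2$w_wtpct_D, tolerance = 1e-9)
})

test_that("doubling the total concentration leaves the shared liquidus branch", {
  # only the soluble fraction is visible: truths sharing the same solubility
  # lines but different total W superimpose below the smaller plateau
  win <- default_windows()
  t_lo <- synthetic_truth("two_polymorph", W_D = 2.5, noise = "none")
  t_hi <- synthetic_truth("two_polymorph", W_D = 5.0, noise = "none")
  temps <- seq(12, 60, 2)
  m_lo <- map_phase_diagram(generate_series(t_lo, seed = 1, temperatures = temps),
                            win)
  m_hi <- map_phase_diagram(generate_series(t_hi, seed = 1, temperatures = temps),
                            win)
  lo <- dplyr::filter(tidy(m_lo), source_window == "CH2O",
                      segment == "liquidus", w_wtpct_D < 2)
  hi <- dplyr::filter(tidy(m_hi), source_window == "CH2O",
                      segment == "liquidus", w_wtpct_D < 2)
  shared <- dplyr::inner_join(lo, hi, by = "temperature_C")
  expect_gte(nrow(shared), 4)
  expect_equal(shared$w_wtpct_D.x, shared$w_wtpct_D.y, tolerance = 0.02)
})

test_that("the stepped-ramp heating rate reproduces the standard schedule", {
  expect_equal(round_half_away(effective_heating_rate(2, 420, 32, 30), 3),
               0.087)
  expect_equal(effective_heating_rate(1, 30, 1, 30), 1.000)
  expect_equal(effective_heating_rate(2, 840, 32, 60),
               effective_heating_rate(2, 420, 32, 30) / 2)
  # schedule-list form
  expect_equal(effective_heating_rate(list(step_C = 2, equilibration_s = 420,
                                           scans = 32, relaxation_delay_s = 30)),
               effective_heating_rate(2, 420, 32, 30))
  expect_error(effective_heating_rate(0, 420, 32, 30), "positive")
  expect_error(effective_heating_rate(2, -1, 32, 30), "positive")
})

test_that("noise presets set the plateau SNR", {
  ref <- synthetic_truth("single", noise = "reference")
  harsh <- synthetic_truth("single", noise = "harsh")
  expect_equal(liquidus:::noise_sigma(ref) * 10,
               liquidus:::noise_sigma(harsh))
  expect_equal(liquidus:::noise_sigma(synthetic_truth("single", noise = "none")),
               0)
  height <- 1 / (pi * ref$linewidth_ppm / 2)
  expect_equal(height / liquidus:::noise_sigma(ref), 50)
})
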