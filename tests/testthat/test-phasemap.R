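# Soluble-fraction curves, the error budget, diagram assembly, corner
# detection and overlays.

fake_correction <- function(values, i_max = 1, sigma = 0, W = 4,
                            temps = seq_along(values) * 2 + 18,
                            t_m = max(temps)) {
  traces <- tibble::tibble(
    window = "NH", role = "gelator", multiplicity = 1L, temperature_C = temps,
    raw = values, sigma_raw = sigma, normalized = values, sigma_norm = sigma,
    corrected = values, sigma_corrected = sigma
  )
  plateaus <- tibble::tibble(
    window = "NH", role = "gelator", multiplicity = 1L, I_max = i_max,
    sigma_Imax = 0, T_m = t_m, n_plateau = 3L, T_plateau_min = t_m
  )
  list(traces = traces, plateaus = plateaus)
}

test_that("w(T) = W I / I_max, with the plateau marked above T_m", {
  fc <- fake_correction(c(0, 0.25, 0.5, 1), i_max = 1, W = 4.44)
  cv <- soluble_fraction(fc$traces, W_D = 4.44, plateaus = fc$plateaus)
  expect_equal(cv$w_wtpct_D, c(0, 1.11, 2.22, 4.44))
  expect_equal(cv$segment, c("liquidus", "liquidus", "liquidus", "plateau"))
})

test_that("w(T) is invariant under a common rescaling of all integrals", {
  v <- c(0.1, 0.4, 0.9, 1, 1, 1)
  a <- fake_correction(v, i_max = 1)
  b <- fake_correction(100 * v, i_max = 100)
  wa <- soluble_fraction(a$traces, W_D = 4, plateaus = a$plateaus)
  wb <- soluble_fraction(b$traces, W_D = 4, plateaus = b$plateaus)
  expect_equal(wa$w_wtpct_D, wb$w_wtpct_D, tolerance = 1e-12)
})

test_that("the error budget adds in quadrature", {
  fc <- fake_correction(c(0.5, 0.8, 1, 1, 1))
  cv <- soluble_fraction(fc$traces, W_D = 4, plateaus = fc$plateaus)

  cv0 <- dplyr::mutate(cv, rel_noise = 0, rel_Imax = 0.02)
  out <- propagate_uncertainty(cv0, error_budget(0, 0))
  expect_equal(out$rel_err, rep(0.02, 5))

  cv1 <- dplyr::mutate(cv, rel_noise = 0, rel_Imax = 0.02)
  out1 <- propagate_uncertainty(cv1, error_budget(0.02, 0.005))
  expect_equal(out1$rel_err, rep(sqrt(0.02^2 + 0.005^2 + 0.02^2), 5))
  expect_equal(round(100 * out1$rel_err[1], 2), 2.87)

  # an SNR-starved point is unreliable
  cv2 <- dplyr::mutate(cv, rel_noise = 0.5, rel_Imax = 0.02)
  out2 <- propagate_uncertainty(cv2, error_budget())
  expect_true(all(out2$rel_err > 0.20))
})

test_that("diagram assembly converts bases and applies the reliability rule", {
  fc <- fake_correction(c(0.05, 0.2, 0.5, 1, 1, 1))
  cv <- soluble_fraction(fc$traces, W_D = 4, plateaus = fc$plateaus)
  cv <- dplyr::mutate(cv, rel_noise = c(0.5, 0.15, 0.05, 0.01, 0.01, 0.01))
  cv <- propagate_uncertainty(cv, error_budget())
  conv <- isotope_mass_ratio("C57H104O6", 101)
  pd <- assemble_phase_diagram(cv, conv, W_D = 4)
  expect_s3_class(pd, "phase_diagram")
  expect_equal(pd$W_H, 100 * convert_weight_fraction(0.04, conv$r),
               tolerance = 1e-12)
  expect_equal(pd$points$w_wtpct_H,
               100 * convert_weight_fraction(pd$points$w_wtpct_D / 100, conv$r),
               tolerance = 1e-12)
  expect_equal(pd$points$reliable, pd$points$rel_err <= 0.2)
  expect_equal(glance(pd)$n_points, 6)

  # a curve that never leaves the plateau yields an empty liquidus
  flat <- fake_correction(rep(1, 5), t_m = 20)
  cvf <- propagate_uncertainty(
    soluble_fraction(flat$traces, W_D = 4, plateaus = flat$plateaus),
    error_budget())
  pdf <- assemble_phase_diagram(cvf, conv, W_D = 4)
  expect_equal(sum(pdf$points$segment == "liquidus"), 0)
  expect_equal(pdf$W_D, 4)
})

test_that("corner detection needs enough reliable points", {
  fc <- fake_correction(c(0.1, 0.3, 0.6, 1, 1, 1))
  cv <- propagate_uncertainty(
    soluble_fraction(fc$traces, W_D = 4, plateaus = fc$plateaus),
    error_budget())
  pd <- assemble_phase_diagram(cv, 1.115, W_D = 4)
  res <- detect_gel_gel_corner(pd)
  expect_false(res$detected)
  expect_equal(res$status, "insufficient_data")
})

test_that("a single-polymorph diagram yields no corner", {
  run <- cached_single_run()
  expect_false(run$map$corner$detected)
  expect_equal(run$map$corner$status, "no_corner")
})

test_that("a sharp two-polymorph slope change is localized at T_GG", {
  truth <- synthetic_truth("two_polymorph")
  m <- map_phase_diagram(generate_series(truth, seed = 51), default_windows(),
                         detect_corner = TRUE)
  expect_true(m$corner$detected)
  expect_lt(abs(m$corner$T_GG_C - truth$T_GG_C), 2 + 1e-9)
  # the low-temperature (metastable) branch is the steeper one
  expect_gt(m$corner$slope_below, m$corner$slope_above)
})

test_that("an attenuated transition scores much weaker evidence", {
  sharp <- synthetic_truth("two_polymorph")
  soft <- synthetic_truth("two_polymorph", B_below_K = 4000)
  ev <- function(tr, s) {
    m <- map_phase_diagram(generate_series(tr, seed = s), default_windows(),
                           detect_corner = TRUE,
                           corner_args = list(evidence_margin = -Inf))
    m$corner$evidence
  }
  expect_lt(ev(soft, 61), ev(sharp, 61) / 2)
})

test_that("overlays are carried through untouched and compared to the liquidus", {
  run <- cached_single_run()
  pd <- run$map$diagram
  truth <- run$truth
  # synthetic DSC points placed exactly on the true liquidus
  w_pts <- c(0.5, 1, 2, 3, 4)
  ov <- tibble::tibble(
    technique = "DSC",
    W_wt_percent_H = 100 * convert_weight_fraction(w_pts / 100, pd$r),
    T_C = true_liquidus_temperature(truth, w_pts)
  )
  pd2 <- attach_overlays(pd, ov)
  expect_equal(nrow(pd2$overlays), 5)
  dev <- overlay_deviations(pd2)
  expect_lt(max(abs(dev$delta_T_C)), 2.5)

  pd3 <- attach_overlays(pd, ov[0, ])
  expect_equal(nrow(pd3$overlays), 0)
  expect_equal(pd3$points, pd$points)

  expect_warning(attach_overlays(pd, dplyr::mutate(ov, technique = "xray")),
                 "xray")
})

test_that("diagram methods print, tidy, glance and plot", {
  run <- cached_single_run()
  pd <- run$map$diagram
  expect_output(print(pd), "phase_diagram")
  expect_s3_class(tidy(pd), "tbl_df")
  g <- glance(run$map)
  expect_true(g$n_reliable_liquidus > 8)
  p <- autoplot(pd)
  expect_s3_class(p, "ggplot")
  p2 <- autoplot(run$map, scale = "linear")
  expect_s3_class(p2, "ggplot")
  expect_s3_class(plot_traces(run$map$traces, "corrected"), "ggplot")
})
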