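# Seeded generator of synthetic VT-NMR experiments with exported ground
# truth, plus acquisition-schedule arithmetic.

#' Ground truth for a synthetic VT-NMR experiment
#'
#' Defines the solubility curve the simulator follows, the overlap floors,
#' the noise level and the line widths. Two solubility models are available:
#'
#' * `"single"` — one polymorph with a van't Hoff-type solubility
#'   `w*(T) = W exp(-B (1/T_K - 1/T_m,K))`, capped at the total concentration
#'   `W` for `T >= T_m`. The default `B` spans roughly a decade and a half of
#'   concentration (~0.1 to ~4 wt%) over a 40-90 degC window.
#' * `"two_polymorph"` — two solid forms with distinct van't Hoff lines
#'   meeting at the concentration-independent gel-gel temperature `T_GG_C`
#'   where the solubility equals `w_corner`; the metastable low-temperature
#'   branch has slope parameter `B_below_K`, the stable branch `B_above_K`,
#'   and `T_m` follows from where the stable branch reaches `W`.
#'
#' Liquid-state NMR only sees the dissolved fraction, so the simulator simply
#' does not emit signal for the solid fraction; gelator peak areas are
#' proportional to `multiplicity * w*(T)`.
#'
#' @param type `"single"` or `"two_polymorph"`.
#' @param W_D Total gelator concentration, wt% in the deuterated solvent.
#' @param T_m_C Full-dissolution temperature (single-polymorph model).
#' @param B_K van't Hoff slope parameter, Kelvin (single-polymorph model).
#' @param T_GG_C,w_corner,B_below_K,B_above_K Two-polymorph parameters (see
#'   above).
#' @param floors Named vector of constant overlap floors for
#'   `gelator_overlapped` windows: the area of the interfering solvent
#'   satellite in units of the per-proton gelator plateau area (0.08 is 4% of
#'   a 2H gelator plateau).
#' @param noise `"reference"` (clean-gelator plateau peak SNR of 50), `"harsh"`
#'   (SNR 5), `"none"`, or a numeric noise standard deviation in intensity
#'   units.
#' @param linewidth_ppm Lorentzian FWHM of the gelator peaks.
#' @param solvent_linewidth_ppm FWHM of the solvent and reference singlets
#'   (sharper than the gelator multiplet envelopes).
#' @param satellite_linewidth_ppm FWHM of the overlapping solvent satellite.
#' @param ref_area,vinyl_area Constant areas of the reference and solvent
#'   peaks in units of the per-proton gelator plateau area. The defaults
#'   mirror a ~1 wt% 18-proton internal standard and the 3 vinyl protons of a
#'   triacylglycerol solvent against a ~4 wt% gelator: the solvent signals
#'   are an order of magnitude larger than the gelator's, so the normalizer's
#'   own integration noise is minor.
#' @param ref_drift Fractional linear drift of the reference area across the
#'   ramp (0 = ideal internal standard).
#' @param drift_ppm Chemical-shift drift applied to every spectrum (tests the
#'   re-referencing step).
#' @return List of class `"synthetic_truth"`, including the derived `T_m_C`
#'   for the two-polymorph model.
#' @export
synthetic_truth <- function(type = c("single", "two_polymorph"),
                            W_D = if (match.arg(type) == "single") 4.0 else 5.0,
                            T_m_C = 80, B_K = 9500,
                            T_GG_C = 22, w_corner = 2.0,
                            B_below_K = 22000, B_above_K = 3100,
                            floors = c(CH2O = 0.08),
                            noise = "reference",
                            linewidth_ppm = 0.010,
                            solvent_linewidth_ppm = 0.006,
                            satellite_linewidth_ppm = 0.012,
                            ref_area = 7.7, vinyl_area = 24,
                            ref_drift = 0, drift_ppm = 0) {
  type <- match.arg(type)
  if (W_D <= 0) stop("`W_D` must be positive (wt%).", call. = FALSE)
  if (any(floors < 0)) stop("Overlap floors must be >= 0.", call. = FALSE)
  if (type == "two_polymorph") {
    if (w_corner <= 0 || w_corner >= W_D) {
      stop("`w_corner` must lie strictly between 0 and W_D.", call. = FALSE)
    }
    # stable-branch crossing of w = W defines T_m
    inv_tm <- 1 / (T_GG_C + 273.15) - log(W_D / w_corner) / B_above_K
    T_m_C <- 1 / inv_tm - 273.15
  }
  structure(
    list(type = type, W_D = W_D, T_m_C = T_m_C, B_K = B_K, T_GG_C = T_GG_C,
         w_corner = w_corner, B_below_K = B_below_K, B_above_K = B_above_K,
         floors = floors, noise = noise, linewidth_ppm = linewidth_ppm,
         solvent_linewidth_ppm = solvent_linewidth_ppm,
         satellite_linewidth_ppm = satellite_linewidth_ppm,
         ref_area = ref_area, vinyl_area = vinyl_area,
         ref_drift = ref_drift, drift_ppm = drift_ppm),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %s, W = %.2f wt%% (D-basis), T_m = %.1f degC",
              x$type, x$W_D, x$T_m_C))
  if (x$type == "two_polymorph") cat(sprintf(", T_GG = %.1f degC", x$T_GG_C))
  cat("\n")
  invisible(x)
}

#' True soluble fraction of a synthetic experiment
#'
#' @param truth A `"synthetic_truth"`.
#' @param temperature_C Temperatures in degC.
#' @return True soluble weight fraction(s), wt% D-basis (non-decreasing,
#'   equal to `W_D` at and above `T_m_C`).
#' @export
true_solubility <- function(truth, temperature_C) {
  t_k <- temperature_C + 273.15
  w <- if (truth$type == "single") {
    truth$W_D * exp(-truth$B_K * (1 / t_k - 1 / (truth$T_m_C + 273.15)))
  } else {
    x_gg <- 1 / (truth$T_GG_C + 273.15)
    b <- ifelse(temperature_C < truth$T_GG_C, truth$B_below_K, truth$B_above_K)
    truth$w_corner * exp(-b * (1 / t_k - x_gg))
  }
  pmin(w, truth$W_D)
}

#' Invert the true solubility curve
#'
#' @param truth A `"synthetic_truth"`.
#' @param w_wtpct_D Soluble fraction(s), wt% D-basis, in (0, W_D].
#' @return Liquidus temperature(s) in degC.
#' @export
true_liquidus_temperature <- function(truth, w_wtpct_D) {
  if (any(w_wtpct_D <= 0 | w_wtpct_D > truth$W_D)) {
    stop("`w_wtpct_D` must lie in (0, W_D].", call. = FALSE)
  }
  if (truth$type == "single") {
    inv <- 1 / (truth$T_m_C + 273.15) + log(truth$W_D / w_wtpct_D) / truth$B_K
    return(1 / inv - 273.15)
  }
  x_gg <- 1 / (truth$T_GG_C + 273.15)
  below <- w_wtpct_D < truth$w_corner
  b <- ifelse(below, truth$B_below_K, truth$B_above_K)
  inv <- x_gg + log(truth$w_corner / w_wtpct_D) / b
  1 / inv - 273.15
}

#' Default synthetic peak windows
#'
#' Four windows mirroring an amide-gelator/triacylglycerol system: a clean
#' 1H gelator peak ("NH"), a 2H gelator peak overlapped by a solvent satellite
#' ("CH2O"), the solvent vinyl peak ("vinyl", the normalizer) and the internal
#' reference at 0.144 ppm ("BTMSA"). Windows are 0.7 ppm wide so that, at the
#' default line width, Lorentzian tail truncation plus edge effects stay
#' within ~2% of the peak area. The quiet region 7.06-7.45 ppm is peak-free.
#'
#' @return A [peak_windows()] tibble with a `quiet_region` attribute.
#' @export
default_windows <- function() {
  peak_windows(tibble::tibble(
    name = c("NH", "CH2O", "vinyl", "BTMSA"),
    ppm_lo = c(6.10, 3.35, 5.05, -0.206),
    ppm_hi = c(6.80, 4.05, 5.75, 0.494),
    multiplicity = c(1L, 2L, 3L, 18L),
    role = c("gelator", "gelator_overlapped", "solvent", "reference")
  ), quiet_region = c(7.06, 7.45))
}

#' Default temperature grids for the two solubility models
#'
#' 25 steps of 2 degC placed so the series spans well below the reliability
#' limit up to several points above full dissolution.
#'
#' @param truth A `"synthetic_truth"`.
#' @export
default_temperatures <- function(truth) {
  if (truth$type == "single") seq(42, 90, by = 2) else seq(12, 60, by = 2)
}

# Lorentzian with the far wings removed: the level at +/- support is
# subtracted and the shape clipped to zero outside, emulating spectra whose
# smooth inter-peak background has been baseline-corrected away. The window
# mass stays closed-form (see lorentzian_window_mass()).
lorentzian <- function(ppm, center, gamma, area, support = 0.6) {
  d <- ppm - center
  l0 <- area / pi * gamma / (support^2 + gamma^2)
  y <- area / pi * gamma / (d^2 + gamma^2) - l0
  y[abs(d) > support | y < 0] <- 0
  y
}

#' Closed-form window mass of the simulator line shape
#'
#' Integral over `[lo, hi]` of the baseline-corrected Lorentzian used by
#' [generate_series()] (wing level at `+/- support` subtracted, zero
#' outside). Serves as an independent oracle for integration tests and for
#' the effective injected floor.
#'
#' @param lo,hi Window bounds, ppm.
#' @param center,gamma_ppm,area Peak centre (ppm), half width at half maximum
#'   (ppm) and total Lorentzian area.
#' @param support Wing clipping half-width, ppm.
#' @export
lorentzian_window_mass <- function(lo, hi, center, gamma_ppm, area,
                                   support = 0.6) {
  b1 <- max(lo - center, -support)
  b2 <- min(hi - center, support)
  if (b2 <= b1) return(0)
  l0 <- area / pi * gamma_ppm / (support^2 + gamma_ppm^2)
  area / pi * (atan(b2 / gamma_ppm) - atan(b1 / gamma_ppm)) - l0 * (b2 - b1)
}

noise_sigma <- function(truth) {
  if (is.numeric(truth$noise)) return(truth$noise)
  gamma <- truth$linewidth_ppm / 2
  height <- 1 / (pi * gamma) # per-proton plateau area is 1
  switch(truth$noise,
         reference = height / 50,
         harsh = height / 5,
         none = 0,
         stop("Unknown noise preset: ", truth$noise, call. = FALSE))
}

#' Generate a synthetic spectrum series
#'
#' Builds one frequency-domain spectrum per temperature from Lorentzian
#' peaks: each gelator window carries a peak at its centre with area
#' `multiplicity * w*(T) / W` (per-proton plateau area 1), the solvent and
#' reference peaks have constant area, each `gelator_overlapped` window
#' additionally receives a constant solvent satellite (the floor), and white
#' Gaussian noise sets the SNR. A fixed seed gives bit-identical output.
#'
#' @param truth A `"synthetic_truth"`.
#' @param windows Window set; needs at least one clean gelator, one
#'   overlapped gelator, one solvent and one reference window. Floors are
#'   matched to overlapped windows by name.
#' @param temperatures Temperature grid, degC (default per
#'   [default_temperatures()]).
#' @param seed Integer seed.
#' @param ppm_range,delta_ppm Axis range and spacing.
#' @return A `"spectrum_series"` with the truth attached as attribute
#'   `"truth"`.
#' @export
generate_series <- function(truth, windows = default_windows(),
                            temperatures = default_temperatures(truth),
                            seed = 1L,
                            ppm_range = c(-0.5, 7.5), delta_ppm = 5e-4) {
  windows <- peak_windows(windows)
  for (role in c("gelator", "gelator_overlapped", "solvent", "reference")) {
    if (!any(windows$role == role)) {
      stop("`windows` must include a window with role \"", role, "\".",
           call. = FALSE)
    }
  }
  over <- windows$name[windows$role == "gelator_overlapped"]
  miss <- setdiff(over, names(truth$floors))
  if (length(miss) > 0) {
    stop("No floor defined for overlapped window(s): ",
         paste(miss, collapse = ", "), ".", call. = FALSE)
  }
  gamma <- truth$linewidth_ppm / 2
  gamma_solv <- truth$solvent_linewidth_ppm / 2
  gamma_sat <- truth$satellite_linewidth_ppm / 2
  too_wide <- 2 * gamma > (windows$ppm_hi - windows$ppm_lo) / 10
  if (any(too_wide)) {
    warning("Peak width is large relative to window(s) ",
            paste(windows$name[too_wide], collapse = ", "),
            "; truncation will exceed ~2%.")
  }
  ax <- seq(ppm_range[1], ppm_range[2], by = delta_ppm)
  n_t <- length(temperatures)
  w_true <- true_solubility(truth, temperatures)
  sigma <- noise_sigma(truth)
  set.seed(as.integer(seed))
  centers <- (windows$ppm_lo + windows$ppm_hi) / 2
  ref_scale <- if (n_t > 1) {
    1 + truth$ref_drift * (seq_len(n_t) - 1) / (n_t - 1)
  } else rep(1, n_t)
  mat <- matrix(0, nrow = length(ax), ncol = n_t)
  for (j in seq_len(n_t)) {
    y <- numeric(length(ax))
    for (i in seq_len(nrow(windows))) {
      area <- switch(windows$role[i],
                     gelator = ,
                     gelator_overlapped =
                       windows$multiplicity[i] * w_true[j] / truth$W_D,
                     solvent = truth$vinyl_area,
                     reference = truth$ref_area * ref_scale[j])
      g <- if (windows$role[i] %in% c("solvent", "reference")) gamma_solv else
        gamma
      y <- y + lorentzian(ax, centers[i] + truth$drift_ppm, g, area)
      if (windows$role[i] == "gelator_overlapped") {
        sat_center <- windows$ppm_lo[i] + 0.17
        y <- y + lorentzian(ax, sat_center + truth$drift_ppm, gamma_sat,
                            truth$floors[[windows$name[i]]])
      }
    }
    if (sigma > 0) y <- y + stats::rnorm(length(ax), sd = sigma)
    mat[, j] <- y
  }
  spectra <- tibble::tibble(
    temperature_C = rep(temperatures, each = length(ax)),
    ppm = rep(ax, times = n_t),
    intensity = as.vector(mat)
  )
  meta <- list(
    W_wt_percent = truth$W_D,
    gelator_formula = "C18H37NO2",
    solvent_formula = "C57H104O6",
    n_deuterium = 101L,
    schedule = list(step_C = 2, equilibration_s = 420, scans = 32,
                    relaxation_delay_s = 30),
    seed = as.integer(seed)
  )
  out <- spectrum_series(spectra, metadata = meta)
  attr(out, "truth") <- truth
  out
}

#' Ground-truth liquidus table for recovery scoring
#'
#' @param truth A `"synthetic_truth"`.
#' @param temperatures Temperature grid, degC.
#' @return Tibble `temperature_C`, `w_wtpct_D` with attributes `T_m_true`,
#'   `T_GG_true` (two-polymorph only) and `floors`; the table follows the
#'   integral-table schema and round-trips through [write_integral_table()].
#' @export
truth_report <- function(truth, temperatures = default_temperatures(truth)) {
  out <- tibble::tibble(
    temperature_C = temperatures,
    w_wtpct_D = true_solubility(truth, temperatures)
  )
  attr(out, "T_m_true") <- truth$T_m_C
  if (truth$type == "two_polymorph") attr(out, "T_GG_true") <- truth$T_GG_C
  attr(out, "floors") <- truth$floors
  out
}

#' Write a complete synthetic experiment to a directory
#'
#' Emits the spectra plus `manifest.yaml` (via [write_spectrum_series()]),
#' the window configuration (`windows.yaml`) and the ground-truth liquidus
#' table (`truth.csv`).
#'
#' @inheritParams generate_series
#' @param dir Output directory.
#' @return Named list of the written paths, invisibly.
#' @export
write_synthetic_experiment <- function(truth, dir, windows = default_windows(),
                                       temperatures = default_temperatures(truth),
                                       seed = 1L) {
  series <- generate_series(truth, windows = windows,
                            temperatures = temperatures, seed = seed)
  manifest <- write_spectrum_series(series, dir)
  wpath <- file.path(dir, "windows.yaml")
  write_peak_windows(windows, wpath)
  tpath <- file.path(dir, "truth.csv")
  tr <- truth_report(truth, temperatures)
  hdr <- sprintf("# T_m_true=%.4f%s", truth$T_m_C,
                 if (truth$type == "two_polymorph")
                   sprintf(" T_GG_true=%.4f", truth$T_GG_C) else "")
  writeLines(c(hdr, "temperature_C,w_wtpct_D",
               sprintf("%.6g,%.8g", tr$temperature_C, tr$w_wtpct_D)), tpath)
  invisible(list(manifest = manifest, windows = wpath, truth = tpath))
}

#' Effective heating rate of a stepped VT acquisition
#'
#' A stepped ramp spends `equilibration_s + scans * (relaxation_delay_s +
#' extra_s)` seconds per `step_C` increment; the effective rate is the step
#' divided by that time, in degC/min. The standard schedule (2 degC steps,
#' 7 min equilibration, 32 scans with a 30 s relaxation delay) gives
#' 0.087 degC/min.
#'
#' @param step_C Temperature increment per step, degC.
#' @param equilibration_s Equilibration time after each increment, s.
#' @param scans Number of scans per spectrum.
#' @param relaxation_delay_s Relaxation delay per scan, s.
#' @param extra_s Additional per-scan time (acquisition, pulsing), s.
#' @return Heating rate in degC/min (full precision; round to 3 decimals for
#'   reporting).
#' @examples
#' effective_heating_rate(2, 420, 32, 30) # ~0.087
#' @export
effective_heating_rate <- function(step_C, equilibration_s, scans,
                                   relaxation_delay_s, extra_s = 0) {
  if (is.list(step_C)) {
    s <- step_C
    return(effective_heating_rate(s$step_C, s$equilibration_s, s$scans,
                                  s$relaxation_delay_s, s$extra_s %||% 0))
  }
  vals <- c(step_C, equilibration_s, scans, relaxation_delay_s)
  if (any(!is.finite(vals)) || any(vals <= 0) || extra_s < 0) {
    stop("Schedule quantities must be positive (extra_s >= 0).", call. = FALSE)
  }
  total_s <- equilibration_s + scans * (relaxation_delay_s + extra_s)
  60 * step_C / total_s
}
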