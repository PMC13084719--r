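# Window integration with a noise-driven error model, and normalization to
# the internal reference or to the solvent vinyl signal.

#' Estimate per-spectrum baseline noise
#'
#' Robust per-point noise of each spectrum, computed in a signal-free ppm
#' interval as 1.4826 times the median absolute deviation of the residuals
#' about a local linear baseline (so slow baseline drift does not inflate the
#' estimate).
#'
#' @param series A `"spectrum_series"`.
#' @param quiet_region Length-2 ppm interval containing no configured peak and
#'   at least 32 axis points.
#' @param windows Optional window set; if given, the quiet region is checked
#'   for overlap against every window.
#' @return Tibble with `temperature_C`, `sigma_noise`.
#' @export
estimate_noise <- function(series, quiet_region, windows = NULL) {
  if (length(quiet_region) != 2L || quiet_region[1] >= quiet_region[2]) {
    stop("`quiet_region` must be an increasing length-2 ppm interval.",
         call. = FALSE)
  }
  if (!is.null(windows)) {
    windows <- peak_windows(windows)
    hit <- windows$ppm_lo < quiet_region[2] & windows$ppm_hi > quiet_region[1]
    if (any(hit)) {
      stop("Quiet region overlaps configured window(s): ",
           paste(windows$name[hit], collapse = ", "), ".", call. = FALSE)
    }
  }
  ax <- ppm_axis(series)
  idx <- which(ax >= quiet_region[1] & ax <= quiet_region[2])
  if (length(idx) < 32L) {
    stop("Quiet region must contain at least 32 axis points (has ",
         length(idx), ").", call. = FALSE)
  }
  x <- ax[idx] - mean(ax[idx])
  sxx <- sum(x^2)
  mat <- intensity_matrix(series)
  tt <- series_temperatures(series)
  sig <- vapply(seq_along(tt), function(j) {
    y <- mat[idx, j]
    slope <- sum(x * y) / sxx
    resid <- y - mean(y) - slope * x
    stats::mad(resid, center = 0)
  }, numeric(1))
  tibble::tibble(temperature_C = tt, sigma_noise = sig)
}

trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  d <- diff(x)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

#' Integrate peak windows over a temperature series
#'
#' Trapezoidal integration of each configured window in every spectrum. The
#' default assumes baseline-corrected (pre-phased, drift-free) input and
#' integrates against a zero baseline; `baseline = "edges"` first subtracts a
#' linear baseline through the medians of the outermost `edge_frac` of points
#' on either side of the window, for data with residual baseline drift. The
#' 1-sigma integration error is the white-noise standard deviation of the
#' trapezoidal sum, `sigma_noise * dppm * sqrt(n_points)`.
#'
#' @param series A `"spectrum_series"` (aligned; see [align_reference()]).
#' @param windows Window set from [peak_windows()].
#' @param quiet_region Noise-estimation interval; defaults to the window set's
#'   attribute.
#' @param baseline `"none"` (default) or `"edges"`.
#' @param edge_frac Fraction of window points used per edge anchor.
#' @return Long trace tibble: `window`, `role`, `multiplicity`,
#'   `temperature_C`, `raw`, `sigma_raw`.
#' @export
integrate_windows <- function(series, windows,
                              quiet_region = attr(windows, "quiet_region", exact = TRUE),
                              baseline = c("none", "edges"),
                              edge_frac = 0.05) {
  baseline <- match.arg(baseline)
  windows <- peak_windows(windows)
  ax <- ppm_axis(series)
  out_lo <- windows$ppm_lo < min(ax)
  out_hi <- windows$ppm_hi > max(ax)
  if (any(out_lo | out_hi)) {
    stop("Window(s) outside the ppm axis range: ",
         paste(windows$name[out_lo | out_hi], collapse = ", "), ".",
         call. = FALSE)
  }
  if (is.null(quiet_region)) {
    stop("No `quiet_region` available for the noise estimate.", call. = FALSE)
  }
  noise <- estimate_noise(series, quiet_region, windows = windows)
  mat <- intensity_matrix(series)
  tt <- series_temperatures(series)
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    idx <- which(ax >= windows$ppm_lo[i] & ax <= windows$ppm_hi[i])
    if (length(idx) < 4L) {
      stop(sprintf("Window \"%s\" covers fewer than 4 axis points.",
                   windows$name[i]), call. = FALSE)
    }
    x <- ax[idx]
    sub <- mat[idx, , drop = FALSE]
    if (baseline == "edges") {
      k <- max(3L, ceiling(edge_frac * length(idx)))
      lo_v <- apply(sub[seq_len(k), , drop = FALSE], 2, stats::median)
      hi_v <- apply(sub[(length(idx) - k + 1L):length(idx), , drop = FALSE],
                    2, stats::median)
      x_lo <- mean(x[seq_len(k)])
      x_hi <- mean(x[(length(idx) - k + 1L):length(idx)])
      slope <- (hi_v - lo_v) / (x_hi - x_lo)
      # subtract the per-column line lo_v + slope * (x - x_lo)
      sub <- sub - outer(x - x_lo, slope) -
        matrix(lo_v, nrow = length(idx), ncol = ncol(sub), byrow = TRUE)
    }
    w <- trapz_weights(x)
    raw <- as.vector(crossprod(sub, w))
    dppm <- mean(diff(x))
    tibble::tibble(
      window = windows$name[i],
      role = windows$role[i],
      multiplicity = windows$multiplicity[i],
      temperature_C = tt,
      raw = raw,
      sigma_raw = noise$sigma_noise * dppm * sqrt(length(idx))
    )
  })
}

#' Normalize integral traces to a reference or solvent window
#'
#' Divides every raw trace by the raw trace of the normalizer window at the
#' same temperature (internal-standard quantification: the normalizer's
#' concentration is temperature-independent). The 1-sigma error of the ratio
#' follows from first-order propagation of the two integration errors.
#'
#' @param traces Trace tibble from [integrate_windows()] or
#'   [traces_from_table()].
#' @param normalizer Name of the normalizer window (typically the reference or
#'   the solvent vinyl window); the choice is explicit, never automatic.
#' @return The traces with added `normalized` and `sigma_norm` columns.
#' @export
normalize_traces <- function(traces, normalizer) {
  if (!normalizer %in% traces$window) {
    stop(sprintf("Normalizer window \"%s\" not present in traces.", normalizer),
         call. = FALSE)
  }
  norm <- dplyr::select(
    dplyr::filter(traces, .data$window == normalizer),
    "temperature_C", norm_raw = "raw", norm_sigma = "sigma_raw"
  )
  bad <- norm$temperature_C[norm$norm_raw <= 0]
  if (length(bad) > 0) {
    stop("Non-positive normalizer integral at temperature(s): ",
         paste(format(bad), collapse = ", "), " degC.", call. = FALSE)
  }
  out <- dplyr::left_join(traces, norm, by = "temperature_C")
  out <- dplyr::mutate(
    out,
    normalized = .data$raw / .data$norm_raw,
    sigma_norm = sqrt(.data$sigma_raw^2 +
                        (.data$normalized * .data$norm_sigma)^2) / .data$norm_raw
  )
  dplyr::select(out, -"norm_raw", -"norm_sigma")
}

#' Check that the solvent and reference signals evolve in parallel
#'
#' An inert internal standard must track the solvent signal up to a constant
#' factor across the whole ramp; systematic drift of the ratio indicates
#' interaction with the oil or instability of either signal. The ratio's
#' relative spread (max minus min, over the mean) is compared against
#' `tolerance`; the largest deviation from the mean ratio and the temperature
#' where it occurs are reported as diagnostics.
#'
#' @param traces Trace tibble containing both windows.
#' @param window_a,window_b Window names whose raw-integral ratio is examined
#'   (e.g. solvent vinyl vs. reference).
#' @param tolerance Maximum tolerated relative spread of the ratio.
#' @return One-row tibble: `pass`, `spread`, `max_abs_deviation`,
#'   `temperature_C`, `tolerance`.
#' @export
reference_consistency_check <- function(traces, window_a, window_b,
                                        tolerance = 0.05) {
  a <- dplyr::arrange(dplyr::filter(traces, .data$window == window_a),
                      .data$temperature_C)
  b <- dplyr::arrange(dplyr::filter(traces, .data$window == window_b),
                      .data$temperature_C)
  if (nrow(a) == 0 || nrow(b) == 0 ||
      !isTRUE(all.equal(a$temperature_C, b$temperature_C))) {
    stop("Both windows must be present on the same temperatures.", call. = FALSE)
  }
  ratio <- a$raw / b$raw
  dev <- ratio / mean(ratio) - 1
  k <- which.max(abs(dev))
  spread <- (max(ratio) - min(ratio)) / mean(ratio)
  tibble::tibble(
    pass = spread <= tolerance,
    spread = spread,
    max_abs_deviation = abs(dev[k]),
    temperature_C = a$temperature_C[k],
    tolerance = tolerance
  )
}
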