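# Plateau detection (I_max, T_m), the solvent overlap floor correction delta,
# and its bounded fine-tuning.

# Core plateau scan on one trace (T ascending): the longest terminal run
# whose points all lie within rel_tol * |run mean| + 2 * sigma(point) of the
# run mean (the noise term is zero for noise-free input).
find_plateau <- function(temperature, value, sigma, rel_tol) {
  n <- length(value)
  run <- NULL
  for (k in n:3) {
    cand <- (n - k + 1L):n
    mu <- mean(value[cand])
    tol <- rel_tol * abs(mu) + 2 * sigma[cand]
    if (all(abs(value[cand] - mu) <= tol)) {
      run <- cand
      break
    }
  }
  if (is.null(run)) {
    return(NULL)
  }
  i_max <- mean(value[run])
  thr <- i_max * (1 - rel_tol) - 2 * sigma
  t_m <- temperature[which(value >= thr)[1]]
  list(I_max = i_max, sigma_Imax = stats::sd(value[run]), T_m = t_m,
       n_plateau = length(run), T_plateau_min = temperature[run[1]])
}

#' Estimate the full-dissolution plateau of each gelator trace
#'
#' Above the melting temperature T_m the gelator is fully dissolved and its
#' normalized integral is constant at I_max. Scanning from the highest
#' temperature downward, the plateau is the longest terminal run whose points
#' stay within `rel_tol` of the running terminal mean (widened by twice the
#' point's own integration error, so finite-noise traces are not truncated
#' spuriously); I_max is the run mean, its error the run standard deviation,
#' and T_m the lowest temperature whose intensity reaches
#' `(1 - rel_tol) * I_max` (again less twice the point's integration error).
#'
#' @param traces Normalized trace tibble (see [normalize_traces()]).
#' @param rel_tol Relative plateau tolerance (default 2%, matching the typical
#'   plateau scatter of the method).
#' @param value Column to analyse: `"normalized"` (default), `"corrected"` or
#'   `"raw"`.
#' @param roles Window roles to analyse; defaults to the gelator roles.
#' @return Tibble with one row per window: `window`, `role`, `multiplicity`,
#'   `I_max`, `sigma_Imax`, `T_m`, `n_plateau`, `T_plateau_min`.
#' @export
estimate_plateau <- function(traces, rel_tol = 0.02, value = "normalized",
                             roles = c("gelator", "gelator_overlapped")) {
  if (!value %in% names(traces)) {
    stop(sprintf("Column \"%s\" not present; normalize or correct first.", value),
         call. = FALSE)
  }
  sig_col <- switch(value, normalized = "sigma_norm", corrected = "sigma_corrected",
                    raw = "sigma_raw", NULL)
  use <- dplyr::filter(traces, .data$role %in% roles)
  purrr::map_dfr(split(use, use$window), function(d) {
    d <- dplyr::arrange(d, .data$temperature_C)
    if (nrow(d) < 4L) {
      stop(sprintf("Trace \"%s\" has fewer than 4 temperatures.", d$window[1]),
           call. = FALSE)
    }
    sigma <- if (!is.null(sig_col) && sig_col %in% names(d)) d[[sig_col]] else
      rep(0, nrow(d))
    p <- find_plateau(d$temperature_C, d[[value]], sigma, rel_tol)
    if (is.null(p)) {
      stop(sprintf(paste0("No plateau found for window \"%s\": fewer than 3 ",
                          "qualifying terminal points (trace likely truncated ",
                          "below full dissolution)."), d$window[1]), call. = FALSE)
    }
    tibble::tibble(window = d$window[1], role = d$role[1],
                   multiplicity = d$multiplicity[1], I_max = p$I_max,
                   sigma_Imax = p$sigma_Imax, T_m = p$T_m,
                   n_plateau = p$n_plateau, T_plateau_min = p$T_plateau_min)
  })
}

#' Raw overlap floor offset from plateau bookkeeping
#'
#' A gelator window that overlaps solvent signals carries a constant excess
#' ("floor") integral delta, visible both as a non-zero residue at low
#' temperature and as an excess of its plateau over the multiplicity-scaled
#' plateau of a clean gelator window:
#' `delta_raw = I_max(overlapped) - (m_over/m_clean) * I_max(clean)`
#' (the NH/CH2OH case of a 1H clean and 2H overlapped peak gives
#' `delta = I_max(CH2OH) - 2 I_max(NH)`).
#'
#' @param plateaus Plateau tibble from [estimate_plateau()].
#' @param overlapped,clean Window names.
#' @return One-row tibble: `window`, `clean_window`, `m_ratio`, `delta_raw`,
#'   `sigma_delta`, `I_max_over` (the overlapped plateau, which scales the
#'   fine-tuning bound).
#' @export
floor_offset <- function(plateaus, overlapped, clean) {
  po <- dplyr::filter(plateaus, .data$window == overlapped)
  pc <- dplyr::filter(plateaus, .data$window == clean)
  if (nrow(po) != 1L || nrow(pc) != 1L) {
    stop("`plateaus` must contain exactly one row for each of the overlapped ",
         "and clean windows.", call. = FALSE)
  }
  m_ratio <- po$multiplicity / pc$multiplicity
  delta_raw <- po$I_max - m_ratio * pc$I_max
  sigma_delta <- sqrt(po$sigma_Imax^2 + (m_ratio * pc$sigma_Imax)^2)
  if (delta_raw < -2 * sigma_delta) {
    warning(sprintf(paste0("Negative floor offset beyond 2 sigma for \"%s\" ",
                           "(delta_raw = %.4g, sigma = %.4g): overlap model ",
                           "violated."), overlapped, delta_raw, sigma_delta))
  }
  tibble::tibble(window = overlapped, clean_window = clean, m_ratio = m_ratio,
                 delta_raw = delta_raw, sigma_delta = sigma_delta,
                 I_max_over = po$I_max)
}

#' Fine-tune the floor offset within a bounded range
#'
#' The raw floor estimate inherits the finite precision of the plateau means,
#' which can leave residual offsets or negative corrected values at low
#' temperature. The offset is therefore adjusted, within
#' `delta_raw +/- bound * I_max(overlapped)` (default +/-4%), to the value that
#' least-squares aligns the per-proton corrected trace with the per-proton
#' clean trace over temperatures at or above `T_floor`. An optimum pinned at
#' the bound is reported with a warning (overlap larger than the correction
#' model assumes). Residual corrected values below -2 sigma are flagged, never
#' clipped.
#'
#' @param traces Normalized trace tibble.
#' @param offset One-row tibble from [floor_offset()].
#' @param plateaus Plateau tibble (for I_max of the overlapped window).
#' @param bound Relative tuning bound (fraction of I_max; default 0.04).
#' @param T_floor Lowest temperature entering the alignment objective; by
#'   default the lowest temperature at which the clean trace's relative
#'   integration error is below 50%.
#' @return The `offset` row with added `delta_tuned`, `pinned`, `T_floor`.
#' @export
fine_tune_offset <- function(traces, offset, plateaus, bound = 0.04,
                             T_floor = NULL) {
  ov <- dplyr::arrange(dplyr::filter(traces, .data$window == offset$window),
                       .data$temperature_C)
  cl <- dplyr::arrange(dplyr::filter(traces, .data$window == offset$clean_window),
                       .data$temperature_C)
  po <- dplyr::filter(plateaus, .data$window == offset$window)
  if (is.null(T_floor)) {
    rel <- cl$sigma_norm / abs(cl$normalized)
    ok <- which(is.finite(rel) & rel < 0.5 & cl$normalized > 0)
    T_floor <- if (length(ok) > 0) min(cl$temperature_C[ok]) else
      min(cl$temperature_C)
  }
  keep <- ov$temperature_C >= T_floor
  if (!any(keep)) {
    stop("`T_floor` excludes every temperature from the tuning objective.",
         call. = FALSE)
  }
  m_ratio <- offset$m_ratio
  cand <- mean(ov$normalized[keep] - m_ratio * cl$normalized[keep])
  lo <- offset$delta_raw - bound * offset$I_max_over
  hi <- offset$delta_raw + bound * offset$I_max_over
  delta_tuned <- min(max(cand, lo), hi)
  pinned <- bound > 0 && (delta_tuned == lo || delta_tuned == hi) &&
    cand != delta_tuned
  if (pinned) {
    warning(sprintf(paste0("Fine-tuned offset for \"%s\" pinned at the +/-%g%% ",
                           "bound; overlap exceeds the correction regime."),
                    offset$window, 100 * bound))
  }
  resid <- ov$normalized - delta_tuned
  n_neg <- sum(resid < -2 * ov$sigma_norm)
  dplyr::mutate(offset, delta_tuned = delta_tuned, pinned = pinned,
                T_floor = T_floor, n_flagged_negative = n_neg)
}

#' Apply the overlap correction to a normalized trace set
#'
#' Runs [floor_offset()] + [fine_tune_offset()] for every
#' `role = "gelator_overlapped"` window against the designated clean gelator
#' window, subtracts the tuned offsets, and re-estimates plateaus on the
#' corrected traces. Clean gelator traces pass through unchanged
#' (`corrected = normalized`).
#'
#' @param traces Normalized trace tibble.
#' @param clean Name of the clean gelator window; defaults to the single
#'   `role = "gelator"` window.
#' @param rel_tol Plateau tolerance passed to [estimate_plateau()].
#' @param bound Tuning bound passed to [fine_tune_offset()].
#' @param T_floor Optional tuning floor temperature.
#' @param plateaus Optional pre-computed plateau tibble (normalized values).
#' @return List of class `"overlap_correction"`: `traces` (with `corrected`,
#'   `sigma_corrected`), `corrections`, `plateaus` (re-estimated on corrected
#'   values), `clean_window`.
#' @export
correct_traces <- function(traces, clean = NULL, rel_tol = 0.02, bound = 0.04,
                           T_floor = NULL, plateaus = NULL) {
  gel <- unique(traces$window[traces$role == "gelator"])
  if (is.null(clean)) {
    if (length(gel) != 1L) {
      stop("Specify `clean`: ", length(gel), " windows have role \"gelator\".",
           call. = FALSE)
    }
    clean <- gel
  }
  if (!clean %in% traces$window) {
    stop(sprintf("Clean window \"%s\" not present in traces.", clean),
         call. = FALSE)
  }
  if (is.null(plateaus)) {
    plateaus <- estimate_plateau(traces, rel_tol = rel_tol)
  }
  over <- unique(traces$window[traces$role == "gelator_overlapped"])
  corrections <- purrr::map_dfr(over, function(wn) {
    off <- floor_offset(plateaus, wn, clean)
    fine_tune_offset(traces, off, plateaus, bound = bound, T_floor = T_floor)
  })
  out <- dplyr::mutate(
    traces,
    corrected = .data$normalized,
    sigma_corrected = .data$sigma_norm
  )
  if (nrow(corrections) > 0) {
    shift <- stats::setNames(corrections$delta_tuned, corrections$window)
    hit <- out$window %in% names(shift)
    out$corrected[hit] <- out$normalized[hit] - shift[out$window[hit]]
  }
  plateaus_corr <- estimate_plateau(out, rel_tol = rel_tol, value = "corrected")
  structure(
    list(traces = out, corrections = corrections, plateaus = plateaus_corr,
         clean_window = clean, rel_tol = rel_tol),
    class = "overlap_correction"
  )
}

#' @export
print.overlap_correction <- function(x, ...) {
  cat(sprintf("<overlap_correction> clean window \"%s\", %d corrected window(s)\n",
              x$clean_window, nrow(x$corrections)))
  if (nrow(x$corrections) > 0) {
    print(dplyr::select(x$corrections, "window", "delta_raw", "delta_tuned",
                        "pinned"))
  }
  invisible(x)
}

#' @export
tidy.overlap_correction <- function(x, ...) x$corrections

#' Check corrected plateau ratios against nominal proton counts
#'
#' After the floor correction, the plateaus of all gelator signals must scale
#' with their proton multiplicities. The achieved multiplicity of a trace is
#' `m_clean * I_max / I_max(clean)`; agreement within `tolerance` (default 4%)
#' validates the window assignment and the correction.
#'
#' @param plateaus Plateau tibble estimated on corrected traces.
#' @param clean Clean gelator window name.
#' @param tolerance Relative tolerance on the achieved multiplicity.
#' @return Tibble: `window`, `nominal`, `achieved`, `rel_deviation`, `pass`.
#' @export
validate_multiplicities <- function(plateaus, clean, tolerance = 0.04) {
  pc <- dplyr::filter(plateaus, .data$window == clean)
  if (nrow(pc) != 1L) {
    stop(sprintf("Clean window \"%s\" not found in `plateaus`.", clean),
         call. = FALSE)
  }
  gel <- dplyr::filter(plateaus,
                       .data$role %in% c("gelator", "gelator_overlapped"))
  out <- dplyr::transmute(
    gel,
    window = .data$window,
    nominal = .data$multiplicity,
    achieved = pc$multiplicity * .data$I_max / pc$I_max,
    rel_deviation = .data$achieved / .data$nominal - 1
  )
  dplyr::mutate(out, pass = abs(.data$rel_deviation) <= tolerance)
}
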