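# End-to-end pipeline: read -> align -> integrate -> normalize -> correct ->
# phase diagram (+ optional corner detection), with an auditable run report.

#' Map an oleogel phase diagram from a VT spectrum series
#'
#' Runs the full analysis: chemical-shift referencing against the internal
#' standard, window integration with the noise-driven error model,
#' normalization, plateau/I_max/T_m estimation, overlap floor correction with
#' bounded fine-tuning, soluble-fraction conversion, the error budget with
#' reliability flags, deuterated-to-protiated concentration conversion, phase
#' diagram assembly and (optionally) gel-gel corner detection.
#'
#' @param x A `"spectrum_series"`, a manifest path (see
#'   [read_spectrum_series()]), or a pre-integrated table read by
#'   [read_integral_table()].
#' @param windows Window set (or path to a windows YAML).
#' @param normalizer Normalizer window name; defaults to the solvent window,
#'   falling back to the reference.
#' @param clean Clean gelator window; defaults to the single
#'   `role = "gelator"` window.
#' @param align Re-reference the ppm axis before integrating (ignored for
#'   pre-integrated input).
#' @param expected_ppm Reference apex position, ppm.
#' @param baseline Integration baseline mode (see [integrate_windows()]).
#' @param reliability_threshold Reliability cutoff on the relative error.
#' @param plateau_rel_tol Plateau tolerance (see [estimate_plateau()]).
#' @param tuning_bound Floor fine-tuning bound (see [fine_tune_offset()]).
#' @param budget An [error_budget()].
#' @param W_D Total concentration (wt%, D-basis); default from the series
#'   metadata.
#' @param conversion An `"isotope_conversion"`; default built from the series
#'   metadata (`solvent_formula`, `n_deuterium`).
#' @param detect_corner Run [detect_gel_gel_corner()] on the result.
#' @param corner_args List of extra arguments for the corner detector.
#' @param overlay Optional overlay table/path (see [attach_overlays()]).
#' @param consistency_tolerance Tolerance for the solvent/reference parallel-
#'   evolution check (skipped when either window is absent).
#' @return Object of class `"liquidus_map"`: fields `diagram`
#'   (`"phase_diagram"`), `traces`, `plateaus`, `corrections`,
#'   `multiplicities`, `consistency`, `corner`, `options`, `metadata`.
#' @export
map_phase_diagram <- function(x, windows,
                              normalizer = NULL, clean = NULL,
                              align = TRUE, expected_ppm = 0.144,
                              baseline = "none",
                              reliability_threshold = 0.20,
                              plateau_rel_tol = 0.02,
                              tuning_bound = 0.04,
                              budget = error_budget(),
                              W_D = NULL, conversion = NULL,
                              detect_corner = FALSE, corner_args = list(),
                              overlay = NULL,
                              consistency_tolerance = 0.05) {
  if (is.character(windows)) windows <- read_peak_windows(windows)
  windows <- peak_windows(windows)
  if (is.null(normalizer)) {
    normalizer <- if (any(windows$role == "solvent")) {
      windows$name[windows$role == "solvent"][1]
    } else {
      windows$name[windows$role == "reference"][1]
    }
  }

  meta <- list()
  if (is.character(x)) x <- read_spectrum_series(x)
  if (inherits(x, "spectrum_series")) {
    meta <- x$metadata
    if (align) x <- align_reference(x, windows, expected_ppm = expected_ppm)
    traces <- integrate_windows(x, windows, baseline = baseline)
  } else {
    meta <- attributes(x)[intersect(names(attributes(x)), "provenance")]
    traces <- traces_from_table(x, windows)
  }

  traces <- normalize_traces(traces, normalizer)

  consistency <- NULL
  solvent_w <- windows$name[windows$role == "solvent"]
  ref_w <- windows$name[windows$role == "reference"]
  if (length(solvent_w) > 0 && length(ref_w) > 0) {
    consistency <- reference_consistency_check(traces, solvent_w[1], ref_w[1],
                                               tolerance = consistency_tolerance)
  }

  corr <- correct_traces(traces, clean = clean, rel_tol = plateau_rel_tol,
                         bound = tuning_bound)
  mult <- validate_multiplicities(corr$plateaus, corr$clean_window)

  if (is.null(W_D)) W_D <- meta$W_wt_percent
  if (is.null(W_D)) {
    stop("Total concentration `W_D` not given and absent from metadata.",
         call. = FALSE)
  }
  if (is.null(conversion)) {
    if (!is.null(meta$solvent_formula) && !is.null(meta$n_deuterium)) {
      conversion <- isotope_mass_ratio(meta$solvent_formula, meta$n_deuterium)
    } else {
      stop("Supply `conversion` (or solvent_formula/n_deuterium metadata).",
           call. = FALSE)
    }
  }

  curves <- soluble_fraction(corr, W_D = W_D)
  curves <- propagate_uncertainty(curves, budget = budget)
  diagram <- assemble_phase_diagram(curves, conversion, W_D = W_D,
                                    threshold = reliability_threshold)

  corner <- NULL
  if (detect_corner) {
    corner <- do.call(detect_gel_gel_corner, c(list(diagram), corner_args))
    diagram$corner <- corner
  }
  if (!is.null(overlay)) diagram <- attach_overlays(diagram, overlay)

  structure(
    list(diagram = diagram, traces = corr$traces, plateaus = corr$plateaus,
         corrections = corr$corrections, multiplicities = mult,
         consistency = consistency, corner = corner,
         options = list(normalizer = normalizer, clean = corr$clean_window,
                        baseline = baseline, align = align,
                        reliability_threshold = reliability_threshold,
                        plateau_rel_tol = plateau_rel_tol,
                        tuning_bound = tuning_bound),
         metadata = meta),
    class = "liquidus_map"
  )
}

#' @export
print.liquidus_map <- function(x, ...) {
  cat("<liquidus_map>\n")
  print(x$diagram)
  if (nrow(x$corrections) > 0) {
    cat(sprintf("  floor offsets: %s\n",
                paste(sprintf("%s delta = %.4f -> %.4f", x$corrections$window,
                              x$corrections$delta_raw, x$corrections$delta_tuned),
                      collapse = "; ")))
  }
  invisible(x)
}

#' @export
tidy.liquidus_map <- function(x, ...) x$diagram$points

#' @export
glance.liquidus_map <- function(x, ...) glance(x$diagram)

#' Write the phase-diagram table and JSON run report
#'
#' The table (`phase_diagram.csv`) holds `source_window`, `T_C`,
#' `w_wtpct_H`, `rel_err`, `reliable`, `segment`; the report (`report.json`)
#' records every intermediate decision: W on both bases, r, per-window T_m
#' and I_max, the raw and fine-tuned floor offsets, achieved multiplicities,
#' corner-detection output and the run options.
#'
#' @param result A `"liquidus_map"`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_run_report <- function(result, dir) {
  stopifnot(inherits(result, "liquidus_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- result$diagram
  tab <- dplyr::transmute(d$points,
                          source_window = .data$source_window,
                          T_C = .data$temperature_C,
                          w_wtpct_H = .data$w_wtpct_H,
                          rel_err = .data$rel_err,
                          reliable = .data$reliable,
                          segment = .data$segment)
  tab_path <- file.path(dir, "phase_diagram.csv")
  utils::write.csv(tab, tab_path, row.names = FALSE, quote = FALSE)
  report <- list(
    W_D_wt_percent = d$W_D,
    W_H_wt_percent = d$W_H,
    r = d$r,
    T_m_C = stats::setNames(as.list(d$T_m$T_m), d$T_m$source_window),
    plateaus = result$plateaus,
    corrections = result$corrections,
    multiplicities = result$multiplicities,
    consistency = result$consistency,
    corner = result$corner,
    options = result$options
  )
  report_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(list(table = tab_path, report = report_path))
}
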