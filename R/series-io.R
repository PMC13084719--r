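# Reading/writing VT spectrum series and integral tables; chemical-shift
# referencing against the internal standard.

peak_roles <- c("gelator", "gelator_overlapped", "solvent", "reference")

#' Define and validate a set of peak integration windows
#'
#' A window set is a tibble with one row per named ppm interval: the clean
#' gelator peaks (`role = "gelator"`, e.g. an amide NH), gelator peaks that
#' overlap with solvent signals (`"gelator_overlapped"`), the solvent peak used
#' for normalization (`"solvent"`, e.g. the triolein vinyl protons) and the
#' inert internal reference (`"reference"`, e.g. BTMSA at 0.144 ppm).
#'
#' @param x Data frame with columns `name`, `ppm_lo`, `ppm_hi`, `multiplicity`
#'   (nominal proton count) and `role`.
#' @param quiet_region Optional length-2 numeric ppm interval free of any
#'   configured peak, used for noise estimation; stored as an attribute.
#' @return A validated tibble with a `quiet_region` attribute.
#' @export
peak_windows <- function(x, quiet_region = attr(x, "quiet_region", exact = TRUE)) {
  x <- tibble::as_tibble(x)
  need <- c("name", "ppm_lo", "ppm_hi", "multiplicity", "role")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("Window set is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$name)) {
    stop("Window names must be unique; duplicated: ",
         paste(unique(x$name[duplicated(x$name)]), collapse = ", "), call. = FALSE)
  }
  if (any(x$ppm_lo >= x$ppm_hi)) {
    stop("Each window needs ppm_lo < ppm_hi (violated by: ",
         paste(x$name[x$ppm_lo >= x$ppm_hi], collapse = ", "), ").", call. = FALSE)
  }
  if (any(x$multiplicity < 1 | x$multiplicity != round(x$multiplicity))) {
    stop("`multiplicity` must be a positive integer for every window.", call. = FALSE)
  }
  bad_role <- setdiff(unique(x$role), peak_roles)
  if (length(bad_role) > 0) {
    stop("Unknown window role(s): ", paste(bad_role, collapse = ", "),
         " (valid: ", paste(peak_roles, collapse = ", "), ").", call. = FALSE)
  }
  if (sum(x$role == "reference") > 1) {
    stop("At most one window may have role = \"reference\".", call. = FALSE)
  }
  if (!any(x$role %in% c("reference", "solvent"))) {
    stop("Window set needs a normalizer: one \"reference\" or \"solvent\" window.",
         call. = FALSE)
  }
  if (!is.null(quiet_region)) {
    if (length(quiet_region) != 2L || quiet_region[1] >= quiet_region[2]) {
      stop("`quiet_region` must be an increasing length-2 ppm interval.",
           call. = FALSE)
    }
    attr(x, "quiet_region") <- as.numeric(quiet_region)
  }
  x
}

#' Read / write a window configuration (YAML)
#'
#' The file holds a `windows:` list of `{name, ppm_lo, ppm_hi, multiplicity,
#' role}` entries and an optional `quiet_region: [lo, hi]`.
#'
#' @param path File path.
#' @return `read_peak_windows()` returns a validated window tibble.
#' @export
read_peak_windows <- function(path) {
  if (!file.exists(path)) stop("Windows file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$windows)) stop("Windows file has no `windows:` entry: ", path,
                               call. = FALSE)
  w <- purrr::map_dfr(y$windows, tibble::as_tibble)
  peak_windows(w, quiet_region = unlist(y$quiet_region))
}

#' @rdname read_peak_windows
#' @param windows A window tibble from [peak_windows()].
#' @export
write_peak_windows <- function(windows, path) {
  windows <- peak_windows(windows)
  out <- list(windows = purrr::transpose(as.list(
    windows[, c("name", "ppm_lo", "ppm_hi", "multiplicity", "role")]
  )))
  qr <- attr(windows, "quiet_region", exact = TRUE)
  if (!is.null(qr)) out$quiet_region <- as.numeric(qr)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Construct a variable-temperature spectrum series
#'
#' @param spectra Long tibble with columns `temperature_C`, `ppm`, `intensity`;
#'   all temperatures must share one strictly monotone ppm axis (a descending
#'   axis is normalized to ascending).
#' @param metadata Named list of sample/acquisition metadata. Recognized
#'   fields: `W_wt_percent` (total gelator weight fraction, deuterated-solvent
#'   basis), `gelator_formula`, `solvent_formula`, `n_deuterium`, `schedule`
#'   (list with `step_C`, `equilibration_s`, `scans`, `relaxation_delay_s`).
#' @return An object of class `"spectrum_series"`.
#' @export
spectrum_series <- function(spectra, metadata = list()) {
  spectra <- tibble::as_tibble(spectra)
  need <- c("temperature_C", "ppm", "intensity")
  miss <- setdiff(need, names(spectra))
  if (length(miss) > 0) {
    stop("`spectra` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  temps <- sort(unique(spectra$temperature_C))
  if (length(temps) < 3L) {
    stop("A spectrum series needs at least 3 distinct temperatures.", call. = FALSE)
  }
  by_t <- split(spectra, spectra$temperature_C)
  axis0 <- by_t[[1]]$ppm
  d0 <- diff(axis0)
  if (all(d0 < 0)) {
    by_t <- lapply(by_t, function(d) d[rev(seq_len(nrow(d))), ])
    axis0 <- rev(axis0)
    d0 <- diff(axis0)
  }
  if (any(d0 <= 0)) {
    stop("The ppm axis must be strictly monotone.", call. = FALSE)
  }
  n0 <- length(axis0)
  for (nm in names(by_t)) {
    ax <- by_t[[nm]]$ppm
    if (all(diff(ax) < 0)) {
      by_t[[nm]] <- by_t[[nm]][rev(seq_len(nrow(by_t[[nm]]))), ]
      ax <- rev(ax)
    }
    if (length(ax) != n0) {
      stop(sprintf("Ragged spectra: %d points at %s degC, expected %d.",
                   length(ax), nm, n0), call. = FALSE)
    }
    if (max(abs(ax - axis0)) > 1e-9) {
      stop(sprintf("Spectrum at %s degC is not on the shared ppm axis.", nm),
           call. = FALSE)
    }
  }
  spectra <- dplyr::bind_rows(by_t[order(as.numeric(names(by_t)))])
  structure(list(spectra = spectra, metadata = metadata),
            class = "spectrum_series")
}

#' @export
print.spectrum_series <- function(x, ...) {
  tt <- series_temperatures(x)
  ax <- ppm_axis(x)
  cat(sprintf("<spectrum_series> %d spectra, %.1f to %.1f degC, %d points (%.4g to %.4g ppm)\n",
              length(tt), min(tt), max(tt), length(ax), min(ax), max(ax)))
  if (!is.null(x$metadata$W_wt_percent)) {
    cat(sprintf("  sample: W = %.3g wt%% (D-solvent basis), gelator %s\n",
                x$metadata$W_wt_percent,
                x$metadata$gelator_formula %||% "?"))
  }
  invisible(x)
}

#' @rdname spectrum_series
#' @param series A `"spectrum_series"`.
#' @export
series_temperatures <- function(series) {
  sort(unique(series$spectra$temperature_C))
}

#' @rdname spectrum_series
#' @export
ppm_axis <- function(series) {
  series$spectra$ppm[series$spectra$temperature_C == series$spectra$temperature_C[1]]
}

# intensity matrix (ppm x temperature), columns ordered by temperature
intensity_matrix <- function(series) {
  tt <- series_temperatures(series)
  n <- nrow(series$spectra) / length(tt)
  matrix(series$spectra$intensity, nrow = n,
         dimnames = list(NULL, format(tt, trim = TRUE)))
}

read_spectrum_file <- function(path) {
  if (!file.exists(path)) stop("Spectrum file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^\\s*#", first) & nzchar(trimws(first))]
  sep <- if (length(first) > 0 && grepl(",", first[1])) "," else ""
  d <- utils::read.table(path, header = FALSE, sep = sep, comment.char = "#",
                         strip.white = TRUE)
  if (ncol(d) < 2L) {
    stop("Spectrum file must have two columns (ppm, intensity): ", path,
         call. = FALSE)
  }
  tibble::tibble(ppm = as.numeric(d[[1]]), intensity = as.numeric(d[[2]]))
}

#' Read a spectrum series from a manifest
#'
#' The manifest is a YAML file with `sample:` metadata (`gelator_formula`,
#' `W_wt_percent`, `solvent_formula`, `n_deuterium`), a `schedule:` block
#' (`step_C`, `equilibration_s`, `scans`, `relaxation_delay_s`) and a `files:`
#' list of `{temperature_C, path}` entries pointing to two-column delimited
#' text spectra (ppm, intensity; `#` comments allowed). Paths are resolved
#' relative to the manifest.
#'
#' @param manifest Path to the manifest file.
#' @return A `"spectrum_series"`, sorted by temperature.
#' @export
read_spectrum_series <- function(manifest) {
  if (!file.exists(manifest)) stop("Manifest not found: ", manifest, call. = FALSE)
  y <- yaml::read_yaml(manifest)
  if (is.null(y$files) || length(y$files) == 0) {
    stop("Manifest lists no spectrum files: ", manifest, call. = FALSE)
  }
  base <- dirname(manifest)
  temps <- purrr::map_dbl(y$files, ~ as.numeric(.x$temperature_C))
  if (anyDuplicated(temps)) {
    stop("Duplicate temperature(s) in manifest: ",
         paste(unique(temps[duplicated(temps)]), collapse = ", "), " degC.",
         call. = FALSE)
  }
  spectra <- purrr::map2_dfr(y$files, temps, function(f, tc) {
    p <- f$path
    if (!file.exists(p)) p <- file.path(base, f$path)
    d <- read_spectrum_file(p)
    d$temperature_C <- tc
    d
  })
  meta <- c(y$sample, list(schedule = y$schedule))
  spectrum_series(spectra, metadata = meta)
}

#' Write a spectrum series to a directory
#'
#' Emits one two-column text file per temperature plus a `manifest.yaml`, in
#' the dialect read by [read_spectrum_series()].
#'
#' @param series A `"spectrum_series"`.
#' @param dir Output directory (created if needed).
#' @param digits Significant digits written for ppm/intensity.
#' @return The manifest path, invisibly.
#' @export
write_spectrum_series <- function(series, dir, digits = 8) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tt <- series_temperatures(series)
  fmt <- paste0("%.", digits, "g")
  files <- purrr::map(tt, function(tc) {
    d <- dplyr::filter(series$spectra, .data$temperature_C == tc)
    fn <- sprintf("spectrum_%07.2fC.txt", tc)
    con <- file.path(dir, fn)
    writeLines(c("# ppm intensity",
                 paste(sprintf(fmt, d$ppm), sprintf(fmt, d$intensity))), con)
    list(temperature_C = tc, path = fn)
  })
  meta <- series$metadata
  manifest <- list(
    sample = meta[intersect(names(meta),
                            c("gelator_formula", "W_wt_percent",
                              "solvent_formula", "n_deuterium"))],
    schedule = meta$schedule,
    files = files
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Reference the chemical-shift axis against the internal standard
#'
#' Each spectrum's ppm axis is shifted so that the apex of the reference peak
#' (located by parabolic interpolation through the three points around the
#' window maximum) sits at `expected_ppm`; intensities are then re-interpolated
#' onto the original shared axis. Per-spectrum shifts are recorded in
#' `metadata$shifts_ppm`. A spectrum whose reference window contains no maximum
#' rising more than three noise standard deviations above the window median is
#' an error, reported with its temperature.
#'
#' @param series A `"spectrum_series"`.
#' @param windows Window set containing one `role = "reference"` window.
#' @param expected_ppm Target position of the reference apex (ppm); 0.144 for
#'   BTMSA.
#' @param quiet_region Signal-free ppm interval for the noise estimate;
#'   defaults to the window set's `quiet_region` attribute.
#' @return The aligned `"spectrum_series"`.
#' @export
align_reference <- function(series, windows, expected_ppm = 0.144,
                            quiet_region = NULL) {
  windows <- peak_windows(windows)
  ref <- dplyr::filter(windows, .data$role == "reference")
  if (nrow(ref) != 1L) {
    stop("`windows` must contain exactly one reference window.", call. = FALSE)
  }
  if (is.null(quiet_region)) quiet_region <- attr(windows, "quiet_region", exact = TRUE)
  if (is.null(quiet_region)) {
    stop("No `quiet_region` available for the noise estimate.", call. = FALSE)
  }
  noise <- estimate_noise(series, quiet_region)
  ax <- ppm_axis(series)
  idx <- which(ax >= ref$ppm_lo & ax <= ref$ppm_hi)
  if (length(idx) < 3L) {
    stop("Reference window contains fewer than 3 axis points.", call. = FALSE)
  }
  tt <- series_temperatures(series)
  mat <- intensity_matrix(series)
  shifts <- stats::setNames(numeric(length(tt)), format(tt, trim = TRUE))
  failed <- numeric(0)
  for (j in seq_along(tt)) {
    y <- mat[idx, j]
    k <- which.max(y)
    sigma <- noise$sigma_noise[j]
    if ((y[k] - stats::median(y)) <= 3 * sigma) {
      failed <- c(failed, tt[j])
      next
    }
    apex <- ax[idx[k]]
    if (k > 1L && k < length(y)) {
      denom <- y[k - 1L] - 2 * y[k] + y[k + 1L]
      if (denom < 0) {
        apex <- apex + 0.5 * (y[k - 1L] - y[k + 1L]) / denom *
          (ax[idx[k] + 1L] - ax[idx[k]])
      }
    }
    shift <- expected_ppm - apex
    shifts[j] <- shift
    if (abs(shift) > 0) {
      mat[, j] <- stats::approx(x = ax + shift, y = mat[, j], xout = ax,
                                rule = 2)$y
    }
  }
  if (length(failed) > 0) {
    stop("No reference maximum above 3x noise at temperature(s): ",
         paste(format(failed), collapse = ", "), " degC.", call. = FALSE)
  }
  out <- series
  out$spectra$intensity <- as.vector(mat)
  prev <- out$metadata$shifts_ppm
  out$metadata$shifts_ppm <- if (is.null(prev)) shifts else prev + shifts
  out
}

#' Read / write a temperature-by-window integral table
#'
#' Delimited text with a header row naming `temperature_C` plus one column per
#' window (optionally `sigma_<window>` columns carrying 1-sigma integration
#' errors). Lets pre-integrated data enter the correction and phase-diagram
#' stages directly, bypassing the spectra.
#'
#' @param path File path.
#' @param provenance `"supplied"` or `"integrated-here"`; stored as attribute.
#' @return A tibble with attribute `provenance`.
#' @export
read_integral_table <- function(path, provenance = "supplied") {
  if (!file.exists(path)) stop("Integral table not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl(",", hdr)) "," else if (grepl("\t", hdr)) "\t" else ""
  d <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                         check.names = FALSE, strip.white = TRUE)
  if (!"temperature_C" %in% names(d)) {
    stop("Integral table must have a `temperature_C` column: ", path,
         call. = FALSE)
  }
  if (anyDuplicated(d$temperature_C)) {
    stop("Duplicated temperature row(s) in integral table: ",
         paste(unique(d$temperature_C[duplicated(d$temperature_C)]),
               collapse = ", "), " degC.", call. = FALSE)
  }
  out <- tibble::as_tibble(d)[order(d$temperature_C), ]
  attr(out, "provenance") <- provenance
  out
}

#' @rdname read_integral_table
#' @param table Tibble with `temperature_C` plus window columns.
#' @export
write_integral_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Integral traces from a pre-integrated table
#'
#' @param table Table from [read_integral_table()].
#' @param windows Window set; every window name must appear as a column.
#' @return A long trace tibble (`window`, `role`, `multiplicity`,
#'   `temperature_C`, `raw`, `sigma_raw`).
#' @export
traces_from_table <- function(table, windows) {
  windows <- peak_windows(windows)
  miss <- setdiff(windows$name, names(table))
  if (length(miss) > 0) {
    stop("Integral table is missing window column(s): ",
         paste(miss, collapse = ", "), ".", call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    nm <- windows$name[i]
    sg <- paste0("sigma_", nm)
    tibble::tibble(
      window = nm,
      role = windows$role[i],
      multiplicity = windows$multiplicity[i],
      temperature_C = table$temperature_C,
      raw = table[[nm]],
      sigma_raw = if (sg %in% names(table)) table[[sg]] else 0
    )
  })
}

#' Widen integral traces into a temperature-by-window table
#'
#' @param traces Long trace tibble.
#' @param value Which column to spread (`"raw"`, `"normalized"`, ...).
#' @export
as_integral_table <- function(traces, value = "raw") {
  out <- tidyr::pivot_wider(
    dplyr::select(traces, "temperature_C", "window", dplyr::all_of(value)),
    names_from = "window", values_from = dplyr::all_of(value)
  )
  out <- dplyr::arrange(out, .data$temperature_C)
  attr(out, "provenance") <- "integrated-here"
  out
}
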