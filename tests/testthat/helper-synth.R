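# Shared fixtures and independent oracles, built in code at test time.

# Numerical-quadrature oracle for the simulator line shape: integrates the
# analytic clipped-offset Lorentzian with stats::integrate, independently of
# both the generator's grid evaluation and the package's closed form.
oracle_window_mass <- function(lo, hi, center, gamma, area, support = 0.6) {
  f <- function(x) {
    d <- x - center
    l0 <- area / pi * gamma / (support^2 + gamma^2)
    y <- area / pi * gamma / (d^2 + gamma^2) - l0
    ifelse(abs(d) > support | y < 0, 0, y)
  }
  stats::integrate(f, lo, hi, subdivisions = 2000L, rel.tol = 1e-10)$value
}

# One reference-condition single-polymorph pipeline run, cached across test files.
cached_single_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- synthetic_truth("single")
      series <- generate_series(truth, seed = 101)
      cache <<- list(
        truth = truth,
        map = map_phase_diagram(series, default_windows(), detect_corner = TRUE)
      )
    }
    cache
  }
})

# Minimal hand-built trace tibble (already "normalized") for unit tests of
# the correction stage.
make_trace <- function(window, values, role = "gelator", multiplicity = 1L,
                       temperatures = seq_along(values) * 2 + 18,
                       sigma = 0) {
  tibble::tibble(
    window = window, role = role, multiplicity = as.integer(multiplicity),
    temperature_C = temperatures, raw = values, sigma_raw = sigma,
    normalized = values, sigma_norm = sigma
  )
}
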