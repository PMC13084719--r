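# Molecular-formula arithmetic: molar masses, elemental percentages,
# isotopologue mass ratios and the deuterated <-> protiated solvent
# weight-fraction conversion.

#' Atomic weights used by the package
#'
#' Standard atomic weights in g/mol for the elements that occur in gelator and
#' triacylglycerol formulas, plus `"D"` for deuterium (isotope mass 2.014).
#' This is the table behind [molar_mass()], [elemental_percentages()] and
#' [isotope_mass_ratio()]; with it, per-deuterated triolein
#' (C57H104O6 with 101 substitutions) gives the mass ratio r = 1.115 at three
#' decimals, and 12-hydroxystearic acid (C18H36O3) gives C 71.95%, H 12.08%.
#'
#' @format Named numeric vector, g/mol.
#' @export
atomic_weights <- c(
  H = 1.008, D = 2.014, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Br = 79.904, I = 126.904
)

#' Parse a Hill-style molecular formula
#'
#' Accepts strings such as `"C18H36O3"` or `"C57H3D101O6"`: an element symbol
#' (one capital letter, optionally one lower-case letter; `"D"` is accepted as
#' explicit deuterium) followed by an optional integer count. A missing count
#' means 1; repeated symbols are summed.
#'
#' @param text A single formula string.
#' @return A named integer vector of element counts, class `"chem_formula"`.
#' @examples
#' parse_formula("C18H36O3")
#' parse_formula("C57H3D101O6")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("`text` must be a single non-empty formula string.", call. = FALSE)
  }
  rest <- text
  counts <- integer(0)
  while (nzchar(rest)) {
    m <- regmatches(rest, regexpr("^[A-Z][a-z]?[0-9]*", rest))
    if (length(m) == 0L || !nzchar(m)) {
      stop(sprintf("Malformed formula token starting at \"%s\" in \"%s\".",
                   substr(rest, 1L, 3L), text), call. = FALSE)
    }
    sym <- gsub("[0-9]", "", m)
    if (!sym %in% names(atomic_weights)) {
      stop(sprintf("Unknown element symbol \"%s\" in \"%s\".", sym, text),
           call. = FALSE)
    }
    num <- gsub("[^0-9]", "", m)
    cnt <- if (nzchar(num)) as.integer(num) else 1L
    if (cnt < 1L) {
      stop(sprintf("Element count must be >= 1 (got \"%s\" in \"%s\").", m, text),
           call. = FALSE)
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + cnt
    rest <- substr(rest, nchar(m) + 1L, nchar(rest))
  }
  structure(counts, class = "chem_formula")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ",
      paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = ""),
      "  (", format(molar_mass(x), digits = 6), " g/mol)\n", sep = "")
  invisible(x)
}

as_chem_formula <- function(f) {
  if (inherits(f, "chem_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  if (is.numeric(f) && !is.null(names(f))) {
    bad <- setdiff(names(f), names(atomic_weights))
    if (length(bad) > 0) {
      stop("Unknown element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(f < 1)) stop("Element counts must be >= 1.", call. = FALSE)
    return(structure(as.integer(f), names = names(f), class = "chem_formula"))
  }
  stop("Cannot interpret `f` as a molecular formula.", call. = FALSE)
}

#' Molar mass of a formula
#'
#' @param f A `"chem_formula"`, a formula string, or a named count vector.
#' @return Molar mass in g/mol (full precision; see [round_half_away()] for
#'   comparison with printed values).
#' @examples
#' molar_mass("C18H36O3")
#' @export
molar_mass <- function(f) {
  f <- as_chem_formula(f)
  sum(atomic_weights[names(f)] * unclass(f))
}

#' Elemental mass percentages
#'
#' Mass percent of each element in a formula. Values are returned at full
#' precision and sum to 100; round with [round_half_away()] to compare against
#' printed elemental analyses (e.g. C18H36O3: C 71.95%, H 12.08%).
#'
#' @inheritParams molar_mass
#' @return A tibble with columns `element`, `count`, `percent`.
#' @examples
#' elemental_percentages("C18H36O3")
#' @export
elemental_percentages <- function(f) {
  f <- as_chem_formula(f)
  mm <- molar_mass(f)
  tibble::tibble(
    element = names(f),
    count = as.integer(unclass(f)),
    percent = unname(100 * atomic_weights[names(f)] * unclass(f) / mm)
  )
}

#' Isotopologue molar-mass ratio r = M_D / M_H
#'
#' Molar-mass ratio between a partially deuterated isotopologue and its
#' protiated parent, given the number of H -> D substitutions. For triolein
#' (C57H104O6) with 101 substitutions, r rounds to 1.115. The same ratio can
#' be obtained by parsing the explicit-deuterium formula (e.g. `"C57H3D101O6"`)
#' and taking the ratio of [molar_mass()] values; the two routes agree exactly.
#'
#' @param protiated Protiated parent formula (string or `"chem_formula"`).
#' @param n_substituted Number of hydrogens replaced by deuterium; must not
#'   exceed the hydrogen count of `protiated`.
#' @return A list of class `"isotope_conversion"` with fields `r`, `M_D`,
#'   `M_H`, `n_substituted`.
#' @examples
#' isotope_mass_ratio("C57H104O6", 101)
#' @export
isotope_mass_ratio <- function(protiated, n_substituted) {
  f <- as_chem_formula(protiated)
  n_h <- if ("H" %in% names(f)) unclass(f)[["H"]] else 0L
  if (!is.numeric(n_substituted) || length(n_substituted) != 1L ||
      n_substituted < 0 || n_substituted != round(n_substituted)) {
    stop("`n_substituted` must be a single non-negative integer.", call. = FALSE)
  }
  if (n_substituted > n_h) {
    stop(sprintf("Cannot substitute %d hydrogens: formula has only %d.",
                 as.integer(n_substituted), n_h), call. = FALSE)
  }
  m_h <- molar_mass(f)
  m_d <- m_h + n_substituted * (atomic_weights[["D"]] - atomic_weights[["H"]])
  structure(
    list(r = m_d / m_h, M_D = m_d, M_H = m_h,
         n_substituted = as.integer(n_substituted)),
    class = "isotope_conversion"
  )
}

#' @export
print.isotope_conversion <- function(x, ...) {
  cat(sprintf("<isotope_conversion> r = M_D/M_H = %.6f  (M_H = %.3f, M_D = %.3f g/mol, %d H -> D)\n",
              x$r, x$M_H, x$M_D, x$n_substituted))
  invisible(x)
}

# Eq. 1 without domain checks; used internally on diagram points that may sit
# marginally outside [0, 1] from noise.
eq1_d_to_h <- function(w, r) w * r / (1 + w * (r - 1))
eq1_h_to_d <- function(w, r) w / (r - w * (r - 1))

#' Convert a weight fraction between deuterated and protiated solvent bases
#'
#' Solutions of the same solute mole fraction in a deuterated solvent (molar
#' mass M_D) and its protiated parent (M_H) have different weight fractions.
#' With r = M_D/M_H, the deuterated-basis fraction w_D converts to the
#' protiated basis as
#' \deqn{w_H = \frac{w_D\, r}{1 + w_D (r - 1)},}
#' and `direction = "H_to_D"` applies the exact algebraic inverse. With
#' r = 1.115 (triolein-d101 vs triolein) a 4.00 wt% deuterated-basis sample is
#' equivalent to 4.44 wt% in the protiated oil.
#'
#' @param w Weight fraction(s) in `[0, 1]` (not wt%).
#' @param r Mass ratio M_D/M_H (> 0), or an `"isotope_conversion"` object.
#' @param direction `"D_to_H"` (default) or `"H_to_D"`.
#' @return Converted weight fraction(s) in `[0, 1]`.
#' @examples
#' convert_weight_fraction(0.0400, 1.115)           # 0.0444
#' convert_weight_fraction(0.0444, 1.115, "H_to_D") # back to ~0.0400
#' @export
convert_weight_fraction <- function(w, r, direction = c("D_to_H", "H_to_D")) {
  direction <- match.arg(direction)
  if (inherits(r, "isotope_conversion")) r <- r$r
  if (!is.numeric(r) || length(r) != 1L || r <= 0) {
    stop("`r` must be a single positive number.", call. = FALSE)
  }
  if (!is.numeric(w) || any(!is.finite(w)) || any(w < 0 | w > 1)) {
    stop("`w` must be weight fraction(s) within [0, 1].", call. = FALSE)
  }
  switch(direction,
         D_to_H = eq1_d_to_h(w, r),
         H_to_D = eq1_h_to_d(w, r))
}

#' Round half away from zero
#'
#' Rounding convention used for comparisons with printed values (R's `round()`
#' rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
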