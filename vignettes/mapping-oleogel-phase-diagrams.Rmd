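---
title: "Mapping oleogel phase diagrams from variable-temperature 1H NMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping oleogel phase diagrams from variable-temperature 1H NMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liquidus)
```

## The physical model

An oleogel is an edible oil structured by a low-molecular-weight gelator at
a few weight percent. At a given total concentration $W$ the system is a
two-phase mixture below its melting temperature $T_m$: solid gelator fibrils
in equilibrium with gelator dissolved in the oil. The solid network is
rigid on the NMR timescale, so its resonances are broadened beyond
detection in a liquid-state spectrum; only the dissolved fraction
contributes sharp peaks. This selectivity is the core premise: the gelator
peak integral at temperature $T$ measures the equilibrium solubility
$w(T)$, and one temperature ramp on a single sample traces the entire
liquidus line of the concentration–temperature diagram.

Quantification proceeds in four steps.

1. **Referencing and normalization.** Spectra are re-referenced so the apex
   of an inert internal standard sits at its nominal shift (0.144 ppm for a
   bis-silyl acetylene standard); gelator window integrals are divided by
   the integral of the standard or of the solvent vinyl signal, both of
   which have temperature-independent concentrations. The package checks
   that the two candidate normalizers evolve in parallel (their ratio's
   relative spread stays within a tolerance, 5% by default) — drift would
   indicate the standard interacts with the oil.

2. **Plateau, $I_{max}$ and $T_m$.** Above full dissolution the normalized
   intensity $I(T)$ is constant at $I_{max} \propto W$. Scanning from the
   highest temperature, the plateau is the longest terminal run whose
   points all lie within `rel_tol` (default 2%) of the run mean, widened by
   twice each point's own integration error so that finite noise does not
   truncate a genuine plateau; $I_{max}$ is the run mean, its error the run
   standard deviation, and $T_m$ the lowest temperature reaching
   $(1-\mathrm{rel\_tol})\,I_{max}$ (again less twice the local error).
   At least 3 plateau points are required; a monotonically rising trace is
   reported as truncated below full dissolution rather than analysed.

3. **Overlap floor correction.** A gelator window that overlaps solvent
   signals carries a constant excess integral $\delta$. With a clean
   gelator window of multiplicity $m_c$ and an overlapped one of
   multiplicity $m_o$, plateau bookkeeping gives
   $\delta = I_{max}^{over} - (m_o/m_c)\, I_{max}^{clean}$ (the classic
   1H-amide / 2H-methylene case reduces to
   $\delta = I_{max}(CH_2) - 2 I_{max}(NH)$). Because the plateaus carry a
   percent-level uncertainty, $\delta$ is then fine-tuned within
   $\pm 4\%$ of $I_{max}^{over}$ — a hard bound — to the value that
   least-squares aligns the per-proton corrected trace with the per-proton
   clean trace, over temperatures where the clean trace's relative error is
   below 50%. The tuning objective is a deliberate formalization: visually
   "eliminating artifacts" is not reproducible, a quadratic alignment
   criterion is, and its closed-form optimum (a mean of per-temperature
   differences, clamped to the band) makes the adjustment auditable.
   Residual negative corrected values are flagged, never clipped, so the
   downstream error analysis stays unbiased. Correction quality is
   validated by the achieved multiplicities
   $m_c\, I_{max}/I_{max}^{clean}$, which must match the nominal proton
   counts within 4%.

4. **Soluble fraction, error budget, diagram.** $w(T) = W\, I(T)/I_{max}$,
   with points below $T_m$ forming the liquidus. Each point's relative
   error is a quadrature sum of four terms: per-point integration noise
   $\sigma_{norm}/I$, a flat 2% integration-range (peak-tail truncation)
   term, 0.5% weighing, and the relative plateau scatter
   $\sigma_{I_{max}}/I_{max}$ (typically ~2%). Points with relative error
   at or below 20% are flagged reliable; at the reference noise level this
   reproduces the characteristic behaviour that errors are sub-percent near
   the plateau and exceed 50% at the coldest points. Floor-offset
   uncertainty is reported in the corrections table but not added as a
   fifth budget term — the four-term budget is the method's convention, and
   double-counting it would bias the reliability flag.

Measurements are made in a deuterated solvent; results are reported on the
protiated-solvent basis used by the comparison techniques. With
$r = M_D/M_H$ the molar-mass ratio of the two solvent isotopologues,
equal mole fractions give

$$w_H = \frac{w_D\, r}{1 + w_D\,(r-1)},$$

applied to every point and to $W$ itself ($r$ is computed from the
molecular formulas; per-deuterated triolein against triolein gives
$r = 1.115$, so 4.00 wt% converts to 4.44 wt%). The exact algebraic
inverse handles the reverse direction, and the round trip is an identity to
machine precision.

## Gel–gel (polymorphic) corner detection

A transition between two solid polymorphs is invariant in concentration
(Gibbs' phase rule for two solids plus a liquid), so the liquidus follows
one solubility branch below the transition temperature $T_{GG}$ and a
different one above, meeting at a corner whose temperature does not depend
on $W$. The detector fits reliable liquidus points in van't Hoff
coordinates — $\ln w$ against $1/T_K$, where a single polymorph's
solubility is a straight line — with (a) one weighted straight line and
(b) a continuous two-segment hinge whose breakpoint is scanned on a
0.25 °C grid at least 4 °C inside the data range (three 2 °C steps are the
minimum needed to estimate a slope on each side). The corner is reported
when the BIC improvement of (b) exceeds an evidence margin.

The margin (default 30) was calibrated on the generator's single-polymorph
null at the reference conditions: because the breakpoint is the maximizer
over many correlated candidate positions, and because percent-level
correction errors bend the curve slightly, the null improvement has a
heavy tail (median ≈ −2, 99th percentile ≈ 12, largest of 200 simulations
≈ 22), while genuine sharp corners score 40–75. The margin therefore
separates the two populations with a wide gap in both directions. An
attenuated transition (branch slopes made similar, emulating gradual
polymorph interconversion) still produces a corner but with a much lower
evidence score, which is exactly the diagnostic behaviour wanted: the
score, not just the binary call, is part of the report.

Detection runs on the curve with the most reliable liquidus points (the
higher-multiplicity corrected window in the default layout), and the fit
is weighted by $1/\mathrm{rel\_err}^2$.

## What the synthetic generator emulates

`synthetic_truth()` + `generate_series()` build a complete frequency-domain
experiment from known ground truth:

* **Solubility truth.** Single-polymorph: van't Hoff form
  $w^*(T) = W e^{-B(1/T_K - 1/T_{m,K})}$ with $B = 9500$ K and
  $T_m = 80$ °C, spanning ~0.16 → 4 wt% across the default 42–90 °C ramp —
  roughly a decade and a half of concentration over the reference temperature window.
  This is a generator choice for realistic curvature, not a thermodynamic
  claim. Two-polymorph: two van't Hoff branches ($B$ = 22000 K metastable,
  3100 K stable) meeting at $T_{GG} = 22$ °C where $w^* = 2$ wt%, with
  $W = 5$ wt% and the derived $T_m \approx 50$ °C.
* **Spectra.** One Lorentzian per window (FWHM 0.010 ppm for gelator
  peaks, 0.006 ppm for the sharper solvent/reference singlets), gelator
  areas $\propto$ multiplicity × $w^*(T)/W$ with the per-proton plateau
  area as the unit, constant solvent (area 24) and reference (area 7.7)
  peaks mirroring realistic amplitude ratios, and a constant solvent
  satellite of area 0.08 inside the overlapped window (the injected
  floor). White Gaussian noise sets the plateau SNR: presets `"reference"`
  (NH-peak SNR 50) and `"harsh"` (SNR 5). Windows are 0.7 ppm wide so that
  Lorentzian tail truncation stays within the ~2% budget term.
* **Line-shape wings.** The far wings of each Lorentzian (beyond
  ±0.6 ppm) are offset-subtracted and clipped, emulating spectra whose
  smooth inter-peak background has already been removed by baseline
  correction. Ideal infinite Lorentzian wings from the large solvent peaks
  would otherwise deposit a constant pseudo-floor in *every* window —
  including the clean one, which the floor correction by construction
  cannot fix — and that artifact is a property of the idealized line
  shape, not of the method. The clipped shape keeps a closed-form window
  mass (`lorentzian_window_mass()`), which the tests use as an
  independent oracle for integrals and injected floors.
* **The NMR-silent solid.** Simply not emitted: gelator signal area tracks
  only the soluble fraction.
* **Not emulated:** temperature-dependent line widths and chemical-shift
  drift (beyond an optional constant drift used to test re-referencing),
  relaxation or exchange broadening, isotopic-impurity satellites beyond
  one constant floor per window, phase/baseline instrument artifacts.
  Passing tests therefore demonstrate correctness of the quantification
  chain under the stated statistical structure, not robustness to every
  instrument pathology.

Determinism: a fixed seed yields bit-identical spectra and files, so every
simulation-based test and report is exactly reproducible.

## Numerical and design choices

* **Integration** is the trapezoid rule over each window. The default
  baseline is zero — the input contract is pre-phased, baseline-corrected
  spectra, and in that regime an edge-anchored local baseline only adds
  variance (anchor noise enters as $\sqrt{n/2k}$ relative to the trapezoid
  noise itself). For data with residual drift, `baseline = "edges"`
  subtracts a line through the medians of the outer 5% of window points on
  each side. The integration error model
  $\sigma_{raw} = \sigma_{noise}\,\Delta_{ppm}\sqrt{n}$ is the white-noise
  variance of the trapezoidal sum; noise $\sigma_{noise}$ is estimated per
  spectrum as 1.4826 × MAD about a local linear fit in a configured quiet
  region (≥ 32 points, checked against window overlap).
* **Truncation is bounded, not corrected**: window choice is the user's,
  and the flat 2% budget term covers the tails left outside.
* **Apex finding** for re-referencing uses parabolic interpolation through
  the three points around the window maximum (sub-grid accuracy without
  line-shape fitting); a window whose maximum does not rise 3 noise
  standard deviations above the window median is reported as a failed
  alignment at that temperature.
* **Plateau tolerance noise-widening.** The membership gate is
  `rel_tol·|mean| + 2σ(point)` rather than `rel_tol·|mean|` alone: with
  per-point noise comparable to the 2% tolerance, the unwidened rule
  aborts a genuine plateau with non-trivial probability; the widening
  vanishes for noise-free input so all closed-form checks are unaffected.
  For the same reason the $T_m$ threshold subtracts twice the local error.
* **Degenerate inputs.** Duplicate temperatures, ragged spectra, windows
  outside the axis, non-positive normalizer integrals, fewer than 3
  plateau points, fewer than 8 reliable points for corner detection — all
  produce descriptive errors naming the offending temperature, file or
  window rather than propagating NaNs.
* **Multiple windows** are kept as separate curves in the diagram (no
  averaging): inter-window agreement is itself a validation statistic.
  An inverse-variance merge was considered and rejected as a default
  because correlated systematics (shared normalizer, shared $I_{max}$
  convention) would make the merged error optimistic.
* **Problem sizes.** Simulation-based tests use 25-spectrum series at
  16001 axis points; replicate counts are 5 (recovery medians), 50 (floor
  recovery) and 100 + 100 (corner detection and its false-positive rate).
  Recovery claims are asserted on medians over replicate seeds so that a
  single noise draw does not decide a capability statement.

## Known limitations

* The floor model assumes the overlapping solvent contribution is
  temperature-independent; a temperature-dependent overlap would bias the
  low-temperature liquidus and is not detected beyond the negative-value
  flags.
* $T_m$ resolution is one temperature step; no interpolation between steps
  is attempted.
* The corner detector assumes at most one breakpoint; two stacked
  polymorphic transitions would be reported as the dominant one.
* Quantification assumes full relaxation between scans (long relaxation
  delay); T1 bias correction is out of scope.
* Only frequency-domain, pre-phased spectra are read; vendor FID formats
  and their processing are out of scope.
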