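---
title: "Methods: thermodynamics of acoustic pH pulses in lipid monolayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermodynamics of acoustic pH pulses in lipid monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monowave)
```

## The physical picture

A Langmuir monolayer is a single lipid layer at the air–water interface of a
trough. Its thermodynamic state is summarised by the lateral pressure $\pi$
(mN/m), the area per molecule $A$ (Å²), the temperature, the subphase pH and
the surface potential. `monowave` implements the analysis chain by which
measurements on such a monolayer — quasi-static $\pi$–$A$ isotherms,
transition-pressure titrations, two-sensor pressure/potential time series and
ratiometric fluorescence records — are converted into statements about
acoustic pulses that propagate along the interface after a local
acidification:

1. **Acoustics from the isotherm.** In the linear regime the in-plane sound
   velocity is $c = (\rho_0 \kappa)^{-1/2}$, with $\rho_0$ the lateral mass
   density and $\kappa$ the (adiabatic) compressibility, approximated here by
   the isothermal compressibility
   $\kappa_T = -(1/A)\,(\partial A/\partial\pi)_T$ read off the isotherm.
   $\kappa_T$ peaks at the first-order liquid-expanded/liquid-condensed (LE/LC)
   transition, so the velocity has a minimum there.
2. **Protonation threshold.** The transition pressure $\pi_T$ of a titratable
   lipid follows a Boltzmann sigmoid in subphase pH,
   $\pi_T(\mathrm{pH}) = A_2 + (A_1-A_2)/(1+e^{(\mathrm{pH}-x_0)/dx})$. The pH
   of maximal slope — analytically equal to $x_0$ — is the operational
   p$K_a$ of the head group, and the normalised rise
   $\alpha = (\pi_T - A_1)/(A_2 - A_1)$ is the deprotonated fraction.
3. **Electrostatics.** With only the serine carboxyl carrying net charge, the
   surface charge density is $\sigma = -\alpha e / A$ and the head-group
   potential follows the Gouy–Chapman relation for a 1:1 electrolyte,
   $\psi = (2kT/e)\,\mathrm{asinh}\!\left(\sigma/\sqrt{8\varepsilon_0
   \varepsilon_r k T n}\right)$. Protons equilibrate across the double layer,
   so the interfacial pH is Boltzmann-shifted from the bulk:
   $\mathrm{pH}_I = \mathrm{pH}_B + e\psi/(kT\ln 10)$. The Kelvin-probe
   surface potential decomposes exactly as
   $V^{\mathrm{tail}} = V^{\mathrm{total}} - \psi$.
4. **Pulse observables.** Two pressure sensors a fixed distance apart give
   the propagation velocity from the transit delay; amplitudes, damping and
   relaxation complete the pulse description. A pH-sensitive ratiometric dye
   ($I_R = I_{535}/I_{605}$), calibrated linearly against pH in a narrow
   pressure window, converts fluorescence into an interfacial pH trace.

The chain's default worked example is a DMPS monolayer on a pH 7 buffered
subphase: sigmoid parameters $A_1 = 4.5$, $A_2 = 24.4$ mN/m, $x_0 = 5.4$,
$dx = 0.83$, which give $\alpha(\mathrm{pH}\,7) = 0.873$, and the Gouy–Chapman
potentials at 75 and 82 Å² of about $-117$ and $-113$ mV, a $+4.5$ mV change
whose Boltzmann conversion is $+0.08$ pH units. `run_reference_analysis()`
recomputes all of these plus the pulse observables and reports them beside
their reference values.

## Tunable parameters

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| `ionic_strength` | 0.11 | mol/L | 100 mM NaCl plus 10 mM phosphate buffer counted as an effective 1:1 contribution. The buffer's exact ionic contribution is composition-dependent; this accounting is the one that reproduces the reference −117/−113 mV pair, and it is documented as such, not as a measured value. With 0.10 mol/L the pair shifts to ≈ −120/−115 mV. |
| `temperature` | 298.15 | K | 25 °C working temperature. |
| `relative_permittivity` | 78.5 | – | Bulk water at 25 °C; no interfacial dielectric correction. |
| `molar_mass` | 679.9 | g/mol | DMPS configuration default; users should check their lipid's data sheet. |
| `effective_density_factor` | 1 | – | Lipid-only lateral density. See *Limitations*. |
| `threshold_fraction` | 0.5 | – | Leading-edge arrival criterion; for well-separated pulses the velocity is insensitive to the exact fraction, and a cross-correlation estimator is provided as the alternative. |
| `baseline_fraction` | 0.1 | – | Pre-arrival window for baseline mean/noise estimates. |
| `smooth_window` | 1 (off) | samples | Moving-average width for noisy traces; odd. Windows of a few tens of ms suppress the positive bias that raw extremum amplitudes inherit from noise maxima, at negligible waveform distortion. |
| `smoothing` (isotherms) | GCV | – | See *Numerical choices*. |

Physical constants are CODATA 2018 exact values (`physical_constants()`);
temperature and permittivity are configuration, not constants.

## What the synthetic-data generator emulates — and what it does not

All downstream stages are exercised on synthetic data because the package's
subject matter is instrument records that are not redistributable. The
generator reproduces the *structure* the analysis relies on:

* **Isotherms** come from a phenomenological equation of state: linear LE and
  LC branches blended by a logistic weight of width `plateau_width` centred
  on $\pi_T$, with an area drop `plateau_area_drop` across the transition.
  This guarantees a strictly decreasing $A(\pi)$ with a single $\kappa_T$
  maximum at $\pi_T$ — the only structural facts the analysis uses. The
  defaults (lift-off 110 Å², branch stiffnesses 0.7 and 4 mN/m per Å², drop
  25 Å², width 1 mN/m) put the LE branch near 75–80 Å² at the pH 7 transition
  pressure, in the range typical for charged phospholipids. The width was
  fixed at 1 mN/m because the $1/A$ factor in $\kappa_T$ shifts the argmax
  above $\pi_T$ by roughly $2w^2 |A'/A|$; at 1 mN/m that shift stays inside
  one 0.25 mN/m grid step. No Maxwell construction or EOS fit is implied —
  real isotherms enter the package as empirical tables.
* **Isotherm noise** perturbs the *placement* of the transition (one Gaussian
  draw of $\pi_T$ per isotherm, realised value recorded as ground truth)
  rather than individual areas. In a quasi-static compression the per-point
  measurement noise is far below the run-to-run variability of the plateau
  position, and placement noise keeps every generated record a valid monotone
  isotherm at any noise level.
* **Pulse traces** impose the transit: channel 2 is channel 1 delayed by
  `separation/velocity` and scaled by the damping ratio, plus i.i.d. Gaussian
  noise per channel and optional quantisation at the instrument resolutions
  (0.01 mN/m, 5 mV). The default waveform is an exponential rise
  (τ = 50 ms) with exponential relaxation (τ = 300 ms), matching the
  asymmetric rise-and-relax shape of observed pulses; a Gaussian is available
  for symmetric-pulse tests. Rise/decay times and noise levels are fixtures,
  not claims — no instrument noise statistics are available to match.
* **Fluorescence traces** follow the calibration line exactly in their
  noiseless part, with the raw channels any positive pair realising the
  ratio.

No wave equation is solved: delay and damping are inputs, so passing tests
demonstrate that the *estimators* recover known truths, not that pulses
propagate as modelled. Dispersion, attenuation physics, capillary waves,
acid-gas transport, dye photophysics and electric-field interference with
emission are all outside the generator and the package.

## Numerical choices

* **Differentiating isotherms.** Finite differences on noisy $A(\pi)$ records
  produce spurious negative compressibilities. `compressibility_profile()`
  fits a smoothing spline and differentiates it analytically. The default
  smoothing parameter comes from generalized cross-validation; because a
  valid monotone isotherm must have a one-signed derivative, the smoothing is
  escalated stepwise (up to `spar = 1.5`) if the interior derivative still
  changes sign, and an error is raised only if that fails. `smoothing = 0`
  requests an interpolating spline for clean analytic or synthetic curves;
  an explicit `spar` is honoured verbatim. Boundary derivatives of splines
  are unreliable, so the profile covers the grid interior only.
* **Transition pressure.** Global maximum of $\kappa_T$; exact ties break
  toward the lower pressure; a maximum on the profile boundary is an error
  (truncated isotherm).
* **Table lookups.** Monotone (Hyman-filtered) cubic splines for ≥ 4
  monotone points, linear interpolation otherwise.
* **Sigmoid fitting.** Levenberg–Marquardt least squares with data-driven
  starts (plateaus from the data extremes, $x_0$ from the half-rise crossing,
  $dx$ from the 25–75 % rise span, which spans $2\ln 3\,dx$ for a logistic)
  and box constraints $dx \in [0.05, 5]$. Fits with $dx$ pinned at a bound
  are flagged non-converged. Flat titration curves ($A_1 = A_2$) are
  rejected as degenerate. No point weighting is applied.
* **Arrival detection.** Threshold method: first leading-edge crossing of
  half the peak excursion, with linear sub-sample interpolation.
  Cross-correlation method: FFT circular cross-correlation with parabolic
  sub-sample refinement, anchored at the channel-1 threshold arrival. The
  detectability precondition (peak ≥ 5× baseline noise) is enforced; an
  identical channel pair (zero delay) is an error.
* **Amplitudes and damping.** Signed extremum minus pre-arrival baseline
  mean; expansion pulses are negative by convention. Relaxation time from a
  log-linear fit of the post-peak return down to 90 % recovery.
* **pH conversion.** The intensity ratio is formed sample-wise *before* any
  smoothing. Conversions outside the calibrated ratio range plus a 10 %
  extrapolation margin are flagged (never silently dropped); the calibration
  is also bounded in lateral pressure (default 5–8 mN/m) because outside
  that window the ratio is no longer pressure-independent. The pressure–pH
  correlation sign over the pulse window is computed and reported rather
  than assumed, because expansion pulses make it negative ("inverse") while
  a co-directed pair would make it positive.
* **Configuration.** A plain-text key–value (YAML) file; unknown keys are
  rejected, missing keys take the defaults of `default_run_config()`.

## Design decisions that were genuinely open

* **$\kappa_S \approx \kappa_T$** is adopted without adiabatic correction;
  the velocity profile is therefore a qualitative object (its minimum marks
  the transition) rather than a quantitative prediction.
* **The dissociation-degree convention** reads $\alpha$ as the deprotonated
  fraction rising with pH. This is the only reading under which the
  reference value at pH 7 (0.873 from the sigmoid parameters, commonly
  rounded to 0.88) is consistent with an acidic-plateau $A_1$.
* **Charge bookkeeping** counts only the carboxyl: the phosphate and amino
  charges of the PS head group compensate. The p$K_a$ decrease that
  accompanies area expansion is deliberately *not* modelled; the Boltzmann
  estimate of the pH pulse is therefore conservative.
* **Arrival criterion** defaults to the 50 % leading edge; peak-based or
  correlation timing are equally defensible, which is why both estimators
  ship and the tests require them to agree on symmetric pulses.
* **The quasi-static/adiabatic gap is reported, not reconciled.** The
  Boltzmann chain predicts a ≈ +0.1 pH quasi-static shift for the 75→82 Å²
  expansion while the fluorescence route recovers the full ≈ +0.6 excursion
  of its input; both numbers appear side by side in the reference report.
  Isothermal and adiabatic responses of the interface differ, and the
  package makes no attempt to model the difference.

## Problem sizes

The shipped tests run at desk scale by choice: isotherm grids of 139 points
(0.5–35 mN/m, step 0.25), titrations of 13 pH points, 10 kHz traces of 2 s
for exactness checks and 1 kHz traces of 1.8–2 s for the 50–100-seed recovery
studies, and 100-seed simulation studies for the p$K_a$ and pH-pulse
estimators. These sizes keep the full suite under a minute while leaving
every estimator's noise regime non-trivial.

## Known limitations

* Eq. $c = (\rho_0\kappa_T)^{-1/2}$ with lipid-only density gives velocities
  of order 10²–10³ m/s, orders of magnitude above measured monolayer pulse
  speeds (≈ 0.6–1.4 m/s); entrained subphase mass is the usual suspect but
  is not modelled. The `effective_density_factor` exposes the ambiguity and
  defaults to 1 — the package makes no claim about absolute speeds.
* The Gouy–Chapman model is the flat-plate 1:1 analytic form: no Stern
  layer, ion-specific binding, or general Poisson–Boltzmann solver.
* Single-site titration only; electrostatically coupled or multi-site
  models are out of scope.
* The ratiometric calibration is dye- and environment-specific; nothing in
  the package generalises it beyond its stated pH and pressure windows.
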