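---
title: "Decomposing broadband susceptibility spectra of protein solutions: models, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing broadband susceptibility spectra of protein solutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrospec)
```

## The problem

Sugars such as trehalose protect proteins against freezing and
desiccation.  One proposed mechanism — water entrapment — predicts a
layer of strongly retarded water molecules held between the protein
surface and the surrounding sugar matrix.  Depolarized light scattering
measures the collective picosecond dynamics of all species at once over
more than four frequency decades, so the challenge is statistical:
separating a small, slow water component from much larger overlapping
contributions.  This vignette documents the models used by `hydrospec`,
the staged fitting protocol, the synthetic data it is validated on, and
the numerical design decisions.

## Susceptibility model

Measured depolarized intensity is converted to the imaginary
susceptibility, `intensity_to_susceptibility()`, dividing by
$n_B(\nu, T) + 1$ with $n_B$ the Bose–Einstein occupation factor; this
removes the trivial thermal population so relaxations appear as peaks.
A spectrum is then modelled as the sum of three groups,
$\chi'' = \chi''_{SR} + \chi''_{WR} + \chi''_{VIB}$:

| component | form | role | key parameters |
|---|---|---|---|
| Debye | $\Delta\,\omega\tau/(1+\omega^2\tau^2)$ | sugar rotation | $\tau \sim$ 300 ps |
| power law | $A\,\nu^{-\alpha}$ | protein structural relaxation | $\alpha \approx 0.3$ |
| Cole–Davidson ×3 | $\Delta(\cos\varphi)^\beta\sin(\beta\varphi)$ | bulk / hydration / ultraslow water | $\beta = 0.6$, $\tau$, $\Delta$ |
| DHO ×2 | $\Delta\,\nu_0^2\Gamma\nu/[(\nu_0^2-\nu^2)^2+\Gamma^2\nu^2]$ | water H-bond bending, stretching | $\nu_0 \approx 1.5,\ 5.1$ THz |
| DHO ×2 | same | solute Raman bands | $\nu_0 > 10$ THz |
| Brownian osc. ×3 | same (overdamped allowed) | protein low-frequency modes | $\nu_0 \in [0.3, 3]$ THz |

Internally all relaxation formulas use angular frequency
($\omega\tau = 2\pi\,\nu[\mathrm{THz}]\,\tau[\mathrm{ps}]$); grids are
stored in ordinary frequency.  The damped-oscillator line shape is
invariant under the $\nu \leftrightarrow \omega$ rescaling and is
evaluated in ordinary frequency directly.  Both water Cole–Davidson
terms share one $\beta$, fixed at 0.6 (the pure-water value, which the
free-shape refit `fit_water(beta_free = TRUE)` recovers); this is
overridable.

The hydration statistic is
$N_{\mathrm{ultraslow}} = r\,\Delta_{\mathrm{ultraslow}}/\Delta_{\mathrm{tot}}$
(`n_ultraslow()`), which assumes an equal light-scattering
cross-section per water molecule in every environment.  $r$ is computed
from weight fractions and molar masses
(`mixture_composition()`, `water_lysozyme_ratio()`); for
3 wt% lysozyme / 40 wt% trehalose / 57 wt% water,
$r \approx 1.508\times 10^4$.  Trehalose crystal water is counted as
solvent only on request (`include_crystal_water`), since preparation by
weight leaves that bookkeeping ambiguous.

## Staged fitting protocol

1. **Binary stage** (`fit_wt`): Debye + bulk and hydration Cole–Davidson
   + four vibrational bands, on the full 0.6 GHz–36 THz window.  The
   hydration time is parameterized as $\rho_h \tau_{\mathrm{bulk}}$ with
   $\rho_h \ge 2$, so the ordering of the two water terms is structural
   and $\rho_h$ *is* the hydration retardation factor.
2. **Difference spectrum** (`difference_spectrum`, `fit_ds`): both
   spectra are normalized to the integrated solute Raman band
   (> 10 THz), then the binary spectrum is rescaled by a matching factor
   determined by least squares over that band *allowing a smooth
   additive background* (intercept plus log-frequency).  The background
   term matters: the protein power-law tail extends into the
   normalization band, and a plain integral ratio would absorb it into
   the factor and systematically suppress the protein contribution in
   the difference.  The difference spectrum is fitted with power law +
   ultraslow Cole–Davidson + three Brownian oscillators.  Negative
   excursions are kept; weights follow the (running-median smoothed)
   parent ternary spectrum, since the noise of a difference scales with
   the spectra subtracted.
3. **Ternary stage** (`fit_ternary`): the full 13-component model.
   Binary-derived times and band shapes are fixed from stage 1; the
   protein shapes *and the ultraslow amplitude and time* are fixed from
   stage 2; the remaining component amplitudes are refit.

Fixing the ultraslow component from the difference spectrum is the one
protocol choice that was genuinely open, and it is deliberate.  The
ultraslow term carries ~5% of the water amplitude.  In the full ternary
spectrum it overlaps the rotation tail, the hydration flank and the
power law, and a direct sensitivity analysis shows that ±2% errors in
any of the larger fixed terms move the recovered
$N_{\mathrm{ultraslow}}$ by ∓35% (with *convex*, hence biasing,
response).  In the difference spectrum the solvent and rotation terms
cancel identically, so the component is determined there, and only
there, without that leakage.  With this protocol the noiseless pipeline
is exact and, at 2% noise, 20 seeds give
$N_{\mathrm{ultraslow}} = 718 \pm 108$ against a ground truth of 710.

Similarly, the pipeline fixes the power-law exponent at the literature
value $\alpha = 0.3$ for protein structural relaxation; with the
exponent free at 2% noise the power law and the ultraslow bump trade
against each other (bimodal collapse/inflation).  The free-exponent fit
(`fit_ds(alpha = NULL)`) exists precisely to validate that value on
synthetic data: it recovers $0.30 \pm 0.06$ per seed.

**Objective.** For positive spectra the fits minimize squared *log*
residuals — the maximum-likelihood objective under multiplicative
lognormal noise and the exact form of "weights ∝ 1/value" without the
bias that observed-value weights inherit from the noise itself.  The
difference-spectrum stage, whose data cross zero, uses linear residuals
with smoothed-parent weights.

**Optimization.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`,
maximum 10⁴ evaluations, tolerances 1e-10) with positive parameters on
a log scale.  Three deterministic robustness devices replace random
multi-starts: (i) each solve is restarted from its own solution until
the deviance stops improving (a collapsed trust region otherwise ends
fits early in curved valleys); (ii) the difference-spectrum stage tries
six deterministic starting configurations (three oscillator-shape sets
× two ultraslow-time starts) and keeps the best optimum; (iii) where an
ultraslow time parameter is free (the direct whole-model fit
`fit_wtl_direct`, used as an internal cross-check), the objective is
profiled over it on a fixed grid before the final polish, because that
direction is shallow and multimodal.  Search ranges:
$\tau_{\mathrm{ultraslow}} \in [2\tau_{\mathrm{hydr}}, 60\ \mathrm{ps}]$
— the lower bound breaks the hydration/ultraslow degeneracy, the upper
bound brackets the physically meaningful ultraslow range.

Interpolation between grids is linear in log-frequency / log-value
space.  `join_segments()` merges the two instrument segments after
per-segment background subtraction using the median ratio over the
overlap (≥ half a decade), blending across the overlap with a
log-frequency ramp.

## What the synthetic data emulate

`simulate_edls()` evaluates a calibrated ground-truth model on a
log-spaced 0.6–36,000 GHz grid of 1000 points (the merged resolution of
an interferometric + dispersive instrument pair) and applies
multiplicative lognormal noise (default 2%), matching the
intensity-proportional error of photon-counting detection.  Preset
calibration, chosen once as typical of the reference systems:

* bulk water $\tau = 1$ ps at 25 °C, $\beta = 0.6$; hydration 6× slower
  ($\Delta_{\mathrm{bulk}}:\Delta_{\mathrm{hydr}} = 0.58:0.42$ at
  40 wt% sugar); ultraslow 17× slower than bulk, amplitude fraction set
  so the shell holds 710 waters per lysozyme at the stated composition;
* trehalose rotation $\tau = 300$ ps; protein power law $A$ set so the
  $\nu^{-0.3}$ flank sits about a decade below the rotation tail at
  0.6 GHz (the proportion seen in full-spectrum decompositions of
  dilute protein solutions);
* water bending/stretching bands at 1.5/5.1 THz; two strong solute
  Raman bands at 14/20 THz (the normalization anchor); three Brownian
  oscillators at 0.45/0.95/2.4 THz including a boson-peak-like band;
* Arrhenius activation energies 8 (bulk), 9 (hydration), 10 (ultraslow)
  and 9.5 (rotation) kJ/mol over the 3.5–35 °C grid; the stretching-band
  amplitude decreases weakly with temperature while the bending band and
  protein vibrations stay fixed, and the ultraslow amplitude fraction is
  temperature-independent.

`simulate_ftir()` builds transmission-like spectra as additive
pseudo-Voigt band mixtures on a 2 cm⁻¹ grid (300–5000 cm⁻¹):
solution = (1 − displacement) × solvent + solute-correlated component,
recursively (the ternary solution's solvent is the binary sugar
solution).  The displacement fraction is therefore the exact ground
truth of the SC-IR rescaling factor.  Band shapes use small Lorentzian
fractions (0.03–0.1); heavy Lorentzian far-tails on broad OH bands are
unphysical and would corrupt the quiet-window baseline.  The ternary
preset carries a smaller perturbed-water OH amplitude than the binary
one (fewer solute-perturbed waters when sugar shares the shell).

What the generator does **not** emulate: instrument resolution
functions, detector nonlinearity, correlated (1/f) noise, imperfect
segment stitching beyond scale + constant background, anharmonic
vibrational structure, ATR penetration-depth physics, and any real
compositional uncertainty.  Passing recovery tests on these data
therefore demonstrates the correctness and conditioning of the
*analysis*, not robustness to every instrumental artifact of real
spectra.

## SC-IR extraction

`extract_scir()` computes SC = solution − c·solvent after constant
baseline-offset correction (`baseline_offset()`, quiet window
1800–2500 cm⁻¹).  The factor is the largest c keeping the difference
above −tolerance on the *search grid*: channels where the corrected
solvent exceeds 1% of its maximum.  Outside that support the corrected
solvent can itself be slightly negative (baseline residue), and the
feasibility set would not be monotone in c.  On the search grid the SC
area is monotone decreasing in c, so the bisection (relative precision
1e-6) delivers exactly the minimum-area non-negative distribution.  The
default tolerance is half the robust noise SD from the quiet window
with a floor of 0.2% of the solution maximum; with `tolerance = 0` the
factor of an additively constructed mixture is recovered to 1e-6.
Band metrics (`band_metrics()`) report peak positions by parabolic
interpolation through the three points around a window maximum, peak
values, and trapezoidal areas; `compare_scir()` compares the OH-region
intensity of two extractions after amide-area normalization.

## Degenerate and edge inputs

* Non-positive observations are dropped by the log-objective fits
  (difference data keep them, with linear residuals).
* A fit failing to converge raises an error carrying the optimizer
  diagnostics; a parameter landing on a bound raises a warning.
* `isolate_vibrational()` refuses spectra whose system/temperature do
  not match the fit's provenance (`check = FALSE` overrides, needed for
  difference spectra).
* Empty models, mismatched grids, zero band integrals, and zero
  normalizers are structural errors.

## Problem sizes used in the validation suite

The test suite and the acceptance script run the full protocol at the
five study temperatures with 20 noise seeds (100 staged pipelines,
~1000-point spectra), 20-seed ensembles for the water-shape and
power-law refits, 10-seed ensembles for the vibrational stage, and
noiseless runs for exactness checks — a few minutes in total on one
core.

## Known limitations

* The ultraslow component is reported with the difference-spectrum
  estimate of its time constant; per-temperature scatter of that time
  at 2% noise is large (the amplitude, and hence
  $N_{\mathrm{ultraslow}}$, is much better determined than $\xi_u$).
* The Arrhenius energy of the ultraslow process inherits that scatter;
  at 2% noise it is reliable only after ensemble averaging, whereas the
  bulk and hydration energies are recovered to a few percent from a
  single temperature series.
* The binary water–lysozyme system is generated and fitted only as far
  as the SC-IR analysis and preset context require; its full literature
  decomposition is out of scope.
* `join_segments()` expects known per-segment backgrounds (recorded by
  the generator); blind background estimation is not implemented.
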