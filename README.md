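# hydrospec

Quantifying protein hydration in aqueous protein/cosolute mixtures from
two complementary spectroscopies:

* **broadband depolarized light scattering (DLS)** — the imaginary
  susceptibility χ″(ν) from ~0.6 GHz to 36 THz, decomposed into solute
  rotation, water relaxations and intermolecular vibrations;
* **ATR-FTIR** — solute-correlated infrared (SC-IR) spectra obtained by
  constrained subtraction of the solvent spectrum, probing the protein
  amide bands and the OH-stretch signature of solute-perturbed water.

The package is aimed at spectroscopists studying bioprotection: the
reference system is lysozyme in concentrated aqueous trehalose (a ternary
water/trehalose/lysozyme mixture), where a sub-population of *ultraslow*
hydration water — an order of magnitude slower than bulk water — shields
the protein.

## The model

A broadband susceptibility spectrum is modelled as

    χ″(ν) = χ″_SR(ν) + χ″_WR(ν) + χ″_VIB(ν)

* χ″_SR — solute terms: a Debye rotation `Δ ωτ/(1+ω²τ²)` for the sugar
  and a power law `A ν^(−α)`, α ≈ 0.3, for the protein structural
  relaxation;
* χ″_WR — water relaxations: Cole–Davidson terms
  `Δ (cos φ)^β sin(βφ)`, `φ = arctan(ωτ)`, with β = 0.6 — *bulk*
  (τ ≈ 1 ps at 25 °C), *hydration* (ξ = τ_hydr/τ_bulk ≈ 6) and, only when
  protein and sugar are both present, an *ultraslow* term with
  ξ ≈ 15–20;
* χ″_VIB — damped harmonic oscillators: the H-bond bending (≈1.5 THz)
  and stretching (≈5.1 THz) bands of water, solute Raman bands above
  10 THz, and three Brownian oscillators for the low-frequency protein
  modes.

The headline statistic is the number of ultraslow waters per protein,

    N_ultraslow = r · Δ_ultraslow / (Δ_ultraslow + Δ_hydr + Δ_bulk)

with `r` the water-to-protein mole ratio of the mixture.

Fitting follows a staged protocol: (1) fit the binary sugar–water
spectrum; (2) form the *difference spectrum* (ternary minus rescaled
binary), which isolates the protein power law, its vibrational modes and
the ultraslow water; (3) refit the full ternary model with the
stage-1/stage-2 parameters as constraints.  Each stage is a bounded
Levenberg–Marquardt fit (`minpack.lm`) returning a classed object with
the usual `print`/`summary`/`coef`/`predict`/`residuals`/`plot`/
`simulate` methods.

Because no public data accompany this analysis, the package ships a
synthetic-spectrum generator (`simulate_edls()`, `simulate_ftir()`) with
a fully known ground truth, calibrated to the reference mixtures; every
stage of the analysis is validated as a parameter-recovery experiment.

## Worked example

```r
library(hydrospec)

## synthetic ternary + binary spectra at 25 degC, 2% multiplicative noise
wtl <- simulate_edls("WTL", T_C = 25, noise = 0.02, seed = 1)
wt  <- simulate_edls("WT",  T_C = 25, noise = 0.02, seed = 501)

pp <- ternary_pipeline(wtl, wt)
summary(pp$wt_fit)$retardation
#> hydration
#>  6.012624
amplitude_fractions(pp$ternary_fit)
#>       bulk  hydration  ultraslow
#> 0.53964172 0.40310804 0.05725024

comp <- mixture_composition(lysozyme = 0.03, trehalose = 0.40, water = 0.57)
water_lysozyme_ratio(comp)
#> [1] 15081.88
n_ultraslow(water_lysozyme_ratio(comp), water_amplitudes(pp$ternary_fit))
#> ultraslow
#>   863.441
```

The binary fit reports hydration water ~6× slower than bulk; the ternary
stage resolves an ultraslow component whose amplitude fraction, scaled by
the ~15,000 waters per lysozyme in the mixture, counts the ultraslow
shell.  A single 2%-noise realization scatters around the true shell size
(here 863 against a ground truth of 710); averaging over the five study
temperatures and 20 noise seeds, as `scripts/acceptance.R` does, recovers
≈705 — a single hydration layer of about 700 waters.

The SC-IR side:

```r
wl <- baseline_offset(simulate_ftir("WL"))
w  <- baseline_offset(simulate_ftir("W"))
sc <- extract_scir(wl, w)
sc$band_metrics[1:2, c("window", "peak_position")]
#>     window peak_position
#> 1  amide_I      1649.598
#> 2 amide_II      1551.769
```

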