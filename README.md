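# obpfluor

Fluorescence characterization of ligand-binding protein stability — binding
isotherms, chemical denaturation, FRET, lifetimes and pH transitions in one
analysis chain.

## What it is for

Lipocalins such as the odorant-binding proteins (OBPs) enclose a hydrophobic
ligand cavity inside an eight-stranded antiparallel β-barrel. Their
functional state is routinely probed by fluorescence: a reporter ligand like
1-aminoanthracene (AMA) lights up when it binds inside the barrel, the
intrinsic tryptophan emission is quenched by Förster resonance energy
transfer (FRET) to the bound ligand, chemical denaturants unfold the barrel
in a two-state transition read out through the Trp band, and acid exposure
populates compact intermediates detected with
8-anilinonaphthalene-1-sulfonate (ANS). `obpfluor` implements the complete
quantitative chain for such experiments, for spectroscopists who want
reproducible, scriptable fits rather than instrument-vendor black boxes:

* **spectra** — emission/absorbance containers, band features (λmax by
  parabolic refinement, FWHH by half-maximum crossings), inner-filter and
  baseline corrections, and per-Trp decomposition of total fluorescence
  across homologues with nested Trp sets.
* **binding** — the exact 1:1 ligand-depletion isotherm
  `PL = ((P0+L0+Kd) − sqrt((P0+L0+Kd)² − 4·P0·L0))/2`, channel models for
  direct ligand excitation, FRET donor quenching and acceptor enhancement,
  single-channel and joint (shared-Kd) fits, and Kd-versus-denaturant
  tables with amplitude-based reliability flags.
* **folding** — two-state equilibrium denaturation with linear baselines,
  `F(C) = [F_N(C) + F_U(C)·e^(−m(C½−C)/RT)] / [1 + e^(−m(C½−C)/RT)]`,
  the native-fraction transform α_N(C), the unfolding constant
  K_U = (1−α_N)/α_N, linear-extrapolation thermodynamics
  ΔG°_U = m·C½, and a hysteresis index for unfolding/refolding pairs.
* **fret** — E = 1 − F_DA/F_D and E = 1 − τ_DA/τ_D, the overlap integral
  J = ∫F̂_D(λ) ε_A(λ) λ⁴ dλ, the Förster radius
  R₀[Å] = 0.2108·(κ² n⁻⁴ Φ_D J)^(1/6), distance inversion
  R = R₀·((1−E)/E)^(1/6), orientation-factor (κ²) inversion from a
  structurally known distance, and comparative-method quantum yields.
* **lifetime** — multi-exponential decay fitting by iterative reconvolution
  against a measured instrument response (Poisson weights, variable
  projection), 1-vs-2 component model selection, and intensity- or
  amplitude-weighted average lifetimes.
* **ph_stability** — Hill-type sigmoid fits of acid transitions and peak
  detection for the non-monotone ANS channel.
* **synthetic_data** — seeded generators for every input type
  (bit-reproducible, noiseless mode exact), so the full pipeline is
  testable without instrument data.

## Worked example

Simulate a titration of 5 μM protein with 0–50 μM ligand (true Kd = 5 μM,
1 % relative noise) and fit the depletion isotherm; then an unfolding curve
and a photon-counting decay:

```r
library(obpfluor)

tit <- gen_titration(Kd_uM = 5, P0_uM = 5, channel = "acceptor_enhance",
                     config = generator_config(42))
fit_binding(tit)
#> Binding fit (acceptor_enhance, depletion model): Kd = 5.16 +/- 0.19 uM

curve <- gen_denaturation(config = generator_config(7))
fit_two_state(curve)
#> Two-state fit: C1/2 = 2.917 +/- 0.010 M, m = 14.91 +/- 0.75 kJ/mol/M
#> dG0(H2O) = m*C1/2 = 43.5 +/- 2.2 kJ/mol (RT = 2.4372)

trace <- gen_decay(config = generator_config(7, "poisson"))
fit <- select_model(trace)
fit
#> 2-exponential decay fit: tau = 2.62 ns (alpha = 0.42), tau = 7.82 ns
#> (alpha = 0.58); chi2_red = 0.829
weighted_average_lifetime(fit, "intensity")
#> [1] 6.79...
```

The binding fit recovers the dissociation constant within its standard
error; the denaturation fit returns the transition midpoint C½ (M), the
cooperativity m (kJ mol⁻¹ M⁻¹) and their linear-extrapolation product
ΔG°_U; the decay fit resolves the two Trp lifetime components from the
reconvolved histogram, and their intensity-weighted average is the donor
lifetime that enters the lifetime-based FRET efficiency
`efficiency_from_lifetime(tau_DA, tau_avg)`.

A thin command-line wrapper (`inst/scripts/obpfluor`) exposes the same
operations as `simulate`/`fit` subcommands for shell pipelines; see
`?run_cli`.

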