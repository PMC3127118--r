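---
title: "Models and methods behind obpfluor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind obpfluor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obpfluor)
```

`obpfluor` implements the quantitative analysis chain for fluorescence
characterization of lipocalin ligand-binding proteins: ligand-binding
isotherms with depletion, two-state chemical denaturation, Förster resonance
energy transfer (FRET), time-correlated single-photon-counting (TCSPC)
lifetime analysis, and acid-transition fitting. This vignette explains each
model, its assumptions, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## The experimental system the defaults emulate

The package defaults describe a monomeric engineered bovine odorant-binding
protein carrying two tryptophan residues, titrated with the fluorescent
ligand 1-aminoanthracene (AMA), unfolded with guanidinium chloride, and
probed at acidic pH with the hydrophobic-surface dye ANS. The numbers wired
into the generators — Trp emission peaking at 346 nm with a 55 nm band
width, a dissociation constant of ~5 μM at 5 μM protein, an unfolding
midpoint of 2.90 M denaturant with cooperativity 14.3 kJ mol⁻¹ M⁻¹, donor
lifetimes of 2.9 and 8.0 ns with amplitude fractions 0.45/0.55 collapsing
to 2.8 ns at saturating acceptor, and an acid transition centred at pH 2 —
are the study conditions under which the fitters are validated. They are
defaults, not constraints: every generator and fitter takes arbitrary
values.

## Ligand binding with depletion

At total protein `P0` comparable to `Kd` (both ~5 μM here), the common
free-ligand hyperbola `f_b = L0/(Kd+L0)` is badly biased because binding
depletes the free ligand. The package therefore works with the exact 1:1
mass-action solution

```
PL = ((P0 + L0 + Kd) − sqrt((P0 + L0 + Kd)² − 4·P0·L0)) / 2
```

evaluated in the numerically stable product form
`2·P0·L0 / (b + sqrt(b² − 4·P0·L0))`, which avoids catastrophic
cancellation when `Kd → 0`. Three readout channels map the bound fraction
`PL/P0` linearly onto signal:

* `direct_ligand` and `acceptor_enhance`:
  `F = F_ref + F_inf·PL/P0 + slope·(L0 − PL)`. The free-ligand background
  slope defaults to 0 — the bound ligand's emission enhancement is orders
  of magnitude above the free-ligand background in this system — but is a
  settable parameter.
* `donor_quench`: `F = F_ref·(1 − E_app·PL/P0)`, where `E_app` is the
  apparent maximal fractional quench at saturation (≈ the FRET efficiency
  when quenching is transfer-dominated).

Because both channel models are **linear in their amplitude parameters once
`Kd` is fixed**, initialization is a 1-D profile scan over `Kd` (121 points,
log-spaced over 10⁻²·⁵–10³·⁵ μM) with an inner linear solve; the profiled
optimum seeds a Levenberg–Marquardt refinement of all parameters, whose
covariance supplies the standard errors. A pure-hyperbola alternative
(`model = "hyperbola"`) is provided for the dilute regime `P0 ≪ Kd`;
depletion is the default because it is correct in both regimes.

Joint donor+acceptor fits share a single `Kd` with channel-specific
amplitudes. Channels are weighted by the inverse residual variance of their
own independent fits, so channels with different dynamic ranges (a quenching
signal dropping by half versus an enhancement rising from zero) contribute
comparably to the pooled objective.

`kd_vs_denaturant()` tabulates per-condition fits. A condition whose
saturation amplitude falls below 20 % (settable) of the reference
(lowest-denaturant) amplitude is flagged `unreliable`: when unfolding
abolishes specific binding, the titration still fits numerically, but `Kd`
no longer measures cavity binding.

## Two-state denaturation and linear extrapolation

The denaturation signal model assumes a reversible N ⇌ U equilibrium with
linearly denaturant-dependent native and unfolded baselines:

```
F(C) = [ (F_N⁰ + k_N·C) + (F_U⁰ + k_U·C)·exp(−m(C½ − C)/RT) ]
       / [ 1 + exp(−m(C½ − C)/RT) ]
```

Internally this is evaluated through the logistic
`α_N(C) = plogis(m(C½ − C)/RT)` as `F = α_N·F_N(C) + (1−α_N)·F_U(C)`, which
is overflow-safe at extreme arguments. Under the linear extrapolation model
ΔG_U(C) = ΔG°_U − mC, the standard unfolding free energy is
`ΔG°_U = m·C½`, with its error propagated from the full `(m, C½)` covariance
of the fit.

Numerical choices:

* **RT** defaults to `8.314e-3 × 293.15 = 2.4373 kJ/mol` (20 °C, the usual
  acquisition temperature for these measurements); it is an explicit,
  overridable argument everywhere it enters.
* Baselines are initialized by line fits to the outer quarters of the
  concentration range; the midpoint from the half-crossing of the
  baseline-normalized signal; `m` from the slope of `ln K_U` versus `C` in
  the transition zone (which equals `m/RT`).
* After convergence the fit *requires* at least two points beyond
  `C½ ± 2RT/m` on each side — a transition without sampled baselines yields
  unidentifiable thermodynamics and is rejected rather than reported.
* Baseline slopes are unconstrained in sign.

Refolding curves are refused for thermodynamic fitting unless
`force = TRUE`: at finite equilibration times refolding lags unfolding
(hysteresis), so only unfolding data represent equilibrium. The
`hysteresis_index()` quantifies that lag as the mean absolute difference
between the two curves after normalizing each to its own lowest-denaturant
value — zero iff the curves coincide, shrinking as re-equilibration
completes. The index is a descriptive summary, not a kinetic model.

## FRET

Efficiencies come from steady state, `E = 1 − F_DA/F_D`, or from lifetimes,
`E = 1 − τ_DA/τ_D`, with `τ_D` the intensity-weighted average donor
lifetime for multi-exponential donors. The overlap integral

```
J = ∫ F̂_D(λ) ε_A(λ) λ⁴ dλ      [M⁻¹ cm⁻¹ nm⁴]
```

is computed by the trapezoid rule on the union grid of both spectra over
their common support; the donor spectrum is area-normalized internally, so
`J` is invariant to donor intensity scaling and linear in the acceptor
extinction. The Förster radius uses the standard constant for these units:

```
R₀ [Å] = 0.2108 · (κ² · n⁻⁴ · Φ_D · J)^(1/6)
```

documented bit-exactly as `FORSTER_PREFACTOR_A = 0.2108` (equivalently
0.02108 nm). The refractive index defaults to `n = 1.33` (aqueous buffer)
and is settable; using the protein-interior convention `n = 1.4` lowers
`R₀` by about 3 %.

**Distance inversion.** The package uses `R = R₀·((1−E)/E)^(1/6)`, the
inversion of `E(R) = R₀⁶/(R₀⁶ + R⁶)`. One sometimes sees the form with
`E/(1−E)` instead; that form would make the inferred distance *grow* with
efficiency and exceed `R₀` for `E > 0.5`, contradicting both the definition
of `R₀` as the 50 %-transfer distance and the physics of dipole–dipole
transfer. With `E = 0.6` and `R₀ = 50 Å` the implemented inversion gives
`R = 46.7 Å`, slightly below `R₀`, as it must be.

**κ² inversion.** When the donor–acceptor distance is known independently
(e.g. a crystal structure), `kappa2_from_structure()` computes
`R₀ = R·(E/(1−E))^(1/6)` (this direction *is* the `E/(1−E)` root) and
inverts the closed form for κ². A κ² far below the isotropic 2/3 —
flagged `restricted_rotation` below 0.05 — indicates rotationally hindered
chromophores, the expected situation for a ligand wedged inside a β-barrel
and for Trp side chains packed against it. Values above 4 are physically
impossible and flagged `unphysical`. The two Trp donors are treated as a
single effective donor; per-donor weighting is a documented extension
point, not implemented.

Comparative quantum yields follow
`Φ = Φ_ref · (I_sample/I_ref) · (A_ref/A_sample)`; both samples must be
optically thin (A < 0.1) and a warning is raised otherwise. With the Trp
in-water reference `Φ_ref = 0.14`, an integral ratio of 5/7 at matched
absorbance gives `Φ_D = 0.1`, the kind of value typical for partially
quenched protein Trp.

## Spectral features and per-Trp decomposition

Band features use 3-point parabolic refinement of the discrete maximum for
λmax and linear interpolation of the two half-maximum crossings for the
FWHH — robust on the 0.5 nm grids these instruments produce, and exact for
a triangle; for a Gaussian the FWHH converges to `2σ√(2 ln 2)` as the grid
refines. A maximum at the grid boundary, or a flank that never reaches half
maximum, is an error (truncated band), not a silent extrapolation.

The synthetic band is a log-normal (Siano–Metzler) peak parameterized
directly by (λmax, FWHH, asymmetry ρ): the half-maximum points sit at
`λmax + FWHH·ρ/(ρ+1)` and `λmax − FWHH/(ρ+1)`, so the requested features
are exact before noise, while `ρ = 1.2` adds the mild red tail a pure
Gaussian cannot show; `ρ → 1` recovers the Gaussian.

`trp_decomposition()` assumes each homologous Trp keeps the same relative
efficiency in every protein carrying it. When the proteins' Trp sets form a
nested chain (one-, two-, three-Trp homologues), the additive system is
triangular and solves exactly by successive differences (implemented as a
QR solve, which also handles repeated sets); non-nested sets make the
system underdetermined and are rejected, and a negative solved efficiency —
the assumption's failure mode — warns rather than errors.

The inner-filter correction is the centre-illuminated-cuvette form
`F_corr = F_obs·10^((A_ex+A_em)/2)`. Textbook treatments offer several
variants differing in geometry factors; this is the standard choice for the
cuvette geometry and is documented here as the package's convention. Under
optically thin conditions (A < 0.1) the correction stays below ~12 %.

## TCSPC reconvolution

The measured decay is the convolution of the molecular decay
`Σ αᵢ·exp(−t/τᵢ)` with the instrument response function (IRF), measured
from scattered light on the same grid. `reconvolve()` performs the causal
discrete convolution (FFT-based) with the IRF normalized to unit sum and
optionally shifted by linear interpolation.

`fit_decay()` minimizes the Poisson-weighted residual
(`σ² = max(counts, 1)`) over the window from the IRF leading edge (1 % of
its peak) to the last bin with ≥ 10 counts (settable). The component scales
and the constant background are **linear** given the lifetimes and the IRF
shift, so the nonlinear search (Levenberg–Marquardt) runs only over
`(log τ, shift)` with the shift bounded to ±2 bins — the variable-projection
structure that makes these fits fast and basin-robust. Standard errors come
from the Gauss–Newton covariance over the full parameter vector at the
optimum. Lifetimes are initialized from the tail slope of the log-counts.

`select_model()` keeps two components only when the reduced chi-square
improves by more than a factor 1.15 (settable) *and* the pair is resolvable
(τ ratio ≥ 1.2, positive amplitudes above 1 %); otherwise the
single-exponential fit is returned, guarding against fitting Poisson noise
with a second component. Both candidate fits are kept in `$candidates`.

The **weighted-average lifetime** defaults to intensity weighting,
`⟨τ⟩ = Σαᵢτᵢ²/Σαᵢτᵢ`, the mean photon-emission time. For components
2.9/8.0 ns with amplitude fractions 0.45/0.55 this gives
`(0.45·2.9² + 0.55·8²)/(0.45·2.9 + 0.55·8) = 6.83 ns`, whereas amplitude
weighting `Σαᵢτᵢ` gives 5.71 ns — a 1.1 ns difference, which is why the
mode is explicit and intensity weighting (the quantity relevant for
steady-state-consistent FRET efficiencies) is the default. Amplitudes are
treated as pre-exponential fractions throughout.

## pH transitions

No mechanistic proton-linkage model is imposed; the protein channel is fit
with the minimal form producing a midpoint, the Hill-type sigmoid
`S(pH) = low + (high−low)/(1 + 10^(n(mid−pH)))`, with the direction
inferred from the data and the fit refused when the signal range is under
three times the noise level (estimated from first differences). The ANS
channel rises and then falls as the compact acid intermediate forms and
then dissolves into the fully denatured state, so it is handled by peak
detection (parabolic refinement) rather than a sigmoid; the two
half-maximum pH values delimit the reported intermediate window. This is an
analysis convention of the package, not a thermodynamic claim.

## Synthetic data: what it does and does not emulate

Generators exist for every input type: emission bands, titrations,
denaturation curves (with a refolding midpoint shift emulating hysteresis),
reconvolved Poisson decays with a separately Poisson-sampled Gaussian IRF
(σ = 0.25 ns, decay peak 10⁴ counts, IRF peak 10⁵ by default), and pH
curves. Steady-state noise is relative Gaussian (default 1 %), matching
photomultiplier behaviour at high signal; decay noise is strictly Poisson.

Each generator call takes a `generator_config` with a **mandatory seed**,
seeds a local RNG and restores the global state afterwards, so identical
configurations are bit-identical and adding or reordering calls never
perturbs other outputs. Noiseless mode (`config = NULL` or
`noise_scale = 0`) returns exact model values, and every fitter round-trips
noiseless generator output to ≤ 10⁻⁶ relative error.

What passing these tests shows: the estimators are unbiased and correctly
scaled under the stated noise models at the stated designs. What it does
not show: robustness to instrument artifacts the generators deliberately
omit — lamp drift, pile-up and afterpulsing in TCSPC, scattering
backgrounds, wavelength-dependent detector response, or correlated
baseline drifts. Real data violating those assumptions will need the
corrections in the `spectra` module (or upstream instrument corrections)
before the fitters' error estimates are trustworthy.

## Validation design and problem sizes

The test suite validates each fitter two ways: exact round trips on
noiseless data, and bias checks on seeded replicate ensembles at the study
designs — 200 replicate unfolding curves (25 points, 0–6 M, 1 % noise),
200 titrations (11 points, 0–50 μM at 5 μM protein, 1 % noise; single and
joint channels), 200 decay pairs (256 bins over 50 ns, 10⁴ peak counts)
including model-selection accuracy, and 200 pH curves (pH 1–7 in 0.25
steps, 2 % noise). Closed-form pieces are checked against independent
oracles: the depletion quadratic against a bisection solution of the
mass-action equation on 1 000 random parameter triples (to 10⁻¹⁰), and the
Förster distance inversion against the forward efficiency (to 10⁻¹²).
These sizes were chosen to estimate ensemble means to well under the
uncertainties being tested while keeping the suite quick to run.

## Known limitations

* Binding is strictly 1:1; no cooperativity, multiple sites or competition.
* Folding is strictly two-state with linear baselines; intermediates,
  kinetics and thermal denaturation are out of scope.
* FRET assumes a single effective donor and a single κ²; distance
  *distributions* and time-resolved FRET are not modelled.
* Lifetime analysis is limited to 1–2 discrete components with a constant
  background; no global multi-wavelength analysis or lifetime
  distributions.
* The pH sigmoid is descriptive; its Hill coefficient should not be read
  as a proton count.
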