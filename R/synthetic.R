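#' Generator configuration
#'
#' Shared configuration for the seeded synthetic-data generators. Every
#' stochastic generator call must carry a seed; an identical configuration
#' produces bit-identical output. Each generator call seeds its own local RNG
#' stream (the global RNG state is saved and restored), so adding or
#' reordering generator calls never perturbs other outputs.
#'
#' @param seed integer seed (mandatory for any noisy output).
#' @param noise_model `"gaussian_relative"` (steady-state channels) or
#'   `"poisson"` (photon-counting decays).
#' @param noise_scale relative noise level for the Gaussian model
#'   (default 0.01, i.e. 1 percent, typical photomultiplier behaviour at
#'   high signal); ignored by the Poisson model.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed, noise_model = c("gaussian_relative",
                                                   "poisson"),
                             noise_scale = 0.01) {
  noise_model <- match.arg(noise_model)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a scalar integer seed is mandatory")
  structure(list(seed = as.integer(seed), noise_model = noise_model,
                 noise_scale = noise_scale),
            class = "generator_config")
}

# Run expr with a locally seeded RNG; global state restored afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.rel_noise <- function(y, config) {
  if (is.null(config) || config$noise_scale == 0) return(y)
  .with_seed(config$seed,
             y * (1 + stats::rnorm(length(y), sd = config$noise_scale)))
}

# Log-normal band shape (Siano-Metzler form) with exact peak position and
# FWHH; rho > 1 puts the heavier tail on the red side, as for Trp emission.
.lognormal_band <- function(lambda, lambda_max, fwhh, rho = 1.2) {
  if (abs(rho - 1) < 1e-6) {
    sigma <- fwhh / (2 * sqrt(2 * log(2)))
    return(exp(-(lambda - lambda_max)^2 / (2 * sigma^2)))
  }
  arg <- 1 + (lambda - lambda_max) * (rho^2 - 1) / (rho * fwhh)
  y <- numeric(length(lambda))
  ok <- arg > 0
  y[ok] <- exp(-(log(2) / log(rho)^2) * log(arg[ok])^2)
  y
}

#' Generate a synthetic emission spectrum
#'
#' Log-normal emission band with exact requested peak position and FWHH
#' before noise. The mild red-tail asymmetry (default `rho = 1.2`) emulates
#' the shape of Trp emission bands; defaults emulate the native protein band
#' (peak 346 nm, FWHH 55 nm). Relative Gaussian noise per the configuration.
#'
#' @param lambda_max_nm band peak (nm).
#' @param fwhh_nm full width at half height (nm), > 0.
#' @param total_au integrated (trapezoid) intensity of the noiseless band.
#' @param grid wavelength grid (nm); must cover `lambda_max +/- 2 fwhh`.
#' @param asymmetry log-normal asymmetry `rho` (1 = Gaussian).
#' @param excitation_nm metadata.
#' @param config [generator_config()] or NULL for a noiseless band.
#' @return An [emission_spectrum()].
#' @export
gen_emission_spectrum <- function(lambda_max_nm = 346, fwhh_nm = 55,
                                  total_au = 1,
                                  grid = seq(lambda_max_nm - 2.5 * fwhh_nm,
                                             lambda_max_nm + 2.5 * fwhh_nm,
                                             by = 0.5),
                                  asymmetry = 1.2, excitation_nm = 295,
                                  config = NULL) {
  if (fwhh_nm <= 0) stop("fwhh must be positive")
  if (min(grid) > lambda_max_nm - 2 * fwhh_nm ||
      max(grid) < lambda_max_nm + 2 * fwhh_nm)
    stop("grid truncates the band: must cover lambda_max +/- 2 FWHH")
  y <- .lognormal_band(grid, lambda_max_nm, fwhh_nm, asymmetry)
  y <- y * total_au / pracma::trapz(grid, y)
  y <- .rel_noise(y, config)
  emission_spectrum(grid, y, excitation_nm = excitation_nm)
}

#' Generate a synthetic binding titration
#'
#' Evaluates the channel signal model on the true parameters and applies
#' relative Gaussian noise. The default design matches the study conditions:
#' 11 points over 0-50 uM total ligand at 5 uM total protein with a true
#' `Kd` of 5 uM.
#'
#' @param Kd_uM true dissociation constant.
#' @param P0_uM total protein.
#' @param channel titration channel (see [titration_series()]).
#' @param F_ref,F_inf,E_app channel amplitudes (see [model_signal()]).
#' @param L0_uM total-ligand grid (uM).
#' @param condition condition label carried into the series.
#' @param config [generator_config()] or NULL for noiseless data.
#' @return A [titration_series()].
#' @export
gen_titration <- function(Kd_uM = 5, P0_uM = 5,
                          channel = c("direct_ligand", "donor_quench",
                                      "acceptor_enhance"),
                          F_ref = if (channel == "donor_quench") 100 else 0,
                          F_inf = 100, E_app = 0.6,
                          L0_uM = seq(0, 50, by = 5), condition = NA,
                          config = NULL) {
  channel <- match.arg(channel)
  y <- model_signal(L0_uM, P0_uM, Kd_uM, channel, F_ref = F_ref,
                    F_inf = F_inf, E_app = E_app)
  y <- .rel_noise(y, config)
  titration_series(L0_uM, y, P0_uM, channel, condition = condition)
}

#' Generate a synthetic denaturation curve
#'
#' Two-state signal with linear baselines evaluated on the true parameters
#' plus relative Gaussian noise. Defaults are the study's unfolding truth for
#' the engineered monomeric protein (midpoint 2.90 M, m = 14.3 kJ/mol/M) on
#' a 25-point 0-6 M denaturant grid. Refolding curves get the midpoint
#' shifted left by `hysteresis_shift`, emulating incomplete re-equilibration
#' at short times.
#'
#' @param C_half_M,m_kJ_mol_M true midpoint and cooperativity.
#' @param FN0,kN,FU0,kU baseline truth.
#' @param C_M denaturant grid (M).
#' @param direction `"unfolding"` or `"refolding"`.
#' @param hysteresis_shift midpoint left-shift (M) applied to refolding.
#' @param RT thermal energy (kJ/mol).
#' @param time_label free text.
#' @param config [generator_config()] or NULL.
#' @return A [denaturation_curve()].
#' @export
gen_denaturation <- function(C_half_M = 2.90, m_kJ_mol_M = 14.3,
                             FN0 = 1.0, kN = -0.02, FU0 = 0.30, kU = 0.01,
                             C_M = seq(0, 6, length.out = 25),
                             direction = c("unfolding", "refolding"),
                             hysteresis_shift = 0, RT = rt_kJ_mol(),
                             time_label = "", config = NULL) {
  direction <- match.arg(direction)
  mid <- if (direction == "refolding") C_half_M - hysteresis_shift
         else C_half_M
  y <- two_state_signal(C_M, mid, m_kJ_mol_M, FN0, kN, FU0, kU, RT)
  y <- .rel_noise(y, config)
  denaturation_curve(C_M, y, direction, time_label)
}

#' Generate a synthetic photon-counting decay
#'
#' Reconvolves the true multi-exponential decay with a Gaussian IRF and
#' applies Poisson counting noise; the IRF is returned as a separately
#' Poisson-sampled scatter trace (as measured from scattered light).
#' Defaults emulate the native-protein truth: lifetimes 2.9/8.0 ns with
#' amplitude fractions 0.45/0.55, IRF sigma 0.25 ns, 1e4 peak counts.
#'
#' @param tau_ns true lifetimes (ns).
#' @param alpha true amplitude fractions.
#' @param irf_sigma_ns Gaussian IRF width (ns).
#' @param irf_center_ns IRF peak position (ns).
#' @param peak_counts decay peak counts (Poisson scale).
#' @param irf_peak_counts IRF trace peak counts.
#' @param background_cps true constant background per bin.
#' @param n_bins,t_max_ns grid: `n_bins` uniform bins over `[0, t_max_ns]`.
#' @param config [generator_config()] with a seed; required for Poisson
#'   sampling. NULL returns the noiseless expected curves.
#' @return A [decay_trace()].
#' @export
gen_decay <- function(tau_ns = c(2.9, 8.0), alpha = c(0.45, 0.55),
                      irf_sigma_ns = 0.25, irf_center_ns = 2,
                      peak_counts = 1e4, irf_peak_counts = 1e5,
                      background_cps = 0, n_bins = 256L, t_max_ns = 50,
                      config = NULL) {
  dt <- t_max_ns / n_bins
  if (min(tau_ns) / dt < 10)
    stop("grid too coarse: need >= 10 bins per shortest lifetime")
  t <- (seq_len(n_bins) - 0.5) * dt
  irf_true <- stats::dnorm(t, irf_center_ns, irf_sigma_ns)
  model <- reconvolve(tau_ns, alpha, t, irf_true,
                      background = 0)
  model <- model * peak_counts / max(model) + background_cps
  irf_scaled <- irf_true * irf_peak_counts / max(irf_true)
  if (is.null(config)) {
    counts <- model
    irf_counts <- irf_scaled
  } else {
    counts <- .with_seed(config$seed, stats::rpois(n_bins, model))
    irf_counts <- .with_seed(config$seed + 1L,
                             stats::rpois(n_bins, irf_scaled))
  }
  decay_trace(t, counts, irf_counts)
}

#' Generate a synthetic pH curve
#'
#' Protein channel: Hill-type sigmoid with the acid transition (default
#' midpoint pH 2.0, Hill slope 2, quenching to 40 percent of the neutral-pH
#' plateau). ANS channel: a Gaussian intensity bump centred slightly below
#' the protein midpoint (default peak pH 1.9, width chosen so the
#' half-maximum window falls inside pH 1.5-2.5), emulating transient
#' population of the compact acid intermediate.
#'
#' @param channel `"protein"` or `"ANS"`.
#' @param midpoint_pH,hill_n,low_plateau,high_plateau sigmoid truth
#'   (protein channel).
#' @param peak_pH,peak_width_pH,baseline,amplitude bump truth (ANS channel).
#' @param pH pH grid.
#' @param config [generator_config()] or NULL.
#' @return A [ph_curve()].
#' @export
gen_ph_curve <- function(channel = c("protein", "ANS"),
                         midpoint_pH = 2.0, hill_n = 2,
                         low_plateau = 40, high_plateau = 100,
                         peak_pH = 1.9, peak_width_pH = 0.3,
                         baseline = 5, amplitude = 100,
                         pH = seq(1, 7, by = 0.25), config = NULL) {
  channel <- match.arg(channel)
  y <- if (channel == "protein")
    low_plateau + (high_plateau - low_plateau) /
      (1 + 10^(hill_n * (midpoint_pH - pH)))
  else
    baseline + amplitude * exp(-(pH - peak_pH)^2 / (2 * peak_width_pH^2))
  y <- .rel_noise(y, config)
  ph_curve(pH, y, channel)
}
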