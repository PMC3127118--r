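#' Thermal energy RT in kJ/mol
#'
#' Default temperature is 20 degrees C (293.15 K), the acquisition temperature
#' assumed throughout; `R = 8.314 J mol^-1 K^-1`, giving RT = 2.4373 kJ/mol.
#'
#' @param temp_C temperature in degrees Celsius.
#' @return RT in kJ/mol.
#' @export
rt_kJ_mol <- function(temp_C = 20) 8.314e-3 * (273.15 + temp_C)

#' Equilibrium denaturation curve
#'
#' @param C_M denaturant concentrations (M), >= 0.
#' @param F_au fluorescence at fixed excitation/emission.
#' @param direction `"unfolding"` or `"refolding"`. Only unfolding data are
#'   taken as true equilibrium values by default (refolding shows hysteresis
#'   at finite equilibration time).
#' @param time_label free-text equilibration time (e.g. `"2 h"`).
#' @return Object of class `denaturation_curve`.
#' @export
denaturation_curve <- function(C_M, F_au,
                               direction = c("unfolding", "refolding"),
                               time_label = "") {
  direction <- match.arg(direction)
  C_M <- as.numeric(C_M); F_au <- as.numeric(F_au)
  if (length(C_M) != length(F_au))
    stop("C and F must have the same length")
  if (length(C_M) < 7L)
    stop("at least 7 points spanning the transition are required")
  if (any(C_M < 0)) stop("denaturant concentrations must be >= 0")
  o <- order(C_M)
  structure(
    list(C_M = C_M[o], F_au = F_au[o], direction = direction,
         time_label = time_label),
    class = "denaturation_curve")
}

#' Two-state denaturation signal
#'
#' Signal of a reversible two-state N <-> U equilibrium with linear native and
#' unfolded baselines:
#' `F(C) = [(FN0 + kN C) + (FU0 + kU C) exp(-m (C_half - C)/RT)] /
#'         [1 + exp(-m (C_half - C)/RT)]`.
#'
#' @param C denaturant concentration (M), vectorized.
#' @param C_half midpoint concentration (M).
#' @param m cooperativity (kJ mol^-1 M^-1).
#' @param FN0,kN native-baseline intercept and slope.
#' @param FU0,kU unfolded-baseline intercept and slope.
#' @param RT thermal energy (kJ/mol), default [rt_kJ_mol()].
#' @return Predicted signal.
#' @export
two_state_signal <- function(C, C_half, m, FN0, kN, FU0, kU,
                             RT = rt_kJ_mol()) {
  aN <- stats::plogis(m * (C_half - C) / RT)
  aN * (FN0 + kN * C) + (1 - aN) * (FU0 + kU * C)
}

#' Native molar fraction
#'
#' `alpha_N(C) = 1 / (1 + exp(-m (C_half - C)/RT))`, the logistic transform of
#' the linear-extrapolation free energy.
#'
#' @inheritParams two_state_signal
#' @return `alpha_N` in (0, 1), monotone decreasing in `C`.
#' @export
native_fraction <- function(C, m, C_half, RT = rt_kJ_mol()) {
  if (m <= 0) stop("m must be positive")
  stats::plogis(m * (C_half - C) / RT)
}

#' Unfolding equilibrium constant from the native fraction
#'
#' `K_U = [U]/[N] = (1 - alpha_N)/alpha_N`; `ln K_U` is linear in denaturant
#' with slope `m/RT`.
#'
#' @param alpha_N native fraction strictly inside (0, 1), vectorized.
#' @return `K_U`.
#' @export
unfolding_K <- function(alpha_N) {
  if (any(alpha_N <= 0) || any(alpha_N >= 1))
    stop("alpha_N must lie strictly inside (0, 1)")
  (1 - alpha_N) / alpha_N
}

#' Standard unfolding free energy by linear extrapolation
#'
#' `dG0 = m * C_half`, the free energy of unfolding extrapolated to zero
#' denaturant under the linear extrapolation model. The standard error is
#' propagated from the fit covariance of `(m, C_half)` when supplied.
#'
#' @param m cooperativity (kJ mol^-1 M^-1), > 0.
#' @param C_half midpoint (M), > 0.
#' @param se_m,se_C standard errors of `m` and `C_half` (optional).
#' @param cov_mC covariance between `m` and `C_half` (optional).
#' @return List with `dG0_kJ_mol` and `se_kJ_mol`.
#' @export
delta_g0 <- function(m, C_half, se_m = NA_real_, se_C = NA_real_,
                     cov_mC = 0) {
  if (m < 0 || C_half < 0) stop("m and C_half must be non-negative")
  se <- if (is.finite(se_m) && is.finite(se_C))
    sqrt((C_half * se_m)^2 + (m * se_C)^2 + 2 * m * C_half * cov_mC)
  else NA_real_
  list(dG0_kJ_mol = m * C_half, se_kJ_mol = se)
}

#' Fit the two-state denaturation model
#'
#' Six-parameter least squares of the two-state signal (midpoint,
#' cooperativity and two linear baselines). Baselines are initialized by line
#' fits to the outer quarters of the concentration range; the midpoint from
#' the half-crossing of the baseline-normalized signal; `m` from the slope of
#' `ln K_U` versus `C` in the transition zone. Refolding curves are refused
#' for thermodynamic fitting unless `force = TRUE`, since only unfolding data
#' represent true equilibrium values at finite equilibration times.
#'
#' @param curve a [denaturation_curve()].
#' @param RT thermal energy (kJ/mol).
#' @param force fit refolding data anyway (exploratory only).
#' @return Object of class `two_state_fit` with `C_half_M`, `m_kJ_mol_M`,
#'   baselines, `dG0_kJ_mol` (= m * C_half), standard errors and covariance.
#' @export
fit_two_state <- function(curve, RT = rt_kJ_mol(), force = FALSE) {
  stopifnot(inherits(curve, "denaturation_curve"))
  if (curve$direction == "refolding" && !force)
    stop("refolding data are not at equilibrium; use force = TRUE for an ",
         "exploratory fit (thermodynamic parameters not trustworthy)")
  C <- curve$C_M; y <- curve$F_au
  rngC <- range(C); span <- diff(rngC)
  loN <- C <= rngC[1] + 0.25 * span
  hiU <- C >= rngC[2] - 0.25 * span
  bN <- stats::coef(stats::lm(y[loN] ~ C[loN]))
  bU <- stats::coef(stats::lm(y[hiU] ~ C[hiU]))
  FN <- bN[1] + bN[2] * C
  FU <- bU[1] + bU[2] * C
  aN <- (y - FU) / (FN - FU)
  mid_idx <- which(diff(sign(aN - 0.5)) != 0)
  if (length(mid_idx) == 0)
    stop("no transition midpoint inside the data range")
  i <- mid_idx[1]
  C_half0 <- stats::approx(aN[i:(i + 1)], C[i:(i + 1)], xout = 0.5)$y
  inz <- aN > 0.05 & aN < 0.95
  m0 <- if (sum(inz) >= 3) {
    lk <- log((1 - aN[inz]) / aN[inz])
    max(stats::coef(stats::lm(lk ~ C[inz]))[2] * RT, 1)
  } else max(4 * RT / (span / 4), 1)
  # require baseline support on both flanks of the transition
  width <- 4 * RT / m0
  if (sum(C < C_half0 - width / 2) < 2)
    stop("no pre-transition (native) baseline points in the curve")
  if (sum(C > C_half0 + width / 2) < 2)
    stop("no post-transition (unfolded) baseline points in the curve")
  dat <- data.frame(C = C, y = y)
  fml <- y ~ two_state_signal(C, C_half, m, FN0, kN, FU0, kU, RT)
  environment(fml) <- list2env(list(RT = RT,
                                    two_state_signal = two_state_signal),
                               parent = environment())
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fml, data = dat,
      start = list(C_half = C_half0, m = m0, FN0 = unname(bN[1]),
                   kN = unname(bN[2]), FU0 = unname(bU[1]),
                   kU = unname(bU[2])),
      lower = c(C_half = 0, m = 1e-3, FN0 = -Inf, kN = -Inf, FU0 = -Inf,
                kU = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) stop("two-state fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 6, 6))
  se <- sqrt(diag(vc))
  if (cf[["C_half"]] < rngC[1] || cf[["C_half"]] > rngC[2])
    stop("fitted transition midpoint outside the data range")
  # both baselines must be sampled beyond the fitted transition zone
  halfw <- 2 * RT / cf[["m"]]
  if (sum(C < cf[["C_half"]] - halfw) < 2)
    stop("no pre-transition (native) baseline points in the curve")
  if (sum(C > cf[["C_half"]] + halfw) < 2)
    stop("no post-transition (unfolded) baseline points in the curve")
  dg <- delta_g0(cf[["m"]], cf[["C_half"]],
                 se_m = se[["m"]], se_C = se[["C_half"]],
                 cov_mC = vc["m", "C_half"])
  structure(
    list(C_half_M = cf[["C_half"]], m_kJ_mol_M = cf[["m"]],
         FN0_au = cf[["FN0"]], kN_au_M = cf[["kN"]],
         FU0_au = cf[["FU0"]], kU_au_M = cf[["kU"]],
         dG0_kJ_mol = dg$dG0_kJ_mol, dG0_se_kJ_mol = dg$se_kJ_mol,
         RT_kJ_mol = RT, se = se, cov = vc,
         direction = curve$direction, forced = force,
         fitted = stats::fitted(fit), residuals = stats::residuals(fit),
         nls = fit),
    class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf(
    "Two-state fit: C1/2 = %.3f +/- %.3f M, m = %.2f +/- %.2f kJ/mol/M\n",
    x$C_half_M, x$se[["C_half"]], x$m_kJ_mol_M, x$se[["m"]]))
  cat(sprintf("dG0(H2O) = m*C1/2 = %.1f +/- %.1f kJ/mol (RT = %.4f)\n",
              x$dG0_kJ_mol, x$dG0_se_kJ_mol, x$RT_kJ_mol))
  if (x$direction == "refolding")
    cat("NOTE: fitted on refolding (non-equilibrium) data\n")
  invisible(x)
}

#' Hysteresis index between unfolding and refolding curves
#'
#' Both curves are normalized to their own lowest-concentration value (the
#' `F/F0` convention) and linearly interpolated onto a fine shared grid; the
#' index is the mean absolute difference over the shared concentration range
#' (area between the curves divided by the range width). It is 0 iff the
#' curves coincide and decreases as the refolding curve relaxes onto the
#' unfolding one at long equilibration times.
#'
#' @param unfold,refold [denaturation_curve()] objects with overlapping
#'   concentration ranges.
#' @param n_grid interpolation grid size.
#' @return Scalar index in `[0, Inf)` (for normalized signals of order 1,
#'   effectively `[0, 1]`).
#' @export
hysteresis_index <- function(unfold, refold, n_grid = 201L) {
  stopifnot(inherits(unfold, "denaturation_curve"),
            inherits(refold, "denaturation_curve"))
  lo <- max(min(unfold$C_M), min(refold$C_M))
  hi <- min(max(unfold$C_M), max(refold$C_M))
  if (lo >= hi) stop("curves have non-overlapping concentration ranges")
  norm <- function(cv) cv$F_au / cv$F_au[which.min(cv$C_M)]
  g <- seq(lo, hi, length.out = n_grid)
  u <- stats::approx(unfold$C_M, norm(unfold), xout = g)$y
  r <- stats::approx(refold$C_M, norm(refold), xout = g)$y
  pracma::trapz(g, abs(u - r)) / (hi - lo)
}
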