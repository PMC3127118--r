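# Forster-radius prefactor in Angstrom for J in M^-1 cm^-1 nm^4:
# R0 = 0.2108 * (kappa2 * n^-4 * phi_D * J)^(1/6) Angstrom
# (equivalently 0.02108 nm), the standard bundling of 9000 ln10 / (128 pi^5 N_A).
FORSTER_PREFACTOR_A <- 0.2108

#' FRET efficiency from steady-state intensities
#'
#' `E = 1 - F_DA / F_D`, with `F_D` and `F_DA` the donor intensity in the
#' absence and presence of saturating acceptor.
#'
#' @param F_D donor intensity without acceptor, > 0.
#' @param F_DA donor intensity with saturating acceptor, `0 <= F_DA <= F_D`.
#' @return Efficiency in `[0, 1]`.
#' @export
efficiency_from_intensity <- function(F_D, F_DA) {
  if (any(F_D <= 0)) stop("F_D must be positive")
  if (any(F_DA < 0)) stop("F_DA must be non-negative")
  if (any(F_DA > F_D))
    stop("F_DA > F_D: donor enhancement, not energy transfer")
  1 - F_DA / F_D
}

#' FRET efficiency from donor lifetimes
#'
#' `E = 1 - tau_DA / tau_D`, with lifetimes of the donor in the presence and
#' absence of the acceptor. For a multi-exponential donor, `tau_D` should be
#' the intensity-weighted average lifetime
#' (see [weighted_average_lifetime()]).
#'
#' @param tau_DA donor lifetime with acceptor (ns), > 0.
#' @param tau_D_avg (average) donor lifetime without acceptor (ns), > 0.
#' @return Efficiency in `[0, 1)`.
#' @export
efficiency_from_lifetime <- function(tau_DA, tau_D_avg) {
  if (any(tau_DA <= 0) || any(tau_D_avg <= 0))
    stop("lifetimes must be positive")
  if (any(tau_DA > tau_D_avg))
    stop("tau_DA exceeds tau_D: no transfer interpretable")
  1 - tau_DA / tau_D_avg
}

#' Spectral overlap integral
#'
#' `J = integral of F_D_norm(lambda) * eps_A(lambda) * lambda^4 d lambda`,
#' in M^-1 cm^-1 nm^4, by the trapezoid rule on the union grid of the two
#' spectra over their common support. The donor spectrum is area-normalized
#' internally over its full grid.
#'
#' @param donor donor [emission_spectrum()].
#' @param acceptor acceptor [absorbance_spectrum()] (molar extinction).
#' @return Overlap integral `J` (M^-1 cm^-1 nm^4); 0 with a warning when the
#'   spectra have no common wavelength support.
#' @export
overlap_integral <- function(donor, acceptor) {
  stopifnot(inherits(donor, "emission_spectrum"),
            inherits(acceptor, "absorbance_spectrum"))
  lo <- max(min(donor$wavelength_nm), min(acceptor$wavelength_nm))
  hi <- min(max(donor$wavelength_nm), max(acceptor$wavelength_nm))
  if (lo >= hi) {
    warning("donor emission and acceptor absorbance do not overlap; J = 0")
    return(0)
  }
  area <- pracma::trapz(donor$wavelength_nm, donor$intensity_au)
  if (area <= 0) stop("donor spectrum has non-positive integrated intensity")
  grid <- sort(unique(c(
    donor$wavelength_nm[donor$wavelength_nm >= lo & donor$wavelength_nm <= hi],
    acceptor$wavelength_nm[acceptor$wavelength_nm >= lo &
                             acceptor$wavelength_nm <= hi],
    lo, hi)))
  fd <- stats::approx(donor$wavelength_nm, donor$intensity_au,
                      xout = grid)$y / area
  ea <- stats::approx(acceptor$wavelength_nm, acceptor$epsilon_M_cm,
                      xout = grid)$y
  pracma::trapz(grid, fd * ea * grid^4)
}

#' Forster radius
#'
#' `R0 [A] = 0.2108 * (kappa2 * n^-4 * phi_D * J)^(1/6)` with `J` in
#' M^-1 cm^-1 nm^4 -- the standard closed form bundling the physical
#' constants of the Forster rate.
#'
#' @param J overlap integral (M^-1 cm^-1 nm^4), > 0.
#' @param kappa2 dipole orientation factor (2/3 for free rotation).
#' @param phi_D donor quantum yield in (0, 1].
#' @param n_refr refractive index of the medium (1.33 for aqueous buffer).
#' @return Forster radius in Angstrom.
#' @export
forster_radius <- function(J, kappa2 = 2 / 3, phi_D, n_refr = 1.33) {
  if (any(J <= 0) || any(kappa2 <= 0) || any(phi_D <= 0) || any(n_refr <= 0))
    stop("J, kappa2, phi_D and n must be positive")
  FORSTER_PREFACTOR_A * (kappa2 * phi_D * J / n_refr^4)^(1 / 6)
}

#' Donor-acceptor distance from the efficiency
#'
#' Standard Forster inversion `R = R0 * ((1 - E)/E)^(1/6)`, consistent with
#' `E(R) = R0^6 / (R0^6 + R^6)` and with `R0` being the distance at which
#' `E = 0.5`.
#'
#' @param E efficiency strictly inside (0, 1).
#' @param R0_A Forster radius (Angstrom), > 0.
#' @return Distance in Angstrom.
#' @export
distance_from_E <- function(E, R0_A) {
  if (any(E <= 0) || any(E >= 1))
    stop("E must lie strictly inside (0, 1): distance unbounded or zero")
  if (any(R0_A <= 0)) stop("R0 must be positive")
  R0_A * ((1 - E) / E)^(1 / 6)
}

#' FRET efficiency at a known distance
#'
#' `E(R) = R0^6 / (R0^6 + R^6)`; the exact inverse of [distance_from_E()].
#'
#' @param R_A donor-acceptor distance (Angstrom), > 0.
#' @param R0_A Forster radius (Angstrom), > 0.
#' @return Efficiency in (0, 1).
#' @export
efficiency_from_distance <- function(R_A, R0_A) {
  if (any(R_A <= 0) || any(R0_A <= 0)) stop("distances must be positive")
  R0_A^6 / (R0_A^6 + R_A^6)
}

#' Orientation factor from a structurally known distance
#'
#' When the donor-acceptor distance is known independently (e.g. from a
#' crystal structure), the measured efficiency fixes the Forster radius
#' `R0 = R * (E/(1-E))^(1/6)`, and inverting the Forster-radius closed form
#' yields `kappa2 = (R0/0.2108)^6 * n^4 / (phi_D * J)`. Values far below 2/3
#' indicate rotationally restricted chromophores; values outside `[0, 4]`
#' are unphysical and flagged (model assumptions violated).
#'
#' @param E measured efficiency strictly inside (0, 1).
#' @param R_known_A independently known distance (Angstrom), > 0.
#' @param J overlap integral (M^-1 cm^-1 nm^4), > 0.
#' @param phi_D donor quantum yield, > 0.
#' @param n_refr refractive index.
#' @return `kappa2` with attribute `"flag"` (`"ok"`, `"restricted_rotation"`
#'   when below 0.05, or `"unphysical"` outside `[0, 4]`).
#' @export
kappa2_from_structure <- function(E, R_known_A, J, phi_D, n_refr = 1.33) {
  if (J <= 0 || phi_D <= 0) stop("J and phi_D must be positive")
  if (E <= 0 || E >= 1) stop("E must lie strictly inside (0, 1)")
  if (R_known_A <= 0) stop("R_known must be positive")
  R0 <- R_known_A * (E / (1 - E))^(1 / 6)
  k2 <- (R0 / FORSTER_PREFACTOR_A)^6 * n_refr^4 / (phi_D * J)
  flag <- if (k2 > 4) "unphysical"
          else if (k2 < 0.05) "restricted_rotation"
          else "ok"
  structure(k2, flag = flag)
}

#' Comparative-method quantum yield
#'
#' `phi = phi_ref * (I_sample / I_ref) * (A_ref / A_sample)` with `I` the
#' integrated emission and `A` the absorbance at the (matched) excitation
#' wavelength; both samples must be optically thin (A < 0.1) for the linear
#' ratio to hold, and a warning is raised otherwise.
#'
#' @param sample_em sample [emission_spectrum()].
#' @param sample_A sample absorbance at the excitation wavelength, > 0.
#' @param ref_em reference [emission_spectrum()].
#' @param ref_A reference absorbance, > 0.
#' @param phi_ref reference quantum yield (e.g. 0.14 for Trp in water).
#' @return Quantum yield estimate.
#' @export
comparative_quantum_yield <- function(sample_em, sample_A, ref_em, ref_A,
                                      phi_ref) {
  stopifnot(inherits(sample_em, "emission_spectrum"),
            inherits(ref_em, "emission_spectrum"))
  if (ref_A <= 0 || sample_A <= 0) stop("absorbances must be positive")
  if (sample_A >= 0.1 || ref_A >= 0.1)
    warning("absorbance >= 0.1: outside the optically thin regime, ",
            "comparative method biased")
  if (is.finite(sample_em$excitation_nm) && is.finite(ref_em$excitation_nm) &&
      sample_em$excitation_nm != ref_em$excitation_nm)
    warning("sample and reference excitation wavelengths differ")
  Is <- pracma::trapz(sample_em$wavelength_nm, sample_em$intensity_au)
  Ir <- pracma::trapz(ref_em$wavelength_nm, ref_em$intensity_au)
  if (Ir <= 0) stop("reference spectrum has non-positive integral")
  phi_ref * (Is / Ir) * (ref_A / sample_A)
}

#' Bundle a FRET analysis
#'
#' Collects the pieces of a FRET determination (efficiency, overlap integral,
#' Forster radius, inferred distance, orientation factor, donor quantum
#' yield, refractive index) into one validated record.
#'
#' @param E efficiency in `[0, 1]`.
#' @param J overlap integral (M^-1 cm^-1 nm^4), optional.
#' @param R0_A Forster radius (Angstrom), optional.
#' @param R_A donor-acceptor distance (Angstrom), optional.
#' @param kappa2 orientation factor in `[0, 4]`, optional.
#' @param phi_D donor quantum yield in (0, 1], optional.
#' @param n_refr refractive index.
#' @return Object of class `fret_result`.
#' @export
fret_result <- function(E, J = NA_real_, R0_A = NA_real_, R_A = NA_real_,
                        kappa2 = NA_real_, phi_D = NA_real_, n_refr = 1.33) {
  if (E < 0 || E > 1) stop("E must lie in [0, 1]")
  if (is.finite(R0_A) && R0_A <= 0) stop("R0 must be positive")
  if (is.finite(R_A) && R_A <= 0) stop("R must be positive")
  if (is.finite(kappa2) && (kappa2 < 0 || kappa2 > 4))
    stop("kappa2 must lie in [0, 4]")
  if (is.finite(phi_D) && (phi_D <= 0 || phi_D > 1))
    stop("phi_D must lie in (0, 1]")
  structure(
    list(E = E, J = as.numeric(J), R0_A = as.numeric(R0_A),
         R_A = as.numeric(R_A), kappa2 = as.numeric(kappa2),
         phi_D = as.numeric(phi_D), n_refr = n_refr),
    class = "fret_result")
}

#' @export
print.fret_result <- function(x, ...) {
  cat(sprintf("FRET: E = %.3f", x$E))
  if (is.finite(x$R0_A)) cat(sprintf(", R0 = %.1f A", x$R0_A))
  if (is.finite(x$R_A)) cat(sprintf(", R = %.1f A", x$R_A))
  if (is.finite(x$kappa2)) cat(sprintf(", kappa2 = %.3g", x$kappa2))
  cat("\n")
  invisible(x)
}
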