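#' Emission spectrum
#'
#' Container for a fluorescence emission trace on a strictly increasing
#' wavelength grid. Intensities are in arbitrary units; acquisition metadata
#' (excitation wavelength, slit bandwidth) travels with the object so that
#' cross-spectrum comparisons can be sanity-checked.
#'
#' @param wavelength_nm numeric, strictly increasing wavelength grid (nm).
#' @param intensity_au numeric signal, same length as the grid. Small negative
#'   values (e.g. after baseline subtraction of noisy data) are allowed but
#'   trigger a warning; they are never clipped.
#' @param excitation_nm optional excitation wavelength (nm).
#' @param bandwidth_nm optional slit bandwidth (nm).
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength_nm, intensity_au,
                              excitation_nm = NA_real_,
                              bandwidth_nm = NA_real_) {
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity_au <- as.numeric(intensity_au)
  if (length(wavelength_nm) < 3L)
    stop("an emission spectrum needs at least 3 points")
  if (length(wavelength_nm) != length(intensity_au))
    stop("wavelength and intensity must have the same length")
  if (!all(is.finite(wavelength_nm)) || !all(is.finite(intensity_au)))
    stop("wavelengths and intensities must be finite")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing (no duplicates)")
  if (any(intensity_au < 0))
    warning("spectrum contains negative intensities (kept, not clipped)")
  structure(
    list(wavelength_nm = wavelength_nm,
         intensity_au = intensity_au,
         excitation_nm = excitation_nm,
         bandwidth_nm = bandwidth_nm),
    class = "emission_spectrum")
}

#' Molar absorbance spectrum
#'
#' @param wavelength_nm strictly increasing wavelength grid (nm).
#' @param epsilon_M_cm molar extinction coefficient (M^-1 cm^-1), >= 0.
#' @return An object of class `absorbance_spectrum`.
#' @export
absorbance_spectrum <- function(wavelength_nm, epsilon_M_cm) {
  wavelength_nm <- as.numeric(wavelength_nm)
  epsilon_M_cm <- as.numeric(epsilon_M_cm)
  if (length(wavelength_nm) < 3L)
    stop("an absorbance spectrum needs at least 3 points")
  if (length(wavelength_nm) != length(epsilon_M_cm))
    stop("wavelength and epsilon must have the same length")
  if (!all(is.finite(wavelength_nm)) || !all(is.finite(epsilon_M_cm)))
    stop("wavelengths and extinction coefficients must be finite")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing (no duplicates)")
  if (any(epsilon_M_cm < 0))
    stop("extinction coefficients must be non-negative")
  structure(
    list(wavelength_nm = wavelength_nm, epsilon_M_cm = epsilon_M_cm),
    class = "absorbance_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("Emission spectrum: %d points, %.1f-%.1f nm",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm)))
  if (is.finite(x$excitation_nm))
    cat(sprintf(", excitation %.0f nm", x$excitation_nm))
  cat("\n")
  invisible(x)
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  cat(sprintf("Absorbance spectrum: %d points, %.1f-%.1f nm\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm)))
  invisible(x)
}

#' Read a two-column spectrum file
#'
#' Parses whitespace- or comma-delimited two-column text (wavelength, signal).
#' Lines starting with `#` and blank lines are ignored. Rows are sorted by
#' wavelength; duplicated wavelengths are rejected.
#'
#' @param path file path.
#' @param kind `"emission"` or `"absorbance"`.
#' @param excitation_nm,bandwidth_nm optional metadata attached to emission
#'   spectra.
#' @return An [emission_spectrum()] or [absorbance_spectrum()].
#' @export
read_spectrum <- function(path, kind = c("emission", "absorbance"),
                          excitation_nm = NA_real_, bandwidth_nm = NA_real_) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    stop(sprintf("'%s': no data rows", path))
  parts <- strsplit(trimws(lines[idx]), "[,\t ]+")
  n <- length(parts)
  wl <- numeric(n); sig <- numeric(n)
  for (k in seq_len(n)) {
    p <- parts[[k]]
    if (length(p) < 2L)
      stop(sprintf("'%s' line %d: expected two columns", path, idx[k]))
    v <- suppressWarnings(as.numeric(p[1:2]))
    if (any(is.na(v)))
      stop(sprintf("'%s' line %d: non-numeric value '%s'", path, idx[k],
                   lines[idx[k]]))
    wl[k] <- v[1]; sig[k] <- v[2]
  }
  if (anyDuplicated(wl))
    stop(sprintf("'%s': duplicated wavelengths", path))
  o <- order(wl)
  if (kind == "emission")
    emission_spectrum(wl[o], sig[o], excitation_nm, bandwidth_nm)
  else
    absorbance_spectrum(wl[o], sig[o])
}

#' Write a spectrum to a two-column text file
#'
#' @param s an emission or absorbance spectrum.
#' @param path output path.
#' @export
write_spectrum <- function(s, path) {
  y <- if (inherits(s, "emission_spectrum")) s$intensity_au else s$epsilon_M_cm
  writeLines(c("# wavelength_nm signal",
               sprintf("%.6g %.8g", s$wavelength_nm, y)), path)
  invisible(path)
}

#' Band features of an emission spectrum
#'
#' Locates the emission maximum by 3-point parabolic refinement around the
#' discrete maximum, and the full width at half height (FWHH) by linear
#' interpolation of the two half-maximum crossings. The total intensity is the
#' trapezoid integral over the grid. Typical Trp emission of folded lipocalins
#' peaks near 346 nm with FWHH near 55 nm.
#'
#' @param s an [emission_spectrum()].
#' @return A list of class `spectral_features` with elements `lambda_max_nm`,
#'   `fwhh_nm`, `total_intensity_au`.
#' @export
extract_features <- function(s) {
  stopifnot(inherits(s, "emission_spectrum"))
  x <- s$wavelength_nm; y <- s$intensity_au
  n <- length(x)
  i <- which.max(y)
  if (i == 1L || i == n)
    stop("emission maximum at grid boundary: band truncated")
  # parabolic vertex through the 3 points around the discrete maximum
  xi <- x[(i - 1):(i + 1)]; yi <- y[(i - 1):(i + 1)]
  co <- unname(solve(cbind(1, xi, xi^2), yi))
  lam_max <- if (co[3] < 0) -co[2] / (2 * co[3]) else x[i]
  peak <- if (co[3] < 0) co[1] + co[2] * lam_max + co[3] * lam_max^2 else y[i]
  half <- peak / 2
  cross <- function(side) {
    if (side == "left") {
      j <- i
      while (j > 1L && y[j - 1L] > half) j <- j - 1L
      if (j == 1L) stop("no half-maximum crossing on the blue side")
      x[j - 1L] + (half - y[j - 1L]) * (x[j] - x[j - 1L]) / (y[j] - y[j - 1L])
    } else {
      j <- i
      while (j < n && y[j + 1L] > half) j <- j + 1L
      if (j == n) stop("no half-maximum crossing on the red side")
      x[j] + (half - y[j]) * (x[j + 1L] - x[j]) / (y[j + 1L] - y[j])
    }
  }
  lo <- cross("left"); hi <- cross("right")
  structure(
    list(lambda_max_nm = lam_max,
         fwhh_nm = hi - lo,
         total_intensity_au = pracma::trapz(x, y)),
    class = "spectral_features")
}

#' @export
print.spectral_features <- function(x, ...) {
  cat(sprintf(
    "lambda_max = %.2f nm, FWHH = %.2f nm, integrated intensity = %.4g\n",
    x$lambda_max_nm, x$fwhh_nm, x$total_intensity_au))
  invisible(x)
}

#' Inner-filter correction
#'
#' Corrects observed fluorescence for primary and secondary inner-filter
#' attenuation with the standard centre-illuminated-cuvette form
#' `F_corr = F_obs * 10^((A_ex + A_em)/2)`. The correction is negligible in
#' the optically thin regime (A < 0.1, at most a 12.2 percent effect).
#'
#' @param F_obs observed fluorescence (vectorized).
#' @param A_ex absorbance at the excitation wavelength (per pathlength used).
#' @param A_em absorbance at the emission wavelength.
#' @return Corrected fluorescence, same shape as `F_obs`.
#' @export
inner_filter_correct <- function(F_obs, A_ex, A_em) {
  if (any(A_ex < 0) || any(A_em < 0))
    stop("absorbances must be non-negative")
  F_obs * 10^((A_ex + A_em) / 2)
}

#' Subtract a blank spectrum
#'
#' Pointwise subtraction of a blank (buffer) trace from a sample spectrum. If
#' the grids differ, the blank is linearly interpolated onto the sample grid;
#' the blank must cover the sample's wavelength range. Negative differences
#' (noise) are kept and flagged by the constructor's warning, never clipped.
#'
#' @param s sample [emission_spectrum()].
#' @param blank blank [emission_spectrum()].
#' @return An [emission_spectrum()] with `s`'s metadata.
#' @export
subtract_baseline <- function(s, blank) {
  stopifnot(inherits(s, "emission_spectrum"),
            inherits(blank, "emission_spectrum"))
  if (min(blank$wavelength_nm) > min(s$wavelength_nm) ||
      max(blank$wavelength_nm) < max(s$wavelength_nm))
    stop("blank does not cover the sample wavelength range")
  if (is.finite(s$excitation_nm) && is.finite(blank$excitation_nm) &&
      s$excitation_nm != blank$excitation_nm)
    warning("sample and blank were acquired at different excitation wavelengths")
  b <- stats::approx(blank$wavelength_nm, blank$intensity_au,
                     xout = s$wavelength_nm)$y
  emission_spectrum(s$wavelength_nm, s$intensity_au - b,
                    s$excitation_nm, s$bandwidth_nm)
}

#' Per-tryptophan fluorescence decomposition
#'
#' Distributes total fluorescence intensities of homologous proteins over
#' their individual Trp residues, assuming each homologous Trp keeps the same
#' relative efficiency in every protein that carries it. The proteins' Trp
#' sets must form a nested chain (e.g. one-Trp, two-Trp and three-Trp
#' homologues), which makes the additive system triangular and exactly
#' solvable by successive differences.
#'
#' @param total_intensities named numeric: total fluorescence per protein,
#'   on a common relative scale (typically normalized to the smallest-set
#'   protein).
#' @param compositions named list of character vectors: Trp labels carried by
#'   each protein; names must match `total_intensities`.
#' @return Named numeric of per-Trp relative efficiencies.
#' @export
trp_decomposition <- function(total_intensities, compositions) {
  if (is.null(names(total_intensities)) ||
      !setequal(names(total_intensities), names(compositions)))
    stop("total_intensities and compositions must share protein names")
  prot <- names(total_intensities)
  sets <- lapply(compositions[prot], as.character)
  o <- order(lengths(sets))
  prot <- prot[o]; sets <- sets[o]
  for (k in seq_along(sets)[-1]) {
    if (!all(sets[[k - 1]] %in% sets[[k]]))
      stop("Trp sets do not form a nested chain: system underdetermined")
  }
  labels <- unique(unlist(sets))
  M <- vapply(labels,
              function(l) as.numeric(vapply(sets, function(s) l %in% s,
                                            logical(1))),
              numeric(length(sets)))
  M <- matrix(M, nrow = length(sets), ncol = length(labels),
              dimnames = list(prot, labels))
  qrM <- qr(M)
  if (qrM$rank < length(labels))
    stop("system underdetermined: more Trp labels than independent proteins")
  eff <- qr.coef(qrM, as.numeric(total_intensities[prot]))
  if (any(eff < 0))
    warning("negative solved efficiency: equal-efficiency assumption violated")
  stats::setNames(as.numeric(eff), labels)
}
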