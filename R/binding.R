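#' Titration series
#'
#' A fluorescence titration at constant total protein `P0` and variable total
#' ligand `L0`, read out in one of three channels: direct ligand excitation
#' (`"direct_ligand"`), FRET quenching of the protein donor
#' (`"donor_quench"`), or FRET enhancement of the bound-ligand acceptor
#' (`"acceptor_enhance"`).
#'
#' @param L0_uM total ligand concentrations (uM), non-negative, increasing.
#' @param signal_au fluorescence per point (arbitrary units).
#' @param P0_uM total protein concentration (uM), constant, > 0.
#' @param channel one of `"direct_ligand"`, `"donor_quench"`,
#'   `"acceptor_enhance"`.
#' @param condition free-text condition label (e.g. denaturant molarity).
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(L0_uM, signal_au, P0_uM,
                             channel = c("direct_ligand", "donor_quench",
                                         "acceptor_enhance"),
                             condition = NA) {
  channel <- match.arg(channel)
  L0_uM <- as.numeric(L0_uM); signal_au <- as.numeric(signal_au)
  if (length(L0_uM) != length(signal_au))
    stop("L0 and signal must have the same length")
  if (length(L0_uM) < 5L)
    stop("at least 5 titration points are required for fitting")
  if (any(L0_uM < 0)) stop("total ligand concentrations must be >= 0")
  if (is.unsorted(L0_uM, strictly = FALSE)) {
    o <- order(L0_uM); L0_uM <- L0_uM[o]; signal_au <- signal_au[o]
  }
  if (!is.numeric(P0_uM) || length(P0_uM) != 1L || P0_uM <= 0)
    stop("P0 must be a single positive concentration")
  structure(
    list(L0_uM = L0_uM, signal_au = signal_au, P0_uM = P0_uM,
         channel = channel, condition = condition),
    class = "titration_series")
}

#' Bound-complex concentration with ligand depletion
#'
#' Exact 1:1 mass-action solution for the protein-ligand complex at total
#' protein `P0` and total ligand `L0`:
#' `PL = ((P0+L0+Kd) - sqrt((P0+L0+Kd)^2 - 4 P0 L0)) / 2`,
#' evaluated in the numerically stable product form. Required whenever the
#' protein concentration is comparable to `Kd` (here both are in the low-uM
#' range), where the free-ligand hyperbola is badly biased.
#'
#' @param P0_uM total protein (uM), >= 0.
#' @param L0_uM total ligand (uM), >= 0 (vectorized).
#' @param Kd_uM dissociation constant (uM), > 0.
#' @return Complex concentration `PL` (uM), within `[0, min(P0, L0)]`.
#' @export
bound_complex <- function(P0_uM, L0_uM, Kd_uM) {
  if (any(P0_uM < 0) || any(L0_uM < 0) || any(Kd_uM < 0))
    stop("concentrations and Kd must be non-negative")
  if (any(Kd_uM == 0)) stop("Kd must be strictly positive")
  b <- P0_uM + L0_uM + Kd_uM
  disc <- pmax(b^2 - 4 * P0_uM * L0_uM, 0)
  pl <- 2 * P0_uM * L0_uM / (b + sqrt(disc))  # stable root
  pmin(pl, pmin(P0_uM, L0_uM))
}

#' Predicted titration signal per channel
#'
#' Channel-specific linear maps of the bound fraction `PL/P0`:
#' direct-ligand and acceptor-enhancement channels report
#' `F = F_ref + F_inf * PL/P0 + free_slope * (L0 - PL)` (free-ligand
#' background off by default); the donor-quench channel reports
#' `F = F_ref * (1 - E_app * PL/P0)` where `E_app` is the apparent maximal
#' fractional quench at saturation.
#'
#' @param L0_uM total ligand grid (uM).
#' @param P0_uM total protein (uM).
#' @param Kd_uM dissociation constant (uM).
#' @param channel titration channel (see [titration_series()]).
#' @param F_ref signal at `L0 = 0` (donor channel) or intercept (ligand
#'   channels, default 0).
#' @param F_inf saturation amplitude for ligand channels.
#' @param E_app apparent maximal fractional quench for the donor channel.
#' @param free_slope linear free-ligand background term (signal per uM),
#'   default 0.
#' @param model `"depletion"` (exact quadratic, default) or `"hyperbola"`
#'   (`PL/P0 = L0/(Kd+L0)`, valid only for `P0 << Kd`).
#' @return Predicted signal over the `L0_uM` grid.
#' @export
model_signal <- function(L0_uM, P0_uM, Kd_uM, channel,
                         F_ref = 0, F_inf = NA_real_, E_app = NA_real_,
                         free_slope = 0,
                         model = c("depletion", "hyperbola")) {
  model <- match.arg(model)
  pl <- if (model == "depletion") bound_complex(P0_uM, L0_uM, Kd_uM)
        else P0_uM * L0_uM / (Kd_uM + L0_uM)
  fb <- pl / P0_uM
  switch(channel,
    donor_quench = F_ref * (1 - E_app * fb),
    direct_ligand = ,
    acceptor_enhance = F_ref + F_inf * fb + free_slope * (L0_uM - pl),
    stop("unknown channel: ", channel))
}

# Kd grid profile with inner linear solve; both channel models are linear in
# their amplitude parameters once Kd is fixed, so initialization reduces to a
# 1-D scan.
.profile_kd <- function(series, free_slope, model) {
  L0 <- series$L0_uM; y <- series$signal_au; P0 <- series$P0_uM
  grid <- 10^seq(-2.5, 3.5, length.out = 121)
  best <- list(ssr = Inf)
  for (kd in grid) {
    pl <- if (model == "depletion") bound_complex(P0, L0, kd)
          else P0 * L0 / (kd + L0)
    fb <- pl / P0
    X <- cbind(1, fb)
    fit <- stats::lm.fit(X, y - free_slope * (L0 - pl))
    ssr <- sum(fit$residuals^2)
    if (ssr < best$ssr) best <- list(ssr = ssr, kd = kd, coef = fit$coefficients)
  }
  best
}

#' Fit a binding isotherm to one titration channel
#'
#' Nonlinear least squares for the dissociation constant and channel
#' amplitudes. Initialization comes from a 1-D profile over `Kd` (the
#' amplitude parameters are linear given `Kd`), refined by
#' Levenberg-Marquardt; parameter standard errors come from the fit
#' covariance.
#'
#' @param series a [titration_series()].
#' @param free_slope fixed free-ligand background slope (ligand channels).
#' @param model `"depletion"` (default) or `"hyperbola"`.
#' @return Object of class `binding_fit` with elements `Kd_uM`, `se`,
#'   `F_ref_au`, `F_inf_au`, `E_app` (donor channel), `amplitude_au`
#'   (absolute saturation signal change), `channel`, `residuals`, `fitted`,
#'   `flags`.
#' @export
fit_binding <- function(series, free_slope = 0,
                        model = c("depletion", "hyperbola")) {
  stopifnot(inherits(series, "titration_series"))
  model <- match.arg(model)
  L0 <- series$L0_uM; y <- series$signal_au; P0 <- series$P0_uM
  rng <- diff(range(y))
  if (rng <= .Machine$double.eps^0.5 * max(abs(y), 1))
    stop("signal does not vary with ligand: Kd non-identifiable")
  prof <- .profile_kd(series, free_slope, model)
  kd0 <- prof$kd; a0 <- unname(prof$coef[1]); b0 <- unname(prof$coef[2])
  dat <- data.frame(L0 = L0, y = y)
  flags <- character()
  if (series$channel == "donor_quench") {
    if (b0 > 0) flags <- c(flags, "unexpected_direction")
    fml <- y ~ Fref + B * .pl_frac(P0, L0, Kd, model)
    start <- list(Fref = a0, B = b0, Kd = kd0)
  } else {
    if (b0 < 0) flags <- c(flags, "unexpected_direction")
    fml <- y ~ Fref + B * .pl_frac(P0, L0, Kd, model) +
      free_slope * (L0 - .pl_frac(P0, L0, Kd, model) * P0)
    start <- list(Fref = a0, B = b0, Kd = kd0)
  }
  env <- list2env(list(P0 = P0, model = model, free_slope = free_slope,
                       .pl_frac = .pl_frac), parent = environment())
  environment(fml) <- env
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = dat, start = start,
                      lower = c(Fref = -Inf, B = -Inf, Kd = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("binding fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  if (cf[["Kd"]] <= 2e-9) flags <- c(flags, "Kd_at_bound")
  kd <- cf[["Kd"]]; Fref <- cf[["Fref"]]; B <- cf[["B"]]
  if (series$channel == "donor_quench") {
    E_app <- -B / Fref
    F_inf <- Fref + B          # plateau signal at full saturation
    amplitude <- abs(B)
  } else {
    E_app <- NA_real_
    F_inf <- B
    amplitude <- abs(B)
  }
  structure(
    list(Kd_uM = kd, F_ref_au = Fref, F_inf_au = F_inf, E_app = E_app,
         amplitude_au = amplitude,
         se = c(Kd_uM = unname(se["Kd"]), F_ref_au = unname(se["Fref"]),
                B = unname(se["B"])),
         channel = series$channel, condition = series$condition,
         model = model, P0_uM = P0,
         fitted = stats::fitted(fit), residuals = stats::residuals(fit),
         flags = flags, nls = fit),
    class = "binding_fit")
}

.pl_frac <- function(P0, L0, Kd, model) {
  if (model == "depletion") bound_complex(P0, L0, Kd) / P0
  else L0 / (Kd + L0)
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Binding fit (%s, %s model): Kd = %.3g +/- %.2g uM\n",
              x$channel, x$model, x$Kd_uM, x$se[["Kd_uM"]]))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Joint donor + acceptor binding fit with a shared Kd
#'
#' Fits the FRET donor-quench and acceptor-enhancement titrations together
#' with one shared dissociation constant and channel-specific amplitudes.
#' Each channel is weighted by the inverse residual variance of its own
#' independent fit, so channels with different dynamic ranges contribute
#' comparably.
#'
#' @param donor a `donor_quench` [titration_series()].
#' @param acceptor an `acceptor_enhance` [titration_series()].
#' @param model `"depletion"` or `"hyperbola"`.
#' @return A `binding_fit` with `channel = "joint"` and per-channel
#'   amplitudes in `$channels`.
#' @export
fit_binding_joint <- function(donor, acceptor,
                              model = c("depletion", "hyperbola")) {
  stopifnot(inherits(donor, "titration_series"),
            inherits(acceptor, "titration_series"))
  model <- match.arg(model)
  if (donor$channel != "donor_quench" ||
      acceptor$channel != "acceptor_enhance")
    stop("expected a donor_quench and an acceptor_enhance series")
  if (abs(donor$P0_uM - acceptor$P0_uM) > 1e-9)
    stop("donor and acceptor series must share the same P0")
  P0 <- donor$P0_uM
  fd <- fit_binding(donor, model = model)
  fa <- fit_binding(acceptor, model = model)
  wd <- 1 / max(stats::var(fd$residuals), .Machine$double.eps)
  wa <- 1 / max(stats::var(fa$residuals), .Machine$double.eps)
  dat <- data.frame(
    L0 = c(donor$L0_uM, acceptor$L0_uM),
    y = c(donor$signal_au, acceptor$signal_au),
    is_d = rep(c(1, 0), c(length(donor$L0_uM), length(acceptor$L0_uM))),
    w = rep(c(wd, wa), c(length(donor$L0_uM), length(acceptor$L0_uM))))
  kd0 <- exp(mean(log(c(fd$Kd_uM, fa$Kd_uM))))
  fml <- y ~ is_d * (Ad + Bd * .pl_frac(P0, L0, Kd, model)) +
    (1 - is_d) * (Aa + Ba * .pl_frac(P0, L0, Kd, model))
  environment(fml) <- list2env(list(P0 = P0, model = model,
                                    .pl_frac = .pl_frac),
                               parent = environment())
  start <- list(Ad = fd$F_ref_au, Bd = -fd$E_app * fd$F_ref_au,
                Aa = fa$F_ref_au, Ba = fa$F_inf_au, Kd = kd0)
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = dat, start = start, weights = dat$w,
                      lower = c(Ad = -Inf, Bd = -Inf, Aa = -Inf, Ba = -Inf,
                                Kd = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("joint binding fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 5))
  structure(
    list(Kd_uM = cf[["Kd"]],
         se = c(Kd_uM = unname(se["Kd"])),
         channels = list(
           donor_quench = list(F_ref_au = cf[["Ad"]],
                               E_app = -cf[["Bd"]] / cf[["Ad"]]),
           acceptor_enhance = list(F_ref_au = cf[["Aa"]],
                                   F_inf_au = cf[["Ba"]])),
         F_ref_au = cf[["Ad"]], F_inf_au = cf[["Ba"]], E_app = -cf[["Bd"]] / cf[["Ad"]],
         amplitude_au = abs(cf[["Ba"]]),
         channel = "joint", model = model, P0_uM = P0,
         fitted = stats::fitted(fit), residuals = stats::residuals(fit),
         flags = character(), nls = fit,
         independent = list(donor = fd, acceptor = fa)),
    class = "binding_fit")
}

#' Dissociation constant versus denaturant
#'
#' Fits each titration independently and tabulates `Kd` and the saturation
#' amplitude `F_inf` per condition. Conditions whose amplitude falls below a
#' settable fraction of the first (reference, typically 0 M denaturant)
#' condition's amplitude are flagged unreliable, reflecting the loss of
#' specific binding signal as the protein unfolds. A failed fit in one
#' condition does not abort the table.
#'
#' @param series_list list of [titration_series()], conditions as labels.
#' @param unreliable_frac amplitude fraction below which a condition is
#'   flagged (default 0.2).
#' @param ... passed to [fit_binding()].
#' @return `data.frame` with columns `condition`, `Kd_uM`, `Kd_se_uM`,
#'   `F_inf_au`, `amplitude_au`, `unreliable`, `error`.
#' @export
kd_vs_denaturant <- function(series_list, unreliable_frac = 0.2, ...) {
  if (length(series_list) < 2L)
    stop("need at least two denaturant conditions")
  rows <- lapply(series_list, function(s) {
    fit <- tryCatch(fit_binding(s, ...), error = function(e) e)
    if (inherits(fit, "error"))
      data.frame(condition = as.character(s$condition), Kd_uM = NA_real_,
                 Kd_se_uM = NA_real_, F_inf_au = NA_real_,
                 amplitude_au = NA_real_, unreliable = TRUE,
                 error = conditionMessage(fit), stringsAsFactors = FALSE)
    else
      data.frame(condition = as.character(s$condition), Kd_uM = fit$Kd_uM,
                 Kd_se_uM = fit$se[["Kd_uM"]], F_inf_au = fit$F_inf_au,
                 amplitude_au = fit$amplitude_au, unreliable = FALSE,
                 error = NA_character_, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ref_amp <- tab$amplitude_au[1]
  if (is.finite(ref_amp) && ref_amp > 0)
    tab$unreliable <- tab$unreliable |
      !is.finite(tab$amplitude_au) |
      tab$amplitude_au < unreliable_frac * ref_amp
  tab
}
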