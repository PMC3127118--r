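#' pH titration curve
#'
#' @param pH pH values (may be unsorted), within `[0, 14]`.
#' @param signal_au fluorescence signal per point.
#' @param channel `"protein"` (intrinsic Trp fluorescence) or `"ANS"`
#'   (extrinsic hydrophobic-surface probe).
#' @return Object of class `ph_curve`.
#' @export
ph_curve <- function(pH, signal_au, channel = c("protein", "ANS")) {
  channel <- match.arg(channel)
  pH <- as.numeric(pH); signal_au <- as.numeric(signal_au)
  if (length(pH) != length(signal_au))
    stop("pH and signal must have the same length")
  if (length(pH) < 6L) stop("at least 6 pH points are required")
  if (any(pH < 0) || any(pH > 14)) stop("pH values must lie in [0, 14]")
  structure(list(pH = pH, signal_au = signal_au, channel = channel),
            class = "ph_curve")
}

#' Fit a sigmoidal pH transition
#'
#' Hill-type sigmoid in pH,
#' `S(pH) = low + (high - low) / (1 + 10^(n (midpoint - pH)))`,
#' the minimal functional form yielding a transition midpoint. The direction
#' (signal rising or falling with pH) is inferred from the data. The fit is
#' refused when the signal range does not exceed three times the noise level
#' (estimated from first differences).
#'
#' @param curve a [ph_curve()].
#' @return Object of class `ph_transition_fit` with `midpoint_pH`, `hill_n`,
#'   `low_plateau_au`, `high_plateau_au` and standard errors.
#' @export
fit_ph_transition <- function(curve) {
  stopifnot(inherits(curve, "ph_curve"))
  o <- order(curve$pH)
  x <- curve$pH[o]; y <- curve$signal_au[o]
  noise <- stats::sd(diff(y)) / sqrt(2)
  rng <- diff(range(y))
  if (!is.finite(noise)) noise <- 0
  if (rng < 3 * noise || rng == 0)
    stop("no transition detectable: signal range below 3x noise level")
  rising <- stats::cor(x, y) > 0
  lo0 <- if (rising) min(y) else max(y)  # plateau at low pH
  hi0 <- if (rising) max(y) else min(y)
  mid_y <- (lo0 + hi0) / 2
  cross <- which(diff(sign(y - mid_y)) != 0)
  mid0 <- if (length(cross)) {
    i <- cross[1]
    stats::approx(y[i:(i + 1)], x[i:(i + 1)], xout = mid_y)$y
  } else stats::median(x)
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ low + (high - low) / (1 + 10^(n * (mid - x))),
      data = dat,
      start = list(low = lo0, high = hi0, n = 2, mid = mid0),
      lower = c(low = -Inf, high = -Inf, n = 1e-3, mid = min(x)),
      upper = c(low = Inf, high = Inf, n = 50, mid = max(x)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("pH transition fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  structure(
    list(midpoint_pH = cf[["mid"]], hill_n = cf[["n"]],
         low_plateau_au = cf[["low"]], high_plateau_au = cf[["high"]],
         se = c(midpoint_pH = unname(se["mid"]), hill_n = unname(se["n"]),
                low_plateau_au = unname(se["low"]),
                high_plateau_au = unname(se["high"])),
         channel = curve$channel, rising = rising,
         fitted = stats::fitted(fit), residuals = stats::residuals(fit),
         nls = fit),
    class = "ph_transition_fit")
}

#' @export
print.ph_transition_fit <- function(x, ...) {
  cat(sprintf("pH transition (%s channel): midpoint %.2f +/- %.2f, n = %.2f\n",
              x$channel, x$midpoint_pH, x$se[["midpoint_pH"]], x$hill_n))
  invisible(x)
}

#' Peak pH of a non-monotone (ANS-type) channel
#'
#' The ANS-enhancement channel peaks where the compact acid intermediate
#' (molten-globule-like state) is maximally populated, before complete acid
#' denaturation abolishes the hydrophobic binding surface. The peak is
#' located by 3-point parabolic refinement of the discrete maximum; the two
#' half-maximum crossings delimit the reported intermediate window.
#'
#' @param curve a [ph_curve()] with `channel = "ANS"`.
#' @return List with `peak_pH` and `window` (the two half-maximum pH values,
#'   flagged as the molten-globule-like window).
#' @export
detect_peak_channel <- function(curve) {
  stopifnot(inherits(curve, "ph_curve"))
  if (curve$channel != "ANS")
    stop("peak detection applies to the ANS channel")
  o <- order(curve$pH)
  x <- curve$pH[o]; y <- curve$signal_au[o]
  n <- length(x)
  i <- which.max(y)
  if (i == 1L || i == n)
    stop("maximum at the edge of the pH range: no interior peak")
  xi <- x[(i - 1):(i + 1)]; yi <- y[(i - 1):(i + 1)]
  co <- unname(solve(cbind(1, xi, xi^2), yi))
  peak <- if (co[3] < 0) -co[2] / (2 * co[3]) else x[i]
  ymax <- if (co[3] < 0) co[1] + co[2] * peak + co[3] * peak^2 else y[i]
  base <- min(y)
  half <- base + (ymax - base) / 2
  left <- {
    j <- i
    while (j > 1L && y[j - 1L] > half) j <- j - 1L
    if (j == 1L) x[1]
    else stats::approx(y[(j - 1):j], x[(j - 1):j], xout = half)$y
  }
  right <- {
    j <- i
    while (j < n && y[j + 1L] > half) j <- j + 1L
    if (j == n) x[n]
    else stats::approx(y[j:(j + 1)], x[j:(j + 1)], xout = half)$y
  }
  list(peak_pH = peak, window = sort(c(left, right)))
}
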