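# Two-state van't Hoff analysis of UV duplex melting curves.
#
# Model: only two states exist, duplex and single strand, with
# temperature-independent formation enthalpy dH (kcal/mol) and entropy dS
# (cal/mol/K) (dCp = 0). The association constant K(T) = exp(-(dH*1000 -
# T*dS)/(R*T)) enters a mass-action equilibrium that is quadratic in the
# duplex strand fraction, solved in closed form. Absorbance is a
# duplex-fraction-weighted mix of two linear baselines (standard
# hyperchromicity treatment).

R_CAL <- 1.98720425864083  # gas constant, cal / (mol K)

#' Fraction of strands in duplex at a temperature
#'
#' Mass-action equilibrium for duplex formation. For a self-complementary
#' sequence the reaction is `2S = D` with `K = [D]/[S]^2`; for an equimolar
#' heteroduplex `S1 + S2 = D` with `K = [D]/([S1][S2])`. With total strand
#' concentration `ct` and duplex strand fraction `f`, both cases reduce to
#' the quadratic `a (1-f)^2 = f` with `a = 2 K ct` (self-complementary) or
#' `a = K ct / 2` (heteroduplex), whose physical root is
#' `f = 2a / (2a + 1 + sqrt(4a + 1))` (numerically stable at both extremes).
#' At the melting temperature `f = 1/2` by construction.
#'
#' @param temp_C Temperature(s) in Celsius.
#' @param dH Duplex formation enthalpy, kcal/mol (negative for a stable
#'   duplex).
#' @param dS Duplex formation entropy, cal/(mol K).
#' @param ct Total strand concentration, mol/L (> 0).
#' @param self_complementary Logical.
#' @return Fraction of strands in duplex, in `[0, 1]` (vectorized over
#'   `temp_C`).
#' @examples
#' tm <- melting_tm(-85, -240, 3.2e-4, self_complementary = TRUE)
#' duplex_fraction(tm, -85, -240, 3.2e-4, self_complementary = TRUE) # 0.5
#' @export
duplex_fraction <- function(temp_C, dH, dS, ct, self_complementary = FALSE) {
  if (!is.finite(ct) || ct <= 0) stop("strand concentration ct must be > 0")
  t_K <- temp_C + 273.15
  if (any(t_K <= 0)) stop("temperature below 0 K")
  K <- exp(-(dH * 1000 - t_K * dS) / (R_CAL * t_K))
  a <- if (self_complementary) 2 * K * ct else K * ct / 2
  if (any(a < 0, na.rm = TRUE)) stop("negative equilibrium constant: nonphysical input")
  f <- ifelse(is.infinite(a), 1, 2 * a / (2 * a + 1 + sqrt(4 * a + 1)))
  pmin(pmax(f, 0), 1)
}

ct_effective <- function(ct, self_complementary) {
  if (self_complementary) ct else ct / 4
}

#' Melting temperature from two-state thermodynamics
#'
#' The temperature at which half the strands are in duplex at the given
#' total strand concentration: `Tm = dH*1000 / (dS + R ln ct_eff)` (kelvin),
#' with `ct_eff = ct` for a self-complementary duplex and `ct/4` for an
#' equimolar heteroduplex. Bimolecular, hence concentration dependent.
#'
#' @inheritParams duplex_fraction
#' @return Melting temperature in Celsius.
#' @export
melting_tm <- function(dH, dS, ct, self_complementary = FALSE) {
  if (!is.finite(ct) || ct <= 0) stop("strand concentration ct must be > 0")
  denom <- dS + R_CAL * log(ct_effective(ct, self_complementary))
  tm_K <- dH * 1000 / denom
  if (!is.finite(tm_K) || tm_K <= 0) {
    stop("nonphysical thermodynamics: no positive melting temperature")
  }
  tm_K - 273.15
}

#' Simulate a UV melting curve
#'
#' Forward model used both for testing and for power analysis: absorbance is
#' the duplex-fraction-weighted combination of linear lower (folded) and upper
#' (melted) baselines, plus optional Gaussian noise.
#'
#' @inheritParams duplex_fraction
#' @param baseline_low,baseline_high Numeric `c(intercept, slope)` of the
#'   folded and melted absorbance baselines (absorbance units vs Celsius).
#' @param temps Temperature grid, Celsius, within the 10-95 scan window.
#' @param noise_sd Gaussian noise SD on absorbance.
#' @param seed Optional integer seed (same seed, same curve).
#' @return data.frame `temperature_C, absorbance`.
#' @export
simulate_melting_curve <- function(dH, dS, ct, self_complementary = FALSE,
                                   baseline_low = c(0.50, 2e-4),
                                   baseline_high = c(0.64, 4e-4),
                                   temps = seq(10, 95, by = 0.5),
                                   noise_sd = 0, seed = NULL) {
  if (!is.finite(dH) || dH >= 0) {
    stop("dH must be negative for a stabilizing duplex")
  }
  if (any(temps < 10 - 1e-9) || any(temps > 95 + 1e-9)) {
    stop("temps must lie within the 10-95 C scan window")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  fd <- duplex_fraction(temps, dH, dS, ct, self_complementary)
  low <- baseline_low[1] + baseline_low[2] * temps
  high <- baseline_high[1] + baseline_high[2] * temps
  absorbance <- low * fd + high * (1 - fd)
  if (noise_sd > 0) absorbance <- absorbance + stats::rnorm(length(temps), 0, noise_sd)
  data.frame(temperature_C = temps, absorbance = absorbance)
}

two_state_absorbance <- function(temp, dH, tm_C, b0l, b1l, b0h, b1h, ct,
                                 self_complementary) {
  dS <- dH * 1000 / (tm_C + 273.15) -
    R_CAL * log(ct_effective(ct, self_complementary))
  fd <- duplex_fraction(temp, dH, dS, ct, self_complementary)
  (b0l + b1l * temp) * fd + (b0h + b1h * temp) * (1 - fd)
}

#' Fit a two-state melting transition
#'
#' Least-squares fit of the forward model in [simulate_melting_curve()] to an
#' experimental curve, parameterized by `(dH, Tm)` plus two linear baselines
#' (the entropy is derived from `dH`, `Tm` and the strand concentration,
#' which conditions the optimization better than fitting `dS` directly).
#' Initial values come from endpoint baseline fits and the half-hyperchromicity
#' crossing; several enthalpy starts are tried and the best convergent fit
#' kept. A curve with no resolvable transition (flat, or baselines
#' indistinguishable) raises a non-convergence error.
#'
#' @param curve data.frame with columns `temperature_C`, `absorbance`.
#' @param ct Total strand concentration, mol/L.
#' @param self_complementary Logical.
#' @return Object of class `melting_fit`: coefficients `dH` (kcal/mol),
#'   `dS` (cal/mol/K), `Tm` (Celsius), baselines, `rss`, data, and fit
#'   metadata. Methods: `print`, `coef`, `predict`, `residuals`, `fitted`,
#'   `plot`, `summary`.
#' @export
fit_two_state <- function(curve, ct, self_complementary = FALSE) {
  if (!all(c("temperature_C", "absorbance") %in% names(curve))) {
    stop("curve requires columns temperature_C and absorbance")
  }
  curve <- curve[order(curve$temperature_C), , drop = FALSE]
  temp <- curve$temperature_C
  A <- curve$absorbance
  n <- length(temp)
  if (n < 10) stop("need at least 10 points across the transition")
  amp_total <- diff(range(A))
  if (amp_total <= .Machine$double.eps) {
    stop("non-convergence: flat curve, no two-state transition detected")
  }

  n_edge <- max(4, floor(0.2 * n))
  lo <- stats::lm(A ~ temp, subset = seq_len(n_edge))
  hi <- stats::lm(A ~ temp, subset = seq(n - n_edge + 1, n))
  # start Tm at the steepest point of the (lightly smoothed) curve
  w <- min(5, n)
  sm <- stats::filter(A, rep(1 / w, w), sides = 2)
  dA <- diff(as.numeric(sm)) / diff(temp)
  tm0 <- temp[which.max(abs(dA))]
  if (length(tm0) != 1 || !is.finite(tm0)) tm0 <- stats::median(temp)

  start_base <- list(b0l = unname(stats::coef(lo)[1]),
                     b1l = unname(stats::coef(lo)[2]),
                     b0h = unname(stats::coef(hi)[1]),
                     b1h = unname(stats::coef(hi)[2]))
  best <- NULL
  for (dh0 in c(-80, -50, -120, -30, -160)) {
    start <- c(list(dH = dh0, tm_C = tm0), start_base)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        absorbance ~ two_state_absorbance(temperature_C, dH, tm_C,
                                          b0l, b1l, b0h, b1h,
                                          ct, self_complementary),
        data = curve, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("non-convergence: unable to fit a two-state transition")
  }
  cf <- stats::coef(best$fit)
  dH <- unname(cf["dH"]); tm_C <- unname(cf["tm_C"])
  # a degenerate fit (coincident baselines, or Tm pushed out of the scan)
  # means the curve carries no resolvable transition
  amp_tm <- abs((cf["b0h"] + cf["b1h"] * tm_C) -
                  (cf["b0l"] + cf["b1l"] * tm_C))
  resid_sd <- sqrt(best$rss / max(1, n - 6))
  if (amp_tm < max(4 * resid_sd, 0.02 * amp_total) ||
      tm_C < min(temp) - 10 || tm_C > max(temp) + 10) {
    stop("non-convergence: no two-state transition detected in the scan range")
  }
  if (dH >= 0) stop("non-convergence: fitted enthalpy is nonnegative")
  dS <- dH * 1000 / (tm_C + 273.15) -
    R_CAL * log(ct_effective(ct, self_complementary))
  structure(list(
    coefficients = c(dH = dH, dS = dS, Tm = tm_C),
    baseline_low = c(intercept = unname(cf["b0l"]), slope = unname(cf["b1l"])),
    baseline_high = c(intercept = unname(cf["b0h"]), slope = unname(cf["b1h"])),
    ct = ct, self_complementary = self_complementary,
    rss = best$rss, fitted = stats::fitted(best$fit),
    residuals = stats::residuals(best$fit), data = curve,
    nls = best$fit),
    class = "melting_fit")
}

#' @export
print.melting_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Two-state van't Hoff melting fit\n")
  cat(sprintf("  dH = %.1f kcal/mol, dS = %.1f cal/(mol K), Tm = %.2f C\n",
              cf["dH"], cf["dS"], cf["Tm"]))
  cat(sprintf("  ct = %.3g M (%s), rss = %.3g over %d points\n",
              x$ct,
              if (x$self_complementary) "self-complementary" else "heteroduplex",
              x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
coef.melting_fit <- function(object, ...) object$coefficients

#' @export
residuals.melting_fit <- function(object, ...) object$residuals

#' @export
fitted.melting_fit <- function(object, ...) object$fitted

#' @export
summary.melting_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Predict absorbance or duplex fraction from a melting fit
#'
#' @param object A `melting_fit`.
#' @param temp_C Temperatures at which to predict (default: fitted grid).
#' @param type `"absorbance"` or `"duplex_fraction"`.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.melting_fit <- function(object, temp_C = object$data$temperature_C,
                                type = c("absorbance", "duplex_fraction"),
                                ...) {
  type <- match.arg(type)
  cf <- object$coefficients
  fd <- unname(duplex_fraction(temp_C, unname(cf["dH"]), unname(cf["dS"]),
                               object$ct, object$self_complementary))
  if (type == "duplex_fraction") return(fd)
  low <- object$baseline_low[1] + object$baseline_low[2] * temp_C
  high <- object$baseline_high[1] + object$baseline_high[2] * temp_C
  as.numeric(low * fd + high * (1 - fd))
}

#' @export
plot.melting_fit <- function(x, ...) {
  graphics::plot(x$data$temperature_C, x$data$absorbance, pch = 1,
                 xlab = "temperature (C)", ylab = "absorbance", ...)
  tt <- seq(min(x$data$temperature_C), max(x$data$temperature_C), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = 2)
  graphics::abline(v = x$coefficients["Tm"], lty = 3)
  invisible(x)
}

#' Percentage of single-stranded DNA at a temperature
#'
#' `100 * (1 - duplex_fraction)` from a fitted melting curve: the quantity
#' used to verify that duplexes remained essentially double stranded at the
#' irradiation temperature.
#'
#' @param fit A `melting_fit`.
#' @param temp_C Temperature, Celsius.
#' @return Percent single stranded, in `[0, 100]`.
#' @export
single_stranded_percent <- function(fit, temp_C) {
  if (!inherits(fit, "melting_fit")) stop("fit must be a melting_fit")
  100 * (1 - predict(fit, temp_C, type = "duplex_fraction"))
}

#' Read a melting curve from CSV
#'
#' Columns `temperature_C,absorbance`.
#' @param path Path to the CSV file.
#' @return data.frame.
#' @export
read_melting_curve <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("temperature_C", "absorbance") %in% names(m))) {
    stop("melting curve requires columns temperature_C and absorbance")
  }
  m
}
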