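# Steady-state and single-trace kinetics: Michaelis-Menten and hyperbolic
# oxygen-affinity fits, initial-rate extraction from A340 traces,
# single-exponential stopped-flow fits, conversions, melting temperatures
# and holoenzyme quantitation.

NADPH_EPSILON_340 <- 6.22   # mM^-1 cm^-1, NADPH at 340 nm
FAD_EPSILON_450 <- 11.3     # mM^-1 cm^-1, protein-bound FAD at 450 nm

# nls with an nlsLM fallback; returns the fitted object or signals a
# flagged failure after the restart schedule is exhausted.
fit_nls <- function(formula, data, starts_list) {
  last <- NULL
  for (st in starts_list) {
    fit <- tryCatch(stats::nls(formula, data = data, start = st,
                               control = stats::nls.control(maxiter = 200,
                                                            warnOnly = FALSE)),
                    error = function(e) e)
    if (!inherits(fit, "error")) return(fit)
    fit2 <- tryCatch(minpack.lm::nlsLM(formula, data = data, start = st,
                                       control = minpack.lm::nls.lm.control(
                                         maxiter = 200)),
                     error = function(e) e)
    if (!inherits(fit2, "error")) return(fit2)
    last <- fit2
  }
  stop("fit failed to converge after restarts: ",
       conditionMessage(last))
}

#' Fit a Michaelis-Menten saturation curve
#'
#' Nonlinear least squares of \eqn{v = V_{max} S / (K_M + S)} to observed
#' initial rates. Standard errors come from the covariance of the fit.
#' When the enzyme concentration is supplied, \eqn{k_{cat} = V_{max}/[E]}
#' and the catalytic efficiency \eqn{k_{cat}/K_M} is reported in
#' s\eqn{^{-1}} mM\eqn{^{-1}} (using \code{conc_unit} to convert).
#'
#' @param conc Substrate (or coenzyme) concentrations; >= 4 distinct values.
#' @param rate Observed rates, same length as \code{conc}.
#' @param enzyme_conc Optional enzyme concentration in the same unit as the
#'   rates' normalization (rates already in s^-1 need \code{enzyme_conc =
#'   NULL}; raw rates are divided by it).
#' @param conc_unit \code{"uM"} or \code{"mM"}; used to express the
#'   catalytic efficiency in s^-1 mM^-1.
#' @return An \code{mm_fit}: \code{K_M}, \code{K_M_se}, \code{V_max},
#'   \code{V_max_se}, \code{k_cat}, \code{k_cat_se}, \code{efficiency}
#'   (s^-1 mM^-1 when computable), \code{fit} (the nls object),
#'   \code{warnings}.
#' @export
fit_michaelis_menten <- function(conc, rate, enzyme_conc = NULL,
                                 conc_unit = c("uM", "mM")) {
  conc_unit <- match.arg(conc_unit)
  if (length(conc) != length(rate)) stop("conc and rate lengths differ")
  if (any(conc < 0)) stop("negative concentration")
  if (length(unique(conc)) < 4) {
    stop("need at least 4 distinct concentrations")
  }
  warnings <- character()
  if (!is.null(enzyme_conc)) rate <- rate / enzyme_conc
  dat <- data.frame(S = conc, v = rate)
  vmax0 <- max(rate)
  km0 <- stats::median(conc)
  # Hanes-Woolf linearization (S/v vs S) as a data-driven seed
  ok <- rate > 0
  hanes <- tryCatch({
    hf <- stats::lm(I(conc[ok] / rate[ok]) ~ conc[ok])
    b <- stats::coef(hf)
    list(Vmax = 1 / b[2], Km = b[1] / b[2])
  }, error = function(e) NULL)
  starts <- list(list(Vmax = vmax0, Km = km0),
                 list(Vmax = vmax0 * 1.2, Km = km0 / 10),
                 list(Vmax = vmax0 * 2, Km = max(conc)),
                 list(Vmax = vmax0 * 5, Km = 10 * max(conc)))
  # the linearized seed is kept even when negative: convergence to a
  # negative optimum is then reported as a flagged fit failure rather than
  # a generic non-convergence
  if (!is.null(hanes) && is.finite(hanes$Vmax) && is.finite(hanes$Km) &&
      abs(hanes$Km) > 0) {
    starts <- c(list(list(Vmax = unname(hanes$Vmax),
                          Km = unname(hanes$Km))), starts)
  }
  fit <- fit_nls(v ~ Vmax * S / (Km + S), dat, starts)
  cf <- summary(fit)$coefficients
  Km <- cf["Km", "Estimate"]; Km_se <- cf["Km", "Std. Error"]
  Vmax <- cf["Vmax", "Estimate"]; Vmax_se <- cf["Vmax", "Std. Error"]
  if (Km <= 0 || Vmax <= 0) stop("flagged fit failure: negative parameter")
  if (max(conc) < Km) {
    warnings <- c(warnings,
      "low information: all concentrations below fitted K_M; SE will be wide")
  }
  if (min(conc) > Km) {
    warnings <- c(warnings, "all concentrations above fitted K_M")
  }
  k_cat <- if (!is.null(enzyme_conc)) Vmax else NA_real_
  k_cat_se <- if (!is.null(enzyme_conc)) Vmax_se else NA_real_
  km_mM <- if (conc_unit == "uM") Km / 1000 else Km
  structure(list(K_M = Km, K_M_se = Km_se, V_max = Vmax, V_max_se = Vmax_se,
                 k_cat = k_cat, k_cat_se = k_cat_se,
                 efficiency = if (!is.na(k_cat)) k_cat / km_mM else NA_real_,
                 conc_unit = conc_unit, fit = fit, warnings = warnings),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: K_M = %.4g +/- %.2g %s, V_max = %.4g +/- %.2g\n",
              x$K_M, x$K_M_se, x$conc_unit, x$V_max, x$V_max_se))
  if (!is.na(x$efficiency)) {
    cat(sprintf("  k_cat = %.4g s^-1, k_cat/K_M = %.4g s^-1 mM^-1\n",
                x$k_cat, x$efficiency))
  }
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' Observed rate from an A340 trace
#'
#' Initial slope of an NAD(P)H-consumption trace, converted to a turnover
#' rate via Beer-Lambert: rate = |slope| / (epsilon * path) / [E]. The
#' window is the longest prefix (>= 5 points) with linear-fit R^2 >= 0.995
#' and absorbance depletion <= 10% of the starting value (absorbance taken
#' as proportional to the remaining cofactor); within the window the slope
#' is the linear coefficient of a quadratic fit, which removes the downward
#' bias a straight line picks up from early curvature. Uncoupling rates are
#' this same operation on substrate-free traces.
#'
#' @param time Time grid (s).
#' @param absorbance Absorbance at 340 nm.
#' @param epsilon Molar absorptivity in mM^-1 cm^-1 (default NADPH, 6.22).
#' @param path_length Cuvette path in cm.
#' @param enzyme_conc Enzyme concentration in uM.
#' @return List: \code{rate} (s^-1), \code{slope} (A/s), \code{window}
#'   (indices used).
#' @export
rate_from_A340 <- function(time, absorbance, epsilon = NADPH_EPSILON_340,
                           path_length = 1, enzyme_conc) {
  if (length(time) != length(absorbance)) stop("length mismatch")
  n <- length(time)
  if (n < 5) stop("trace too short")
  a0 <- absorbance[1]
  best <- NULL
  for (end in n:5) {
    idx <- 1:end
    if (a0 != 0 && abs(a0 - absorbance[end]) / abs(a0) > 0.10 && end > 5) next
    fit <- stats::lm(absorbance[idx] ~ time[idx])
    # summary() warns on exactly-linear traces; the R^2 is still valid
    r2 <- suppressWarnings(summary(fit)$r.squared)
    slope <- stats::coef(fit)[2]
    if (is.na(r2)) r2 <- 1  # flat trace: zero slope, perfectly linear
    if (r2 >= 0.995 || abs(slope) < .Machine$double.eps^0.5) {
      # curvature-corrected initial slope: linear term of a quadratic fit
      qfit <- stats::lm(absorbance[idx] ~ time[idx] + I(time[idx]^2))
      best <- list(slope = unname(stats::coef(qfit)[2]), window = idx)
      break
    }
  }
  if (is.null(best)) stop("no initial linear segment found")
  # slope in A/s; epsilon in mM^-1 cm^-1 => conc slope in mM/s = 1000 uM/s
  rate_uM_s <- abs(best$slope) / (epsilon * path_length) * 1000
  list(rate = rate_uM_s / enzyme_conc, slope = best$slope,
       window = best$window)
}

#' Fit a single-exponential trace
#'
#' \eqn{A(t) = A_\infty + \Delta A\, e^{-k t}} by nonlinear least squares;
#' the workhorse for flavin-reduction (k_red) and single-wavelength
#' oxidation (k_ox) stopped-flow traces. A runs test on the residuals flags
#' systematic misfit (e.g. biphasic traces that need the sequential model).
#'
#' @param time Time grid (s).
#' @param absorbance Observed trace.
#' @return An \code{exp_fit}: \code{k}, \code{k_se}, \code{A_inf},
#'   \code{dA}, \code{biphasic_warning} (logical), \code{runs_p},
#'   \code{fit}.
#' @export
fit_single_exponential <- function(time, absorbance) {
  if (length(time) != length(absorbance)) stop("length mismatch")
  dat <- data.frame(t = time, A = absorbance)
  dA0 <- absorbance[1] - absorbance[length(absorbance)]
  span <- max(time) - min(time)
  k0s <- c(2 / span, 10 / span, 0.5 / span)
  starts <- lapply(k0s, function(k0) {
    list(Ainf = absorbance[length(absorbance)], dA = dA0, k = k0)
  })
  fit <- fit_nls(A ~ Ainf + dA * exp(-k * t), dat, starts)
  cf <- summary(fit)$coefficients
  res <- stats::residuals(fit)
  runs_p <- residual_runs_test(res)
  biphasic <- !is.na(runs_p) && runs_p < 0.01
  if (biphasic) {
    warning("systematic residual structure (runs test p = ",
            signif(runs_p, 2),
            "); consider the two-step sequential model")
  }
  structure(list(k = cf["k", "Estimate"], k_se = cf["k", "Std. Error"],
                 A_inf = cf["Ainf", "Estimate"], dA = cf["dA", "Estimate"],
                 biphasic_warning = biphasic, runs_p = runs_p, fit = fit),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("single-exponential fit: k_obs = %.4g +/- %.2g s^-1\n",
              x$k, x$k_se))
  invisible(x)
}

# Wald-Wolfowitz runs test on residual signs (normal approximation).
residual_runs_test <- function(res) {
  s <- sign(res)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  runs <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / (n1 + n2) + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) /
    ((n1 + n2)^2 * (n1 + n2 - 1))
  if (v <= 0) return(NA_real_)
  2 * stats::pnorm(-abs((runs - mu) / sqrt(v)))
}

#' Fit oxygen affinity (hyperbolic k_obs vs [O2])
#'
#' \eqn{k_{obs} = k_{max} [O_2] / (K_M^{O_2} + [O_2])}. When the observed
#' rates are flat within noise across the tested O2 range, the enzyme is
#' saturated and the affinity is only bounded above by the lowest tested
#' concentration; the fit is flagged.
#'
#' @param o2 O2 concentrations after mixing (mM or uM, caller's unit).
#' @param kobs Observed rates (s^-1).
#' @return List: \code{K_M_O2}, \code{K_M_O2_se}, \code{k_max},
#'   \code{k_max_se}, \code{saturated} (logical), \code{fit}.
#' @export
fit_oxygen_affinity <- function(o2, kobs) {
  if (length(unique(o2)) < 4) stop("need at least 4 O2 concentrations")
  mm <- fit_michaelis_menten(o2, kobs, conc_unit = "mM")
  # saturated: the fitted affinity sits below the tested range and is not
  # statistically distinguishable from zero
  saturated <- mm$K_M < min(o2) && mm$K_M_se >= mm$K_M
  list(K_M_O2 = mm$K_M, K_M_O2_se = mm$K_M_se,
       k_max = mm$V_max, k_max_se = mm$V_max_se,
       saturated = saturated, fit = mm$fit)
}

#' Conversion percentage from peak areas
#'
#' Substrate-depletion conversion normalized by the internal standard:
#' \eqn{100 (1 - (A_s/A_{IS})_{sample} / (A_s/A_{IS})_{control})},
#' clamped to [0, 100] with a warning outside that range. The control is
#' the enzyme-free reaction.
#'
#' @param sample_substrate,sample_is Substrate and internal-standard peak
#'   areas of the enzymatic reaction.
#' @param control_substrate,control_is Same for the no-enzyme control.
#' @return Conversion in percent.
#' @export
conversion_percent <- function(sample_substrate, sample_is,
                               control_substrate, control_is) {
  if (any(c(sample_is, control_is) == 0)) {
    stop("zero internal-standard area")
  }
  ratio_s <- sample_substrate / sample_is
  ratio_c <- control_substrate / control_is
  conv <- 100 * (1 - ratio_s / ratio_c)
  if (any(conv < 0 | conv > 100)) {
    warning("conversion outside [0, 100]%; clamped")
    conv <- pmin(pmax(conv, 0), 100)
  }
  conv
}

#' Melting temperature from a melt curve
#'
#' T_m is the temperature of the tallest maximum of the smoothed first
#' derivative dF/dT (centered moving-average smoothing, default window 5
#' points). A secondary transition, when present, is reported as the next
#' tallest interior derivative peak.
#'
#' @param temperature Temperature grid (degC), >= 20 points.
#' @param fluorescence Reporter fluorescence.
#' @param window Odd smoothing window in points.
#' @return List: \code{T_m}, \code{secondary_T_m} (NA if none),
#'   \code{no_transition} (logical), \code{derivative} (data.frame).
#' @export
melting_temperature <- function(temperature, fluorescence, window = 5) {
  if (length(temperature) < 20) stop("need >= 20 points")
  if (window %% 2 == 0) stop("window must be odd")
  dT <- diff(temperature)
  dF <- diff(fluorescence)
  deriv <- dF / dT
  mid <- (temperature[-1] + temperature[-length(temperature)]) / 2
  ker <- rep(1 / window, window)
  sm <- stats::filter(deriv, ker, sides = 2)
  sm <- as.numeric(sm)
  ok <- !is.na(sm)
  sm_ok <- sm[ok]; mid_ok <- mid[ok]
  # interior local maxima of the smoothed derivative
  n <- length(sm_ok)
  peaks <- which(sm_ok[2:(n - 1)] > sm_ok[1:(n - 2)] &
                 sm_ok[2:(n - 1)] >= sm_ok[3:n]) + 1
  # require a real rise over baseline, not numerical ripple
  span <- max(sm_ok) - min(sm_ok)
  peaks <- peaks[sm_ok[peaks] > min(sm_ok) + 0.2 * span & span > 0]
  if (length(peaks) == 0 || span <= .Machine$double.eps) {
    return(list(T_m = NA_real_, secondary_T_m = NA_real_,
                no_transition = TRUE,
                derivative = data.frame(temperature = mid, dFdT = sm)))
  }
  ord <- peaks[order(sm_ok[peaks], decreasing = TRUE)]
  # parabolic vertex interpolation refines the peak below grid resolution
  refine <- function(p) {
    if (p <= 1 || p >= length(sm_ok)) return(mid_ok[p])
    y1 <- sm_ok[p - 1]; y2 <- sm_ok[p]; y3 <- sm_ok[p + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) < .Machine$double.eps) return(mid_ok[p])
    h <- mid_ok[p + 1] - mid_ok[p]
    mid_ok[p] + 0.5 * h * (y1 - y3) / den
  }
  list(T_m = refine(ord[1]),
       secondary_T_m = if (length(ord) > 1) refine(ord[2]) else NA_real_,
       no_transition = FALSE,
       derivative = data.frame(temperature = mid, dFdT = sm))
}

#' Holoenzyme concentration from flavin absorbance
#'
#' Beer-Lambert quantitation of protein-bound FAD:
#' concentration (uM) = 1000 * A450 / (11.3 * path).
#'
#' @param A450 Absorbance at 450 nm (>= 0).
#' @param path_length Path in cm.
#' @return Concentration in uM.
#' @export
holoenzyme_concentration <- function(A450, path_length = 1) {
  if (any(A450 < 0)) stop("negative absorbance")
  1000 * A450 / (FAD_EPSILON_450 * path_length)
}
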