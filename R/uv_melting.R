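#' Single-strand fraction of a two-state duplex melt
#'
#' For the bimolecular equilibrium (duplex <-> two single strands of a
#' non-self-complementary duplex at total duplex-equivalent concentration
#' `C_total`), the fraction of strands in single-stranded form is the
#' closed-form root of the mass-action quadratic anchored at the melting
#' temperature:
#' `p_ss = (sqrt(1 + 8 x) - 1) / (4 x)` with
#' `x = exp(-(1/Tm - 1/T) dH / R)`, so that `p_ss(Tm) = 0.5` exactly and
#' `p_ss -> 1` as `T -> Inf` for `dH > 0` (melting convention).
#'
#' @param T_kelvin temperature(s) in kelvin.
#' @param Tm melting temperature in kelvin.
#' @param dH standard enthalpy of melting, kcal/mol (positive).
#' @return Single-strand fraction in (0, 1).
#' @export
p_single_strand <- function(T_kelvin, Tm, dH) {
  stopifnot(Tm > 0, all(T_kelvin > 0), dH > 0)
  # log-space guard against overflow at extreme arguments
  lx <- -(1 / Tm - 1 / T_kelvin) * dH / R_KCAL
  lx <- pmin(lx, 700)
  x <- exp(lx)
  ifelse(x < 1e-12, 1 - 2 * x, (sqrt(1 + 8 * x) - 1) / (4 * x))
}

#' Two-state melting model for A260(T)
#'
#' `A260(T) = (m_ss T + b_ss) p_ss + (m_ds T + b_ds) p_ds` with sloped
#' single-strand and duplex baselines and `p_ss` from [p_single_strand()].
#'
#' @param T_kelvin temperatures in kelvin.
#' @param Tm,dH melting temperature (K) and enthalpy (kcal/mol).
#' @param m_ss,b_ss,m_ds,b_ds baseline slope/intercept coefficients for
#'   single strands and duplex (absorbance/K and absorbance).
#' @return Predicted A260 values.
#' @export
melting_model <- function(T_kelvin, Tm, dH, m_ss, b_ss, m_ds, b_ds) {
  pss <- p_single_strand(T_kelvin, Tm, dH)
  (m_ss * T_kelvin + b_ss) * pss + (m_ds * T_kelvin + b_ds) * (1 - pss)
}

#' Standard entropy of melting from Tm
#'
#' `dS = dH / Tm - R ln(C_total / 2)` (kcal/mol/K) for a
#' non-self-complementary duplex at total duplex concentration `C_total`
#' (mol/L), with `R = 1.987e-3` kcal/mol/K.
#'
#' @param dH enthalpy of melting, kcal/mol.
#' @param Tm melting temperature, kelvin.
#' @param C_total total duplex concentration, mol/L.
#' @return Entropy in kcal/mol/K.
#' @export
entropy_from_tm <- function(dH, Tm, C_total) {
  stopifnot(dH > 0, Tm > 0, C_total > 0)
  dH / Tm - R_KCAL * log(C_total / 2)
}

#' Free energy at a given temperature
#'
#' `dG = dH - T dS`; with `T = 298.15` K this is the standard dG at 25
#' degrees C.
#'
#' @param dH enthalpy, kcal/mol.
#' @param dS entropy, kcal/mol/K.
#' @param T_kelvin temperature, kelvin (default 298.15).
#' @return Free energy in kcal/mol.
#' @export
free_energy_at <- function(dH, dS, T_kelvin = 298.15) {
  dH - T_kelvin * dS
}

#' Fit a UV melting curve to the two-state model
#'
#' Nonlinear least squares over (Tm, dH, 4 baseline coefficients), then
#' derived dS and dG25 via [entropy_from_tm()] and [free_energy_at()].
#' Initialization: baselines from linear fits to the lowest/highest
#' temperature quartiles, Tm from the steepest point of the smoothed curve.
#'
#' @param T_kelvin temperatures (kelvin), >= 20 points spanning both
#'   baselines.
#' @param A260 absorbances.
#' @param C_total total duplex concentration, mol/L.
#' @return Object of class `"melt_fit"`: `Tm` (K), `dH` (kcal/mol), `dS`
#'   (kcal/mol/K), `dG25` (kcal/mol), baselines, `fitted`, `residuals`,
#'   `rss`.
#' @export
fit_melting <- function(T_kelvin, A260, C_total = 3e-6) {
  stopifnot(length(T_kelvin) == length(A260), length(T_kelvin) >= 20L,
            C_total > 0)
  ord <- order(T_kelvin)
  Tk <- T_kelvin[ord]
  y <- A260[ord]
  n <- length(Tk)

  q <- max(5L, n %/% 4L)
  lo <- stats::coef(stats::lm(y[1:q] ~ Tk[1:q]))
  hi <- stats::coef(stats::lm(y[(n - q + 1L):n] ~ Tk[(n - q + 1L):n]))
  # transition location from the steepest slope of the smoothed curve
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  dy <- diff(as.numeric(ys))
  tm0 <- Tk[which.max(abs(dy))]
  amp <- unname((hi[1L] + hi[2L] * tm0) - (lo[1L] + lo[2L] * tm0))
  if (!is.finite(amp) ||
      abs(amp) < max(6 * stats::sd(diff(y)), 1e-3 * max(abs(y)))) {
    stop("no sigmoid melting transition detected (baseline-only data?)")
  }

  resid_fn <- function(par, Tk, y) {
    y - melting_model(Tk, par[1L], par[2L], par[3L], par[4L], par[5L],
                      par[6L])
  }
  fit <- minpack.lm::nls.lm(
    par = c(tm0, 80, hi[2L], hi[1L], lo[2L], lo[1L]),
    lower = c(min(Tk), 1, -Inf, -Inf, -Inf, -Inf),
    upper = c(max(Tk), 500, Inf, Inf, Inf, Inf),
    fn = resid_fn, Tk = Tk, y = y,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$info %in% 1:4) {
    stop(sprintf("melting fit did not converge (info = %d, %s)",
                 fit$info, fit$message))
  }
  p <- unname(fit$par)
  fitted <- melting_model(Tk, p[1L], p[2L], p[3L], p[4L], p[5L], p[6L])
  dS <- entropy_from_tm(p[2L], p[1L], C_total)
  structure(
    list(Tm = p[1L], dH = p[2L], dS = dS,
         dG25 = free_energy_at(p[2L], dS, 298.15),
         m_ss = p[3L], b_ss = p[4L], m_ds = p[5L], b_ds = p[6L],
         C_total = C_total, T_kelvin = Tk, A260 = y,
         fitted = fitted, residuals = y - fitted,
         rss = sum((y - fitted)^2)),
    class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Two-state melt: Tm = %.2f K (%.2f C), dH = %.2f kcal/mol\n",
              x$Tm, x$Tm - 273.15, x$dH))
  cat(sprintf("  dS = %.4f kcal/mol/K, dG25 = %.3f kcal/mol (C_total = %g M)\n",
              x$dS, x$dG25, x$C_total))
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) {
  c(Tm = object$Tm, dH = object$dH, m_ss = object$m_ss, b_ss = object$b_ss,
    m_ds = object$m_ds, b_ds = object$b_ds)
}

#' @export
plot.melt_fit <- function(x, ...) {
  graphics::plot(x$T_kelvin, x$A260, pch = 16, cex = 0.5,
                 xlab = "T (K)", ylab = "A260", ...)
  graphics::lines(x$T_kelvin, x$fitted, col = "red3")
  graphics::abline(v = x$Tm, lty = 2, col = "grey50")
  invisible(x)
}

#' @export
predict.melt_fit <- function(object, T_kelvin = object$T_kelvin, ...) {
  melting_model(T_kelvin, object$Tm, object$dH, object$m_ss, object$b_ss,
                object$m_ds, object$b_ds)
}

#' Aggregate replicate melting fits
#'
#' Per-parameter mean and SD over independent replicate fits (>= 2;
#' typically >= 3), the replicate-based uncertainty convention for melting
#' thermodynamics.
#'
#' @param fits list of `"melt_fit"` objects.
#' @return data.frame with rows Tm, dH, dS, dG25 and columns `mean`, `sd`,
#'   `n`.
#' @export
aggregate_melts <- function(fits) {
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "melt_fit")))
  vals <- sapply(fits, function(f) c(Tm = f$Tm, dH = f$dH, dS = f$dS,
                                     dG25 = f$dG25))
  data.frame(parameter = rownames(vals),
             mean = rowMeans(vals),
             sd = apply(vals, 1L, stats::sd),
             n = length(fits), row.names = NULL)
}
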