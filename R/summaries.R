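#' @export
summary.lorentz_fit <- function(object, ...) {
  n <- object$n
  out <- list(peaks = object$peaks,
              rss = object$rss,
              sigma = sqrt(object$rss / max(1L, n - object$k)),
              bic = object$bic,
              baseline = object$baseline,
              populations = tryCatch(
                populations_from_peaks(object), error = function(e) NULL))
  class(out) <- "summary.lorentz_fit"
  out
}

#' @export
print.summary.lorentz_fit <- function(x, ...) {
  cat(sprintf("Lorentzian deconvolution (%d peak(s))\n", nrow(x$peaks)))
  print(x$peaks, digits = 4)
  cat(sprintf("residual SD %.4g, BIC %.4g, baseline %.4g\n",
              x$sigma, x$bic, x$baseline))
  if (!is.null(x$populations)) print(x$populations)
  invisible(x)
}

#' @export
summary.melt_fit <- function(object, ...) {
  out <- list(
    table = data.frame(
      parameter = c("Tm_K", "dH_kcal_mol", "dS_kcal_mol_K", "dG25_kcal_mol"),
      value = c(object$Tm, object$dH, object$dS, object$dG25)),
    baselines = c(m_ss = object$m_ss, b_ss = object$b_ss,
                  m_ds = object$m_ds, b_ds = object$b_ds),
    rss = object$rss, n = length(object$T_kelvin),
    C_total = object$C_total)
  class(out) <- "summary.melt_fit"
  out
}

#' @export
print.summary.melt_fit <- function(x, ...) {
  cat(sprintf("Two-state melting fit (%d points, C_total = %g M)\n",
              x$n, x$C_total))
  print(x$table, row.names = FALSE, digits = 5)
  cat("baselines:", sprintf("%s = %.4g", names(x$baselines), x$baselines),
      "\n")
  cat(sprintf("RSS %.4g\n", x$rss))
  invisible(x)
}

#' @export
summary.bm_fit <- function(object, ...) {
  sh <- unlist(object$shared)
  tab <- data.frame(parameter = names(sh), estimate = unname(sh),
                    sigma = NA_real_)
  if (!is.null(object$sigma_par)) {
    idx <- match(tab$parameter, names(object$sigma_par))
    tab$sigma <- unname(object$sigma_par[idx])
  }
  out <- list(shared = tab, per_nucleus = object$per_nucleus,
              chisq = object$chisq,
              dof = nrow(object$points) - length(object$par),
              n_points = nrow(object$points), nuclei = object$nuclei)
  class(out) <- "summary.bm_fit"
  out
}

#' @export
print.summary.bm_fit <- function(x, ...) {
  cat(sprintf("3-state Bloch-McConnell fit: chi-square %.4g on %d dof (%d points)\n",
              x$chisq, x$dof, x$n_points))
  print(x$shared, row.names = FALSE, digits = 4)
  for (nu in x$nuclei) {
    p <- x$per_nucleus[[nu]]
    cat(sprintf("  [%s] dw1 %.4g  dw2 %.4g ppm; R1 %.4g  R2 %.4g 1/s\n",
                nu, p$dw_es1, p$dw_es2, p$r1, p$r2))
  }
  invisible(x)
}

#' Simulate melting curves from a fitted model
#'
#' Parametric simulation: evaluates the fitted two-state model on the
#' fitted temperature grid and adds Gaussian noise at the residual SD.
#'
#' @param object a `"melt_fit"`.
#' @param nsim number of simulated curves.
#' @param seed integer seed.
#' @param ... unused.
#' @return data.frame with `T_kelvin` and one `sim_i` column per curve.
#' @export
simulate.melt_fit <- function(object, nsim = 1, seed = 1, ...) {
  mu <- object$fitted
  s <- sqrt(object$rss / max(1L, length(mu) - 6L))
  sims <- withr::with_seed(seed, {
    replicate(nsim, mu + stats::rnorm(length(mu), 0, s))
  })
  out <- data.frame(T_kelvin = object$T_kelvin, sims)
  names(out)[-1L] <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
residuals.melt_fit <- function(object, ...) object$residuals

#' @export
residuals.bm_fit <- function(object, ...) {
  (object$points$r1rho - object$points$fitted) / object$points$sigma
}
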