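#' Construct a 1D spectrum object
#'
#' A minimal container for a processed 1D spectrum: a strictly monotone
#' chemical-shift axis (ppm) and finite intensities, with optional metadata
#' (pH, temperature, sequence-context label).  Axes in decreasing ppm order
#' (the usual NMR plotting convention) are accepted.
#'
#' @param shift numeric chemical-shift axis in ppm, strictly monotone.
#' @param intensity numeric intensities, same length as `shift`.
#' @param pH,temperature,context optional metadata.
#' @return An `"nmr_spectrum"` object.
#' @export
nmr_spectrum <- function(shift, intensity, pH = NA_real_, temperature = NA_real_,
                     context = NA_character_) {
  shift <- as.numeric(shift)
  intensity <- as.numeric(intensity)
  if (length(shift) != length(intensity)) {
    stop("shift and intensity must have equal length")
  }
  d <- diff(shift)
  if (length(shift) < 2L || !(all(d > 0) || all(d < 0))) {
    stop("shift axis must be strictly monotone")
  }
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  structure(
    list(shift = shift, intensity = intensity,
         meta = list(pH = pH, temperature = temperature, context = context)),
    class = "nmr_spectrum"
  )
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("1D spectrum: %d points, %.4g to %.4g ppm\n",
              length(x$shift), x$shift[1L], x$shift[length(x$shift)]))
  if (!is.na(x$meta$pH)) cat(sprintf("  pH %.2f\n", x$meta$pH))
  if (!is.na(x$meta$context)) cat(sprintf("  context %s\n", x$meta$context))
  invisible(x)
}

#' Lorentzian line shape parameterized by integrated area
#'
#' `L(x) = A * (2 / (pi * fwhm)) / (1 + (2 (x - center) / fwhm)^2)` so that
#' the integral over the whole real line equals `area`.
#'
#' @param x evaluation points (ppm).
#' @param center peak position (ppm).
#' @param fwhm full width at half maximum (ppm), `> 0`.
#' @param area integrated area (intensity * ppm), `> 0`.
#' @return Intensities at `x`.
#' @export
lorentzian <- function(x, center, fwhm, area) {
  stopifnot(fwhm > 0)
  amp <- 2 * area / (pi * fwhm)
  amp / (1 + (2 * (x - center) / fwhm)^2)
}

#' Closed-form area of a Lorentzian peak
#'
#' For the amplitude parameterization `amp / (1 + (2(x-c)/fwhm)^2)` the
#' integral is `amp * pi * fwhm / 2`.  Peaks carry `area` as the invariant
#' quantity; this helper converts either representation.
#'
#' @param peak a one-row data.frame or list with `fwhm` and either `area`
#'   or `amplitude`.
#' @return Numeric area (intensity * ppm).
#' @export
peak_area <- function(peak) {
  if (!is.null(peak$area)) return(as.numeric(peak$area))
  stopifnot(!is.null(peak$amplitude), !is.null(peak$fwhm))
  as.numeric(peak$amplitude) * pi * as.numeric(peak$fwhm) / 2
}

# residual function for a sum of Lorentzians (+ optional constant baseline)
.lorentz_resid <- function(par, x, y, n_peaks, baseline) {
  model <- rep(if (baseline) par[3L * n_peaks + 1L] else 0, length(x))
  for (i in seq_len(n_peaks)) {
    p <- par[(3L * (i - 1L) + 1L):(3L * i)]
    model <- model + lorentzian(x, p[1L], p[2L], p[3L])
  }
  y - model
}

# forward-difference Jacobian of a residual function
.fd_jacobian <- function(fn, par, ...) {
  r0 <- fn(par, ...)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- max(1e-7, 1e-7 * abs(par[j]))
    pj <- par
    pj[j] <- pj[j] + h
    J[, j] <- (fn(pj, ...) - r0) / h
  }
  J
}

# robust noise scale: MAD of first differences (peaks contribute little)
.noise_mad <- function(intensity) {
  stats::mad(diff(intensity)) / sqrt(2)
}

# run one Levenberg-Marquardt pass for a fixed peak count
.lorentz_lm <- function(par0, x, y, n_peaks, baseline) {
  lower <- rep(c(-Inf, 1e-12, 1e-12), n_peaks)
  upper <- rep(Inf, 3L * n_peaks)
  if (baseline) {
    lower <- c(lower, -Inf)
    upper <- c(upper, Inf)
  }
  minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = .lorentz_resid, x = x, y = y, n_peaks = n_peaks,
    baseline = baseline,
    control = minpack.lm::nls.lm.control(maxiter = 500))
}

# deterministic sequential initialization: peaks are added one at a time at
# the maximum of the current fit residual (a small peak next to a tall one
# is then found reliably), refitting after each addition
.seq_fit <- function(x, y, n_peaks, baseline) {
  span <- abs(x[length(x)] - x[1L])
  fw0 <- span / 20
  par <- numeric(0)
  fit <- NULL
  for (k in seq_len(n_peaks)) {
    resid <- if (is.null(fit)) y else
      .lorentz_resid(fit$par, x, y, k - 1L, baseline)
    i <- which.max(resid)
    new_peak <- c(x[i], fw0, max(resid[i], 1e-8) * pi * fw0 / 2)
    par <- if (is.null(fit)) new_peak else {
      if (baseline) {
        nb <- length(fit$par)
        c(fit$par[-nb], new_peak, fit$par[nb])
      } else c(fit$par, new_peak)
    }
    if (k == 1L && baseline) par <- c(par, stats::median(y))
    fit <- .lorentz_lm(par, x, y, k, baseline)
  }
  fit
}

#' Fit a 1D spectrum as a sum of 1-3 Lorentzian peaks
#'
#' Nonlinear least squares (Levenberg-Marquardt) of `n_peaks` Lorentzians,
#' optionally with an additive constant baseline.  Unless `init` is
#' supplied, peaks are initialized deterministically and sequentially: each
#' peak is placed at the maximum of the residual of the previous fit, so a
#' weak resonance beside a dominant one is located reliably.  Parameter
#' uncertainties are the square roots of the diagonal of the covariance
#' matrix `sigma^2 (J'J)^-1`.
#'
#' @param spec an [nmr_spectrum()] object.
#' @param n_peaks integer 1, 2 or 3.
#' @param init optional data.frame with columns `center`, `fwhm`, `area`
#'   giving starting values (one row per peak).
#' @param baseline logical; fit an additive constant baseline term.
#' @return An object of class `"lorentz_fit"` with components `peaks`
#'   (data.frame: center, fwhm, area, amplitude and standard errors),
#'   `vcov`, `residuals`, `fitted`, `rss`, `bic`, `baseline`.
#' @export
fit_lorentzians <- function(spec, n_peaks, init = NULL, baseline = FALSE) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  if (!n_peaks %in% 1:3) stop("n_peaks must be 1, 2 or 3")
  x <- spec$shift
  y <- spec$intensity
  if (length(x) < 10L) stop("spectrum must have at least 10 points")

  if (is.null(init)) {
    fit <- .seq_fit(x, y, n_peaks, baseline)
  } else {
    stopifnot(nrow(init) == n_peaks)
    par0 <- as.vector(t(as.matrix(init[, c("center", "fwhm", "area")])))
    if (baseline) par0 <- c(par0, stats::median(y))
    fit <- .lorentz_lm(par0, x, y, n_peaks, baseline)
  }
  if (!fit$info %in% 1:4) {
    stop(sprintf(
      "Lorentzian fit did not converge (info = %d, %s); residual sum of squares %.4g",
      fit$info, fit$message, fit$deviance))
  }

  par <- fit$par
  resid <- .lorentz_resid(par, x, y, n_peaks, baseline)
  n <- length(y)
  k <- length(par)
  sigma2 <- sum(resid^2) / max(1L, n - k)
  J <- .fd_jacobian(.lorentz_resid, par, x = x, y = y, n_peaks = n_peaks,
                    baseline = baseline)
  vc <- tryCatch(sigma2 * chol2inv(chol(crossprod(J))),
                 error = function(e) matrix(NA_real_, k, k))
  se <- sqrt(pmax(0, diag(vc)))

  idx <- function(i) (3L * (i - 1L) + 1L):(3L * i)
  peaks <- do.call(rbind, lapply(seq_len(n_peaks), function(i) {
    p <- par[idx(i)]
    data.frame(center = p[1L], fwhm = p[2L], area = p[3L],
               amplitude = 2 * p[3L] / (pi * p[2L]),
               se_center = se[idx(i)][1L], se_fwhm = se[idx(i)][2L],
               se_area = se[idx(i)][3L],
               assignment = NA_character_)
  }))
  # report peaks in increasing-ppm order regardless of axis direction
  ord <- order(peaks$center)
  peaks <- peaks[ord, , drop = FALSE]
  perm <- as.vector(vapply(ord, idx, integer(3)))
  if (baseline) perm <- c(perm, k)
  vc <- vc[perm, perm, drop = FALSE]
  rownames(peaks) <- NULL

  rss <- sum(resid^2)
  structure(
    list(peaks = peaks, vcov = vc, residuals = resid, fitted = y - resid,
         rss = rss, n = n, k = k,
         bic = n * log(rss / n) + k * log(n),
         baseline = if (baseline) par[k] else 0,
         has_baseline = baseline, spectrum = spec),
    class = "lorentz_fit"
  )
}

#' @export
print.lorentz_fit <- function(x, ...) {
  cat(sprintf("Lorentzian deconvolution: %d peak(s), RSS = %.4g\n",
              nrow(x$peaks), x$rss))
  print(x$peaks[, c("center", "fwhm", "area", "assignment")], digits = 4)
  invisible(x)
}

#' @export
coef.lorentz_fit <- function(object, ...) {
  p <- object$peaks
  out <- as.vector(t(as.matrix(p[, c("center", "fwhm", "area")])))
  names(out) <- paste0(rep(c("center", "fwhm", "area"), nrow(p)),
                       rep(seq_len(nrow(p)), each = 3L))
  if (object$has_baseline) out <- c(out, baseline = object$baseline)
  out
}

#' @export
fitted.lorentz_fit <- function(object, ...) object$fitted

#' @export
residuals.lorentz_fit <- function(object, ...) object$residuals

#' @export
plot.lorentz_fit <- function(x, ...) {
  s <- x$spectrum
  graphics::plot(s$shift, s$intensity, type = "l", xlab = "chemical shift (ppm)",
                 ylab = "intensity", xlim = rev(range(s$shift)), ...)
  graphics::lines(s$shift, x$fitted, col = "red3")
  for (i in seq_len(nrow(x$peaks))) {
    graphics::lines(s$shift, x$baseline +
                      lorentzian(s$shift, x$peaks$center[i], x$peaks$fwhm[i],
                                 x$peaks$area[i]), col = "grey50", lty = 2)
  }
  invisible(x)
}

#' Assign fitted peaks to conformational states
#'
#' The mapping of the wobble and anionic resonances to the upfield/downfield
#' peaks is sequence-dependent and must be supplied by the user — it is
#' never guessed.  With three peaks, the middle peak is labelled `"other"`.
#'
#' @param fit a `"lorentz_fit"`.
#' @param wobble_side `"upfield"` (lower ppm) or `"downfield"` (higher ppm):
#'   which end of the axis carries the wobble resonance.
#' @return The fit with the `assignment` column filled in.
#' @export
assign_peaks <- function(fit, wobble_side = c("upfield", "downfield")) {
  stopifnot(inherits(fit, "lorentz_fit"))
  wobble_side <- match.arg(wobble_side)
  n <- nrow(fit$peaks)
  lab <- switch(as.character(n),
    "1" = "wobble",
    "2" = c("wobble", "anion"),
    "3" = c("wobble", "other", "anion"))
  if (wobble_side == "downfield") lab <- rev(lab)
  fit$peaks$assignment <- lab   # peaks are stored in increasing ppm order
  fit
}

#' State populations from fitted peak areas
#'
#' `p_state = area_state / sum(areas)`, with uncertainties propagated to
#' first order from the area block of the fit covariance matrix.
#'
#' @param fit a `"lorentz_fit"` whose peaks have been assigned (see
#'   [assign_peaks()]), or a data.frame of peaks with columns `area` and
#'   `assignment` (then `vcov` may be supplied separately).
#' @param vcov optional covariance matrix of the stacked per-peak
#'   `(center, fwhm, area)` parameters; taken from the fit if available.
#' @return An object of class `"state_populations"`: a list with
#'   `p` (named fractions summing to 1) and `sigma` (propagated SDs).
#' @export
populations_from_peaks <- function(fit, vcov = NULL) {
  if (inherits(fit, "lorentz_fit")) {
    peaks <- fit$peaks
    if (is.null(vcov)) vcov <- fit$vcov
  } else {
    peaks <- as.data.frame(fit)
  }
  if (!any(peaks$assignment %in% c("wobble", "anion"))) {
    stop("at least one peak must be assigned 'wobble' or 'anion'")
  }
  a <- peaks$area
  tot <- sum(a)
  if (tot <= 0) stop("all peak areas are zero; populations undefined")
  p <- a / tot
  names(p) <- peaks$assignment

  m <- length(a)
  sig <- rep(NA_real_, m)
  if (!is.null(vcov) && all(is.finite(vcov))) {
    aidx <- 3L * seq_len(m)          # area positions in (c,w,a) stacking
    Va <- vcov[aidx, aidx, drop = FALSE]
    for (i in seq_len(m)) {
      g <- -a[i] / tot^2             # d p_i / d a_j, j != i
      grad <- rep(g, m)
      grad[i] <- (tot - a[i]) / tot^2
      sig[i] <- sqrt(max(0, drop(t(grad) %*% Va %*% grad)))
    }
  }
  full <- c(wobble = 0, anion = 0, other = 0)
  sfull <- c(wobble = 0, anion = 0, other = 0)
  for (i in seq_len(m)) {
    full[peaks$assignment[i]] <- full[peaks$assignment[i]] + p[i]
    sfull[peaks$assignment[i]] <- sqrt(sfull[peaks$assignment[i]]^2 +
                                         ifelse(is.na(sig[i]), 0, sig[i])^2)
  }
  structure(list(p = full, sigma = sfull), class = "state_populations")
}

#' @export
print.state_populations <- function(x, ...) {
  cat("State populations:\n")
  for (nm in names(x$p)) {
    cat(sprintf("  %-7s %.4f (sd %.4f)\n", nm, x$p[nm], x$sigma[nm]))
  }
  invisible(x)
}

#' Median-filter baseline pre-correction
#'
#' Subtracts a running-median baseline (window width `k` points, odd) from
#' the spectrum, emulating the automatic baseline correction applied to
#' processed spectra.
#'
#' @param spec an [nmr_spectrum()].
#' @param k odd window width in points (default about a quarter of the axis).
#' @return A baseline-corrected [nmr_spectrum()].
#' @export
correct_baseline <- function(spec, k = NULL) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  n <- length(spec$intensity)
  if (is.null(k)) k <- max(3L, 2L * (n %/% 8L) + 1L)
  if (k %% 2L == 0L) k <- k + 1L
  base <- stats::runmed(spec$intensity, k)
  nmr_spectrum(spec$shift, spec$intensity - base, pH = spec$meta$pH,
           temperature = spec$meta$temperature, context = spec$meta$context)
}

#' Choose the number of Lorentzian peaks by BIC
#'
#' Fits 1..`max_peaks` Lorentzians and returns the smallest model whose
#' Bayesian information criterion is within 2 of the minimum.  A
#' low-confidence flag is set when the tallest fitted peak does not exceed
#' 5x the noise MAD (e.g. pure-noise input).
#'
#' @param spec an [nmr_spectrum()].
#' @param max_peaks maximum peaks to consider (<= 3).
#' @param baseline passed to [fit_lorentzians()].
#' @return List with `n_peaks`, `bic` (vector), `low_confidence`.
#' @export
select_peak_count <- function(spec, max_peaks = 3, baseline = FALSE) {
  stopifnot(inherits(spec, "nmr_spectrum"), max_peaks >= 1, max_peaks <= 3)
  fits <- lapply(seq_len(max_peaks), function(n) {
    tryCatch(fit_lorentzians(spec, n, baseline = baseline),
             error = function(e) NULL)
  })
  # floor the RSS at a numerical noise level so that on noiseless data
  # extra peaks cannot win on round-off alone
  npts <- length(spec$intensity)
  floor_rss <- npts * (1e-9 * max(abs(spec$intensity)))^2
  bic <- vapply(fits, function(f) {
    if (is.null(f)) return(Inf)
    npts * log(max(f$rss, floor_rss) / npts) + f$k * log(npts)
  }, numeric(1))
  best <- min(bic)
  n_sel <- which(bic <= best + 2)[1L]
  amp_max <- max(fits[[n_sel]]$peaks$amplitude)
  noise <- .noise_mad(spec$intensity)
  list(n_peaks = n_sel, bic = bic,
       low_confidence = is.finite(noise) && noise > 0 && amp_max < 5 * noise)
}

#' Read a two-column delimited spectrum file
#'
#' Expects a header line and two columns (chemical shift in ppm, intensity),
#' whitespace-, comma- or tab-separated.
#'
#' @param path file path.
#' @param ... metadata passed to [nmr_spectrum()].
#' @return An [nmr_spectrum()].
#' @export
read_spectrum <- function(path, ...) {
  d <- utils::read.table(path, header = TRUE, sep = "",
                         blank.lines.skip = TRUE)
  if (ncol(d) == 1L) d <- utils::read.csv(path)
  nmr_spectrum(d[[1L]], d[[2L]], ...)
}

#' Write a spectrum as two-column delimited text
#'
#' @param spec an [nmr_spectrum()].
#' @param path output path.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  utils::write.table(
    data.frame(shift_ppm = spec$shift, intensity = spec$intensity),
    path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
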