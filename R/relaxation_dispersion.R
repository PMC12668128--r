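#' Three-state chemical-exchange model
#'
#' Parameterizes exchange between a ground state (GS) and two excited
#' states (ES1, ES2) with triangular topology.  Pairwise exchange rates are
#' `kex = k_forward + k_backward`; chemical-shift differences are
#' `dw = omega_ES - omega_GS` in ppm of the observed nucleus.  A single R1
#' and a single R2 are shared by all three states.
#'
#' @param p_es1,p_es2 excited-state fractional populations (sum < 1).
#' @param kex_gs_es1,kex_gs_es2,kex_es1_es2 pairwise exchange rates, 1/s.
#' @param dw_es1,dw_es2 chemical-shift differences, ppm.
#' @param r1,r2 longitudinal and transverse relaxation rates, 1/s.
#' @return An object of class `"exchange_model"`.
#' @export
exchange_model <- function(p_es1 = 0, p_es2 = 0,
                           kex_gs_es1 = 0, kex_gs_es2 = 0, kex_es1_es2 = 0,
                           dw_es1 = 0, dw_es2 = 0, r1 = 2, r2 = 20) {
  stopifnot(p_es1 >= 0, p_es2 >= 0, p_es1 + p_es2 < 1,
            kex_gs_es1 >= 0, kex_gs_es2 >= 0, kex_es1_es2 >= 0,
            r1 >= 0, r2 >= 0)
  structure(
    list(p_es1 = p_es1, p_es2 = p_es2,
         kex_gs_es1 = kex_gs_es1, kex_gs_es2 = kex_gs_es2,
         kex_es1_es2 = kex_es1_es2,
         dw_es1 = dw_es1, dw_es2 = dw_es2, r1 = r1, r2 = r2),
    class = "exchange_model")
}

#' @export
print.exchange_model <- function(x, ...) {
  cat("3-state triangular exchange model\n")
  cat(sprintf("  pES1 = %.4g  pES2 = %.4g  (pGS = %.4g)\n",
              x$p_es1, x$p_es2, 1 - x$p_es1 - x$p_es2))
  cat(sprintf("  kex GS:ES1 = %.4g  GS:ES2 = %.4g  ES1:ES2 = %.4g  (1/s)\n",
              x$kex_gs_es1, x$kex_gs_es2, x$kex_es1_es2))
  cat(sprintf("  dw ES1 = %.4g  ES2 = %.4g ppm;  R1 = %.4g  R2 = %.4g 1/s\n",
              x$dw_es1, x$dw_es2, x$r1, x$r2))
  invisible(x)
}

#' Effective-field geometry at a grid point
#'
#' Tilt angle `theta = atan2(omega1, Omega)` between the effective field and
#' the z-axis, computed by default from the ground-state offset (the
#' observed resonance).
#'
#' @param power_hz spin-lock power omega1/2pi in Hz.
#' @param offset_hz carrier offset Omega/2pi from the GS resonance in Hz.
#' @return List with `theta` (radians) and `omega_eff` (rad/s).
#' @export
effective_field <- function(power_hz, offset_hz) {
  w1 <- 2 * pi * power_hz
  om <- 2 * pi * offset_hz
  list(theta = atan2(w1, om), omega_eff = sqrt(w1^2 + om^2))
}

#' Bloch-McConnell generator matrix
#'
#' Builds the 9x9 evolution matrix of the triangular 3-state system at one
#' (power, offset) grid point: per-state Bloch blocks with state-specific
#' offsets `Omega_i = Omega_GS + dw_i` and spin-lock along x, damped by
#' R1/R2, coupled by first-order exchange rates obeying detailed balance
#' `k_{i->j} = kex_ij * p_j / (p_i + p_j)`.
#'
#' @param model an [exchange_model()].
#' @param power_hz spin-lock power in Hz.
#' @param offset_hz offset from the GS resonance in Hz.
#' @param larmor_mhz spectrometer frequency of the observed nucleus in MHz
#'   (converts ppm to rad/s); no default — must be explicit.
#' @return 9x9 numeric matrix, magnetization ordered
#'   `(x,y,z)` per state, states GS, ES1, ES2.
#' @export
build_bm_generator <- function(model, power_hz, offset_hz, larmor_mhz) {
  stopifnot(inherits(model, "exchange_model"), larmor_mhz > 0)
  p <- c(1 - model$p_es1 - model$p_es2, model$p_es1, model$p_es2)
  if (p[1L] <= 0) stop("excited-state populations must sum to < 1")
  w1 <- 2 * pi * power_hz
  om <- 2 * pi * offset_hz +
    c(0, model$dw_es1, model$dw_es2) * larmor_mhz * 2 * pi

  fwd <- function(kex, pi_, pj) if (pi_ + pj > 0) kex * pj / (pi_ + pj) else 0
  k <- matrix(0, 3, 3)
  k[1, 2] <- fwd(model$kex_gs_es1, p[1], p[2])
  k[2, 1] <- fwd(model$kex_gs_es1, p[2], p[1])
  k[1, 3] <- fwd(model$kex_gs_es2, p[1], p[3])
  k[3, 1] <- fwd(model$kex_gs_es2, p[3], p[1])
  k[2, 3] <- fwd(model$kex_es1_es2, p[2], p[3])
  k[3, 2] <- fwd(model$kex_es1_es2, p[3], p[2])

  L <- matrix(0, 9, 9)
  for (i in 1:3) {
    o <- 3L * (i - 1L)
    B <- matrix(c(-model$r2, -om[i], 0,
                  om[i], -model$r2, -w1,
                  0, w1, -model$r1), 3, 3, byrow = TRUE)
    L[o + 1:3, o + 1:3] <- B - diag(sum(k[i, -i]), 3)
    for (j in setdiff(1:3, i)) {
      oj <- 3L * (j - 1L)
      L[o + 1:3, oj + 1:3] <- L[o + 1:3, oj + 1:3] + diag(k[j, i], 3)
    }
  }
  L
}

# alignment axis offset per the kex/|dw| rule of the major excited state
.bm_alignment <- function(model, larmor_mhz,
                          align = c("auto", "gs", "avg"), thresh = 1) {
  align <- match.arg(align)
  if (align == "gs") return(FALSE)
  if (align == "avg") return(TRUE)
  if (model$p_es1 <= 0 && model$p_es2 <= 0) return(FALSE)
  if (model$p_es1 >= model$p_es2) {
    kmaj <- model$kex_gs_es1; dw <- model$dw_es1
  } else {
    kmaj <- model$kex_gs_es2; dw <- model$dw_es2
  }
  dw_rad <- abs(dw) * larmor_mhz * 2 * pi
  if (dw_rad == 0) return(TRUE)
  (kmaj / dw_rad) > thresh
}

.align_code <- function(align) match(align, c("auto", "gs", "avg"))[1L] - 1L

#' Simulate R1rho at one or more grid points
#'
#' Propagates the stacked magnetization with the matrix exponential of the
#' Bloch-McConnell generator at each delay, projects onto the alignment
#' axis, and extracts R1rho as the mono-exponential decay rate of the
#' projected signal.  The initial alignment follows the kex/|dw| rule of
#' the major excited state: average-state effective field when
#' `kex / |dw| > align_thresh` (default 1), ground-state effective field
#' otherwise.
#'
#' @inheritParams build_bm_generator
#' @param power_hz,offset_hz numeric vectors (recycled to equal length).
#' @param delays relaxation delays in seconds (>= 2 distinct values).
#' @param align `"auto"`, `"gs"` or `"avg"` initial-alignment rule.
#' @param align_thresh threshold for the auto rule.
#' @param engine `"cpp"` (compiled, default) or `"R"` (reference
#'   implementation, identical algorithm).
#' @return Numeric vector of R1rho values (1/s), one per grid point.
#' @export
simulate_r1rho <- function(model, power_hz, offset_hz, delays, larmor_mhz,
                           align = c("auto", "gs", "avg"), align_thresh = 1,
                           engine = c("cpp", "R")) {
  stopifnot(inherits(model, "exchange_model"), larmor_mhz > 0,
            length(delays) >= 2L, all(delays >= 0))
  align <- match.arg(align)
  engine <- match.arg(engine)
  n <- max(length(power_hz), length(offset_hz))
  power_hz <- rep_len(power_hz, n)
  offset_hz <- rep_len(offset_hz, n)

  if (engine == "cpp") {
    return(as.numeric(bm_r1rho_cpp(
      model$p_es1, model$p_es2,
      model$kex_gs_es1, model$kex_gs_es2, model$kex_es1_es2,
      model$dw_es1, model$dw_es2, model$r1, model$r2,
      power_hz, offset_hz, sort(delays), larmor_mhz,
      .align_code(align), align_thresh)))
  }

  use_avg <- .bm_alignment(model, larmor_mhz, align, align_thresh)
  p <- c(1 - model$p_es1 - model$p_es2, model$p_es1, model$p_es2)
  dw_rad <- c(0, model$dw_es1, model$dw_es2) * larmor_mhz * 2 * pi
  out <- numeric(n)
  for (g in seq_len(n)) {
    w1 <- 2 * pi * power_hz[g]
    om_gs <- 2 * pi * offset_hz[g]
    om_align <- if (use_avg) sum(p * (om_gs + dw_rad)) else om_gs
    weff <- sqrt(w1^2 + om_align^2)
    st <- if (weff > 0) w1 / weff else 0
    ct <- if (weff > 0) om_align / weff else 1
    L <- build_bm_generator(model, power_hz[g], offset_hz[g], larmor_mhz)
    m0 <- as.vector(rbind(p * st, 0, p * ct))
    u <- as.vector(rbind(rep(st, 3), 0, rep(ct, 3)))
    e <- eigen(L)
    cc <- solve(e$vectors, m0 + 0i)
    wv <- as.vector((u + 0i) %*% e$vectors)
    td <- sort(delays)
    sig <- vapply(td, function(t) {
      Re(sum(wv * cc * exp(e$values * t)))
    }, numeric(1))
    keep <- sig > 0
    if (sum(keep) < 2L) { out[g] <- NA_real_; next }
    out[g] <- -unname(stats::coef(stats::lm(log(sig[keep]) ~ td[keep]))[2L])
  }
  out
}

#' Fit a mono-exponential decay to delay-series intensities
#'
#' Nonlinear least squares of `I(t) = I0 exp(-R1rho t)`, initialized from a
#' log-linear regression.  The uncertainty is estimated by a Monte-Carlo
#' procedure: residual-scale noise is added to the fitted curve and the fit
#' repeated (`n_mc` replicates, seeded); sigma is the SD of the refitted
#' rates.
#'
#' @param delays delay times in seconds (>= 3 distinct values).
#' @param intensities observed intensities.
#' @param n_mc Monte-Carlo replicates (default 500).
#' @param seed integer seed for the Monte-Carlo resampling.
#' @param noise optional fixed intensity-noise SD for the Monte-Carlo
#'   resampling; by default it is estimated from the fit residuals.  A
#'   pooled estimate across many decay series (see [reduce_to_r1rho()]) is
#'   far more stable than the per-series one, which rests on only
#'   `length(delays) - 2` residual degrees of freedom.
#' @return Object of class `"decay_fit"`: list with `r1rho`, `sigma`, `i0`,
#'   `fitted`, `residuals`.
#' @export
fit_decay <- function(delays, intensities, n_mc = 500, seed = 1,
                      noise = NULL) {
  stopifnot(length(delays) == length(intensities),
            length(unique(delays)) >= 3L)
  if (stats::sd(intensities) == 0) {
    stop("intensities are constant: no decay to fit")
  }
  pos <- intensities > 0
  if (sum(pos) < 2L) stop("need at least 2 positive intensities")
  sl <- stats::coef(stats::lm(log(intensities[pos]) ~ delays[pos]))
  if (sl[2L] >= 0) {
    stop(sprintf(
      "intensities do not decay with delay (log-linear slope %.3g >= 0)",
      sl[2L]))
  }
  resid_fn <- function(par, t, y) y - par[1L] * exp(-par[2L] * t)
  fit <- minpack.lm::nls.lm(
    par = c(exp(sl[1L]), -sl[2L]), lower = c(0, 0),
    fn = resid_fn, t = delays, y = intensities)
  par <- fit$par
  fitted <- par[1L] * exp(-par[2L] * delays)
  res <- intensities - fitted
  if (is.null(noise)) {
    noise <- sqrt(sum(res^2) / max(1L, length(res) - 2L))
  }

  sig <- 0
  if (n_mc > 0 && noise > 0) {
    rates <- withr::with_seed(seed, vapply(seq_len(n_mc), function(i) {
      y2 <- fitted + stats::rnorm(length(fitted), 0, noise)
      f2 <- minpack.lm::nls.lm(par = par, lower = c(0, 0),
                               fn = resid_fn, t = delays, y = y2)
      f2$par[2L]
    }, numeric(1)))
    sig <- stats::sd(rates)
  }
  structure(
    list(r1rho = unname(par[2L]), sigma = sig, i0 = unname(par[1L]),
         fitted = fitted, residuals = res, noise = noise),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("R1rho = %.4g +/- %.2g 1/s  (I0 = %.4g)\n",
              x$r1rho, x$sigma, x$i0))
  invisible(x)
}

#' Reduce a long-format intensity dataset to per-point R1rho values
#'
#' Groups rows by (nucleus, power, offset) and runs [fit_decay()] on each
#' delay series.  By default (`pool_noise = TRUE`) the intensity-noise SD
#' used by the per-point Monte-Carlo is pooled across all series of a
#' nucleus: with only five delays per series the per-series noise estimate
#' has 3 residual degrees of freedom and its sampling error would corrupt
#' the chi-square weighting of the downstream global fit.
#'
#' @param data data.frame with columns `nucleus`, `power_hz`, `offset_hz`,
#'   `delay_s`, `intensity`.
#' @param n_mc,seed passed to [fit_decay()].
#' @param pool_noise logical; pool the noise estimate per nucleus.
#' @return data.frame with columns `nucleus`, `power_hz`, `offset_hz`,
#'   `r1rho`, `sigma`.
#' @export
reduce_to_r1rho <- function(data, n_mc = 200, seed = 1, pool_noise = TRUE) {
  need <- c("nucleus", "power_hz", "offset_hz", "delay_s", "intensity")
  stopifnot(all(need %in% names(data)))
  key <- interaction(data$nucleus, data$power_hz, data$offset_hz, drop = TRUE)
  groups <- split(data, key)

  fits <- lapply(groups, function(g) {
    fit_decay(g$delay_s, g$intensity, n_mc = 0)
  })
  noise_by_nuc <- NULL
  if (pool_noise) {
    nuc <- vapply(groups, function(g) as.character(g$nucleus[1L]),
                  character(1))
    rss <- vapply(fits, function(f) sum(f$residuals^2), numeric(1))
    dof <- vapply(fits, function(f) max(1L, length(f$residuals) - 2L),
                  numeric(1))
    noise_by_nuc <- vapply(split(seq_along(fits), nuc), function(i) {
      sqrt(sum(rss[i]) / sum(dof[i]))
    }, numeric(1))
  }

  out <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    nz <- if (pool_noise) noise_by_nuc[[as.character(g$nucleus[1L])]]
          else NULL
    f <- fit_decay(g$delay_s, g$intensity, n_mc = n_mc, seed = seed + i,
                   noise = nz)
    data.frame(nucleus = g$nucleus[1L], power_hz = g$power_hz[1L],
               offset_hz = g$offset_hz[1L], r1rho = f$r1rho, sigma = f$sigma,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$nucleus, out$power_hz, out$offset_hz), , drop = FALSE]
}

# parameter packing for the global fit ---------------------------------------

.bm_par_names <- function(nuclei, free) {
  shared <- c("lp1", "lp2", "lk1", "lk2", "lk12")[free$shared]
  fields <- c("dw1", "dw2", "r1", "r2")[free$per]
  per <- as.vector(t(outer(nuclei, fields, paste, sep = ".")))
  c(shared, per)
}

.bm_unpack <- function(par, nuclei, fixed, fixed_per = NULL) {
  g <- as.list(par)
  names(g) <- names(par)
  take <- function(nm, fix_nm, trans = identity) {
    if (!is.null(fixed[[fix_nm]])) fixed[[fix_nm]] else trans(g[[nm]])
  }
  shared <- list(
    p_es1 = take("lp1", "p_es1", exp),
    p_es2 = take("lp2", "p_es2", exp),
    kex_gs_es1 = take("lk1", "kex_gs_es1", exp),
    kex_gs_es2 = take("lk2", "kex_gs_es2", exp),
    kex_es1_es2 = take("lk12", "kex_es1_es2", exp))
  take_per <- function(nu, nm, field) {
    v <- g[[paste0(nu, ".", nm)]]
    if (is.null(v)) v <- fixed_per[[nu]][[field]]
    v
  }
  per <- lapply(nuclei, function(nu) {
    list(dw_es1 = take_per(nu, "dw1", "dw_es1"),
         dw_es2 = take_per(nu, "dw2", "dw_es2"),
         r1 = take_per(nu, "r1", "r1"),
         r2 = take_per(nu, "r2", "r2"))
  })
  names(per) <- nuclei
  list(shared = shared, per = per)
}

.bm_sim_points <- function(pars, points, delays, larmor_mhz, align,
                           align_thresh) {
  sim <- numeric(nrow(points))
  for (nu in unique(points$nucleus)) {
    idx <- points$nucleus == nu
    pn <- pars$per[[nu]]
    sh <- pars$shared
    if (sh$p_es1 + sh$p_es2 >= 1) return(rep(1e6, nrow(points)))
    m <- exchange_model(p_es1 = sh$p_es1, p_es2 = sh$p_es2,
                        kex_gs_es1 = sh$kex_gs_es1,
                        kex_gs_es2 = sh$kex_gs_es2,
                        kex_es1_es2 = sh$kex_es1_es2,
                        dw_es1 = pn$dw_es1, dw_es2 = pn$dw_es2,
                        r1 = pn$r1, r2 = pn$r2)
    sim[idx] <- simulate_r1rho(m, points$power_hz[idx], points$offset_hz[idx],
                               delays, larmor_mhz, align = align,
                               align_thresh = align_thresh)
  }
  sim
}

#' Global fit of R1rho dispersion data to the 3-state exchange model
#'
#' Weighted least squares over all (nucleus, power, offset) points,
#' minimizing `sum(((R1rho_obs - R1rho_sim) / sigma)^2)`.  Populations and
#' the three pairwise exchange rates are shared across nuclei; dw_ES1,
#' dw_ES2, R1 and R2 are per-nucleus.  Populations and rates are fitted on
#' the log scale; the fit is restarted from log-spaced kex values
#' (`10^2, 10^3, 10^4` 1/s) and the best solution kept.  Any parameter can
#' be frozen through `fix` (e.g. `fix = list(p_es2 = 0, kex_gs_es2 = 0,
#' kex_es1_es2 = 0)` for a 2-state model).
#'
#' @param points data.frame from [reduce_to_r1rho()] (columns `nucleus`,
#'   `power_hz`, `offset_hz`, `r1rho`, `sigma`).
#' @param larmor_mhz spectrometer frequency of the observed nucleus, MHz.
#' @param delays delay grid used when re-simulating R1rho (the simulated
#'   observable depends mildly on it); default `seq(0, 0.12, length.out=5)`.
#' @param start optional [exchange_model()] giving starting values for the
#'   shared parameters and the default per-nucleus parameters.  In practice
#'   the chemical-shift differences of the excited states are approximately
#'   known beforehand (e.g. from the shifts of the mimicked tautomeric /
#'   anionic species), and supplying them as starting values is the normal
#'   workflow; the Bloch-McConnell objective is multimodal and a blind
#'   global search is not attempted beyond `kex_starts` and `dw_flip`.
#' @param start_per_nucleus optional named list (one entry per nucleus) of
#'   lists with `dw_es1`, `dw_es2`, `r1`, `r2` start values overriding
#'   `start` for that nucleus.
#' @param fix named list of parameters to freeze at given values.
#' @param kex_starts multi-start kex values (1/s).
#' @param dw_flip logical; also restart from sign-flipped dw combinations
#'   (4 combinations per kex start).
#' @param align,align_thresh initial-alignment rule (see
#'   [simulate_r1rho()]).
#' @return Object of class `"bm_fit"`: `model` (fitted [exchange_model()]
#'   per nucleus parameters in `per_nucleus`), `chisq`, `points` with a
#'   `fitted` column, convergence info.
#' @export
fit_exchange <- function(points, larmor_mhz,
                         delays = seq(0, 0.12, length.out = 5),
                         start = NULL, start_per_nucleus = NULL,
                         fix = list(), fix_dw = FALSE,
                         kex_starts = c(1e2, 1e3, 1e4), dw_flip = FALSE,
                         align = "auto", align_thresh = 1) {
  stopifnot(all(c("nucleus", "power_hz", "offset_hz", "r1rho") %in%
                  names(points)))
  if (is.null(points$sigma) || any(!is.finite(points$sigma)) ||
      any(points$sigma <= 0)) {
    points$sigma <- rep(0.01 * stats::median(points$r1rho), nrow(points))
  }
  nuclei <- unique(as.character(points$nucleus))
  free <- list(shared = !(c("p_es1", "p_es2", "kex_gs_es1", "kex_gs_es2",
                            "kex_es1_es2") %in% names(fix)),
               per = c(!fix_dw, !fix_dw, TRUE, TRUE))
  n_free_shared <- sum(free$shared)
  n_par <- n_free_shared + sum(free$per) * length(nuclei)
  if (nrow(points) < n_par) {
    warning("fewer R1rho points than free parameters; fit is underdetermined")
  }

  if (is.null(start)) {
    start <- exchange_model(p_es1 = 0.01, p_es2 = 0.005,
                            kex_gs_es1 = 1e3, kex_gs_es2 = 1e3,
                            kex_es1_es2 = 1e2, dw_es1 = 3, dw_es2 = -3,
                            r1 = 2, r2 = max(1, min(points$r1rho)))
  }

  nuc_start <- function(nu) {
    s <- list(dw_es1 = start$dw_es1, dw_es2 = start$dw_es2,
              r1 = start$r1, r2 = start$r2)
    if (!is.null(start_per_nucleus[[nu]])) {
      s[names(start_per_nucleus[[nu]])] <- start_per_nucleus[[nu]]
    }
    s
  }

  fixed_per <- if (fix_dw) {
    out <- lapply(nuclei, function(nu) nuc_start(nu)[c("dw_es1", "dw_es2")])
    names(out) <- nuclei
    out
  } else NULL

  build_par <- function(kex0, sgn = c(1, 1)) {
    shared_all <- c(lp1 = log(max(start$p_es1, 1e-4)),
                    lp2 = log(max(start$p_es2, 1e-4)),
                    lk1 = log(kex0), lk2 = log(kex0),
                    lk12 = log(max(kex0 / 10, 1)))
    p <- shared_all[free$shared]
    for (nu in nuclei) {
      s <- nuc_start(nu)
      vals <- c(sgn[1L] * s$dw_es1, sgn[2L] * s$dw_es2, s$r1, s$r2)
      nm <- paste(nu, c("dw1", "dw2", "r1", "r2"), sep = ".")
      p <- c(p, stats::setNames(vals[free$per], nm[free$per]))
    }
    p
  }

  resid_fn <- function(par, pts) {
    names(par) <- par_names
    pars <- .bm_unpack(par, nuclei, fix, fixed_per)
    sim <- .bm_sim_points(pars, pts, delays, larmor_mhz, align, align_thresh)
    sim[!is.finite(sim)] <- 1e6
    (pts$r1rho - sim) / pts$sigma
  }

  par_names <- .bm_par_names(nuclei, free)
  lower <- stats::setNames(rep(-Inf, n_par), par_names)
  upper <- stats::setNames(rep(Inf, n_par), par_names)
  lower[grepl("^lp", par_names)] <- log(1e-6)
  upper[grepl("^lp", par_names)] <- log(0.45)
  lower[grepl("^lk", par_names)] <- log(1e-2)
  upper[grepl("^lk", par_names)] <- log(1e6)
  lower[grepl("\\.r[12]$", par_names)] <- 1e-3

  signs <- if (dw_flip) {
    list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  } else list(c(1, 1))
  best <- NULL
  for (k0 in kex_starts) {
    for (sgn in signs) {
      p0 <- build_par(k0, sgn)
      f <- tryCatch(
        minpack.lm::nls.lm(par = p0, lower = lower[par_names],
                           upper = upper[par_names],
                           fn = resid_fn, pts = points,
                           control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$deviance < best$deviance)) {
        best <- f
      }
    }
  }
  if (is.null(best)) stop("exchange fit failed from every start")
  if (!best$info %in% 1:4) {
    warning(sprintf("best fit did not formally converge (info = %d); %s",
                    best$info, best$message))
  }

  par <- best$par
  names(par) <- par_names
  pars <- .bm_unpack(par, nuclei, fix, fixed_per)
  sim <- .bm_sim_points(pars, points, delays, larmor_mhz, align, align_thresh)
  points$fitted <- sim
  structure(
    list(shared = pars$shared, per_nucleus = pars$per, par = par,
         fix = fix, fixed_per = fixed_per, chisq = best$deviance,
         points = points,
         nuclei = nuclei, larmor_mhz = larmor_mhz, delays = delays,
         align = align, align_thresh = align_thresh, info = best$info,
         sigma_par = NULL, mc = NULL),
    class = "bm_fit")
}

#' @export
coef.bm_fit <- function(object, ...) {
  sh <- unlist(object$shared)
  per <- unlist(object$per_nucleus)
  c(sh, per)
}

#' @export
print.bm_fit <- function(x, ...) {
  cat(sprintf("3-state Bloch-McConnell global fit: %d points, %d nucle%s, chi-square = %.4g\n",
              nrow(x$points), length(x$nuclei),
              if (length(x$nuclei) > 1L) "i" else "us", x$chisq))
  s <- x$shared
  fmt <- function(nm, v) {
    sig <- if (!is.null(x$sigma_par) && nm %in% names(x$sigma_par))
      sprintf(" +/- %.3g", x$sigma_par[[nm]]) else ""
    sprintf("%.4g%s", v, sig)
  }
  cat("  pES1 =", fmt("p_es1", s$p_es1), " pES2 =", fmt("p_es2", s$p_es2), "\n")
  cat("  kex GS:ES1 =", fmt("kex_gs_es1", s$kex_gs_es1),
      " GS:ES2 =", fmt("kex_gs_es2", s$kex_gs_es2),
      " ES1:ES2 =", fmt("kex_es1_es2", s$kex_es1_es2), "1/s\n")
  for (nu in x$nuclei) {
    p <- x$per_nucleus[[nu]]
    cat(sprintf("  [%s] dw1 = %.4g  dw2 = %.4g ppm;  R1 = %.4g  R2 = %.4g 1/s\n",
                nu, p$dw_es1, p$dw_es2, p$r1, p$r2))
  }
  invisible(x)
}

#' Monte-Carlo uncertainties for an exchange fit
#'
#' Resamples each R1rho point from `N(value, sigma)`, refits (warm-started
#' from the converged solution), and reports the SD of each parameter over
#' the replicates.
#'
#' @param fit a converged `"bm_fit"`.
#' @param n_iter Monte-Carlo iterations (default 100).
#' @param seed integer seed.
#' @return The fit with `sigma_par` (named SDs on the natural scale) and
#'   `mc` (matrix of replicate parameter values) filled in.
#' @export
mc_exchange_uncertainty <- function(fit, n_iter = 100, seed = 1) {
  stopifnot(inherits(fit, "bm_fit"))
  pts <- fit$points
  par_names <- names(fit$par)
  nuclei <- fit$nuclei

  resid_fn <- function(par, pts) {
    names(par) <- par_names
    pars <- .bm_unpack(par, nuclei, fit$fix, fit$fixed_per)
    sim <- .bm_sim_points(pars, pts, fit$delays, fit$larmor_mhz, fit$align,
                          fit$align_thresh)
    sim[!is.finite(sim)] <- 1e6
    (pts$r1rho - sim) / pts$sigma
  }
  lower <- rep(-Inf, length(fit$par))
  upper <- rep(Inf, length(fit$par))
  lower[grepl("^lp", par_names)] <- log(1e-6)
  upper[grepl("^lp", par_names)] <- log(0.45)
  lower[grepl("^lk", par_names)] <- log(1e-2)
  upper[grepl("^lk", par_names)] <- log(1e6)
  lower[grepl("\\.r[12]$", par_names)] <- 1e-3

  natural <- function(par) {
    names(par) <- par_names
    pars <- .bm_unpack(par, nuclei, fit$fix, fit$fixed_per)
    c(unlist(pars$shared), unlist(pars$per))
  }

  draws <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      p2 <- pts
      p2$r1rho <- stats::rnorm(nrow(pts), pts$r1rho, pts$sigma)
      f <- tryCatch(
        minpack.lm::nls.lm(par = fit$par, lower = lower, upper = upper,
                           fn = resid_fn, pts = p2,
                           control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      if (is.null(f)) rep(NA_real_, length(natural(fit$par)))
      else natural(f$par)
    }, natural(fit$par))
  })
  draws <- t(draws)
  fit$mc <- draws
  fit$sigma_par <- apply(draws, 2L, stats::sd, na.rm = TRUE)
  fit
}

#' R2+Rex dispersion profile
#'
#' Converts R1rho points to the exchange-augmented transverse rate
#' `R2 + Rex = (R1rho - R1 cos^2(theta)) / sin^2(theta)` with theta computed
#' from the ground-state offset; sigma is propagated as
#' `sigma_R1rho / sin^2(theta)`.  Points with `theta == 0` are excluded and
#' flagged.
#'
#' @param points data.frame with `power_hz`, `offset_hz`, `r1rho` and
#'   optionally `sigma`.
#' @param R1 longitudinal relaxation rate, 1/s.
#' @return data.frame: `power_hz`, `offset_hz`, `omega_eff` (rad/s),
#'   `theta`, `r2rex`, `sigma`, `excluded`.
#' @export
r2rex_profile <- function(points, R1) {
  ef <- effective_field(points$power_hz, points$offset_hz)
  s2 <- sin(ef$theta)^2
  excl <- s2 <= 0
  r2rex <- ifelse(excl, NA_real_,
                  (points$r1rho - R1 * cos(ef$theta)^2) / s2)
  sig <- if (!is.null(points$sigma)) ifelse(excl, NA_real_, points$sigma / s2)
         else rep(NA_real_, nrow(points))
  data.frame(power_hz = points$power_hz, offset_hz = points$offset_hz,
             omega_eff = ef$omega_eff, theta = ef$theta,
             r2rex = r2rex, sigma = sig, excluded = excl)
}

#' @export
plot.bm_fit <- function(x, nucleus = x$nuclei[1L], ...) {
  pts <- x$points[x$points$nucleus == nucleus, , drop = FALSE]
  r1 <- x$per_nucleus[[nucleus]]$r1
  prof <- r2rex_profile(pts, r1)
  pal <- grDevices::hcl.colors(length(unique(pts$power_hz)), "Dark 3")
  cols <- pal[as.integer(factor(pts$power_hz))]
  graphics::plot(prof$omega_eff / (2 * pi * 1000), prof$r2rex, col = cols,
                 pch = 16, xlab = expression(Omega[eff] / 2 * pi ~ "(kHz)"),
                 ylab = expression(R[2] + R[ex] ~ (s^-1)), ...)
  fitted_prof <- r2rex_profile(
    data.frame(power_hz = pts$power_hz, offset_hz = pts$offset_hz,
               r1rho = pts$fitted), r1)
  graphics::points(fitted_prof$omega_eff / (2 * pi * 1000),
                   fitted_prof$r2rex, col = cols, pch = 3)
  invisible(x)
}
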