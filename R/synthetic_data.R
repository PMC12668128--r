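#' Synthetic pH-dependent titration spectra
#'
#' Generates, for each pH on the grid, a two-Lorentzian spectrum whose peak
#' areas follow the Henderson-Hasselbalch two-state titration: the
#' anion/wobble area ratio equals `10^(pH - true_pKa)`, with the total area
#' conserved across pH.  Additive i.i.d. Gaussian noise (default 1% of the
#' maximum noiseless intensity) emulates detector noise.
#'
#' @param true_pKa true apparent pKa.
#' @param pH_grid strictly increasing pH values (length >= 2).
#' @param wobble_center,anion_center peak positions, ppm.
#' @param fwhm full widths at half maximum, ppm (length 1 or 2:
#'   wobble, anion).
#' @param total_area total integrated area (arbitrary units).
#' @param noise_sd intensity noise SD; `NULL` uses 1% of the maximum
#'   noiseless intensity across the series.
#' @param shift_axis numeric `c(min, max, n_points)` for the ppm axis.
#' @param seed integer seed (generation is bit-reproducible).
#' @return Named list of [nmr_spectrum()] objects, one per pH.
#' @export
gen_titration_series <- function(true_pKa, pH_grid = seq(7, 10, by = 0.5),
                                 wobble_center = 0, anion_center = 2.5,
                                 fwhm = 0.25, total_area = 10,
                                 noise_sd = NULL,
                                 shift_axis = c(-2, 4.5, 600), seed = 1) {
  if (length(pH_grid) < 2L) stop("pH grid must have at least 2 points")
  if (any(diff(pH_grid) <= 0)) stop("pH grid must be strictly increasing")
  fwhm <- rep_len(fwhm, 2L)
  stopifnot(all(fwhm > 0), total_area > 0, length(shift_axis) == 3L)
  x <- seq(shift_axis[1L], shift_axis[2L], length.out = shift_axis[3L])

  clean <- lapply(pH_grid, function(ph) {
    p_an <- population_at_pH(true_pKa, ph)
    lorentzian(x, wobble_center, fwhm[1L], total_area * (1 - p_an)) +
      lorentzian(x, anion_center, fwhm[2L], total_area * p_an)
  })
  if (is.null(noise_sd)) noise_sd <- 0.01 * max(unlist(clean))
  stopifnot(noise_sd >= 0)

  withr::with_seed(seed, {
    out <- lapply(seq_along(pH_grid), function(i) {
      nmr_spectrum(x, clean[[i]] + stats::rnorm(length(x), 0, noise_sd),
               pH = pH_grid[i])
    })
  })
  names(out) <- sprintf("pH%.2f", pH_grid)
  out
}

#' Synthetic additive per-context pKa table
#'
#' Constructs the 16-context table `pKa(Z, W) = base + inc5[Z] + inc3[W] +
#' noise`, the exact-additivity ground truth for testing the mutational
#' cycle analysis.
#'
#' @param base baseline pKa.
#' @param inc5,inc3 named increments for the four 5' and 3' neighbours
#'   (names A, C, G, T); defaults emulate the measured behaviour: 3'
#'   purines destabilize the anionic state (raise pKa) far more than the 5'
#'   neighbour does.
#' @param noise_sd SD of additive Gaussian noise (0 = exactly additive).
#' @param seed integer seed.
#' @return Named numeric vector of 16 pKa values ([triplet_contexts()]
#'   order).
#' @export
gen_additive_pka_table <- function(base = 8.6,
                                   inc5 = c(A = 0.05, C = -0.15, G = 0.10,
                                            T = 0.00),
                                   inc3 = c(A = 0.75, C = -0.65, G = 0.55,
                                            T = -0.45),
                                   noise_sd = 0, seed = 1) {
  stopifnot(setequal(names(inc5), BASES), setequal(names(inc3), BASES),
            noise_sd >= 0)
  ctx <- triplet_contexts()
  vals <- base + inc5[substr(ctx, 1L, 1L)] + inc3[substr(ctx, 3L, 3L)]
  names(vals) <- ctx
  if (noise_sd > 0) {
    vals <- withr::with_seed(seed,
      vals + stats::rnorm(length(vals), 0, noise_sd))
  }
  vals
}

#' Synthetic off-resonance R1rho dataset
#'
#' Simulates the full long-format intensity dataset of an off-resonance
#' R1rho experiment: for each spin-lock power, offsets on a uniform grid
#' spanning `±offset_multiple x power`; per (power, offset), intensities at
#' each delay are `exp(-R1rho_sim * t) * (1 + noise)` with `R1rho_sim` from
#' the Bloch-McConnell forward model ([simulate_r1rho()]).  The default
#' grid mirrors the acquisition conditions: powers 500-2000 Hz, offsets
#' `±3.5 x` power (20 per power), five delays up to 120 ms.
#'
#' @param model an [exchange_model()] (the ground truth).
#' @param larmor_mhz spectrometer frequency of the observed nucleus, MHz.
#' @param powers_hz spin-lock powers (> 0).
#' @param offset_multiple offset span as a multiple of each power.
#' @param n_offsets offsets per power.
#' @param delays delay times in seconds, must include 0.
#' @param noise_fraction multiplicative intensity noise SD (default 1%).
#' @param nucleus nucleus label.
#' @param seed integer seed.
#' @return data.frame: `nucleus`, `power_hz`, `offset_hz`, `delay_s`,
#'   `intensity`, plus the noiseless `r1rho_true` per row.
#' @export
gen_r1rho_dataset <- function(model, larmor_mhz = 70.96,
                              powers_hz = c(500, 1000, 1500, 2000),
                              offset_multiple = 3.5, n_offsets = 20,
                              delays = seq(0, 0.12, length.out = 5),
                              noise_fraction = 0.01, nucleus = "N1",
                              seed = 1) {
  stopifnot(inherits(model, "exchange_model"), length(powers_hz) >= 1L,
            all(powers_hz > 0), n_offsets >= 1L, all(delays >= 0),
            any(delays == 0), noise_fraction >= 0)
  grid <- do.call(rbind, lapply(powers_hz, function(p) {
    data.frame(power_hz = p,
               offset_hz = seq(-offset_multiple * p, offset_multiple * p,
                               length.out = n_offsets))
  }))
  r1rho <- simulate_r1rho(model, grid$power_hz, grid$offset_hz, delays,
                          larmor_mhz)
  long <- grid[rep(seq_len(nrow(grid)), each = length(delays)), ]
  long$delay_s <- rep(delays, nrow(grid))
  long$r1rho_true <- rep(r1rho, each = length(delays))
  clean <- exp(-long$r1rho_true * long$delay_s)
  long$intensity <- withr::with_seed(seed, {
    clean * (1 + stats::rnorm(nrow(long), 0, noise_fraction))
  })
  long$nucleus <- nucleus
  rownames(long) <- NULL
  long[, c("nucleus", "power_hz", "offset_hz", "delay_s", "intensity",
           "r1rho_true")]
}

#' Synthetic UV melting curve
#'
#' Two-state duplex melt ([melting_model()]) with sloped baselines and
#' additive Gaussian absorbance noise, over a heating ramp (default 15-95
#' degrees C).
#'
#' @param Tm melting temperature, kelvin (must lie inside `T_grid`).
#' @param dH melting enthalpy, kcal/mol (> 0).
#' @param m_ss,b_ss,m_ds,b_ds baseline coefficients.
#' @param T_grid temperatures, kelvin.
#' @param noise_sd absorbance noise SD.
#' @param seed integer seed.
#' @return data.frame with `T_kelvin`, `A260`.
#' @export
gen_melting_curve <- function(Tm = 325, dH = 85,
                              m_ss = 2e-4, b_ss = 0.92, m_ds = 5e-5,
                              b_ds = 0.70,
                              T_grid = seq(288.15, 368.15, by = 0.5),
                              noise_sd = 0.002, seed = 1) {
  stopifnot(dH > 0, noise_sd >= 0,
            Tm > min(T_grid), Tm < max(T_grid))
  a <- melting_model(T_grid, Tm, dH, m_ss, b_ss, m_ds, b_ds)
  if (noise_sd > 0) {
    a <- withr::with_seed(seed, a + stats::rnorm(length(a), 0, noise_sd))
  }
  data.frame(T_kelvin = T_grid, A260 = a)
}

# one symmetric Dirichlet draw of dimension k
.rdirichlet1 <- function(k, concentration) {
  g <- stats::rgamma(k, shape = concentration, rate = 1)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

#' Synthetic SBS96 signature catalog with one planted signature
#'
#' Background signature columns are symmetric-Dirichlet draws over the 96
#' channels.  In the planted signature, the 16-context vector of the
#' planted substitution class is replaced by the mixture
#' `(1 - eps) * fingerprint + eps * noise` (noise = a fresh Dirichlet draw
#' over 16 contexts) before the whole column is renormalized, so the
#' planted channel correlates with the fingerprint with weight `1 - eps`.
#'
#' @param planted_fingerprint named probability vector over all 16 contexts
#'   (sums to 1).
#' @param n_signatures number of columns (default 80).
#' @param planted_index which column carries the plant.
#' @param planted_substitution substitution class of the plant.
#' @param contamination_eps mixing weight of the noise component in [0, 1].
#' @param dirichlet_concentration symmetric Dirichlet concentration of
#'   background channels (default 0.5, giving COSMIC-like sparsity).
#' @param seed integer seed.
#' @return 96 x n_signatures probability matrix (columns `SBS_syn1`, ...),
#'   validated by [validate_signature_matrix()].
#' @export
gen_signature_catalog <- function(planted_fingerprint,
                                  n_signatures = 80, planted_index = 1,
                                  planted_substitution = "C>T",
                                  contamination_eps = 0.1,
                                  dirichlet_concentration = 0.5, seed = 1) {
  planted_substitution <- match.arg(planted_substitution,
                                    substitution_classes())
  fp <- as.numeric(planted_fingerprint)
  if (length(fp) != 16L || abs(sum(fp) - 1) > 1e-9 || any(fp < 0)) {
    stop("planted_fingerprint must be 16 non-negative entries summing to 1")
  }
  stopifnot(contamination_eps >= 0, contamination_eps <= 1,
            planted_index >= 1, planted_index <= n_signatures)
  fpctx <- names(planted_fingerprint)
  if (!is.null(fpctx)) {
    key <- paste0(substr(fpctx, 1L, 1L), substr(fpctx, 3L, 3L))
    ctx <- substitution_contexts(planted_substitution)
    ord <- match(paste0(substr(ctx, 1L, 1L), substr(ctx, 3L, 3L)), key)
    if (anyNA(ord)) stop("fingerprint context names do not cover 16 contexts")
    fp <- fp[ord]
  }

  chan <- sbs96_channels()
  sub_block <- substr(chan, 3L, 5L) == planted_substitution

  withr::with_seed(seed, {
    m <- vapply(seq_len(n_signatures), function(j) {
      .rdirichlet1(96L, dirichlet_concentration)
    }, numeric(96L))
    noise <- .rdirichlet1(16L, dirichlet_concentration)
    mix <- (1 - contamination_eps) * fp + contamination_eps * noise
    col <- m[, planted_index]
    block_mass <- sum(col[sub_block])
    if (block_mass <= 0) block_mass <- 1 / 6
    col[sub_block] <- mix * block_mass
    m[, planted_index] <- col / sum(col)
  })
  rownames(m) <- chan
  colnames(m) <- sprintf("SBS_syn%d", seq_len(n_signatures))
  validate_signature_matrix(m, tol = 1e-9)
  m
}
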