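delays5 <- seq(0, 0.12, length.out = 5)
LARMOR <- 70.96

test_that("mono-exponential decay fitting is exact on clean data and rejects junk", {
  t <- delays5
  y <- 2.3 * exp(-10 * t)
  f <- fit_decay(t, y, n_mc = 0)
  expect_equal(f$r1rho, 10, tolerance = 1e-8)
  expect_equal(f$i0, 2.3, tolerance = 1e-8)

  expect_error(fit_decay(t, rep(1, 5)), "constant")
  expect_error(fit_decay(t, exp(2 * t)), "decay")
})

test_that("decay-rate Monte-Carlo sigma scales linearly with noise and is seeded", {
  t <- seq(0, 0.12, length.out = 8)
  sig <- vapply(c(0.01, 0.02, 0.04), function(nf) {
    y <- withr::with_seed(42, exp(-15 * t) * (1 + rnorm(8, 0, nf)))
    fit_decay(t, y, n_mc = 200, seed = 9)$sigma
  }, numeric(1))
  expect_equal(sig[2] / sig[1], 2, tolerance = 0.5)
  expect_equal(sig[3] / sig[1], 4, tolerance = 1.2)

  y <- withr::with_seed(1, exp(-15 * t) * (1 + rnorm(8, 0, 0.02)))
  s1 <- fit_decay(t, y, n_mc = 100, seed = 5)$sigma
  s2 <- fit_decay(t, y, n_mc = 100, seed = 5)$sigma
  expect_identical(s1, s2)
})

test_that("the generator obeys detailed balance and block structure", {
  m <- exchange_model(p_es1 = 0.01, p_es2 = 0.004, kex_gs_es1 = 2000,
                      kex_gs_es2 = 800, kex_es1_es2 = 150,
                      dw_es1 = 3, dw_es2 = -7, r1 = 2, r2 = 16)
  L <- build_bm_generator(m, 1000, 300, LARMOR)
  p <- c(1 - m$p_es1 - m$p_es2, m$p_es1, m$p_es2)
  # exchange rate i->j sits on the diagonal of off-diagonal block (j, i)
  k <- function(i, j) L[3 * (j - 1) + 1, 3 * (i - 1) + 1]
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    expect_equal(p[i] * k(i, j), p[j] * k(j, i), tolerance = 1e-12)
  }
  # no-exchange model gives a block-diagonal generator
  L0 <- build_bm_generator(exchange_model(r1 = 2, r2 = 16), 1000, 300, LARMOR)
  off <- L0
  for (i in 1:3) off[3 * (i - 1) + 1:3, 3 * (i - 1) + 1:3] <- 0
  expect_true(all(off == 0))
  expect_error(build_bm_generator(
    exchange_model, 1000, 300, LARMOR))
})

test_that("no-exchange R1rho equals R1 cos2(theta) + R2 sin2(theta)", {
  grid <- expand.grid(power = c(500, 1000, 2000),
                      offset = c(0, -1200, 700, 3500))
  # exact regimes: R1 = R2 anywhere, and on-resonance for R1 != R2
  m_eq <- exchange_model(r1 = 5, r2 = 5)
  r <- simulate_r1rho(m_eq, grid$power, grid$offset, delays5, LARMOR)
  expect_equal(r, oracle_r1rho_noexch(5, 5, grid$power, grid$offset),
               tolerance = 1e-8)

  m_ne <- exchange_model(r1 = 2, r2 = 20)
  r_on <- simulate_r1rho(m_ne, c(500, 2000), c(0, 0), delays5, LARMOR)
  expect_equal(r_on, c(20, 20), tolerance = 1e-8)

  # off-resonance with R1 != R2: agreement to O(((R2-R1)/omega_eff)^2)
  r_off <- simulate_r1rho(m_ne, grid$power, grid$offset, delays5, LARMOR)
  expect_equal(r_off, oracle_r1rho_noexch(2, 20, grid$power, grid$offset),
               tolerance = 1e-4)
})

test_that("R and C++ engines agree to numerical precision", {
  m <- exchange_model(p_es1 = 0.01, p_es2 = 0.003, kex_gs_es1 = 3000,
                      kex_gs_es2 = 900, kex_es1_es2 = 100,
                      dw_es1 = 2.5, dw_es2 = -6, r1 = 2.2, r2 = 18)
  pw <- c(500, 500, 1200, 2000)
  of <- c(-900, 400, 0, 2500)
  expect_equal(simulate_r1rho(m, pw, of, delays5, LARMOR, engine = "R"),
               simulate_r1rho(m, pw, of, delays5, LARMOR, engine = "cpp"),
               tolerance = 1e-8)
})

test_that("fast-exchange Rex matches the algebraic approximation within 10%", {
  p <- 0.01; kex <- 20000; dw <- 3
  m <- exchange_model(p_es1 = p, kex_gs_es1 = kex, dw_es1 = dw,
                      r1 = 2, r2 = 16)
  dw_rad <- dw * LARMOR * 2 * pi
  for (pw in c(500, 1000, 2000)) {
    r <- simulate_r1rho(m, pw, 0, delays5, LARMOR)
    rex_sim <- r - 16          # on resonance: R1rho = R2 + Rex
    rex_alg <- oracle_rex_fast(p, kex, dw_rad, 2 * pi * pw)
    expect_equal(rex_sim, rex_alg, tolerance = 0.10)
  }
})

test_that("exchange leaves R1rho at R1 when R1 = R2 and when dw = 0", {
  m <- exchange_model(p_es1 = 0.02, kex_gs_es1 = 1500, dw_es1 = 4,
                      r1 = 6, r2 = 6)
  # with R1 = R2 and no exchange contribution at dw = 0
  m0 <- exchange_model(p_es1 = 0.02, kex_gs_es1 = 1500, dw_es1 = 0,
                       r1 = 6, r2 = 6)
  r <- simulate_r1rho(m0, c(600, 1500), c(-800, 500), delays5, LARMOR)
  expect_equal(r, c(6, 6), tolerance = 1e-6)

  # offset sign symmetry when both dw = 0
  m00 <- exchange_model(p_es1 = 0.01, p_es2 = 0.005, kex_gs_es1 = 2000,
                        kex_gs_es2 = 500, dw_es1 = 0, dw_es2 = 0,
                        r1 = 2, r2 = 18)
  rp <- simulate_r1rho(m00, 800, 1200, delays5, LARMOR)
  rm <- simulate_r1rho(m00, 800, -1200, delays5, LARMOR)
  expect_equal(rp, rm, tolerance = 1e-9)
})

test_that("a 3-state model with an empty ES2 reduces to the 2-state system", {
  base <- exchange_model(p_es1 = 0.01, kex_gs_es1 = 2500, dw_es1 = 3,
                         r1 = 2, r2 = 16)
  with_ghost <- exchange_model(p_es1 = 0.01, p_es2 = 0,
                               kex_gs_es1 = 2500, kex_gs_es2 = 0,
                               kex_es1_es2 = 777, dw_es1 = 3, dw_es2 = -11,
                               r1 = 2, r2 = 16)
  pw <- c(500, 1000, 2000); of <- c(-700, 300, 1500)
  expect_identical(simulate_r1rho(base, pw, of, delays5, LARMOR),
                   simulate_r1rho(with_ghost, pw, of, delays5, LARMOR))
})

test_that("Rex is suppressed by increasing spin-lock power in fast exchange", {
  m <- exchange_model(p_es1 = 0.01, kex_gs_es1 = 20000, dw_es1 = 3,
                      r1 = 2, r2 = 16)
  r <- simulate_r1rho(m, c(500, 1000, 1500, 2000), 0, delays5, LARMOR)
  expect_true(all(diff(r) < 0))
})

test_that("noiseless 2-state data are recovered by the global fit to <=1%", {
  truth <- exchange_model(p_es1 = 0.008, kex_gs_es1 = 2200, dw_es1 = 3.2,
                          r1 = 2.4, r2 = 15)
  d <- gen_r1rho_dataset(truth, larmor_mhz = LARMOR,
                         powers_hz = c(600, 1200, 2000), n_offsets = 12,
                         noise_fraction = 0, seed = 3)
  pts <- reduce_to_r1rho(d, n_mc = 0)
  fit <- fit_exchange(pts, LARMOR,
                      fix = list(p_es2 = 0, kex_gs_es2 = 0,
                                 kex_es1_es2 = 0))
  expect_equal(fit$shared$p_es1, truth$p_es1, tolerance = 0.01)
  expect_equal(fit$shared$kex_gs_es1, truth$kex_gs_es1, tolerance = 0.01)
  expect_equal(abs(fit$per_nucleus[["N1"]]$dw_es1), truth$dw_es1,
               tolerance = 0.01)
  expect_equal(fit$per_nucleus[["N1"]]$r2, truth$r2, tolerance = 0.01)
})

test_that("data simulated without exchange fit to populations near zero", {
  truth <- exchange_model(r1 = 2.0, r2 = 14)
  d <- gen_r1rho_dataset(truth, larmor_mhz = LARMOR,
                         powers_hz = c(600, 2000), n_offsets = 10,
                         noise_fraction = 0.01, seed = 8)
  pts <- reduce_to_r1rho(d, n_mc = 30, seed = 2)
  fit <- fit_exchange(pts, LARMOR,
                      fix = list(p_es2 = 0, kex_gs_es2 = 0,
                                 kex_es1_es2 = 0),
                      kex_starts = 1e3)
  # on exchange-free data the fitted model must not introduce detectable
  # exchange broadening: fitted R1rho stays at the tilt-formula values
  formula_r <- oracle_r1rho_noexch(fit$per_nucleus[["N1"]]$r1,
                                   fit$per_nucleus[["N1"]]$r2,
                                   fit$points$power_hz,
                                   fit$points$offset_hz)
  expect_lt(max(abs(fit$points$fitted - formula_r)),
            3 * stats::median(pts$sigma))
})

test_that("Monte-Carlo exchange uncertainties are seeded and noise-scaled", {
  truth <- exchange_model(p_es1 = 0.01, kex_gs_es1 = 2000, dw_es1 = 3,
                          r1 = 2, r2 = 15)
  d <- gen_r1rho_dataset(truth, larmor_mhz = LARMOR,
                         powers_hz = c(600, 2000), n_offsets = 10,
                         noise_fraction = 0, seed = 1)
  pts <- reduce_to_r1rho(d, n_mc = 0)
  pts$sigma <- 0.05
  fit <- fit_exchange(pts, LARMOR, kex_starts = 1e3,
                      fix = list(p_es2 = 0, kex_gs_es2 = 0,
                                 kex_es1_es2 = 0))
  f1 <- mc_exchange_uncertainty(fit, n_iter = 25, seed = 11)
  f2 <- mc_exchange_uncertainty(fit, n_iter = 25, seed = 11)
  expect_identical(f1$sigma_par, f2$sigma_par)

  pts2 <- pts; pts2$sigma <- 0.1
  fit2 <- fit_exchange(pts2, LARMOR, kex_starts = 1e3,
                       fix = list(p_es2 = 0, kex_gs_es2 = 0,
                                  kex_es1_es2 = 0))
  f3 <- mc_exchange_uncertainty(fit2, n_iter = 25, seed = 11)
  # doubling the point sigmas roughly doubles the parameter spread
  ratio <- f3$sigma_par[["kex_gs_es1"]] / f1$sigma_par[["kex_gs_es1"]]
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.5)
})

test_that("R2+Rex profiles follow the tilt-angle transformation", {
  pts <- data.frame(power_hz = c(1000, 1000), offset_hz = c(0, 1500),
                    r1rho = c(12, 9), sigma = c(0.2, 0.2))
  prof <- r2rex_profile(pts, R1 = 2)
  # on resonance theta = pi/2: R2+Rex = R1rho, sigma unchanged
  expect_equal(prof$r2rex[1], 12)
  expect_equal(prof$sigma[1], 0.2)
  # off resonance: matches the closed form and the finite-difference
  # derivative of the transformation
  th <- atan2(2 * pi * 1000, 2 * pi * 1500)
  expect_equal(prof$r2rex[2], (9 - 2 * cos(th)^2) / sin(th)^2)
  h <- 1e-6
  fd <- ((9 + h - 2 * cos(th)^2) / sin(th)^2 -
           (9 - 2 * cos(th)^2) / sin(th)^2) / h
  expect_equal(prof$sigma[2], abs(fd) * 0.2, tolerance = 1e-6)

  # a no-exchange dataset yields a flat profile at R2
  m <- exchange_model(r1 = 2, r2 = 17)
  grid <- expand.grid(power_hz = c(600, 1500), offset_hz = c(0, 900, -2000))
  grid$r1rho <- simulate_r1rho(m, grid$power_hz, grid$offset_hz, delays5,
                               LARMOR)
  flat <- r2rex_profile(grid, R1 = 2)
  expect_equal(flat$r2rex, rep(17, 6), tolerance = 1e-3)
})
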