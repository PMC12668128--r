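# Independent oracles used across tests.  These deliberately re-derive
# quantities by different routes than the package implementation.

# Mass-action equilibrium oracle for a non-self-complementary duplex:
# D <-> S1 + S2, van 't Hoff K(T) anchored at Tm where half the strands are
# single-stranded (K(Tm) = C_total / 2).  Solves the equilibrium for the
# single-strand fraction f by root finding.
oracle_pss_mass_action <- function(T_kelvin, Tm, dH, C_total,
                                   R = 1.987e-3) {
  vapply(T_kelvin, function(Tk) {
    K <- (C_total / 2) * exp(-(dH / R) * (1 / Tk - 1 / Tm))
    g <- function(f) C_total * f^2 / (1 - f) - K
    stats::uniroot(g, c(1e-12, 1 - 1e-12), tol = 1e-14)$root
  }, numeric(1))
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1L], slope = beta[2L])
}

# Exhaustive rectangle enumeration of additivity cycles, written
# independently of the package: loops over corner quadruples directly.
oracle_cycle_deviations <- function(values) {
  b <- c("A", "C", "G", "T")
  devs <- c()
  for (z1 in 1:4) for (z2 in 1:4) for (w1 in 1:3) for (w2 in (w1 + 1):4) {
    if (z1 == z2) next
    if (z1 > z2) next  # unordered 5' pair; both orientations below
    for (orient in 1:2) {
      zr <- if (orient == 1) c(z1, z2) else c(z2, z1)
      f <- function(i, j) values[[paste0(b[i], "T", b[j])]]
      dev <- (f(zr[2], w2) - f(zr[1], w1)) -
        ((f(zr[2], w1) - f(zr[1], w1)) + (f(zr[1], w2) - f(zr[1], w1)))
      devs <- c(devs, dev)
    }
  }
  devs
}

# Algebraic fast-exchange approximation for a 2-state system:
# Rex = pG * pE * dw^2 * kex / (kex^2 + omega_eff^2), all in rad/s.
oracle_rex_fast <- function(p_es, kex, dw_rad, omega_eff) {
  (1 - p_es) * p_es * dw_rad^2 * kex / (kex^2 + omega_eff^2)
}

# Laboratory-frame no-exchange R1rho.
oracle_r1rho_noexch <- function(r1, r2, power_hz, offset_hz) {
  th <- atan2(2 * pi * power_hz, 2 * pi * offset_hz)
  r1 * cos(th)^2 + r2 * sin(th)^2
}

# Trapezoidal integral on an (x, y) grid.
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
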