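test_that("Henderson-Hasselbalch relations are exact and mutually inverse", {
  expect_equal(pka_from_population(7.4, 0.5), 7.4)
  expect_equal(pka_from_population(8.31, 0.2), 8.31 - log10(0.25))
  expect_equal(pka_from_population(8.31, 0.2), 8.912, tolerance = 1e-3)
  expect_equal(population_at_pH(7.4, 7.4), 0.5)
  expect_equal(population_at_pH(9.7, 7.4), 0.00499, tolerance = 1e-3)

  # round trips over (0, 1)
  for (p in c(1e-4, 0.1, 10 / 11, 1 - 1e-6)) {
    expect_equal(population_at_pH(pka_from_population(8.2, p), 8.2), p,
                 tolerance = 1e-12)
  }
  expect_equal(population_at_pH(8.0, 9.0), 10 / 11)

  expect_error(pka_from_population(7, 0), "strictly inside")
  expect_error(pka_from_population(7, 1), "strictly inside")
})

test_that("the printed pKa extremes imply a ~50-fold propensity range", {
  fold <- population_at_pH(7.9, 7.4) / population_at_pH(9.7, 7.4)
  expect_equal(fold, 48.2, tolerance = 0.01)
})

test_that("per-pH pKa values pool by inverse-variance weighting", {
  r <- aggregate_pka(c(8.0, 8.2), c(0.1, 0.1))
  expect_equal(r$pKa_app, 8.1)
  expect_equal(r$sigma, 0.1 / sqrt(2), tolerance = 1e-9)

  expect_equal(aggregate_pka(rep(8.3, 4), rep(0.2, 4))$pKa_app, 8.3)
  one <- aggregate_pka(9.1, 0.05)
  expect_equal(one$pKa_app, 9.1)
  expect_equal(one$sigma, 0.05)
  expect_error(aggregate_pka(numeric(0)), "no usable")
})

test_that("free energies scale with RT ln10 and reproduce the measured span", {
  expect_equal(free_energy(8.0, 8.0), 0)
  # 1.8 pKa-unit span at 1 degree C
  span <- free_energy(9.7, 7.9, 274.15)
  expect_equal(span, 1.987e-3 * 274.15 * log(10) * 1.8)
  expect_equal(span, 2.26, tolerance = 0.005)
  # linear in T for fixed pKa - pH
  expect_equal(free_energy(9, 7, 600), 2 * free_energy(9, 7, 300))
  # ddG between contexts is pH independent
  d1 <- free_energy(9.7, 7.4) - free_energy(7.9, 7.4)
  d2 <- free_energy(9.7, 5.0) - free_energy(7.9, 5.0)
  expect_equal(d1, d2)
})

test_that("delta tables are referenced, translation-invariant and propagate sigma", {
  v <- c(CTA = 8.0, GTA = 9.0, ATA = 8.5)
  d <- delta_table(v, "CTA", sigma = c(0.1, 0.1, 0.1))
  expect_equal(d$delta[d$context == "CTA"], 0)
  expect_equal(d$delta[d$context == "GTA"], 1.0)
  expect_equal(d$sigma[d$context == "GTA"], sqrt(0.02), tolerance = 1e-9)
  expect_equal(d$sigma[d$context == "GTA"], 0.1414, tolerance = 1e-3)

  d2 <- delta_table(v + 3.7, "CTA")
  expect_equal(d2$delta, d$delta)
  expect_error(delta_table(v, "TTT"), "not found")
  expect_equal(delta_table(c(a = 2, b = 2, c = 2), "a")$delta, c(0, 0, 0))
})

test_that("cycle enumeration yields 72 cycles matching an exhaustive oracle", {
  tab <- gen_additive_pka_table(noise_sd = 0)
  cy <- enumerate_additivity_cycles(tab)
  expect_identical(nrow(cy), 72L)
  expect_true(all(abs(cy$deviation) < 1e-12))

  rnd <- withr::with_seed(11, setNames(rnorm(16), triplet_contexts()))
  cy2 <- enumerate_additivity_cycles(rnd)
  expect_equal(sort(cy2$deviation), sort(oracle_cycle_deviations(rnd)),
               tolerance = 1e-12)

  # deviations are antisymmetric under swapping the rectangle diagonal:
  # the two orientations of each rectangle are emitted consecutively
  expect_equal(cy2$deviation[seq(1, 71, 2)], -cy2$deviation[seq(2, 72, 2)],
               tolerance = 1e-12)
  expect_error(enumerate_additivity_cycles(rnd[-1]), "full")
})

test_that("additivity summary has exact behaviour on constructed tables", {
  cy <- enumerate_additivity_cycles(gen_additive_pka_table(noise_sd = 0))
  s <- additivity_summary(cy)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)
  expect_equal(s$pearson_r, 1, tolerance = 1e-9)
  expect_equal(s$slope, 1, tolerance = 1e-9)
  expect_equal(s$intercept, 0, tolerance = 1e-12)

  # anti-correlated construction: observed = -predicted
  cy_neg <- cy
  cy_neg$observed <- -cy_neg$predicted + withr::with_seed(2, rnorm(72, 0, 1e-6))
  cy_neg$deviation <- cy_neg$observed - cy_neg$predicted
  expect_lt(additivity_summary(cy_neg)$pearson_r, 0)
})

test_that("iid table noise of sd sigma yields cycle RMSD near 2 sigma", {
  # each deviation combines 4 iid table entries with +/- signs -> sd 2*sigma
  sigma <- 0.05
  rmsds <- vapply(1:120, function(i) {
    tab <- gen_additive_pka_table(noise_sd = sigma, seed = i)
    additivity_summary(enumerate_additivity_cycles(tab))$rmsd
  }, numeric(1))
  expect_equal(mean(rmsds), 2 * sigma, tolerance = 0.05)
})

test_that("partition test equals exhaustive enumeration", {
  ctx <- triplet_contexts()
  purine3 <- substr(ctx, 3, 3) %in% c("A", "G")
  # complete separation of 8 vs 8
  v <- setNames(ifelse(purine3, 10, 0) + seq_along(ctx) * 1e-3, ctx)
  pt <- partition_test(v)
  expect_equal(pt$p_value, 2 / 12870, tolerance = 1e-12)

  # identical groups -> p = 1
  expect_equal(partition_test(setNames(rep(1, 16), ctx))$p_value, 1)

  # matches wilcox.test exact p on tie-free 4+4 data
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rnorm(8))
    g <- rep(c(TRUE, FALSE), each = 4)
    ours <- partition_test(setNames(x, paste0("c", 1:8)), group = g)$p_value
    ref <- stats::wilcox.test(x[g], x[!g], exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("fingerprint comparison reproduces closed-form OLS and RMSD", {
  x <- setNames(c(0.1, 0.5, -0.2, 0.9, 0.3), paste0("c", 1:5))
  # exact-identity input: lm warns about a perfect fit, which is expected
  perfect <- suppressWarnings(compare_fingerprints(x, x))
  expect_equal(perfect$rmsd, 0)
  expect_equal(perfect$slope, 1, tolerance = 1e-9)

  off <- suppressWarnings(compare_fingerprints(x, x + 0.3))
  expect_equal(off$rmsd, 0.3, tolerance = 1e-12)
  expect_equal(off$slope, 1, tolerance = 1e-9)
  expect_equal(off$intercept, 0.3, tolerance = 1e-9)

  y <- withr::with_seed(3, x + rnorm(5, 0, 0.2))
  cf <- compare_fingerprints(x, y)
  ref <- oracle_ols(as.numeric(x), as.numeric(y))
  expect_equal(cf$slope, unname(ref["slope"]), tolerance = 1e-9)
  expect_equal(cf$intercept, unname(ref["intercept"]), tolerance = 1e-9)
  expect_true(cf$ci_slope[1] < cf$slope && cf$slope < cf$ci_slope[2])
  expect_error(compare_fingerprints(x[1:2], y[1:2]), "3")
})

test_that("per-context tables round-trip through CSV", {
  v <- gen_additive_pka_table(noise_sd = 0.1, seed = 2)
  s <- setNames(rep(0.05, 16), names(v))
  path <- withr::local_tempfile(fileext = ".csv")
  write_context_table(v, path, sigma = s)
  v2 <- read_context_table(path)
  expect_equal(unclass(v2)[names(v)], unclass(v), tolerance = 1e-12)
  expect_equal(attr(v2, "sigma")[["CTA"]], 0.05)
})

test_that("de-shearing decomposition is elementwise with quadrature sigma", {
  ctx <- triplet_contexts()
  gt <- setNames(rep(1.0, 16), ctx)
  gc <- setNames(rep(0.4, 16), ctx)
  d <- deshear_decomposition(gt, gc)
  expect_equal(d$ddG_deshear, rep(0.6, 16))
  expect_equal(deshear_decomposition(gt, gt)$ddG_deshear, rep(0, 16))

  sg <- setNames(rep(0.08, 16), ctx)
  sc <- setNames(rep(0.06, 16), ctx)
  d2 <- deshear_decomposition(gt, gc, sg, sc)
  expect_equal(d2$sigma, rep(0.1, 16), tolerance = 1e-9)

  # quadrature matches Monte-Carlo resampling within 5%
  mc <- withr::with_seed(4, {
    draws <- replicate(4000, (gt[1] + rnorm(1, 0, 0.08)) -
                         (gc[1] + rnorm(1, 0, 0.06)))
    sd(draws)
  })
  expect_equal(d2$sigma[1], mc, tolerance = 0.05)

  expect_error(deshear_decomposition(gt, gc[-1], sg, sc), "matching")
})
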