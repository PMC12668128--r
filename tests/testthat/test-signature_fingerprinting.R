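test_that("fingerprints normalize propensities and convert pKa tables", {
  ctx <- triplet_contexts()
  uniform <- make_fingerprint(setNames(rep(8.8, 16), ctx), from = "pka")
  expect_equal(as.numeric(uniform), rep(1 / 16, 16))
  expect_equal(sum(uniform), 1)

  two <- make_fingerprint(c(CTC = 7.9, GTA = 9.7), from = "pka",
                          reference_pH = 7.4)
  expect_equal(unname(two["CTC"]), 0.9797, tolerance = 1e-3)
  expect_equal(unname(two["GTA"]), 0.0203, tolerance = 1e-2)

  twelve <- make_fingerprint(setNames(runif(12, 0.5, 2), ctx[1:12]))
  expect_length(twelve, 12L)
  expect_equal(sum(twelve), 1)
  expect_length(attr(twelve, "missing"), 4L)

  expect_error(make_fingerprint(c(a = 1)), "2 contexts")
  expect_error(make_fingerprint(c(a = 0, b = 0)), "zero")
})

test_that("SBS96 files round-trip bit-identically and are validated", {
  fp <- make_fingerprint(gen_additive_pka_table(), from = "pka")
  m <- gen_signature_catalog(fp, n_signatures = 3, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signatures(m, path)
  m2 <- read_signatures(path)
  expect_identical(m2, m)

  # shuffled row order canonicalizes to the same matrix
  d <- read.delim(path, check.names = FALSE)
  d <- d[withr::with_seed(1, sample(96)), ]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(d, path2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_signatures(path2), m)

  bad <- m
  bad[, 2] <- bad[, 2] * 0.8
  expect_error(validate_signature_matrix(bad), "not normalized")
  pb <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(Type = rownames(m)[1:10], S1 = rep(0.1, 10)),
              pb, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_signatures(pb), "96")
})

test_that("channel extraction restricts and renormalizes correctly", {
  uniform <- matrix(1 / 96, 96, 1, dimnames = list(sbs96_channels(), "U"))
  v <- extract_channel(uniform, "U", "C>T")
  expect_equal(as.numeric(v), rep(1 / 16, 16))

  ctx12 <- triplet_contexts()[1:12]
  v12 <- extract_channel(uniform, "U", "C>T", contexts = ctx12)
  expect_length(v12, 12L)
  expect_equal(sum(v12), 1)
  expect_identical(names(v12), ctx12)

  # manual arithmetic oracle on a hand-built matrix
  m <- matrix(0, 96, 1, dimnames = list(sbs96_channels(), "S"))
  m["A[C>T]A", 1] <- 0.5
  m["A[C>T]G", 1] <- 0.25
  m["T[C>T]T", 1] <- 0.05
  m["A[C>A]A", 1] <- 0.2
  v3 <- extract_channel(m, "S", "C>T")
  expect_equal(unname(v3["ACA"]), 0.5 / 0.8)
  expect_equal(unname(v3["ACG"]), 0.25 / 0.8)
  expect_equal(unname(v3["TCT"]), 0.05 / 0.8)
  expect_equal(sum(v3), 1)
  expect_error(extract_channel(m, "S", "T>G"), "zero mass")
  expect_error(extract_channel(m, "nope", "C>T"), "not present")
})

test_that("JSD satisfies its axioms and the hand-computed value", {
  expect_equal(jsd(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)
  p <- c(0.1, 0.3, 0.6); q <- c(0.5, 0.25, 0.25)
  expect_equal(jsd(p, q), jsd(q, p))
  expect_equal(jsd(c(0.5, 0.5), c(1, 0)), 0.3113, tolerance = 1e-4)
  # H(0.75, 0.25) - 0.5 by direct entropy arithmetic
  expect_equal(jsd(c(0.5, 0.5), c(1, 0)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)) - 0.5)
  expect_gte(jsd(c(0.9, 0.1, 0), c(0, 0.1, 0.9)), 0)
  expect_lte(jsd(c(0.9, 0.1, 0), c(0, 0.1, 0.9)), 1)
  expect_error(jsd(c(0.5, 0.6), c(0.5, 0.5)), "sum to 1")
})

test_that("the pooled null reduces to known distributions in edge cases", {
  fp <- make_fingerprint(setNames(c(2, 1, 1, 4), paste0("c", 1:4)))
  # single-value pool: every null vector is uniform
  m1 <- matrix(1 / 96, 96, 2, dimnames = list(sbs96_channels(), c("a", "b")))
  nul <- null_distribution(m1, fp, n_draws = 50, seed = 3)
  expect_equal(var(nul$samples), 0)
  expect_equal(nul$samples[1], jsd(as.numeric(fp), rep(0.25, 4)))

  # two-value pool, 2 contexts: matches exhaustive enumeration
  fp2 <- make_fingerprint(setNames(c(0.7, 0.3), paste0("k", 1:2)))
  a <- 0.004; b <- 0.016  # pool values in ratio 1:4
  m2 <- matrix(c(rep(a, 48), rep(b, 48)), 96, 1,
               dimnames = list(sbs96_channels(), "s"))
  expect_equal(sum(m2), 0.96)  # not a valid signature; fine as a pool
  nul2 <- null_distribution(m2, fp2, n_draws = 4000, seed = 5)
  # possible renormalized vectors: (.5,.5), (.2,.8), (.8,.2) w.p. .5,.25,.25
  vals <- c(jsd(as.numeric(fp2), c(0.5, 0.5)),
            jsd(as.numeric(fp2), c(0.2, 0.8)),
            jsd(as.numeric(fp2), c(0.8, 0.2)))
  expect_equal(sort(unique(round(nul2$samples, 9))),
               sort(unique(round(vals, 9))), tolerance = 1e-8)
  expect_equal(mean(abs(nul2$samples - vals[1]) < 1e-9), 0.5,
               tolerance = 0.06)

  nul_a <- null_distribution(m1, fp, n_draws = 20, seed = 9)
  nul_b <- null_distribution(m1, fp, n_draws = 20, seed = 9)
  expect_identical(nul_a$samples, nul_b$samples)
})

test_that("p-values use the add-one left-tail estimator", {
  nul <- structure(list(samples = c(0.2, 0.3, 0.4, 0.5), n_contexts = 4),
                   class = "jsd_null")
  expect_equal(p_value(0.1, nul), 1 / 5)
  expect_equal(p_value(0.9, nul), 1)
  expect_equal(p_value(0.35, nul), 3 / 5)
})

test_that("BH q-values match hand computation", {
  expect_equal(fdr(c(0.01, 0.02, 0.03, 0.9)), c(0.04, 0.04, 0.04, 0.9))
  expect_equal(fdr(0.37), 0.37)
  expect_equal(fdr(rep(0.2, 5)), rep(0.2, 5))
})

test_that("scan_all finds a planted signature and is column-order invariant", {
  fp <- make_fingerprint(gen_additive_pka_table(), from = "pka",
                         state = "GT_anion")
  m <- gen_signature_catalog(fp, n_signatures = 15, planted_index = 6,
                             planted_substitution = "C>T",
                             contamination_eps = 0, seed = 13)
  sc <- scan_all(m, fp, n_draws = 2000, seed = 1)
  expect_s3_class(sc, "fp_scan")
  expect_identical(sc$signature[1], "SBS_syn6")
  expect_identical(sc$substitution[1], "C>T")
  expect_equal(sc$jsd[1], 0, tolerance = 1e-12)
  expect_equal(sc$p_value[1], 1 / 2001)
  expect_identical(nrow(sc), 30L)   # 15 signatures x {C>T, T>C}

  perm <- m[, withr::with_seed(2, sample(ncol(m)))]
  sc2 <- scan_all(perm, fp, n_draws = 2000, seed = 1)
  expect_equal(sc2$jsd, sc$jsd)
  expect_identical(sc2$signature, sc$signature)

  empty <- scan_all(m, fp, substitutions = character(0))
  expect_identical(nrow(empty), 0L)
})

test_that("restriction-then-renormalization commutes with relabeling", {
  fp <- make_fingerprint(gen_additive_pka_table(), from = "pka")
  m <- gen_signature_catalog(fp, n_signatures = 5, seed = 6)
  ctx <- names(fp)[c(3, 1, 8, 12)]
  v1 <- extract_channel(m, "SBS_syn2", "C>T", contexts = ctx)
  v2 <- extract_channel(m, "SBS_syn2", "C>T", contexts = rev(ctx))
  expect_equal(v1[ctx], v2[ctx])
})
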