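#' Gas constant in kcal/mol/K
#'
#' @export
R_KCAL <- 1.987e-3

#' Apparent pKa from an anionic population at known pH
#'
#' Henderson-Hasselbalch applied to the two-state wobble/anion equilibrium:
#' `pKa_app = pH - log10(p_anion / (1 - p_anion))`.
#'
#' @param pH solution pH.
#' @param p_anion anionic-state fraction, strictly inside (0, 1).
#' @return Apparent pKa (dimensionless).
#' @export
#' @examples
#' pka_from_population(8.31, 0.2)   # 8.912
pka_from_population <- function(pH, p_anion) {
  stopifnot(is.numeric(pH), is.numeric(p_anion))
  if (any(p_anion <= 0 | p_anion >= 1)) {
    stop("p_anion must lie strictly inside (0, 1); a value of 0 or 1 ",
         "signals an out-of-range titration point")
  }
  pH - log10(p_anion / (1 - p_anion))
}

#' Anionic population at a given pH from the apparent pKa
#'
#' Inverse Henderson-Hasselbalch: `p = 1 / (1 + 10^(pKa - pH))`.
#'
#' @param pKa_app apparent pKa.
#' @param pH solution pH.
#' @return Anionic fraction in (0, 1).
#' @export
population_at_pH <- function(pKa_app, pH) {
  stopifnot(is.finite(pKa_app), is.finite(pH))
  1 / (1 + 10^(pKa_app - pH))
}

#' Aggregate per-pH pKa estimates into one record
#'
#' Per-point apparent pKa values (each derived from populations at one pH)
#' are pooled by inverse-variance weighting; with unit/unknown sigmas this
#' reduces to the plain mean.
#'
#' @param pka numeric vector of per-point pKa values.
#' @param sigma per-point SDs (same length); `NULL` for equal weights.
#' @param context optional context label.
#' @return List (class `"pka_record"`) with `pKa_app`, `sigma`,
#'   `n_points`, `context`.
#' @export
aggregate_pka <- function(pka, sigma = NULL, context = NA_character_) {
  pka <- pka[is.finite(pka)]
  if (length(pka) == 0L) stop("no usable titration points")
  if (is.null(sigma)) sigma <- rep(1, length(pka))
  stopifnot(length(sigma) == length(pka), all(sigma > 0))
  w <- 1 / sigma^2
  est <- sum(w * pka) / sum(w)
  structure(
    list(pKa_app = est, sigma = sqrt(1 / sum(w)), n_points = length(pka),
         context = context),
    class = "pka_record")
}

#' @export
print.pka_record <- function(x, ...) {
  cat(sprintf("pKa_app = %.3f +/- %.3f (%d point%s%s)\n", x$pKa_app, x$sigma,
              x$n_points, if (x$n_points > 1L) "s" else "",
              if (is.na(x$context)) "" else paste0(", context ", x$context)))
  invisible(x)
}

#' Conformational free energy from the apparent pKa
#'
#' Two-state free energy of forming the anionic state at a given pH:
#' `dG = R T ln(10) (pKa - pH)` in kcal/mol, positive when the anion is the
#' minor species (pKa > pH).
#'
#' @param pKa_app apparent pKa.
#' @param pH solution pH.
#' @param T_kelvin absolute temperature; defaults to 274.15 K (1 degree C,
#'   the titration temperature).
#' @return Free energy in kcal/mol.
#' @export
free_energy <- function(pKa_app, pH, T_kelvin = 274.15) {
  stopifnot(all(T_kelvin > 0))
  R_KCAL * T_kelvin * log(10) * (pKa_app - pH)
}

#' Per-context differences relative to a reference context
#'
#' `delta(seq) = value(seq) - value(ref)`; the reference delta is exactly 0.
#' Uncertainties combine in quadrature (the reference keeps its own sigma as
#' the comparison baseline uncertainty, but its delta sigma is reported as
#' the quadrature sum like every other row for consistency).
#'
#' @param values named numeric vector (names = context labels).
#' @param reference reference context label, present in `names(values)`.
#' @param sigma optional named SDs.
#' @return data.frame with columns `context`, `delta`, `sigma`.
#' @export
delta_table <- function(values, reference, sigma = NULL) {
  stopifnot(!is.null(names(values)))
  if (!reference %in% names(values)) {
    stop("reference context '", reference, "' not found")
  }
  d <- values - values[[reference]]
  s <- rep(NA_real_, length(values))
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(values))
    if (is.null(names(sigma))) names(sigma) <- names(values)
    s <- sqrt(sigma^2 + sigma[[reference]]^2)
    s[names(values) == reference] <- 0
  }
  data.frame(context = names(values), delta = as.numeric(d), sigma = s,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Enumerate all nearest-neighbour additivity (mutational) cycles
#'
#' For a full 4x4 table of per-context values `f(Z, W)` (Z = 5' neighbour,
#' W = 3' neighbour) every rectangle `{Z, Z'} x {W, W'}` defines two cycles,
#' one per diagonal orientation: reference `(Z, W)` -> double mutant
#' `(Z', W')` via singles `(Z', W)` and `(Z, W')`.  6 x 6 rectangles x 2
#' orientations = 72 cycles.  For each, the predicted double perturbation is
#' the sum of the single perturbations and the deviation is
#' `observed - predicted`.
#'
#' @param values named numeric vector of 16 per-context values (names
#'   `"ZTW"` as in [triplet_contexts()]).
#' @return data.frame of 72 rows: `reference`, `double`, `single5`,
#'   `single3`, `predicted`, `observed`, `deviation`.
#' @export
enumerate_additivity_cycles <- function(values) {
  ctx <- triplet_contexts()
  if (is.null(names(values)) || !all(ctx %in% names(values)) ||
      any(!is.finite(values[ctx]))) {
    stop("a full, finite 16-context table is required")
  }
  f <- function(z, w) values[[paste0(z, "T", w)]]
  rows <- vector("list", 72L)
  k <- 0L
  for (zi in 1:3) for (zj in (zi + 1):4) {
    for (wi in 1:3) for (wj in (wi + 1):4) {
      for (o in 1:2) {
        if (o == 1L) { z <- BASES[zi]; z2 <- BASES[zj] }
        else         { z <- BASES[zj]; z2 <- BASES[zi] }
        w <- BASES[wi]; w2 <- BASES[wj]
        pred <- (f(z2, w) - f(z, w)) + (f(z, w2) - f(z, w))
        obs  <- f(z2, w2) - f(z, w)
        k <- k + 1L
        rows[[k]] <- data.frame(
          reference = paste0(z, "T", w), double = paste0(z2, "T", w2),
          single5 = paste0(z2, "T", w), single3 = paste0(z, "T", w2),
          predicted = pred, observed = obs, deviation = obs - pred,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize additivity cycles
#'
#' Ordinary least squares of observed vs predicted double-mutant
#' perturbations, plus the root-mean-square deviation from perfect
#' additivity.
#'
#' @param cycles output of [enumerate_additivity_cycles()].
#' @return List with `rmsd`, `pearson_r`, `slope`, `intercept`, `n`.
#' @export
additivity_summary <- function(cycles) {
  stopifnot(is.data.frame(cycles), nrow(cycles) >= 3L)
  x <- cycles$predicted
  y <- cycles$observed
  if (stats::var(x) <= 0) stop("degenerate predicted values (zero variance)")
  fit <- stats::lm(y ~ x)
  list(
    rmsd = sqrt(mean(cycles$deviation^2)),
    pearson_r = stats::cor(x, y),
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    n = nrow(cycles))
}

#' Exact two-sided Wilcoxon rank-sum partition test
#'
#' Tests whether per-context values partition by a grouping (by default the
#' 3' neighbour: purine vs pyrimidine) using the exact permutation
#' distribution of the rank-sum statistic — every `choose(n, n1)` relabelling
#' is enumerated, so no normal approximation is used even with ties
#' (mid-ranks).
#'
#' @param values named numeric vector of per-context values.
#' @param group logical/2-level vector aligned with `values`; if `NULL`,
#'   contexts are grouped by purine (A/G) vs pyrimidine (C/T) 3' neighbour.
#' @return List with `p_value`, `statistic` (rank sum of group 1), `n1`,
#'   `n2`.
#' @export
partition_test <- function(values, group = NULL) {
  if (is.null(group)) {
    stopifnot(!is.null(names(values)))
    group <- substr(names(values), 3L, 3L) %in% c("A", "G")
  }
  group <- as.logical(group)
  stopifnot(length(group) == length(values), !any(is.na(group)))
  n <- length(values)
  n1 <- sum(group)
  if (n1 == 0L || n1 == n) stop("both groups must be non-empty")
  r <- rank(values)            # mid-ranks under ties
  W <- sum(r[group])
  mu <- n1 * (n + 1) / 2
  combs <- utils::combn(n, n1)
  sums <- colSums(matrix(r[combs], nrow = n1))
  p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-12)
  list(p_value = p, statistic = W, n1 = n1, n2 = n - n1)
}

#' Compare two conformational fingerprints by linear regression
#'
#' Ordinary least squares of `y` on `x` over the shared contexts, with 95%
#' confidence intervals on slope and intercept, plus the RMSD about the
#' identity line `y = x` (the quantity of interest when both fingerprints
#' should measure the same energetics).
#'
#' @param x,y named numeric vectors of per-context values (e.g. ddG in
#'   kcal/mol); only shared finite contexts are used.
#' @return List with `rmsd` (about y = x), `pearson_r`, `slope`,
#'   `intercept`, `ci_slope`, `ci_intercept`, `n`, `contexts`.
#' @export
compare_fingerprints <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    shared <- intersect(names(x), names(y))
    x <- x[shared]; y <- y[shared]
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("at least 3 shared contexts are required")
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit, level = 0.95)
  list(
    rmsd = sqrt(mean((y - x)^2)),
    pearson_r = stats::cor(x, y),
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    ci_slope = unname(ci[2L, ]),
    ci_intercept = unname(ci[1L, ]),
    n = length(x),
    contexts = names(x))
}

#' Read and write per-context tables
#'
#' Per-context CSV files have columns `context`, `value` and optionally
#' `sigma` — the exchange format for pKa, ddG and propensity tables.
#'
#' @param path file path.
#' @return `read_context_table`: named numeric vector (context names), with
#'   a `"sigma"` attribute when the column is present.
#' @export
read_context_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("context", "value") %in% names(d)))
  v <- stats::setNames(as.numeric(d$value), d$context)
  if ("sigma" %in% names(d)) {
    attr(v, "sigma") <- stats::setNames(as.numeric(d$sigma), d$context)
  }
  v
}

#' @param values named numeric vector.
#' @param sigma optional named SDs.
#' @rdname read_context_table
#' @export
write_context_table <- function(values, path, sigma = NULL) {
  stopifnot(!is.null(names(values)))
  d <- data.frame(context = names(values), value = as.numeric(values))
  if (!is.null(sigma)) d$sigma <- as.numeric(sigma)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' De-shearing free-energy decomposition from melting data
#'
#' Isolates the neutral de-shearing penalty of the wobble-to-WC transition
#' as the per-context difference of duplex-destabilization energies,
#' `ddG_deshear = ddG_melt(G-T) - ddG_melt(G-C)`, using the G-C duplex as
#' the Watson-Crick proxy.  Uncertainties combine in quadrature.
#'
#' @param ddG_GT named vector of G-T duplex ddG_melt values (kcal/mol).
#' @param ddG_GC named vector of G-C duplex ddG_melt values, same contexts.
#' @param sigma_GT,sigma_GC optional SDs.
#' @return data.frame with `context`, `ddG_deshear`, `sigma`.
#' @export
deshear_decomposition <- function(ddG_GT, ddG_GC,
                                  sigma_GT = NULL, sigma_GC = NULL) {
  if (is.null(names(ddG_GT)) || is.null(names(ddG_GC)) ||
      !setequal(names(ddG_GT), names(ddG_GC))) {
    stop("ddG_GT and ddG_GC must carry matching context names")
  }
  ctx <- names(ddG_GT)
  d <- ddG_GT[ctx] - ddG_GC[ctx]
  s <- rep(NA_real_, length(ctx))
  if (!is.null(sigma_GT) && !is.null(sigma_GC)) {
    s <- sqrt(sigma_GT[ctx]^2 + sigma_GC[ctx]^2)
  }
  data.frame(context = ctx, ddG_deshear = as.numeric(d), sigma = as.numeric(s),
             row.names = NULL, stringsAsFactors = FALSE)
}
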