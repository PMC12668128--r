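#' Build a conformational fingerprint
#'
#' Normalizes per-context propensities of a rare DNA state into a
#' probability vector over the available trinucleotide contexts.  For the
#' anionic G•T⁻ state, propensities are populations at a reference pH
#' computed from apparent pKa values via [population_at_pH()].  Missing
#' contexts are recorded and omitted — never imputed.
#'
#' @param x named numeric vector: either raw propensities, or apparent pKa
#'   values if `from = "pka"`.
#' @param state rare-state name (see [state_substitution_map()]), stored as
#'   metadata.
#' @param from `"propensity"` (default) or `"pka"`.
#' @param reference_pH pH at which pKa values are converted to populations
#'   (default 7.4).
#' @return Object of class `"fingerprint"`: named probability vector
#'   attribute-tagged with `state`, `reference_pH` and `missing` contexts.
#' @export
#' @examples
#' fp <- make_fingerprint(c(CTC = 7.9, GTA = 9.7), state = "GT_anion",
#'                        from = "pka")
make_fingerprint <- function(x, state = "GT_anion",
                             from = c("propensity", "pka"),
                             reference_pH = 7.4) {
  from <- match.arg(from)
  stopifnot(!is.null(names(x)))
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("at least 2 contexts with finite values required")
  prop <- if (from == "pka") {
    vapply(x, population_at_pH, numeric(1), pH = reference_pH)
  } else {
    if (any(x < 0)) stop("propensities must be non-negative")
    x
  }
  if (sum(prop) <= 0) stop("all propensities are zero")
  p <- prop / sum(prop)
  structure(p, class = "fingerprint", state = state,
            reference_pH = if (from == "pka") reference_pH else NA_real_,
            missing = setdiff(triplet_contexts(), names(p)))
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("Conformational fingerprint '%s' over %d contexts\n",
              attr(x, "state"), length(x)))
  miss <- attr(x, "missing")
  if (length(miss)) cat("  missing contexts:", paste(miss, collapse = " "), "\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Read a COSMIC-dialect SBS96 signature matrix
#'
#' Tab-separated file with a `Type` column of channel labels (`"A[C>A]A"`)
#' and one probability column per signature.  Rows are canonicalized to the
#' order of [sbs96_channels()]; columns must sum to 1 within `tol`.
#'
#' @param path file path.
#' @param tol column-sum tolerance (default 1e-3).
#' @return Numeric matrix, 96 rows (rownames = channels), one column per
#'   signature.
#' @export
read_signatures <- function(path, tol = 1e-3) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  type_col <- which(tolower(names(d)) %in% c("type", "mutationtype",
                                             "mutation type"))[1L]
  if (is.na(type_col)) stop("no 'Type' column found in ", path)
  chan <- sbs96_channels()
  if (nrow(d) != 96L || !setequal(d[[type_col]], chan)) {
    stop("expected exactly the 96 SBS96 channels; got ", nrow(d), " rows")
  }
  m <- as.matrix(d[, -type_col, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- d[[type_col]]
  m <- m[chan, , drop = FALSE]
  validate_signature_matrix(m, tol = tol)
  m
}

#' Validate an SBS96 signature matrix
#'
#' @param m numeric matrix with 96 rows named by [sbs96_channels()].
#' @param tol column-sum tolerance.
#' @return The matrix, invisibly; stops with a report on violation.
#' @export
validate_signature_matrix <- function(m, tol = 1e-3) {
  if (nrow(m) != 96L || !identical(rownames(m), sbs96_channels())) {
    stop("matrix must have exactly 96 rows in canonical channel order")
  }
  if (any(m < 0)) stop("signature probabilities must be non-negative")
  cs <- colSums(m)
  bad <- which(abs(cs - 1) > tol)
  if (length(bad)) {
    stop("signature column(s) not normalized: ",
         paste(sprintf("%s (sum %.4f)", colnames(m)[bad], cs[bad]),
               collapse = ", "))
  }
  invisible(m)
}

#' Write a signature matrix in COSMIC SBS96 dialect
#'
#' @param m matrix as returned by [read_signatures()].
#' @param path output path.
#' @export
write_signatures <- function(m, path) {
  validate_signature_matrix(m)
  # 17 significant digits so probabilities survive a write/read round trip
  chr <- apply(m, 2L, function(col) sprintf("%.17g", col))
  out <- data.frame(Type = rownames(m), chr, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract and renormalize one substitution channel of a signature
#'
#' Pulls the 16 trinucleotide-context probabilities of `substitution` from
#' one signature column, restricts them to `contexts` (the fingerprint's
#' available contexts, named by the central pyrimidine of the substitution)
#' and renormalizes to sum 1.
#'
#' @param m signature matrix.
#' @param signature column name or index.
#' @param substitution one of [substitution_classes()].
#' @param contexts character vector of context labels to keep; `NULL` keeps
#'   all 16.  Labels may be written with any central base (e.g. `"ATA"`
#'   for a `C>T` channel): only the flanking bases are matched.
#' @return Named probability vector over the kept contexts (original
#'   labels preserved).
#' @export
extract_channel <- function(m, signature, substitution, contexts = NULL) {
  substitution <- match.arg(substitution, substitution_classes())
  if (is.character(signature) && !signature %in% colnames(m)) {
    stop("signature '", signature, "' not present")
  }
  chan_ctx <- substitution_contexts(substitution)
  chan <- paste0(substr(chan_ctx, 1L, 1L), "[", substitution, "]",
                 substr(chan_ctx, 3L, 3L))
  v <- m[chan, signature]
  names(v) <- chan_ctx
  if (!is.null(contexts)) {
    key <- paste0(substr(contexts, 1L, 1L), substr(contexts, 3L, 3L))
    have <- paste0(substr(chan_ctx, 1L, 1L), substr(chan_ctx, 3L, 3L))
    idx <- match(key, have)
    if (anyNA(idx)) stop("unrecognized context label(s)")
    v <- v[idx]
    names(v) <- contexts
  }
  if (sum(v) <= 0) {
    stop("channel ", substitution, " of signature '", signature,
         "' has zero mass over the requested contexts")
  }
  v / sum(v)
}

#' Jensen-Shannon divergence (base 2)
#'
#' `JSD(P, Q) = H(M) - (H(P) + H(Q)) / 2` with `M = (P + Q)/2` and Shannon
#' entropy in bits, so the divergence lies in [0, 1]: 0 for identical
#' distributions, 1 for disjoint point masses.  `0 log 0` is taken as 0.
#'
#' @param p,q probability vectors on the same support, each summing to 1
#'   within `tol`.
#' @param tol normalization tolerance (default 1e-9).
#' @return JSD in [0, 1].
#' @export
#' @examples
#' jsd(c(0.5, 0.5), c(1, 0))   # 0.3113
jsd <- function(p, q, tol = 1e-9) {
  stopifnot(length(p) == length(q))
  if (abs(sum(p) - 1) > tol || abs(sum(q) - 1) > tol) {
    stop("inputs must each sum to 1 within ", tol)
  }
  if (any(p < 0) || any(q < 0)) stop("probabilities must be non-negative")
  h <- function(v) {
    v <- v[v > 0]
    -sum(v * log2(v))
  }
  m <- (p + q) / 2
  h(m) - (h(p) + h(q)) / 2
}

#' Null JSD distribution by pooled resampling
#'
#' Draws `n_contexts` values i.i.d. from the pooled multiset of all channel
#' probabilities (all signatures x all 96 channels), renormalizes each draw
#' to a probability vector, and computes its JSD against the fingerprint.
#' Draws whose values are all zero are redrawn (counted).
#'
#' @param m signature matrix (pool source).
#' @param fingerprint a [make_fingerprint()] vector (its length fixes
#'   `n_contexts`).
#' @param n_draws number of null draws (default 1e6).
#' @param seed integer seed.
#' @return Object of class `"jsd_null"`: list with `samples` (numeric
#'   vector), `n_redraws`, `n_contexts`.
#' @export
null_distribution <- function(m, fingerprint, n_draws = 1e6, seed = 1) {
  pool <- as.numeric(m)
  if (length(pool) == 0L) stop("empty probability pool")
  k <- length(fingerprint)
  fp <- as.numeric(fingerprint)
  out <- numeric(n_draws)
  n_redraws <- 0L
  chunk <- 20000L
  withr::with_seed(seed, {
    done <- 0L
    while (done < n_draws) {
      nb <- min(chunk, n_draws - done)
      X <- matrix(sample(pool, nb * k, replace = TRUE), nrow = nb)
      rs <- rowSums(X)
      bad <- which(rs == 0)
      while (length(bad)) {
        n_redraws <- n_redraws + length(bad)
        X[bad, ] <- sample(pool, length(bad) * k, replace = TRUE)
        rs[bad] <- rowSums(X[bad, , drop = FALSE])
        bad <- bad[rs[bad] == 0]
      }
      P <- X / rs
      # vectorized JSD of each row against fp
      M <- (P + matrix(fp, nb, k, byrow = TRUE)) / 2
      hM <- -rowSums(ifelse(M > 0, M * log2(M), 0))
      hP <- -rowSums(ifelse(P > 0, P * log2(P), 0))
      hQ <- -sum(ifelse(fp > 0, fp * log2(fp), 0))
      out[(done + 1L):(done + nb)] <- hM - (hP + hQ) / 2
      done <- done + nb
    }
  })
  structure(list(samples = out, n_redraws = n_redraws, n_contexts = k),
            class = "jsd_null")
}

#' @export
print.jsd_null <- function(x, ...) {
  cat(sprintf("Null JSD distribution: %d draws over %d contexts (median %.3f)\n",
              length(x$samples), x$n_contexts, stats::median(x$samples)))
  invisible(x)
}

#' Left-tail empirical p-value with add-one correction
#'
#' Small JSD means high similarity, so the p-value is the left-tail mass:
#' `p = (1 + #{null <= observed}) / (1 + n_draws)`.
#'
#' @param observed_jsd observed JSD value(s).
#' @param null a `"jsd_null"` or numeric vector of null samples.
#' @return p-value(s) in (0, 1].
#' @export
p_value <- function(observed_jsd, null) {
  s <- if (inherits(null, "jsd_null")) null$samples else as.numeric(null)
  if (length(s) == 0L) stop("need at least one null sample")
  vapply(observed_jsd, function(o) (1 + sum(s <= o)) / (1 + length(s)),
         numeric(1))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up q-values across all tested (signature, substitution) pairs.
#'
#' @param p numeric vector of p-values.
#' @return q-values, same length, monotone and <= 1.
#' @export
fdr <- function(p) {
  stopifnot(length(p) >= 1L)
  stats::p.adjust(p, method = "BH")
}

#' Scan a fingerprint against every signature and substitution class
#'
#' Computes one JSD + p-value per (signature, substitution) pair over the
#' fingerprint's available contexts, with a single pooled null (the null
#' depends only on the fingerprint and pool, not on the pair), then BH FDR
#' across the scan.  Pairs whose channel has zero mass over the contexts
#' are skipped with a reason.  Strong similarity requires
#' `JSD <= 0.090` with `p < 0.05` and `FDR < 0.05`.
#'
#' @param m signature matrix.
#' @param fingerprint a [make_fingerprint()].
#' @param substitutions substitution classes to scan; defaults to
#'   [state_substitution_map()] of the fingerprint's state.
#' @param n_draws null draws (default 1e6).
#' @param seed integer seed.
#' @param jsd_strong,alpha strong-similarity thresholds (0.090 and 0.05).
#' @return Object of class `"fp_scan"`: data.frame sorted ascending by JSD
#'   with columns `signature`, `substitution`, `jsd`, `p_value`, `fdr`,
#'   `n_contexts`, `strong`; skipped pairs in `attr(, "skipped")`.
#' @export
scan_all <- function(m, fingerprint, substitutions = NULL,
                     n_draws = 1e6, seed = 1,
                     jsd_strong = 0.090, alpha = 0.05) {
  validate_signature_matrix(m)
  stopifnot(inherits(fingerprint, "fingerprint"))
  if (is.null(substitutions)) {
    substitutions <- state_substitution_map(attr(fingerprint, "state"))
  }
  if (length(substitutions) == 0L) {
    out <- data.frame(signature = character(0), substitution = character(0),
                      jsd = numeric(0), p_value = numeric(0),
                      fdr = numeric(0), n_contexts = integer(0),
                      strong = logical(0))
    return(structure(out, class = c("fp_scan", "data.frame"),
                     skipped = data.frame()))
  }
  nul <- null_distribution(m, fingerprint, n_draws = n_draws, seed = seed)
  ctx <- names(fingerprint)
  rows <- list()
  skipped <- list()
  for (sub in substitutions) {
    for (sig in colnames(m)) {
      ch <- tryCatch(extract_channel(m, sig, sub, contexts = ctx),
                     error = function(e) e)
      if (inherits(ch, "error")) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(signature = sig, substitution = sub,
                     reason = conditionMessage(ch))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        signature = sig, substitution = sub,
        jsd = jsd(as.numeric(fingerprint), as.numeric(ch)),
        n_contexts = length(ctx), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_value <- p_value(out$jsd, nul)
  out$fdr <- fdr(out$p_value)
  out$strong <- out$jsd <= jsd_strong & out$p_value < alpha & out$fdr < alpha
  out <- out[order(out$jsd), c("signature", "substitution", "jsd", "p_value",
                               "fdr", "n_contexts", "strong")]
  rownames(out) <- NULL
  structure(out, class = c("fp_scan", "data.frame"),
            skipped = if (length(skipped)) do.call(rbind, skipped)
                      else data.frame(),
            null = nul)
}

#' @export
print.fp_scan <- function(x, n = 10L, ...) {
  cat(sprintf("Fingerprint scan: %d (signature, substitution) pairs, %d strong\n",
              nrow(x), sum(x$strong)))
  print.data.frame(utils::head(x, n), digits = 4)
  sk <- attr(x, "skipped")
  if (!is.null(sk) && nrow(sk)) cat(sprintf("  (%d pairs skipped)\n", nrow(sk)))
  invisible(x)
}

#' Write scan results as CSV
#'
#' @param x an `"fp_scan"`.
#' @param path output path.
#' @export
write_scan <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
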