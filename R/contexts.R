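#' Trinucleotide sequence contexts
#'
#' The sixteen `ZTW` triplet contexts formed by the four possible 5'
#' neighbours (Z) and four possible 3' neighbours (W) flanking a central
#' position (the mismatched or mutated pyrimidine).  Context labels are
#' ordered 5'-base major, i.e. `ATA, ATC, ATG, ATT, CTA, ...`.
#'
#' @param central single character placed between the flanking bases
#'   (default `"T"`).
#' @return Character vector of 16 context labels.
#' @export
#' @examples
#' triplet_contexts()
triplet_contexts <- function(central = "T") {
  stopifnot(is.character(central), length(central) == 1L, nchar(central) == 1L)
  bases <- c("A", "C", "G", "T")
  as.vector(t(outer(bases, bases, function(z, w) paste0(z, central, w))))
}

BASES <- c("A", "C", "G", "T")

#' Split context labels into flanking bases
#'
#' @param context character vector of 3-letter context labels, e.g. `"CTA"`.
#' @return data.frame with columns `five_prime`, `central`, `three_prime`.
#' @export
split_context <- function(context) {
  stopifnot(is.character(context), all(nchar(context) == 3L))
  data.frame(
    five_prime  = substr(context, 1L, 1L),
    central     = substr(context, 2L, 2L),
    three_prime = substr(context, 3L, 3L),
    row.names   = context,
    stringsAsFactors = FALSE
  )
}

#' The six pyrimidine-centric substitution classes
#'
#' @return Character vector `c("C>A","C>G","C>T","T>A","T>C","T>G")`.
#' @export
substitution_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' Canonical SBS96 channel labels
#'
#' Channels are ordered by substitution class (`C>A` first), then 5' flank,
#' then 3' flank, alphabetically — the standard COSMIC dialect, e.g.
#' `"A[C>A]A"`.
#'
#' @return Character vector of 96 channel labels.
#' @export
sbs96_channels <- function() {
  out <- character(0)
  for (sub in substitution_classes()) {
    for (z in BASES) for (w in BASES) {
      out <- c(out, paste0(z, "[", sub, "]", w))
    }
  }
  out
}

#' Contexts of one substitution class, in channel order
#'
#' @param substitution one of [substitution_classes()].
#' @return 16 context labels `ZxW` where `x` is the mutated pyrimidine.
#' @export
substitution_contexts <- function(substitution) {
  substitution <- match.arg(substitution, substitution_classes())
  pyr <- substr(substitution, 1L, 1L)
  as.vector(t(outer(BASES, BASES, function(z, w) paste0(z, pyr, w))))
}

# registry of rare-state -> plausible substitution classes
.state_registry <- list(
  GT_anion     = c("C>T", "T>C"),
  AT_hoogsteen = c("T>A", "T>C", "T>G"),
  GC_hoogsteen = c("C>A", "C>T", "C>G"),
  AT_open      = c("T>A", "T>G")
)

#' Substitution classes mechanistically linked to a rare DNA state
#'
#' Maps a rare conformational state to the base-substitution classes it can
#' plausibly drive: the Watson-Crick-like anionic G•T⁻ mispair can escape
#' proofreading/repair to give C>T or T>C; the A(syn)-T Hoogsteen pair
#' exposes adenine to alkylation whose lesions yield T>A, T>C or T>G via
#' translesion synthesis; G(syn)-C⁺ Hoogsteen analogously yields C>A, C>T or
#' C>G; the A-T base-opened state is an intermediate for T>A and T>G.
#'
#' @param state one of `"GT_anion"`, `"AT_hoogsteen"`, `"GC_hoogsteen"`,
#'   `"AT_open"`.
#' @return Character vector of substitution classes.
#' @export
#' @examples
#' state_substitution_map("GT_anion")
state_substitution_map <- function(state) {
  stopifnot(is.character(state), length(state) == 1L)
  if (!state %in% names(.state_registry)) {
    stop("unknown rare-state name: '", state, "'; known states: ",
         paste(names(.state_registry), collapse = ", "))
  }
  .state_registry[[state]]
}
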