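#' @useDynLib respiromap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# 20-letter amino-acid alphabet, alphabetical; X is scored as background.
AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Robinson & Robinson amino-acid background frequencies (the BLOSUM62 null),
# renormalised to sum to exactly 1.
.RR_FREQS <- c(
  A = 0.0787, C = 0.0192, D = 0.0542, E = 0.0594, F = 0.0386,
  G = 0.0723, H = 0.0219, I = 0.0526, K = 0.0580, L = 0.0896,
  M = 0.0216, N = 0.0409, P = 0.0484, Q = 0.0367, R = 0.0551,
  S = 0.0714, T = 0.0567, V = 0.0660, W = 0.0125, Y = 0.0311
)

#' Background amino-acid frequencies
#'
#' The i.i.d. null model used throughout: profile log-odds scores, decoy
#' generation and E-value calibration all measure departure from this
#' composition (Robinson--Robinson frequencies, renormalised).
#'
#' @return Named numeric vector of length 20 (alphabetical amino-acid order),
#'   summing to 1.
#' @examples
#' sum(backgroundFrequencies())
#' @export
backgroundFrequencies <- function() {
  f <- .RR_FREQS[AA_ALPHABET20]
  f / sum(f)
}

#' The 13-gene respiratory marker panel
#'
#' Representative genes indicative of each pathway or complex: classical
#' naphthoquinone (NQ) biosynthesis (menB, menC, menF), the futalosine NQ
#' route (mqnA, mqnC, mqnD), ubiquinone (UQ) biosynthesis (ubiA, ubiC, ubiG),
#' NDH-1 subunits (nuoA, nuoE, nuoJ) and NDH-2 (ndh).
#'
#' @return Character vector of the 13 marker gene names.
#' @examples
#' markerPanel()
#' @export
markerPanel <- function() {
  c("menB", "menC", "menF", "mqnA", "mqnC", "mqnD",
    "ubiA", "ubiC", "ubiG", "nuoA", "nuoE", "nuoJ", "ndh")
}

# Typical E. coli protein lengths for each marker, used as synthetic family
# master lengths so bit-score magnitudes are realistic.
MARKER_LENGTHS <- c(
  menB = 285, menC = 320, menF = 431, mqnA = 270, mqnC = 380, mqnD = 270,
  ubiA = 290, ubiC = 165, ubiG = 240, nuoA = 147, nuoE = 166, nuoJ = 184,
  ndh = 434
)

# Map a residue character vector to 0-based codes (X and unknowns -> 20).
.aa_codes <- function(chars) {
  idx <- match(chars, AA_ALPHABET20)
  idx[is.na(idx)] <- 21L
  idx - 1L
}
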