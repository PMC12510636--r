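# Pack a ProfileHMM into the flat list consumed by the C++ kernels.
.pack_profile <- function(profile) {
  tr <- profile@transitions
  list(me = unname(profile@matchEmissions),
       ie = unname(profile@insertEmissions),
       null = unname(profile@nullModel),
       mm = tr$mm, mi = tr$mi, md = tr$md, im = tr$im, ii = tr$ii,
       dm = tr$dm, dd = tr$dd, bm = tr$bm, bd = tr$bd)
}

.seq_to_codes <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (methods::is(seqs, "XString")) seqs <- as.character(seqs)
  if (!is.character(seqs)) stop("sequences must be character or AAStringSet")
  if (any(nchar(seqs) == 0L)) stop("sequences must be non-empty")
  chars <- strsplit(toupper(seqs), "")
  bad <- vapply(chars, function(ch) any(!ch %in% c(AA_ALPHABET20, "X")),
                logical(1))
  if (any(bad))
    stop("sequence contains residues outside the amino-acid alphabet (X allowed)")
  lapply(chars, .aa_codes)
}

#' Forward bit score of sequences against a profile
#'
#' The full forward log-odds score: log2 of the total probability of the
#' sequence under the profile (summed over all alignments) divided by its
#' probability under the i.i.d. background null. The profile is traversed
#' begin-to-end (glocal mode); sequence outside the modelled region is
#' absorbed by flanking states whose self-loop probability is
#' length-calibrated to `n/(n+2)` unless `eta` is given.
#'
#' @param profile A [ProfileHMM-class].
#' @param seqs Character vector or `AAStringSet` of protein sequences
#'   (residues over the 20-letter alphabet; `X` is scored as background).
#' @param eta Optional flank self-loop probability in `[0,1)`; the default
#'   `NULL` uses the length-calibrated value per sequence.
#' @return Numeric vector of bit scores (one per sequence); `-Inf` when a
#'   sequence has zero probability under the profile (possible only with
#'   zero pseudocounts).
#' @seealso [viterbiBits()], [calibrateEvalue()]
#' @export
forwardBits <- function(profile, seqs, eta = NULL) {
  stopifnot(methods::is(profile, "ProfileHMM"))
  codes <- .seq_to_codes(seqs)
  e <- if (is.null(eta)) -1 else eta
  if (!is.null(eta) && (any(eta < 0) || any(eta >= 1)))
    stop("eta must be in [0, 1)")
  out <- cpp_forward_batch(.pack_profile(profile), codes, as.numeric(e))
  names(out) <- names(seqs)
  out
}

#' Viterbi bit score and best alignment path
#'
#' Like [forwardBits()] but maximising over state paths instead of summing;
#' the bit score of the single best alignment. For one sequence the argmax
#' path is returned alongside the score.
#'
#' @inheritParams forwardBits
#' @param withPath If `TRUE` (and a single sequence), also return the state
#'   path as a character vector (`"N"`, `"M3"`, `"I2"`, `"D5"`, `"C"`, ...).
#' @return If `withPath` is `FALSE`, a numeric vector of Viterbi bit scores;
#'   otherwise a list with elements `bits` and `path`.
#' @export
viterbiBits <- function(profile, seqs, eta = NULL, withPath = FALSE) {
  stopifnot(methods::is(profile, "ProfileHMM"))
  codes <- .seq_to_codes(seqs)
  e <- if (is.null(eta)) -1 else eta
  if (!is.null(eta) && (any(eta < 0) || any(eta >= 1)))
    stop("eta must be in [0, 1)")
  if (withPath) {
    if (length(codes) != 1L)
      stop("withPath = TRUE requires a single sequence")
    return(cpp_viterbi(.pack_profile(profile), codes[[1]], as.numeric(e)[1]))
  }
  out <- cpp_viterbi_batch(.pack_profile(profile), codes, as.numeric(e))
  names(out) <- names(seqs)
  out
}
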