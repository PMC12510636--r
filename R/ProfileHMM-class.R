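#' ProfileHMM: a position-specific probabilistic model of a protein family
#'
#' A glocal (global-in-model, local-in-sequence) profile hidden Markov model
#' with `L` match states, per-match emission distributions, a shared insert
#' emission distribution, affine match/insert/delete transition structure and
#' flanking states that absorb sequence outside the modelled region. Scores
#' are log2 odds (bits) against an i.i.d. background null. An optional
#' calibration slot holds a Gumbel fit of the null score distribution used to
#' convert bit scores to E-values.
#'
#' @slot name Character, typically the marker gene the profile models.
#' @slot matchEmissions L x 20 matrix; row k is the emission distribution of
#'   match state k over the amino-acid alphabet (rows sum to 1).
#' @slot insertEmissions Length-20 probability vector shared by all insert
#'   states.
#' @slot transitions Named list of numeric vectors `mm`, `mi`, `md`, `im`,
#'   `ii`, `dm`, `dd` (each length L) plus scalars `bm`, `bd`. Position L of
#'   `mm` and `dm` are the exits to the end state; `mi[L]`, `md[L]`, `ii[L]`,
#'   `im[L]`, `dd[L]` are structurally zero (no insert after the last match).
#' @slot nullModel Length-20 background frequency vector.
#' @slot calibration List with elements `mu`, `lambda`, `n_calibration`,
#'   `db_size` once [calibrateEvalue()] has been run; empty list before.
#'
#' @seealso [buildProfile()], [forwardBits()], [viterbiBits()],
#'   [calibrateEvalue()]
#' @export
setClass("ProfileHMM",
  representation(
    name = "character",
    matchEmissions = "matrix",
    insertEmissions = "numeric",
    transitions = "list",
    nullModel = "numeric",
    calibration = "list"
  ),
  prototype(calibration = list())
)

setValidity("ProfileHMM", function(object) {
  msgs <- character()
  L <- nrow(object@matchEmissions)
  if (L < 1L) msgs <- c(msgs, "profile must have at least one match state")
  if (ncol(object@matchEmissions) != 20L)
    msgs <- c(msgs, "matchEmissions must have 20 columns")
  if (any(abs(rowSums(object@matchEmissions) - 1) > 1e-9))
    msgs <- c(msgs, "every match emission row must sum to 1")
  if (length(object@insertEmissions) != 20L ||
      abs(sum(object@insertEmissions) - 1) > 1e-9)
    msgs <- c(msgs, "insertEmissions must be a 20-vector summing to 1")
  if (length(object@nullModel) != 20L || abs(sum(object@nullModel) - 1) > 1e-9)
    msgs <- c(msgs, "nullModel must be a 20-vector summing to 1")
  tr <- object@transitions
  need <- c("mm", "mi", "md", "im", "ii", "dm", "dd", "bm", "bd")
  if (!all(need %in% names(tr))) {
    msgs <- c(msgs, "transitions must contain mm, mi, md, im, ii, dm, dd, bm, bd")
  } else {
    for (v in c("mm", "mi", "md", "im", "ii", "dm", "dd"))
      if (length(tr[[v]]) != L)
        msgs <- c(msgs, sprintf("transitions$%s must have length L", v))
    if (length(msgs) == 0L) {
      if (any(abs(tr$mm + tr$mi + tr$md - 1) > 1e-9))
        msgs <- c(msgs, "match transition rows must sum to 1")
      if (L > 1L && any(abs(tr$im[-L] + tr$ii[-L] - 1) > 1e-9))
        msgs <- c(msgs, "insert transition rows must sum to 1")
      if (any(abs(tr$dm + tr$dd - 1) > 1e-9))
        msgs <- c(msgs, "delete transition rows must sum to 1")
      if (abs(tr$bm + tr$bd - 1) > 1e-9)
        msgs <- c(msgs, "begin transitions must sum to 1")
    }
  }
  if (length(object@calibration) > 0L) {
    cal <- object@calibration
    if (!all(c("mu", "lambda", "n_calibration", "db_size") %in% names(cal)))
      msgs <- c(msgs, "calibration must contain mu, lambda, n_calibration, db_size")
    else if (cal$lambda <= 0)
      msgs <- c(msgs, "calibration lambda must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ProfileHMM Number of match states.
#' @param x,object A `ProfileHMM`.
#' @export
profileLength <- function(x) nrow(x@matchEmissions)

#' @describeIn ProfileHMM Name of the modelled family.
#' @export
profileName <- function(x) x@name

#' @describeIn ProfileHMM Match emission matrix (L x 20).
#' @export
matchEmissions <- function(x) x@matchEmissions

#' @describeIn ProfileHMM Gumbel calibration parameters (empty list if the
#'   profile has not been calibrated).
#' @export
calibration <- function(x) x@calibration

#' @describeIn ProfileHMM `TRUE` once E-value calibration has been attached.
#' @export
isCalibrated <- function(x) length(x@calibration) > 0L

setMethod("show", "ProfileHMM", function(object) {
  cat(sprintf("ProfileHMM '%s': %d match states\n",
              object@name, profileLength(object)))
  if (isCalibrated(object)) {
    cal <- object@calibration
    cat(sprintf("  calibrated: Gumbel mu=%.3f lambda=%.4f (n=%d, db=%g)\n",
                cal$mu, cal$lambda, cal$n_calibration, cal$db_size))
  } else {
    cat("  not calibrated\n")
  }
  invisible(NULL)
})
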