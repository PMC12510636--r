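#' Binding enthalpy change from component docking energies
#'
#' `deltaH = e_complex - (e_protein + e_dna)`: the energy of the modelled
#' protein-DNA complex minus the sum of its unbound components. More
#' negative values indicate more favourable binding. Unit-agnostic and
#' exact in double precision; vectorised.
#'
#' @param eComplex,eProtein,eDna Finite numeric energies (any consistent
#'   unit).
#' @return `eComplex - (eProtein + eDna)`.
#' @examples
#' deltaH(-350, -200, -120)  # -30
#' @export
deltaH <- function(eComplex, eProtein, eDna) {
  if (any(!is.finite(c(eComplex, eProtein, eDna))))
    stop("all energies must be finite")
  eComplex - (eProtein + eDna)
}

#' Compare variant binding enthalpies against the wild type
#'
#' For every DNA box with both a wild-type and a variant record, computes
#' per-record deltaH, the difference `ddH = deltaH(variant) - deltaH(WT)`
#' and a qualitative call: `stronger` when ddH is below `-tolerance` (more
#' negative, more favourable binding), `weaker` above `+tolerance`,
#' `unchanged` within the tolerance band. Swapping which label is treated
#' as wild type flips the sign of ddH and the stronger/weaker calls.
#'
#' @param records data.frame with columns `variant`, `box`, `e_complex`,
#'   `e_protein`, `e_dna` (e.g. read from a docking-energy CSV).
#' @param wildtype Value of `variant` naming the reference (default
#'   `"WT"`).
#' @param tolerance Non-negative energy tolerance for the `unchanged` call.
#' @return data.frame with one row per (variant, box) pair other than the
#'   wild type: box, variant, delta_h, delta_h_wt, ddh, call.
#' @examples
#' recs <- data.frame(
#'   variant = c("WT", "WT", "mPdhR", "mPdhR"),
#'   box = c("ndh", "PDC", "ndh", "PDC"),
#'   e_complex = c(-350, -340, -330, -360),
#'   e_protein = c(-200, -200, -200, -200),
#'   e_dna = c(-120, -115, -120, -115))
#' compareVariants(recs, tolerance = 1)
#' @export
compareVariants <- function(records, wildtype = "WT", tolerance = 0) {
  need <- c("variant", "box", "e_complex", "e_protein", "e_dna")
  if (!all(need %in% names(records)))
    stop("records needs columns: ", paste(need, collapse = ", "))
  if (tolerance < 0) stop("tolerance must be >= 0")
  records$delta_h <- deltaH(records$e_complex, records$e_protein,
                            records$e_dna)
  wt <- records[records$variant == wildtype, , drop = FALSE]
  mut <- records[records$variant != wildtype, , drop = FALSE]
  if (nrow(mut) == 0L) stop("no non-wild-type records to compare")
  out <- lapply(seq_len(nrow(mut)), function(i) {
    b <- mut$box[i]
    wrow <- wt[wt$box == b, , drop = FALSE]
    if (nrow(wrow) == 0L)
      stop("missing wild-type counterpart for box '", b, "'")
    if (nrow(wrow) > 1L)
      stop("multiple wild-type records for box '", b, "'")
    ddh <- mut$delta_h[i] - wrow$delta_h[1]
    call <- if (abs(ddh) <= tolerance) "unchanged"
            else if (ddh < 0) "stronger" else "weaker"
    data.frame(box = b, variant = mut$variant[i],
               delta_h = mut$delta_h[i], delta_h_wt = wrow$delta_h[1],
               ddh = ddh, call = call, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Read a docking-energy table
#'
#' @param file CSV with columns `variant`, `box`, `e_complex`, `e_protein`,
#'   `e_dna`.
#' @return data.frame suitable for [compareVariants()].
#' @export
readDockingEnergies <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}
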