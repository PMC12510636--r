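# Default transition prior (pseudocount mass is spread in these proportions).
# Heavily favours match-to-match, as real protein families do.
.TRANS_PRIOR <- list(
  m = c(mm = 0.90, mi = 0.05, md = 0.05),
  i = c(im = 0.70, ii = 0.30),
  d = c(dm = 0.70, dd = 0.30),
  b = c(bm = 0.90, bd = 0.10)
)

.as_alignment_matrix <- function(alignment) {
  if (methods::is(alignment, "XStringSet")) alignment <- as.character(alignment)
  if (!is.character(alignment) || length(alignment) < 1L)
    stop("alignment must be a character vector or AAStringSet of aligned rows")
  if (length(unique(nchar(alignment))) != 1L)
    stop("alignment rows must all have the same length")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  m[m == "."] <- "-"
  m
}

#' Build a profile HMM from a multiple alignment
#'
#' Alignment columns whose gap fraction is below `gapFractionCutoff` become
#' match states; the remaining columns feed the shared insert state. Emission
#' and transition probabilities are maximum-likelihood counts regularised with
#' background-proportional pseudocounts (emissions) and a match-favouring
#' transition prior, both scaled by `pseudocount`.
#'
#' @param alignment Aligned rows: a gapped `AAStringSet` or character vector
#'   of equal-length strings (`-` or `.` for gaps).
#' @param pseudocount Non-negative pseudocount weight; 0 gives raw counts.
#' @param gapFractionCutoff Columns with gap fraction strictly below this
#'   value become match states (default 0.5).
#' @param name Profile name (defaults to `"profile"`).
#' @param background Null-model frequencies (default
#'   [backgroundFrequencies()]).
#' @return A [ProfileHMM-class] object (uncalibrated).
#' @examples
#' aln <- c("MKV-A", "MKVQA", "MRV-A")
#' p <- buildProfile(aln, name = "toy")
#' profileLength(p)
#' @export
buildProfile <- function(alignment, pseudocount = 1, gapFractionCutoff = 0.5,
                         name = "profile", background = backgroundFrequencies()) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  m <- .as_alignment_matrix(alignment)
  nseq <- nrow(m)
  gapfrac <- colMeans(m == "-")
  is_match <- gapfrac < gapFractionCutoff
  L <- sum(is_match)
  if (L == 0L)
    stop("no alignment column passes the gap-fraction cutoff; cannot build profile")
  bg <- background / sum(background)

  # Emissions: match columns individually, insert columns pooled.
  me <- matrix(0, nrow = L, ncol = 20L, dimnames = list(NULL, AA_ALPHABET20))
  match_cols <- which(is_match)
  for (k in seq_len(L)) {
    res <- m[, match_cols[k]]
    res <- res[res %in% AA_ALPHABET20]
    cnt <- table(factor(res, levels = AA_ALPHABET20))
    row <- as.numeric(cnt) + pseudocount * bg
    if (sum(row) == 0) row <- bg
    me[k, ] <- row / sum(row)
  }
  ins_res <- m[, !is_match, drop = FALSE]
  ins_res <- ins_res[ins_res %in% AA_ALPHABET20]
  icnt <- as.numeric(table(factor(ins_res, levels = AA_ALPHABET20)))
  ie <- icnt + max(pseudocount, if (length(ins_res) == 0L) 1 else 0) * bg
  if (sum(ie) == 0) ie <- bg
  ie <- ie / sum(ie)
  names(ie) <- AA_ALPHABET20

  # Transition counts from each row's implied state path.
  cmm <- cmi <- cmd <- cim <- cii <- cdm <- cdd <- numeric(L)
  cb <- c(bm = 0, bd = 0)
  state_of_col <- ifelse(is_match, "match", "insert")
  kindex <- cumsum(is_match)        # match-state index at/after each column
  for (r in seq_len(nseq)) {
    prev <- "B"; prevk <- 0L
    for (j in seq_len(ncol(m))) {
      ch <- m[r, j]
      if (state_of_col[j] == "insert") {
        if (ch == "-") next
        cur <- "I"; curk <- kindex[j]       # insert between match curk, curk+1
      } else {
        cur <- if (ch == "-") "D" else "M"
        curk <- kindex[j]
      }
      if (prev == "B") {
        if (cur == "M") cb["bm"] <- cb["bm"] + 1
        else if (cur == "D") cb["bd"] <- cb["bd"] + 1
        # an insert before the first match column is absorbed by the flank
        else next
      } else if (prev == "M") {
        if (cur == "M") cmm[prevk] <- cmm[prevk] + 1
        else if (cur == "I") cmi[prevk] <- cmi[prevk] + 1
        else cmd[prevk] <- cmd[prevk] + 1
      } else if (prev == "I") {
        if (cur == "M") cim[prevk] <- cim[prevk] + 1
        else if (cur == "I") cii[prevk] <- cii[prevk] + 1
        else next  # I -> D not modelled; skip (rare, needs adjacent gap run)
      } else { # prev == "D"
        if (cur == "M") cdm[prevk] <- cdm[prevk] + 1
        else if (cur == "D") cdd[prevk] <- cdd[prevk] + 1
        else next  # D -> I not modelled
      }
      prev <- cur; prevk <- curk
    }
    # exit to E from the last core state counts toward mm[L] / dm[L]
    if (prev == "M" && prevk == L) cmm[L] <- cmm[L] + 1
    if (prev == "D" && prevk == L) cdd[L] <- cdd[L] + 1  # tallied, renormalised below
  }

  pr <- .TRANS_PRIOR
  mm <- mi <- md <- numeric(L)
  for (k in seq_len(L)) {
    if (k < L) {
      a <- cmm[k] + pseudocount * pr$m[["mm"]]
      b <- cmi[k] + pseudocount * pr$m[["mi"]]
      c2 <- cmd[k] + pseudocount * pr$m[["md"]]
      s <- a + b + c2
      if (s == 0) { a <- pr$m[["mm"]]; b <- pr$m[["mi"]]; c2 <- pr$m[["md"]]; s <- 1 }
      mm[k] <- a / s; mi[k] <- b / s; md[k] <- c2 / s
    } else {
      mm[k] <- 1; mi[k] <- 0; md[k] <- 0   # M_L -> E is forced
    }
  }
  im <- ii <- numeric(L)
  for (k in seq_len(L)) {
    if (k < L) {
      a <- cim[k] + pseudocount * pr$i[["im"]]
      b <- cii[k] + pseudocount * pr$i[["ii"]]
      s <- a + b
      if (s == 0) { im[k] <- pr$i[["im"]]; ii[k] <- pr$i[["ii"]] }
      else { im[k] <- a / s; ii[k] <- b / s }
    } else { im[k] <- 0; ii[k] <- 0 }
  }
  dm <- dd <- numeric(L)
  for (k in seq_len(L)) {
    if (k < L) {
      a <- cdm[k] + pseudocount * pr$d[["dm"]]
      b <- cdd[k] + pseudocount * pr$d[["dd"]]
      s <- a + b
      if (s == 0) { dm[k] <- pr$d[["dm"]]; dd[k] <- pr$d[["dd"]] }
      else { dm[k] <- a / s; dd[k] <- b / s }
    } else { dm[k] <- 1; dd[k] <- 0 }      # D_L -> E is forced
  }
  a <- cb["bm"] + pseudocount * pr$b[["bm"]]
  b <- cb["bd"] + pseudocount * pr$b[["bd"]]
  s <- a + b
  if (s == 0) { bm <- pr$b[["bm"]]; bd <- pr$b[["bd"]] } else {
    bm <- as.numeric(a / s); bd <- as.numeric(b / s)
  }

  methods::new("ProfileHMM",
    name = name,
    matchEmissions = me,
    insertEmissions = ie,
    transitions = list(mm = mm, mi = mi, md = md, im = im, ii = ii,
                       dm = dm, dd = dd, bm = bm, bd = bd),
    nullModel = bg,
    calibration = list()
  )
}
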