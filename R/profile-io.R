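#' Write / read the plain-text profile format
#'
#' A documented line-oriented serialisation (not HMMER3-compatible):
#' ```
#' PROFILE <name> L=<L>
#' NULL <20 freqs>
#' INSERT <20 freqs>
#' BEGIN <bm> <bd>
#' STATE <k> EMIT <20 probs> TRANS <mm mi md im ii dm dd>
#' CALIBRATION <mu> <lambda> <n> <db_size>     (only when calibrated)
#' END
#' ```
#' Numbers are written with full double precision; `writeProfile()` /
#' `readProfile()` round-trip exactly.
#'
#' @param profile A [ProfileHMM-class].
#' @param file Path to write to / read from.
#' @return `readProfile()` returns the reconstructed `ProfileHMM`;
#'   `writeProfile()` returns `file` invisibly.
#' @export
writeProfile <- function(profile, file) {
  stopifnot(methods::is(profile, "ProfileHMM"))
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  L <- profileLength(profile)
  tr <- profile@transitions
  lines <- c(
    sprintf("PROFILE %s L=%d", profile@name, L),
    paste("NULL", num(profile@nullModel)),
    paste("INSERT", num(profile@insertEmissions)),
    sprintf("BEGIN %.17g %.17g", tr$bm, tr$bd),
    vapply(seq_len(L), function(k) {
      sprintf("STATE %d EMIT %s TRANS %s", k,
              num(profile@matchEmissions[k, ]),
              num(c(tr$mm[k], tr$mi[k], tr$md[k], tr$im[k], tr$ii[k],
                    tr$dm[k], tr$dd[k])))
    }, character(1))
  )
  if (isCalibrated(profile)) {
    cal <- profile@calibration
    lines <- c(lines, sprintf("CALIBRATION %.17g %.17g %d %.17g",
                              cal$mu, cal$lambda, cal$n_calibration,
                              cal$db_size))
  }
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' @rdname writeProfile
#' @export
readProfile <- function(file) {
  lines <- readLines(file)
  toks <- strsplit(trimws(lines), "\\s+")
  hd <- toks[[1]]
  if (hd[1] != "PROFILE") stop("not a profile file (missing PROFILE header)")
  name <- hd[2]
  L <- as.integer(sub("L=", "", hd[3]))
  nums <- function(v) as.numeric(v)
  nullm <- ins <- NULL; bm <- bd <- NA_real_
  me <- matrix(NA_real_, L, 20, dimnames = list(NULL, AA_ALPHABET20))
  tr <- list(mm = numeric(L), mi = numeric(L), md = numeric(L),
             im = numeric(L), ii = numeric(L), dm = numeric(L),
             dd = numeric(L))
  cal <- list()
  for (tk in toks[-1]) {
    key <- tk[1]
    if (key == "NULL") nullm <- nums(tk[-1])
    else if (key == "INSERT") ins <- nums(tk[-1])
    else if (key == "BEGIN") { bm <- as.numeric(tk[2]); bd <- as.numeric(tk[3]) }
    else if (key == "STATE") {
      k <- as.integer(tk[2])
      e_at <- which(tk == "EMIT") + 1L
      t_at <- which(tk == "TRANS") + 1L
      me[k, ] <- nums(tk[e_at:(e_at + 19L)])
      tv <- nums(tk[t_at:(t_at + 6L)])
      tr$mm[k] <- tv[1]; tr$mi[k] <- tv[2]; tr$md[k] <- tv[3]
      tr$im[k] <- tv[4]; tr$ii[k] <- tv[5]; tr$dm[k] <- tv[6]
      tr$dd[k] <- tv[7]
    } else if (key == "CALIBRATION") {
      cal <- list(mu = as.numeric(tk[2]), lambda = as.numeric(tk[3]),
                  n_calibration = as.integer(tk[4]),
                  db_size = as.numeric(tk[5]))
    } else if (key == "END") break
  }
  if (is.null(nullm) || is.null(ins) || anyNA(me))
    stop("malformed profile file: missing NULL/INSERT/STATE blocks")
  names(ins) <- AA_ALPHABET20
  names(nullm) <- AA_ALPHABET20
  tr$bm <- bm; tr$bd <- bd
  methods::new("ProfileHMM", name = name, matchEmissions = me,
               insertEmissions = ins, transitions = tr, nullModel = nullm,
               calibration = cal)
}
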