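#' Random background protein sequences
#'
#' Sequences drawn i.i.d. from the null amino-acid composition; used for
#' E-value calibration and as a generic null ensemble.
#'
#' @param n Number of sequences.
#' @param lengths Integer vector of lengths, recycled to `n`.
#' @param seed Optional integer seed (local RNG, no global state touched).
#' @param background Amino-acid frequencies (default
#'   [backgroundFrequencies()]).
#' @return `AAStringSet` of `n` sequences.
#' @export
randomBackgroundSequences <- function(n, lengths, seed = NULL,
                                      background = backgroundFrequencies()) {
  stopifnot(n >= 1, all(lengths >= 1))
  lengths <- rep_len(as.integer(lengths), n)
  runner <- function() {
    bg <- background / sum(background)
    vapply(lengths, function(len) {
      paste(sample(AA_ALPHABET20, len, replace = TRUE, prob = bg),
            collapse = "")
    }, character(1))
  }
  seqs <- if (is.null(seed)) runner() else withr::with_seed(seed, runner())
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- sprintf("random%04d", seq_len(n))
  out
}

# Maximum-likelihood Gumbel fit with method-of-moments initialisation.
# With tailFraction < 1, scores below the (1 - tailFraction) quantile enter
# the likelihood only through the censoring probability F(t), so the fit
# tracks the high-score tail that E-values are computed from (the bulk of a
# forward-score null is narrower than Gumbel, and a full-sample fit would
# overestimate tail mass).
.fit_gumbel <- function(x, tailFraction = 0.25) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps)
    stop("degenerate score distribution: cannot calibrate E-values")
  lambda0 <- pi / (s * sqrt(6))
  mu0 <- mean(x) - 0.57721566490153286 / lambda0
  if (tailFraction >= 1) {
    nll <- function(theta) {
      z <- exp(theta[2]) * (x - theta[1])
      -sum(theta[2] - z - exp(-z))
    }
  } else {
    t <- stats::quantile(x, 1 - tailFraction, names = FALSE)
    n_below <- sum(x < t)
    xs <- x[x >= t]
    nll <- function(theta) {
      lambda <- exp(theta[2])
      z <- lambda * (xs - theta[1])
      log_Ft <- -exp(-lambda * (t - theta[1]))
      -(n_below * log_Ft + sum(theta[2] - z - exp(-z)))
    }
  }
  fit <- stats::optim(c(mu0, log(lambda0)), nll, method = "Nelder-Mead")
  list(mu = fit$par[1], lambda = exp(fit$par[2]))
}

#' Calibrate a profile's E-values against random sequences
#'
#' Scores `nRandom` background-composition random sequences with
#' [forwardBits()] and fits a Gumbel extreme-value distribution (location
#' `mu`, inverse scale `lambda`) to the null score distribution by maximum
#' likelihood (method-of-moments start). The fit is tail-censored: only the
#' top `tailFraction` of null scores enter the likelihood as exact
#' observations, the rest only through the censoring probability, so the
#' fitted survival function is accurate where E-values matter. The E-value
#' of a score `S` searched against `dbSize` sequences is then
#' `E(S) = dbSize * P_gumbel(score >= S)`.
#'
#' @param profile A [ProfileHMM-class].
#' @param nRandom Number of random calibration sequences (>= 100).
#' @param lengths Lengths of the random sequences; default the profile
#'   length.
#' @param dbSize Default database size stored with the calibration (can be
#'   overridden at E-value computation time).
#' @param tailFraction Fraction of highest scores fitted exactly (default
#'   0.25); 1 gives a plain full-sample fit.
#' @param seed Integer seed for the random ensemble.
#' @return The profile with its `calibration` slot filled.
#' @seealso [evalueFromBits()]
#' @export
calibrateEvalue <- function(profile, nRandom = 2000,
                            lengths = profileLength(profile),
                            dbSize = 1, tailFraction = 0.25, seed = NULL) {
  stopifnot(methods::is(profile, "ProfileHMM"))
  if (nRandom < 100) stop("nRandom must be >= 100 for a stable Gumbel fit")
  seqs <- randomBackgroundSequences(nRandom, lengths, seed = seed,
                                    background = profile@nullModel)
  scores <- forwardBits(profile, seqs)
  scores <- scores[is.finite(scores)]
  if (length(scores) < 100)
    stop("too few finite null scores for calibration")
  fit <- .fit_gumbel(scores, tailFraction = tailFraction)
  profile@calibration <- list(mu = fit$mu, lambda = fit$lambda,
                              n_calibration = as.integer(nRandom),
                              db_size = dbSize)
  methods::validObject(profile)
  profile
}

#' E-value of a bit score under a calibrated profile
#'
#' `E(S) = dbSize * (1 - exp(-exp(-lambda (S - mu))))`, the expected number
#' of random sequences at or above score `S` in a database of `dbSize`
#' sequences, under the fitted Gumbel null.
#'
#' @param profile A calibrated [ProfileHMM-class].
#' @param bits Numeric vector of bit scores.
#' @param dbSize Database size; defaults to the value stored at calibration.
#' @return Numeric vector of E-values (strictly decreasing in `bits`).
#' @export
evalueFromBits <- function(profile, bits, dbSize = NULL) {
  if (!isCalibrated(profile))
    stop("profile is not calibrated; run calibrateEvalue() first")
  cal <- profile@calibration
  if (is.null(dbSize)) dbSize <- cal$db_size
  z <- exp(-cal$lambda * (bits - cal$mu))
  dbSize * -expm1(-z)
}
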