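# Independent brute-force oracles used to validate the DP kernels.
# These enumerate explicit state paths / alignments; they share no code with
# the package implementation.

# Flat parameter list for an arbitrary-alphabet profile:
# me (L x A emissions), ie (A), null (A), mm, mi, md, im, ii, dm, dd (len L),
# bm, bd. Mirrors the glocal architecture: N flank (self-loop eta, null
# emission) -> B -> M/I/D core -> E -> C flank -> T.
oracle_pack <- function(profile) {
  tr <- profile@transitions
  list(me = unname(profile@matchEmissions),
       ie = unname(profile@insertEmissions),
       null = unname(profile@nullModel),
       mm = tr$mm, mi = tr$mi, md = tr$md, im = tr$im, ii = tr$ii,
       dm = tr$dm, dd = tr$dd, bm = tr$bm, bd = tr$bd)
}

# Enumerate all core paths recursively; returns summed (mode = "sum") or
# maximal (mode = "max") path probability of the FULL sequence x (1-based
# integer codes into the alphabet), including flank emissions of null[x].
# Raw probabilities, no odds: the caller divides by prod(null[x]).
oracle_path_prob <- function(pp, x, eta, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  L <- nrow(pp$me)
  n <- length(x)
  comb <- if (mode == "sum") sum else function(v) if (length(v)) max(v) else 0
  tailw <- function(j) {                 # C flank from consumed j to end
    if (n - j > 0) eta^(n - j) * prod(pp$null[x[(j + 1):n]]) * (1 - eta)
    else (1 - eta)
  }
  rec <- function(type, k, i) {
    # weight of all completions entering state (type, k) with residue i next
    if (type == "M") {
      if (i > n) return(0)
      w0 <- pp$me[k, x[i]]
      if (w0 == 0) return(0)
      if (k == L) return(w0 * pp$mm[L] * tailw(i))
      w0 * comb(c(pp$mm[k] * rec("M", k + 1, i + 1),
                  pp$mi[k] * rec("I", k, i + 1),
                  pp$md[k] * rec("D", k + 1, i + 1)))
    } else if (type == "I") {
      if (i > n) return(0)
      w0 <- pp$ie[x[i]]
      if (w0 == 0) return(0)
      w0 * comb(c(pp$im[k] * rec("M", k + 1, i + 1),
                  pp$ii[k] * rec("I", k, i + 1)))
    } else { # D
      if (k == L) return(pp$dm[L] * tailw(i - 1))
      comb(c(pp$dm[k] * rec("M", k + 1, i),
             pp$dd[k] * rec("D", k + 1, i)))
    }
  }
  entries <- numeric(0)
  for (f1 in 0:n) {
    pre <- if (f1 > 0) eta^f1 * prod(pp$null[x[seq_len(f1)]]) else 1
    pre <- pre * (1 - eta)
    entries <- c(entries,
                 pre * pp$bm * rec("M", 1, f1 + 1),
                 pre * pp$bd * rec("D", 1, f1 + 1))
  }
  comb(entries)
}

# log2-odds oracle matching forwardBits()/viterbiBits() for 20-letter
# profiles; chars is a character vector of residues.
oracle_bits <- function(profile, seq, mode = "sum", eta = NULL) {
  chars <- strsplit(seq, "")[[1]]
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  x <- match(chars, alpha)
  stopifnot(!anyNA(x))
  n <- length(x)
  if (is.null(eta)) eta <- n / (n + 2)
  pp <- oracle_pack(profile)
  p <- oracle_path_prob(pp, x, eta, mode = mode)
  pnull <- prod(pp$null[x])
  log2(p / pnull)
}

# Random tiny profile over the 20-letter alphabet (valid distributions,
# strictly positive so all paths are live).
random_tiny_profile <- function(L, seed) {
  withr::with_seed(seed, {
    dirich <- function(n, a = 1) { g <- stats::rgamma(n, a); g / sum(g) }
    me <- t(vapply(seq_len(L), function(k) dirich(20, 0.8),
                   numeric(20)))
    colnames(me) <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    ie <- dirich(20, 2)
    nullm <- dirich(20, 20)
    mm <- mi <- md <- im <- ii <- dm <- dd <- numeric(L)
    for (k in seq_len(L)) {
      if (k < L) {
        v <- dirich(3, 2); mm[k] <- v[1]; mi[k] <- v[2]; md[k] <- v[3]
        w <- dirich(2, 2); im[k] <- w[1]; ii[k] <- w[2]
        u <- dirich(2, 2); dm[k] <- u[1]; dd[k] <- u[2]
      } else {
        mm[k] <- 1; dm[k] <- 1
      }
    }
    bv <- dirich(2, 2)
    names(ie) <- names(nullm) <- colnames(me)
    methods::new("ProfileHMM", name = sprintf("tiny%d", seed),
                 matchEmissions = me, insertEmissions = ie,
                 transitions = list(mm = mm, mi = mi, md = md, im = im,
                                    ii = ii, dm = dm, dd = dd,
                                    bm = bv[1], bd = bv[2]),
                 nullModel = nullm, calibration = list())
  })
}

random_aa_seq <- function(len, seed) {
  withr::with_seed(seed, {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
                 replace = TRUE), collapse = "")
  })
}

# Exhaustive global-alignment oracle for tiny sequences: enumerates every
# alignment (match/insert/delete move sequences), scores it with BLOSUM62
# and affine gaps (each run costs open + len * extend), and returns the
# identity fraction (matches / shorter length) of the best-scoring
# alignment, breaking score ties toward higher identity.
oracle_identity <- function(a, b, open = 11, extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- get("BLOSUM62", envir = environment())
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- list(score = -Inf, ident = 0)
  rec <- function(i, j, score, matches, prev) {
    if (i > length(av) && j > length(bv)) {
      id <- matches / min(length(av), length(bv))
      if (score > best$score ||
          (score == best$score && id > best$ident))
        best <<- list(score = score, ident = id)
      return(invisible(NULL))
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1,
          score + S[av[i], bv[j]],
          matches + (av[i] == bv[j]), "M")
    }
    if (i <= length(av)) {
      pen <- extend + (if (prev == "D") 0 else open)
      rec(i + 1, j, score - pen, matches, "D")
    }
    if (j <= length(bv)) {
      pen <- extend + (if (prev == "I") 0 else open)
      rec(i, j + 1, score - pen, matches, "I")
    }
  }
  rec(1, 1, 0, 0, "start")
  best
}
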