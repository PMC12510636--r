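test_that("a single ungapped sequence yields an indicator profile", {
  p <- buildProfile("MKVLW", pseudocount = 0, name = "toy")
  expect_equal(profileLength(p), 5)
  me <- matchEmissions(p)
  for (k in 1:5) {
    res <- substr("MKVLW", k, k)
    expect_equal(unname(me[k, res]), 1)
    expect_equal(sum(me[k, ]), 1)
  }
  expect_equal(p@transitions$mm, rep(1, 5))
  expect_equal(p@transitions$bm, 1)
})

test_that("emission and transition rows are normalised for arbitrary alignments", {
  fam <- generateFamily("menF", 40, 8, divergence = 0.3, indelRate = 0.05,
                        seed = 43)
  p <- buildProfile(fam$alignment, pseudocount = 1)
  expect_true(all(abs(rowSums(matchEmissions(p)) - 1) < 1e-9))
  tr <- p@transitions
  expect_true(all(abs(tr$mm + tr$mi + tr$md - 1) < 1e-9))
  L <- profileLength(p)
  if (L > 1) {
    expect_true(all(abs((tr$im + tr$ii)[-L] - 1) < 1e-9))
  }
  expect_true(all(abs(tr$dm + tr$dd - 1) < 1e-9))
  expect_equal(tr$bm + tr$bd, 1)
})

test_that("columns at the gap-fraction cutoff are excluded from match states", {
  aln <- c("MK-VA", "MK-VA", "MKQVA", "MKWVA")  # column 3: 2/4 gaps
  p <- buildProfile(aln, gapFractionCutoff = 0.5)
  expect_equal(profileLength(p), 4)
  all_gaps <- c("M--K-", "M--K-", "M--K-")      # 3/3 gaps in cols 2,3,5
  p2 <- buildProfile(all_gaps, gapFractionCutoff = 0.5)
  expect_equal(profileLength(p2), 2)
  expect_error(buildProfile(c("---", "---")), "cutoff")
})

test_that("forward and Viterbi match exhaustive path enumeration on tiny cases", {
  for (case in 1:40) {
    L <- (case %% 3) + 1
    p <- random_tiny_profile(L, seed = 1000 + case)
    len <- (case %% 4) + 1
    s <- random_aa_seq(len, seed = 2000 + case)
    fb <- forwardBits(p, s)
    vb <- viterbiBits(p, s)
    expect_equal(fb, oracle_bits(p, s, "sum"), tolerance = 1e-9,
                 info = sprintf("forward case %d", case))
    expect_equal(vb, oracle_bits(p, s, "max"), tolerance = 1e-9,
                 info = sprintf("viterbi case %d", case))
    expect_lte(vb, fb + 1e-6)
  }
})

test_that("a deterministic single-path profile gives viterbi == forward", {
  p <- buildProfile("MKVLWAALKV", pseudocount = 0)
  s <- "MKVLWAALKV"  # length equals L, so flanks and indels are impossible
  expect_equal(viterbiBits(p, s), forwardBits(p, s), tolerance = 1e-9)
  r <- viterbiBits(p, s, withPath = TRUE)
  expect_identical(r$path, sprintf("M%d", 1:10))
})

test_that("profiles score background shuffles negatively on average", {
  seq0 <- as.character(randomBackgroundSequences(1, 120, seed = 47))
  p <- buildProfile(seq0, pseudocount = 1)
  shuffles <- vapply(1:100, function(i) {
    withr::with_seed(5000 + i,
      paste(sample(strsplit(seq0, "")[[1]]), collapse = ""))
  }, character(1))
  expect_lt(mean(forwardBits(p, shuffles)), 0)
  # and the original sequence itself scores far above the shuffles
  expect_gt(forwardBits(p, seq0), 100)
})

test_that("viterbi path accounts for every residue and X scores as background", {
  fam <- generateFamily("nuoA", 40, 4, divergence = 0.2, indelRate = 0.03,
                        seed = 53)
  p <- buildProfile(fam$alignment[-1])
  s <- as.character(fam$members[[2]])
  r <- viterbiBits(p, s, withPath = TRUE)
  emitted <- sum(grepl("^[NMIC]", r$path))
  expect_equal(emitted, nchar(s))
  sx <- sub("^.", "X", s)
  expect_true(is.finite(forwardBits(p, sx)))
  expect_error(forwardBits(p, sub("^.", "b", s)), "alphabet")
  expect_error(forwardBits(p, "Z*Z"), "alphabet")
})

test_that("log-odds scores shift by the exact predicted constant under a null swap", {
  # deterministic-transition profile with strictly positive emissions: a
  # length-L sequence is forced through the L match states, so swapping the
  # null multiplies the odds by exactly prod bg(x)/uni(x)
  L <- 8
  me <- t(vapply(1:L, function(k) {
    withr::with_seed(600 + k, { g <- stats::rgamma(20, 1); g / sum(g) })
  }, numeric(20)))
  colnames(me) <- names(backgroundFrequencies())
  bg <- backgroundFrequencies()
  uni <- setNames(rep(1 / 20, 20), names(bg))
  tr <- list(mm = rep(1, L), mi = rep(0, L), md = rep(0, L),
             im = c(rep(1, L - 1), 0), ii = rep(0, L),
             dm = c(rep(1, L - 1), 1), dd = rep(0, L), bm = 1, bd = 0)
  p_bg <- methods::new("ProfileHMM", name = "det", matchEmissions = me,
                       insertEmissions = bg, transitions = tr,
                       nullModel = bg, calibration = list())
  p_uni <- methods::new("ProfileHMM", name = "det", matchEmissions = me,
                        insertEmissions = bg, transitions = tr,
                        nullModel = uni, calibration = list())
  for (s in c("MKVLWAAC", "WWYYHHRR", "ACDEFGHI")) {
    shift <- sum(log2(bg[strsplit(s, "")[[1]]] / (1 / 20)))
    expect_equal(forwardBits(p_uni, s) - forwardBits(p_bg, s), shift,
                 tolerance = 1e-9)
  }
})

test_that("path mass and sequence mass agree on a reduced alphabet", {
  # generator-level conservation: summing P(seq) over the complete sequence
  # space of each length equals the transition-only path mass for that
  # length (emissions marginalise out). Uses the enumeration oracle on a
  # 4-letter alphabet.
  dirich <- function(n, seed) withr::with_seed(seed, {
    g <- stats::rgamma(n, 2); g / sum(g)
  })
  L <- 2
  pp <- list(me = rbind(dirich(4, 61), dirich(4, 62)),
             ie = dirich(4, 63), null = dirich(4, 64),
             mm = c(0.6, 1), mi = c(0.25, 0), md = c(0.15, 0),
             im = c(0.7, 0), ii = c(0.3, 0),
             dm = c(0.8, 1), dd = c(0.2, 0), bm = 0.85, bd = 0.15)
  ones <- list(me = matrix(1, L, 1), ie = 1, null = 1,
               mm = pp$mm, mi = pp$mi, md = pp$md, im = pp$im, ii = pp$ii,
               dm = pp$dm, dd = pp$dd, bm = pp$bm, bd = pp$bd)
  eta <- 0.4
  for (m in 1:3) {
    seqs <- as.matrix(expand.grid(rep(list(1:4), m)))
    seq_mass <- sum(apply(seqs, 1, function(x)
      oracle_path_prob(pp, as.integer(x), eta, "sum")))
    path_mass <- oracle_path_prob(ones, rep(1L, m), eta, "sum")
    expect_equal(seq_mass, path_mass, tolerance = 1e-12,
                 info = sprintf("length %d", m))
  }
})

test_that("E-values are monotone, anchored at the Gumbel location, and reproducible", {
  fam <- generateFamily("ubiC", 100, 10, divergence = 0.2, seed = 59)
  p <- buildProfile(fam$alignment[-1], name = "ubiC")
  pc <- calibrateEvalue(p, nRandom = 300, dbSize = 50, seed = 67)
  cal <- calibration(pc)
  expect_true(isCalibrated(pc))
  expect_gt(cal$lambda, 0)
  # Gumbel CDF at its location: survival = 1 - exp(-1)
  expect_equal(evalueFromBits(pc, cal$mu, dbSize = 1), 1 - exp(-1),
               tolerance = 1e-12)
  ss <- seq(cal$mu - 5, cal$mu + 50, length.out = 50)
  expect_true(all(diff(evalueFromBits(pc, ss)) < 0))
  # far below the location the survival function saturates at dbSize
  expect_equal(evalueFromBits(pc, cal$mu - 200), 50)
  pc2 <- calibrateEvalue(p, nRandom = 300, dbSize = 50, seed = 67)
  expect_identical(calibration(pc2), cal)
  expect_error(calibrateEvalue(p, nRandom = 50), ">= 100")
})

test_that("degenerate null score distributions are rejected at calibration", {
  bg <- backgroundFrequencies()
  me <- matrix(bg, nrow = 1, dimnames = list(NULL, names(bg)))
  flat <- methods::new("ProfileHMM", name = "flat", matchEmissions = me,
                       insertEmissions = bg,
                       transitions = list(mm = 1, mi = 0, md = 0, im = 0,
                                          ii = 0, dm = 1, dd = 0,
                                          bm = 1, bd = 0),
                       nullModel = bg, calibration = list())
  # every length-1 sequence scores identically (match odds are 1 everywhere)
  expect_error(calibrateEvalue(flat, nRandom = 100, lengths = 1, seed = 3),
               "degenerate")
})

test_that("profile text serialisation round-trips exactly", {
  fam <- generateFamily("mqnC", 60, 6, divergence = 0.25, indelRate = 0.02,
                        seed = 71)
  p <- calibrateEvalue(buildProfile(fam$alignment[-1], name = "mqnC"),
                       nRandom = 150, seed = 73)
  f <- tempfile(fileext = ".phmm")
  writeProfile(p, f)
  q <- readProfile(f)
  expect_equal(matchEmissions(q), matchEmissions(p))
  expect_equal(q@transitions, p@transitions)
  expect_equal(calibration(q), calibration(p))
  s <- as.character(fam$members[[1]])
  expect_identical(forwardBits(q, s), forwardBits(p, s))
})

test_that("ProfileHMM validity catches malformed objects", {
  fam <- generateFamily("menB", 30, 3, seed = 79)
  p <- buildProfile(fam$alignment[-1])
  bad <- p
  bad@matchEmissions[1, ] <- bad@matchEmissions[1, ] * 2
  expect_error(methods::validObject(bad), "sum to 1")
  bad2 <- p
  bad2@calibration <- list(mu = 0, lambda = -1, n_calibration = 10L,
                           db_size = 1)
  expect_error(methods::validObject(bad2), "lambda")
})
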