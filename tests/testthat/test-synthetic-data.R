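test_that("zero-divergence families are exact copies with gap-free alignment", {
  fam <- generateFamily("menB", masterLength = 40, nMembers = 5,
                        divergence = 0, indelRate = 0, seed = 7)
  expect_length(fam$members, 5)
  expect_true(all(as.character(fam$members) == fam$master))
  expect_false(any(grepl("-", as.character(fam$alignment), fixed = TRUE)))
  expect_equal(unique(Biostrings::width(fam$alignment)), 40)
})

test_that("family generation is deterministic under a fixed seed", {
  a <- generateFamily("mqnA", 60, 8, divergence = 0.2, indelRate = 0.02,
                      seed = 11)
  b <- generateFamily("mqnA", 60, 8, divergence = 0.2, indelRate = 0.02,
                      seed = 11)
  expect_identical(as.character(a$members), as.character(b$members))
  expect_identical(as.character(a$alignment), as.character(b$alignment))
  c <- generateFamily("mqnA", 60, 8, divergence = 0.2, indelRate = 0.02,
                      seed = 12)
  expect_false(identical(as.character(a$members), as.character(c$members)))
})

test_that("mean identity to master tracks the divergence parameter", {
  # oracle: direct column-wise identity over the tracked alignment
  fam <- generateFamily("menC", masterLength = 200, nMembers = 50,
                        divergence = 0.2, indelRate = 0, seed = 3)
  aln <- as.character(fam$alignment)
  master <- strsplit(aln[[1]], "")[[1]]
  ids <- vapply(aln[-1], function(s) {
    mean(strsplit(s, "")[[1]] == master)
  }, numeric(1))
  expect_lt(abs(mean(ids) - exp(-0.2)), 0.03)
})

test_that("family parameter validation rejects out-of-range specs", {
  expect_error(generateFamily("x", 5, 3), "masterLength")
  expect_error(generateFamily("x", 50, 0), "nMembers")
  expect_error(generateFamily("x", 50, 3, divergence = 1), "divergence")
  expect_error(generateFamily("x", 50, 3, indelRate = 0.5), "indelRate")
})

test_that("proteomes contain planted members plus decoys with the header dialect", {
  fams <- list(ndh = generateFamily("ndh", 50, 6, divergence = 0.1, seed = 2))
  prot <- generateProteome("spA", "gA", "ndh", fams, nDecoys = 10, seed = 5)
  expect_length(prot, 11)
  parts <- strsplit(names(prot), "|", fixed = TRUE)
  expect_true(all(lengths(parts) == 3))
  expect_true(all(vapply(parts, `[[`, "", 1) == "gA"))
  expect_true(all(vapply(parts, `[[`, "", 2) == "spA"))
  labels <- vapply(parts, `[[`, "", 3)
  expect_identical(labels[1], "ndh")
  expect_true(all(grepl("^decoy", labels[-1])))
  # planted member is a real family member, never the master
  expect_true(as.character(prot[[1]]) %in% as.character(fams$ndh$members))
  expect_false(identical(as.character(prot[[1]]), fams$ndh$master))
})

test_that("empty species give empty proteomes and missing families error", {
  fams <- list(ndh = generateFamily("ndh", 50, 3, seed = 1))
  empty <- generateProteome("sp", "g", character(0), fams, nDecoys = 0)
  expect_length(empty, 0)
  expect_error(generateProteome("sp", "g", "menB", fams, nDecoys = 0),
               "no family")
  expect_error(generateProteome("sp", "g", "notagene", fams), "panel")
})

test_that("shuffled decoys preserve the amino-acid multiset of their source", {
  fams <- list(ubiC = generateFamily("ubiC", 80, 1, divergence = 0.1,
                                     seed = 4))
  prot <- generateProteome("sp", "g", "ubiC", fams, nDecoys = 15,
                           decoyMode = "shuffled", seed = 9)
  src <- sort(strsplit(as.character(prot[[1]]), "")[[1]])
  for (d in 2:16) {
    expect_identical(sort(strsplit(as.character(prot[[d]]), "")[[1]]), src)
    expect_false(identical(as.character(prot[[d]]), as.character(prot[[1]])))
  }
})

test_that("a degenerate category distribution plants that category everywhere", {
  fams <- generateMarkerFamilies(nMembers = 3, seed = 1)
  set <- generateSpeciesSet(30, categoryFreqs = c(NQ_NDH2 = 1),
                            families = fams, nDecoys = 0, seed = 6)
  expect_equal(nrow(set$truth), 30)
  expect_true(all(set$truth$category == "NQ_NDH2"))
  expect_true(all(set$truth$quinone_category == "NQ-only"))
  expect_true(all(set$truth$dh_category == "NDH2-only"))
  expect_true(all(set$truth$ndh))
  expect_false(any(set$truth$ubiA))
})

test_that("planted category frequencies are recovered within binomial error", {
  sheet_truth <- generateSpeciesSet(
    1000, families = generateMarkerFamilies(nMembers = 2, seed = 2),
    nDecoys = 0, seed = 8)$truth
  calls <- callPathways(sheet_truth)
  tab <- tabulateCooccurrence(calls)
  sd3 <- 3 * sqrt(0.654 * (1 - 0.654) / tab$n_nq)
  expect_lt(abs(tab$frac_nq_with_ndh2 - 0.654), sd3)
  expect_lt(abs(tab$frac_ndh2_with_uq_by[["all"]] - 0.009),
            3 * sqrt(0.009 * 0.991 / 1000))
})

test_that("species-set truth flags equal the pathway rule applied to planted genes", {
  set <- generateSpeciesSet(
    200, families = generateMarkerFamilies(nMembers = 2, seed = 5),
    nDecoys = 0, seed = 13)
  calls <- callPathways(set$truth)
  expect_identical(calls$quinone_category, set$truth$quinone_category)
  expect_identical(calls$dh_category, set$truth$dh_category)
})

test_that("species-set generation is deterministic and validates frequencies", {
  fams <- generateMarkerFamilies(nMembers = 2, seed = 3)
  a <- generateSpeciesSet(10, families = fams, seed = 21)
  b <- generateSpeciesSet(10, families = fams, seed = 21)
  expect_identical(a$truth, b$truth)
  expect_identical(as.character(a$proteomes), as.character(b$proteomes))
  expect_error(generateSpeciesSet(10, categoryFreqs = c(NQ_NDH2 = 0.6),
                                  families = fams), "summing to 1")
})

test_that("presence sheets reproduce planted fractions at survey scale", {
  sheet <- generatePresenceSheet(2000, seed = 17)
  expect_equal(nrow(sheet), 2000)
  r <- recomputeFromSheet(sheet)
  sd3 <- 3 * sqrt(0.654 * 0.346 / r$table$n_nq)
  expect_lt(abs(r$table$frac_nq_with_ndh2 - 0.654), sd3)
})

test_that("noise-free growth curves follow the closed-form models", {
  g <- generateGrowthCurve("exponential", mu = 0.6, od0 = 0.02, noiseCv = 0,
                           tGrid = seq(0, 5, 0.25))
  expect_equal(g$od600, 0.02 * exp(0.6 * g$time_h), tolerance = 1e-12)
  gl <- generateGrowthCurve("logistic", mu = 0.8, od0 = 0.02, K = 1,
                            noiseCv = 0, tGrid = seq(0, 20, 0.25))
  expect_true(all(gl$od600 < 1))
  expect_true(all(diff(gl$od600) >= 0))
})

test_that("multiplicative noise has the stated CV and is reproducible", {
  tg <- seq(0, 10, length.out = 200)
  g1 <- generateGrowthCurve("exponential", mu = 0.5, noiseCv = 0.05,
                            tGrid = tg, seed = 31)
  g2 <- generateGrowthCurve("exponential", mu = 0.5, noiseCv = 0.05,
                            tGrid = tg, seed = 31)
  expect_identical(g1$od600, g2$od600)
  clean <- generateGrowthCurve("exponential", mu = 0.5, noiseCv = 0,
                               tGrid = tg)
  resid <- g1$od600 / clean$od600
  expect_lt(abs(sd(resid) / mean(resid) - 0.05), 0.3 * 0.05)
})

test_that("growth-curve generation rejects invalid inputs", {
  expect_error(generateGrowthCurve("exponential", mu = -1), "mu")
  expect_error(generateGrowthCurve("exponential", mu = 1,
                                   tGrid = c(0, 1, 1)), "increasing")
  expect_error(generateGrowthCurve("logistic", mu = 1, od0 = 2, K = 1), "K")
})
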