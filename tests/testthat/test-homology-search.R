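# Shared small panel: two marker genes, calibrated once per test file.
local_panel <- local({
  fams <- list(
    menB = generateFamily("menB", 120, 10, divergence = 0.2, seed = 101),
    ndh = generateFamily("ndh", 150, 10, divergence = 0.2, seed = 103))
  panel <- NULL
  function() {
    if (is.null(panel))
      panel <<- buildMarkerPanel(fams, nRandom = 300, seed = 105)
    list(panel = panel, fams = fams)
  }
})

test_that("empty proteomes give zero hits and all-false presence", {
  pf <- local_panel()
  res <- searchProteome(pf$panel, Biostrings::AAStringSet(),
                        geneThresholds())
  expect_equal(nrow(res$hits), 0)
  expect_false(any(unlist(res$presence[, names(pf$panel)])))
})

test_that("planted orthologs are found and shuffled decoys rejected", {
  pf <- local_panel()
  prot <- generateProteome("spX", "gX", "menB", pf$fams, nDecoys = 50,
                           decoyMode = "shuffled", seed = 107)
  res <- searchProteome(pf$panel, prot, geneThresholds())
  expect_true(res$presence$menB)
  expect_false(res$presence$ndh)
  expect_equal(res$hits$gene, "menB")
  expect_match(res$hits$sequence_id, "\\|menB$")
  expect_gte(res$hits$bit_score, 100)
  # no decoy scores anywhere near the bit threshold
  decoys <- prot[grepl("decoy", names(prot))]
  for (g in names(pf$panel))
    expect_true(all(forwardBits(pf$panel[[g]], decoys) < 100))
})

test_that("bit-score and E-value thresholds are inclusive boundaries", {
  pf <- local_panel()
  prot <- generateProteome("spY", "gY", "menB", pf$fams, nDecoys = 5,
                           seed = 109)
  base <- searchProteome(pf$panel, prot, geneThresholds())
  s <- base$hits$bit_score[base$hits$gene == "menB"]
  ev <- base$hits$evalue[base$hits$gene == "menB"]
  # a minimum exactly at the observed score retains the hit ...
  at <- searchProteome(pf$panel, prot,
                       geneThresholds(minBitScore = s))
  expect_true(at$presence$menB)
  # ... just above it excludes the hit
  above <- searchProteome(pf$panel, prot,
                          geneThresholds(minBitScore = s + 1e-6))
  expect_false(above$presence$menB)
  # E-value cutoff is inclusive too
  ev_at <- searchProteome(pf$panel, prot,
                          geneThresholds(evalue = max(ev, 1e-300)))
  expect_true(ev_at$presence$menB)
})

test_that("tightening any cutoff never adds hits", {
  pf <- local_panel()
  prot <- generateProteome("spZ", "gZ", c("menB", "ndh"), pf$fams,
                           nDecoys = 20, seed = 113)
  loose <- searchProteome(pf$panel, prot,
                          geneThresholds(evalue = 1e-3, minBitScore = 50))
  tight <- searchProteome(pf$panel, prot,
                          geneThresholds(evalue = 1e-30, minBitScore = 150))
  expect_true(all(tight$hits$sequence_id %in% loose$hits$sequence_id))
  expect_lte(nrow(tight$hits), nrow(loose$hits))
})

test_that("at most one hit is retained per genome and gene", {
  pf <- local_panel()
  fams <- pf$fams
  # plant two menB members in one genome: only the best may be retained
  two <- c(generateProteome("spW", "gW", "menB", fams, nDecoys = 0,
                            seed = 127),
           generateProteome("spW", "gW", "menB", fams, nDecoys = 0,
                            seed = 131))
  names(two)[2] <- "gW|spW|menBcopy"
  res <- searchProteome(pf$panel, two, geneThresholds())
  expect_equal(sum(res$hits$gene == "menB"), 1)
  all_bits <- forwardBits(pf$panel$menB, two)
  expect_equal(res$hits$bit_score[res$hits$gene == "menB"],
               unname(max(all_bits)))
})

test_that("uncalibrated profiles and missing thresholds are rejected", {
  pf <- local_panel()
  raw <- buildProfile(pf$fams$menB$alignment[-1], name = "menB")
  prot <- generateProteome("spQ", "gQ", "menB", pf$fams, nDecoys = 0,
                           seed = 137)
  expect_error(searchProteome(list(menB = raw), prot), "uncalibrated")
  expect_error(
    searchProteome(pf$panel, prot,
                   structure(list(evalue_by_gene = c(menB = 1e-10),
                                  min_bit_score = 100),
                             class = "geneThresholds")),
    "missing")
})

test_that("species collapse follows any/all/majority semantics", {
  pres <- data.frame(
    genome_id = c("g1", "g2", "g3", "h1"),
    species_id = c("sp1", "sp1", "sp1", "sp2"),
    ndh = c(TRUE, TRUE, FALSE, TRUE),
    menB = c(FALSE, FALSE, FALSE, TRUE))
  any_r <- collapseToSpecies(pres, "any")
  all_r <- collapseToSpecies(pres, "all")
  maj_r <- collapseToSpecies(pres, "majority")
  sp1 <- function(d) d[d$species_id == "sp1", ]
  expect_true(sp1(any_r)$ndh)
  expect_false(sp1(all_r)$ndh)
  expect_true(sp1(maj_r)$ndh)          # 2 of 3 vote yes
  expect_false(sp1(maj_r)$menB)
  # single-genome species collapse to themselves under every rule
  sp2 <- function(d) d[d$species_id == "sp2", ]
  for (d in list(any_r, all_r, maj_r)) {
    expect_true(sp2(d)$ndh)
    expect_true(sp2(d)$menB)
  }
  expect_error(collapseToSpecies(pres[0, ]), "empty")
})

test_that("collapse rules nest: any >= majority >= all", {
  withr::with_seed(139, {
    pres <- data.frame(
      genome_id = sprintf("g%02d", 1:30),
      species_id = rep(sprintf("sp%d", 1:10), each = 3),
      ndh = sample(c(TRUE, FALSE), 30, replace = TRUE),
      menB = sample(c(TRUE, FALSE), 30, replace = TRUE))
  })
  any_r <- collapseToSpecies(pres, "any")
  maj_r <- collapseToSpecies(pres, "majority")
  all_r <- collapseToSpecies(pres, "all")
  for (g in c("ndh", "menB")) {
    expect_true(all(any_r[[g]] >= maj_r[[g]]))
    expect_true(all(maj_r[[g]] >= all_r[[g]]))
  }
})

test_that("multi-genome search splits genomes and warns on double-gene hits", {
  pf <- local_panel()
  prots <- c(
    generateProteome("spA", "gA1", "menB", pf$fams, nDecoys = 3, seed = 149),
    generateProteome("spA", "gA2", character(0), pf$fams, nDecoys = 3,
                     seed = 151),
    generateProteome("spB", "gB1", c("menB", "ndh"), pf$fams, nDecoys = 3,
                     seed = 157))
  res <- searchGenomes(pf$panel, prots, geneThresholds())
  expect_equal(nrow(res$presence), 3)
  sp <- collapseToSpecies(res$presence, "any")
  expect_true(sp$menB[sp$species_id == "spA"])
  expect_false(sp$ndh[sp$species_id == "spA"])
  expect_true(all(unlist(sp[sp$species_id == "spB", c("menB", "ndh")])))
})

test_that("threshold constructor and TSV reader agree", {
  th <- geneThresholds(evalue = c(menB = 1e-5), minBitScore = 90)
  expect_equal(th$evalue_by_gene[["menB"]], 1e-5)
  expect_equal(th$evalue_by_gene[["ndh"]], 1e-10)  # default fill
  expect_error(geneThresholds(evalue = -1), "positive")
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tevalue_cutoff", "menB\t1e-05", "ndh\t1e-08"), f)
  th2 <- readThresholds(f, minBitScore = 90)
  expect_equal(th2$evalue_by_gene[["menB"]], 1e-5)
  expect_equal(th2$evalue_by_gene[["ndh"]], 1e-8)
  expect_equal(th2$evalue_by_gene[["ubiA"]], 1e-10)
})
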