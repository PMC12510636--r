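# Probability that a site still shows the ancestral residue after an
# expected `d` substitutions per site under a Jukes-Cantor-like 20-state
# model with uniform replacement over the 19 alternatives.
.p_identical <- function(d) 1 / 20 + (19 / 20) * exp(-(20 / 19) * d)

#' Generate a divergent protein family with a tracked true alignment
#'
#' Simulates a family for one marker gene: a master sequence drawn from the
#' background composition, plus `nMembers` descendants mutated independently
#' from the master. Substitutions follow a 20-state Jukes-Cantor-like model
#' (`divergence` = expected substitutions per site, uniform replacement over
#' the other 19 residues); single-residue indels occur at `indelRate` per
#' site (half deletions, half insertions). Because indels are recorded as
#' they happen, the exact multiple alignment of master and members is
#' returned alongside the unaligned sequences.
#'
#' @param geneName Family label (e.g. one of [markerPanel()]).
#' @param masterLength Master sequence length in residues (>= 10).
#' @param nMembers Number of family members (>= 1).
#' @param divergence Expected substitutions per site, in `[0, 1)`.
#' @param indelRate Per-site indel probability, in `[0, 0.1]`.
#' @param seed Integer seed; identical seeds give identical families.
#' @param background Amino-acid composition of the master.
#' @return List with elements `gene`, `master` (character), `members`
#'   (`AAStringSet`), `alignment` (gapped `AAStringSet`, master first) and
#'   `params`.
#' @examples
#' fam <- generateFamily("menB", masterLength = 60, nMembers = 5,
#'                       divergence = 0.1, seed = 1)
#' fam$members
#' @export
generateFamily <- function(geneName, masterLength, nMembers,
                           divergence = 0.2, indelRate = 0.01, seed = 1,
                           background = backgroundFrequencies()) {
  if (masterLength < 10) stop("masterLength must be >= 10")
  if (nMembers < 1) stop("nMembers must be >= 1")
  if (divergence < 0 || divergence >= 1)
    stop("divergence must be in [0, 1)")
  if (indelRate < 0 || indelRate > 0.1)
    stop("indelRate must be in [0, 0.1]")
  bg <- background / sum(background)
  withr::with_seed(as.integer(seed), {
    master <- sample(AA_ALPHABET20, masterLength, replace = TRUE, prob = bg)
    p_same <- .p_identical(divergence)
    # member residues per master column ("-" = deleted) and insertions after
    # each column (index 0 = before the first column)
    res <- matrix("", nrow = nMembers, ncol = masterLength)
    ins <- vector("list", nMembers)
    for (m in seq_len(nMembers)) {
      keep <- stats::runif(masterLength) >= indelRate / 2
      same <- stats::runif(masterLength) < p_same
      row <- master
      nsub <- sum(!same)
      if (nsub > 0) {
        row[!same] <- vapply(master[!same], function(a) {
          sample(setdiff(AA_ALPHABET20, a), 1L)
        }, character(1))
      }
      row[!keep] <- "-"
      res[m, ] <- row
      ins_here <- which(stats::runif(masterLength) < indelRate / 2)
      ins[[m]] <- if (length(ins_here))
        setNames(sample(AA_ALPHABET20, length(ins_here), replace = TRUE,
                        prob = bg), ins_here)
      else setNames(character(0), character(0))
    }
    # assemble alignment column by column; each member's insertion after a
    # column gets its own all-gap column in the other rows
    aln_cols <- list()
    for (j in seq_len(masterLength)) {
      aln_cols[[length(aln_cols) + 1L]] <- c(master[j], res[, j])
      for (m in seq_len(nMembers)) {
        v <- ins[[m]]
        if (as.character(j) %in% names(v)) {
          col <- rep("-", nMembers + 1L)
          col[m + 1L] <- v[[as.character(j)]]
          aln_cols[[length(aln_cols) + 1L]] <- col
        }
      }
    }
    aln_mat <- do.call(cbind, aln_cols)
    rows <- apply(aln_mat, 1, paste, collapse = "")
    member_ids <- sprintf("%s_m%02d", geneName, seq_len(nMembers))
    names(rows) <- c(paste0(geneName, "_master"), member_ids)
    members <- vapply(seq_len(nMembers), function(m) {
      gsub("-", "", rows[m + 1L], fixed = TRUE)
    }, character(1))
    names(members) <- member_ids
    list(gene = geneName,
         master = paste(master, collapse = ""),
         members = Biostrings::AAStringSet(members),
         alignment = Biostrings::AAStringSet(rows),
         params = list(masterLength = masterLength, nMembers = nMembers,
                       divergence = divergence, indelRate = indelRate,
                       seed = as.integer(seed)))
  })
}

#' Default synthetic families for the 13-marker panel
#'
#' One family per marker gene, with master lengths matching typical
#' bacterial protein lengths for each marker, so search bit scores have
#' realistic magnitudes.
#'
#' @param nMembers Members per family.
#' @param divergence,indelRate As in [generateFamily()].
#' @param seed Base seed; family i uses `seed + i`.
#' @return Named list of families (one per [markerPanel()] gene).
#' @export
generateMarkerFamilies <- function(nMembers = 20, divergence = 0.2,
                                   indelRate = 0.01, seed = 1) {
  genes <- markerPanel()
  fams <- lapply(seq_along(genes), function(i) {
    generateFamily(genes[i], masterLength = MARKER_LENGTHS[[genes[i]]],
                   nMembers = nMembers, divergence = divergence,
                   indelRate = indelRate, seed = as.integer(seed) + i)
  })
  names(fams) <- genes
  fams
}

.shuffle_seq <- function(s) {
  paste(sample(strsplit(s, "")[[1]]), collapse = "")
}

#' Generate one synthetic proteome with planted orthologs and decoys
#'
#' For every gene in `genesPresent` one family member (never the master) is
#' planted; `nDecoys` decoys are added, either residue shuffles of real
#' family members (identical amino-acid composition, no surviving homology)
#' or random background sequences. Headers follow the
#' `genomeID|speciesID|label` dialect.
#'
#' @param speciesId,genomeId Identifier strings (no `|` allowed).
#' @param genesPresent Character vector, subset of [markerPanel()].
#' @param families Named list of families from [generateFamily()], covering
#'   every gene in `genesPresent`.
#' @param nDecoys Number of decoy sequences (>= 0).
#' @param decoyMode `"shuffled"` or `"random-background"`.
#' @param seed Integer seed.
#' @return `AAStringSet` of planted members plus decoys.
#' @export
generateProteome <- function(speciesId, genomeId, genesPresent, families,
                             nDecoys = 20, decoyMode = c("shuffled",
                                                         "random-background"),
                             seed = 1) {
  decoyMode <- match.arg(decoyMode)
  if (any(grepl("|", c(speciesId, genomeId), fixed = TRUE)))
    stop("ids must not contain '|'")
  genesPresent <- unique(as.character(genesPresent))
  if (!all(genesPresent %in% markerPanel()))
    stop("genesPresent must be a subset of the 13-gene marker panel")
  missing <- setdiff(genesPresent, names(families))
  if (length(missing))
    stop("no family provided for gene(s): ", paste(missing, collapse = ", "))
  withr::with_seed(as.integer(seed), {
    seqs <- character(0)
    labels <- character(0)
    for (g in genesPresent) {
      mem <- as.character(families[[g]]$members)
      pick <- mem[[sample(length(mem), 1L)]]
      seqs <- c(seqs, pick)
      labels <- c(labels, g)
    }
    if (nDecoys > 0) {
      pool <- if (length(seqs)) seqs else
        unlist(lapply(families, function(f) as.character(f$members)))
      for (d in seq_len(nDecoys)) {
        src <- pool[[sample(length(pool), 1L)]]
        dec <- if (decoyMode == "shuffled") .shuffle_seq(src) else
          as.character(randomBackgroundSequences(1, nchar(src)))
        seqs <- c(seqs, dec)
        labels <- c(labels, sprintf("decoy%03d", d))
      }
    }
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- sprintf("%s|%s|%s", genomeId, speciesId, labels)
    out
  })
}

#' Default quinone-by-dehydrogenase category frequencies
#'
#' The generator's default species-category distribution. It reproduces the
#' headline structure of the cross-species survey: 65% of species carry the
#' naphthoquinone (NQ) pathway, of which 65.4% also carry NDH-2; NDH-2
#' coexists with ubiquinone (UQ) in 0.9% of all species.
#'
#' @return Named numeric vector summing to 1. Category names follow
#'   `<quinone>_<dh>` with quinone in `{NQ, UQ, bothQ, noQ}` and dh in
#'   `{NDH1, NDH2, bothDH, noDH}`.
#' @export
defaultCategoryFreqs <- function() {
  c(NQ_NDH2 = 0.2251, NQ_bothDH = 0.2000, NQ_NDH1 = 0.2049, NQ_noDH = 0.0200,
    UQ_NDH1 = 0.2810, UQ_NDH2 = 0.0040, UQ_bothDH = 0.0050, UQ_noDH = 0.0100,
    noQ_NDH1 = 0.0300, noQ_noDH = 0.0200)
}

# genes realising one category; NQ picks the classical or futalosine route
.category_genes <- function(category, nq_route = c("classical", "futalosine")) {
  nq_route <- match.arg(nq_route)
  parts <- strsplit(category, "_", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("category must look like '<quinone>_<dh>', got: ", category)
  q <- parts[1]; dh <- parts[2]
  nq_genes <- if (nq_route == "classical") c("menB", "menC", "menF") else
    c("mqnA", "mqnC", "mqnD")
  uq_genes <- c("ubiA", "ubiC", "ubiG")
  genes <- switch(q,
    NQ = nq_genes, UQ = uq_genes, bothQ = c(nq_genes, uq_genes),
    noQ = character(0),
    stop("unknown quinone category: ", q))
  genes <- c(genes, switch(dh,
    NDH1 = c("nuoA", "nuoE", "nuoJ"), NDH2 = "ndh",
    bothDH = c("nuoA", "nuoE", "nuoJ", "ndh"), noDH = character(0),
    stop("unknown dehydrogenase category: ", dh)))
  genes
}

.category_calls <- function(category) {
  parts <- strsplit(category, "_", fixed = TRUE)[[1]]
  q <- switch(parts[1], NQ = "NQ-only", UQ = "UQ-only", bothQ = "both",
              noQ = "neither")
  dh <- switch(parts[2], NDH1 = "NDH1-only", NDH2 = "NDH2-only",
               bothDH = "both", noDH = "neither")
  c(quinone = q, dh = dh)
}

#' Generate a species set with planted category frequencies
#'
#' Species categories are drawn i.i.d. from `categoryFreqs`; each species
#' receives the marker genes realising its category (NQ species use the
#' classical or futalosine route with equal probability) and `nGenomes`
#' genome proteomes built by [generateProteome()]. The returned truth table
#' records, per species, the planted genes and the expected pathway
#' category, independently of any downstream calling code.
#'
#' @param nSpecies Number of species (>= 1).
#' @param categoryFreqs Named probabilities summing to 1 (default
#'   [defaultCategoryFreqs()]).
#' @param families Marker families (default [generateMarkerFamilies()] built
#'   from `seed`).
#' @param nDecoys Decoys per genome.
#' @param nGenomes Genomes per species.
#' @param decoyMode Passed to [generateProteome()].
#' @param seed Integer seed.
#' @return List with `proteomes` (one `AAStringSet` covering all genomes),
#'   `truth` (data.frame: species_id, category, quinone_category,
#'   dh_category, one logical column per marker gene) and `families`.
#' @export
generateSpeciesSet <- function(nSpecies, categoryFreqs = defaultCategoryFreqs(),
                               families = NULL, nDecoys = 20, nGenomes = 1,
                               decoyMode = "shuffled", seed = 1) {
  stopifnot(nSpecies >= 1, nGenomes >= 1)
  p <- as.numeric(categoryFreqs)
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9)
    stop("categoryFreqs must be probabilities summing to 1")
  if (is.null(names(categoryFreqs)))
    stop("categoryFreqs must be named by category")
  if (is.null(families))
    families <- generateMarkerFamilies(seed = as.integer(seed))
  genes <- markerPanel()
  withr::with_seed(as.integer(seed) + 10000L, {
    cats <- sample(names(categoryFreqs), nSpecies, replace = TRUE, prob = p)
    routes <- sample(c("classical", "futalosine"), nSpecies, replace = TRUE)
    prot_seeds <- sample.int(.Machine$integer.max / 2L, nSpecies * nGenomes)
  })
  all_prot <- vector("list", nSpecies * nGenomes)
  truth_rows <- vector("list", nSpecies)
  idx <- 0L
  for (s in seq_len(nSpecies)) {
    sid <- sprintf("sp%05d", s)
    gset <- .category_genes(cats[s], routes[s])
    for (g in seq_len(nGenomes)) {
      idx <- idx + 1L
      gid <- sprintf("%s.g%02d", sid, g)
      all_prot[[idx]] <- generateProteome(sid, gid, gset, families,
                                          nDecoys = nDecoys,
                                          decoyMode = decoyMode,
                                          seed = prot_seeds[idx])
    }
    calls <- .category_calls(cats[s])
    row <- data.frame(species_id = sid, category = cats[s],
                      quinone_category = calls[["quinone"]],
                      dh_category = calls[["dh"]],
                      stringsAsFactors = FALSE)
    for (g in genes) row[[g]] <- g %in% gset
    truth_rows[[s]] <- row
  }
  list(proteomes = do.call(c, all_prot),
       truth = do.call(rbind, truth_rows),
       families = families)
}

#' Generate a synthetic per-genome presence sheet
#'
#' A lightweight, sequence-free analogue of a per-genome search-result
#' sheet: species categories are drawn i.i.d. from `categoryFreqs` and the
#' realising marker genes are written as a wide presence table (one row per
#' genome), suitable for [recomputeFromSheet()]. Useful for exercising the
#' tabulation stages at survey scale (thousands of species) where full
#' sequence simulation would be wasteful.
#'
#' @inheritParams generateSpeciesSet
#' @return data.frame with columns `genome_id`, `species_id` and one
#'   logical column per marker gene.
#' @export
generatePresenceSheet <- function(nSpecies,
                                  categoryFreqs = defaultCategoryFreqs(),
                                  nGenomes = 1, seed = 1) {
  stopifnot(nSpecies >= 1, nGenomes >= 1)
  p <- as.numeric(categoryFreqs)
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9)
    stop("categoryFreqs must be probabilities summing to 1")
  withr::with_seed(as.integer(seed), {
    cats <- sample(names(categoryFreqs), nSpecies, replace = TRUE, prob = p)
    routes <- sample(c("classical", "futalosine"), nSpecies, replace = TRUE)
  })
  sid <- sprintf("sp%05d", seq_len(nSpecies))
  rows <- data.frame(
    genome_id = sprintf("%s.g%02d", rep(sid, each = nGenomes),
                        rep(seq_len(nGenomes), nSpecies)),
    species_id = rep(sid, each = nGenomes),
    stringsAsFactors = FALSE)
  gene_sets <- mapply(.category_genes, cats, routes, SIMPLIFY = FALSE)
  for (g in markerPanel())
    rows[[g]] <- rep(vapply(gene_sets, function(s) g %in% s, logical(1)),
                     each = nGenomes)
  rows
}

#' Generate a synthetic OD600 growth curve
#'
#' Exponential (`OD = od0 * exp(mu * (t - lag))` after the lag) or logistic
#' growth with optional multiplicative lognormal noise of coefficient of
#' variation `noiseCv` (mean 1, so `noiseCv = 0` returns the exact model
#' curve).
#'
#' @param model `"exponential"` or `"logistic"`.
#' @param mu Specific growth rate, per hour (> 0).
#' @param od0 Initial OD600.
#' @param lag Lag time in hours before growth starts.
#' @param K Carrying capacity (logistic only; must exceed `od0`).
#' @param noiseCv Coefficient of variation of the multiplicative noise.
#' @param tGrid Strictly increasing time grid, hours.
#' @param seed Integer seed (only used when `noiseCv > 0`).
#' @return data.frame with columns `time_h` and `od600`.
#' @export
generateGrowthCurve <- function(model = c("exponential", "logistic"),
                                mu, od0 = 0.02, lag = 0, K = 1.0,
                                noiseCv = 0, tGrid = seq(0, 10, by = 1 / 6),
                                seed = 1) {
  model <- match.arg(model)
  if (mu <= 0) stop("mu must be positive")
  if (any(diff(tGrid) <= 0)) stop("tGrid must be strictly increasing")
  if (model == "logistic" && K <= od0) stop("K must exceed od0")
  tt <- pmax(tGrid - lag, 0)
  od <- if (model == "exponential") od0 * exp(mu * tt) else
    K / (1 + ((K - od0) / od0) * exp(-mu * tt))
  if (noiseCv > 0) {
    sdlog <- sqrt(log(1 + noiseCv^2))
    fac <- withr::with_seed(as.integer(seed), {
      stats::rlnorm(length(od), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    })
    od <- od * fac
  }
  data.frame(time_h = tGrid, od600 = od)
}
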