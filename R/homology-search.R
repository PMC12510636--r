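#' Per-gene search thresholds
#'
#' Hit filtering uses two criteria jointly: an E-value at or below the
#' gene-specific cutoff AND a bit score at or above `minBitScore` (default
#' 100 bits; both thresholds inclusive). The default per-gene cutoff of
#' 1e-10 applies to any gene without an explicit value.
#'
#' @param evalue Either a single default cutoff or a named vector of
#'   per-gene cutoffs (all > 0).
#' @param minBitScore Minimum bit score (finite).
#' @param genes Genes the thresholds must cover (default [markerPanel()]).
#' @return Object of class `geneThresholds`.
#' @export
geneThresholds <- function(evalue = 1e-10, minBitScore = 100,
                           genes = markerPanel()) {
  if (any(evalue <= 0)) stop("E-value cutoffs must be positive")
  if (!is.finite(minBitScore)) stop("minBitScore must be finite")
  ev <- setNames(rep(if (is.null(names(evalue))) evalue[[1]] else 1e-10,
                     length(genes)), genes)
  if (!is.null(names(evalue))) {
    unknown <- setdiff(names(evalue), genes)
    if (length(unknown))
      stop("thresholds given for unknown gene(s): ",
           paste(unknown, collapse = ", "))
    ev[names(evalue)] <- evalue
  }
  structure(list(evalue_by_gene = ev, min_bit_score = minBitScore),
            class = "geneThresholds")
}

#' Read thresholds from a TSV/CSV table
#'
#' Expects columns `gene` and `evalue_cutoff` (one row per gene), mirroring
#' a per-gene cutoff table; genes absent from the table fall back to the
#' default cutoff.
#'
#' @param file Path to a TSV or CSV file.
#' @param minBitScore Minimum bit score.
#' @param default Cutoff for genes missing from the table.
#' @return A `geneThresholds` object.
#' @export
readThresholds <- function(file, minBitScore = 100, default = 1e-10) {
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("gene", "evalue_cutoff") %in% names(tab)))
    stop("threshold table needs columns 'gene' and 'evalue_cutoff'")
  ev <- setNames(rep(default, length(markerPanel())), markerPanel())
  keep <- tab$gene %in% markerPanel()
  ev[tab$gene[keep]] <- tab$evalue_cutoff[keep]
  geneThresholds(evalue = ev, minBitScore = minBitScore)
}

.parse_headers <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("sequence headers must follow 'genomeID|speciesID|label'")
  data.frame(sequence_id = ids,
             genome_id = vapply(parts, `[[`, character(1), 1L),
             species_id = vapply(parts, `[[`, character(1), 2L),
             label = vapply(parts, `[[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

.empty_hits <- function() {
  data.frame(genome_id = character(0), species_id = character(0),
             gene = character(0), sequence_id = character(0),
             bit_score = numeric(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

#' Search one proteome with a calibrated profile panel
#'
#' Every sequence is scored against every profile with [forwardBits()]; a
#' hit is retained iff its E-value is at or below the gene's cutoff AND its
#' bit score is at or above the minimum (both inclusive). Per gene, only the
#' best retained hit (maximum bit score) is kept and sets presence. A
#' sequence satisfying several profiles is retained for each (with a
#' warning): profiles do not compete.
#'
#' @param profiles Named list of calibrated [ProfileHMM-class] objects, one
#'   per gene.
#' @param proteome `AAStringSet` with `genomeID|speciesID|label` names (one
#'   genome), or a FASTA path. May be empty.
#' @param thresholds A [geneThresholds()] object covering every profile.
#' @param dbSize Database size for E-values; defaults to the number of
#'   sequences in the proteome (min 1).
#' @return List with `hits` (data.frame: genome_id, species_id, gene,
#'   sequence_id, bit_score, evalue; best hit per gene) and `presence`
#'   (one-row data.frame: genome_id, species_id, then one logical column per
#'   gene).
#' @export
searchProteome <- function(profiles, proteome, thresholds = geneThresholds(),
                           dbSize = NULL) {
  if (is.character(proteome) && length(proteome) == 1L && file.exists(proteome))
    proteome <- readFastaAA(proteome)
  genes <- names(profiles)
  if (is.null(genes) || any(genes == ""))
    stop("profiles must be a named list (gene names)")
  uncal <- genes[!vapply(profiles, isCalibrated, logical(1))]
  if (length(uncal))
    stop("uncalibrated profile(s): ", paste(uncal, collapse = ", "))
  missing <- setdiff(genes, names(thresholds$evalue_by_gene))
  if (length(missing))
    stop("thresholds missing for gene(s): ", paste(missing, collapse = ", "))

  n <- length(proteome)
  if (n == 0L) {
    pres <- data.frame(genome_id = NA_character_, species_id = NA_character_,
                       stringsAsFactors = FALSE)
    for (g in genes) pres[[g]] <- FALSE
    return(list(hits = .empty_hits(), presence = pres))
  }
  hdr <- .parse_headers(names(proteome))
  if (length(unique(hdr$genome_id)) != 1L)
    stop("searchProteome expects a single genome; use searchGenomes()")
  codes <- .seq_to_codes(proteome)

  hits <- list()
  for (g in genes) {
    prof <- profiles[[g]]
    bits <- cpp_forward_batch(.pack_profile(prof), codes, -1)
    ev <- evalueFromBits(prof, bits,
                         dbSize = if (is.null(dbSize)) max(n, 1L) else dbSize)
    pass <- ev <= thresholds$evalue_by_gene[[g]] &
      bits >= thresholds$min_bit_score
    if (any(pass)) {
      best <- which(pass)[which.max(bits[pass])]
      hits[[g]] <- data.frame(genome_id = hdr$genome_id[best],
                              species_id = hdr$species_id[best],
                              gene = g,
                              sequence_id = hdr$sequence_id[best],
                              bit_score = bits[best], evalue = ev[best],
                              stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else .empty_hits()
  rownames(hits) <- NULL
  dup <- hits$sequence_id[duplicated(hits$sequence_id)]
  if (length(dup))
    warning("sequence(s) retained by more than one profile: ",
            paste(unique(dup), collapse = ", "))
  pres <- data.frame(genome_id = hdr$genome_id[1],
                     species_id = hdr$species_id[1],
                     stringsAsFactors = FALSE)
  for (g in genes) pres[[g]] <- g %in% hits$gene
  list(hits = hits, presence = pres)
}

#' Search many genomes with a profile panel
#'
#' Splits a combined `AAStringSet` (headers `genomeID|speciesID|label`) by
#' genome and runs [searchProteome()] on each.
#'
#' @inheritParams searchProteome
#' @param proteomes Combined `AAStringSet` covering one or more genomes, or
#'   a FASTA path.
#' @return List with `hits` (row-bound hit table) and `presence` (one row
#'   per genome).
#' @export
searchGenomes <- function(profiles, proteomes, thresholds = geneThresholds(),
                          dbSize = NULL) {
  if (is.character(proteomes) && length(proteomes) == 1L &&
      file.exists(proteomes))
    proteomes <- readFastaAA(proteomes)
  if (length(proteomes) == 0L)
    return(searchProteome(profiles, proteomes, thresholds, dbSize))
  hdr <- .parse_headers(names(proteomes))
  by_genome <- split(seq_along(proteomes), hdr$genome_id)
  res <- lapply(by_genome, function(ix) {
    searchProteome(profiles, proteomes[ix], thresholds, dbSize = dbSize)
  })
  hits <- do.call(rbind, c(lapply(res, `[[`, "hits"),
                           list(make.row.names = FALSE)))
  presence <- do.call(rbind, c(lapply(res, `[[`, "presence"),
                               list(make.row.names = FALSE)))
  list(hits = hits, presence = presence)
}

#' Collapse genome-level presence to species level
#'
#' @param presence data.frame from [searchGenomes()] (columns genome_id,
#'   species_id, then logical gene columns).
#' @param rule `"any"` (default): a gene is present in the species if any
#'   genome has it; `"all"`: all genomes must have it; `"majority"`: more
#'   than half must (ties are absent).
#' @return data.frame with one row per species (species_id, n_genomes,
#'   gene columns).
#' @export
collapseToSpecies <- function(presence, rule = c("any", "all", "majority")) {
  rule <- match.arg(rule)
  if (nrow(presence) == 0L) stop("empty presence table")
  genes <- setdiff(names(presence), c("genome_id", "species_id"))
  f <- factor(presence$species_id)
  mat <- sapply(genes, function(g) as.integer(presence[[g]]))
  if (nrow(presence) == 1L)
    mat <- matrix(mat, nrow = 1, dimnames = list(NULL, genes))
  counts <- rowsum(mat, f)                      # hits per species x gene
  n_genomes <- as.integer(table(f))
  res <- data.frame(species_id = levels(f), n_genomes = n_genomes,
                    stringsAsFactors = FALSE)
  for (g in genes) {
    res[[g]] <- switch(rule,
      any = counts[, g] > 0L,
      all = counts[, g] == n_genomes,
      majority = counts[, g] > n_genomes / 2)
  }
  res
}

#' Build and calibrate a profile panel from marker families
#'
#' The seed set of each family is de-redundified with
#' [clusterAtIdentity()] (50% identity by default), the surviving
#' representatives' alignment rows (all-gap columns dropped) feed
#' [buildProfile()], and each profile is calibrated with
#' [calibrateEvalue()].
#'
#' @param families Named list of families from [generateFamily()] (or the
#'   same structure assembled from real data).
#' @param identity Clustering identity threshold (default 0.5).
#' @param cluster Set to `FALSE` to skip de-redundification.
#' @param pseudocount,gapFractionCutoff Passed to [buildProfile()].
#' @param nRandom,seed Passed to [calibrateEvalue()]; profile i uses
#'   `seed + i`.
#' @return Named list of calibrated [ProfileHMM-class] objects.
#' @export
buildMarkerPanel <- function(families, identity = 0.5, cluster = TRUE,
                             pseudocount = 1, gapFractionCutoff = 0.5,
                             nRandom = 2000, seed = 1) {
  genes <- names(families)
  profs <- vector("list", length(genes))
  names(profs) <- genes
  for (i in seq_along(genes)) {
    fam <- families[[genes[i]]]
    aln <- fam$alignment
    keep_ids <- setdiff(names(aln), paste0(fam$gene, "_master"))
    if (cluster && length(keep_ids) > 1L) {
      cl <- clusterAtIdentity(fam$members, threshold = identity)
      keep_ids <- clusterRepresentatives(cl)
    }
    rows <- as.character(aln[keep_ids])
    mat <- do.call(rbind, strsplit(rows, ""))
    allgap <- colSums(mat != "-") == 0L
    rows <- apply(mat[, !allgap, drop = FALSE], 1, paste, collapse = "")
    prof <- buildProfile(rows, pseudocount = pseudocount,
                         gapFractionCutoff = gapFractionCutoff,
                         name = genes[i])
    profs[[i]] <- calibrateEvalue(prof, nRandom = nRandom,
                                  seed = as.integer(seed) + i)
  }
  profs
}
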