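#' Run the full co-conservation pipeline on a synthetic species set
#'
#' Convenience wrapper chaining every stage on generated data with planted
#' ground truth: marker families -> identity clustering -> profile build ->
#' E-value calibration -> proteome search -> species collapse -> pathway
#' calls -> co-occurrence table, plus an accuracy comparison against the
#' planted truth.
#'
#' @param nSpecies Number of synthetic species.
#' @param categoryFreqs Planted category frequencies (default
#'   [defaultCategoryFreqs()]).
#' @param divergence,indelRate,nMembers Family generation parameters.
#' @param nDecoys Shuffled decoys per genome.
#' @param nGenomes Genomes per species.
#' @param identity Clustering threshold for seed de-redundification.
#' @param nRandom Calibration sequences per profile.
#' @param thresholds [geneThresholds()] for hit filtering.
#' @param collapseRule Genome-to-species collapse rule.
#' @param scheme [pathwayScheme()] for pathway calling.
#' @param seed Integer master seed.
#' @return List: `table` (cooccurrenceTable), `calls`, `species_presence`,
#'   `truth`, `gene_accuracy` (fraction of species x gene presence calls
#'   matching the planted truth), `hits`, `panel`.
#' @export
runCoconservationPipeline <- function(nSpecies = 500,
                                      categoryFreqs = defaultCategoryFreqs(),
                                      divergence = 0.2, indelRate = 0.01,
                                      nMembers = 20, nDecoys = 20,
                                      nGenomes = 1, identity = 0.5,
                                      nRandom = 2000,
                                      thresholds = geneThresholds(),
                                      collapseRule = "any",
                                      scheme = pathwayScheme(), seed = 1) {
  seed <- as.integer(seed)
  families <- generateMarkerFamilies(nMembers = nMembers,
                                     divergence = divergence,
                                     indelRate = indelRate, seed = seed)
  set <- generateSpeciesSet(nSpecies, categoryFreqs = categoryFreqs,
                            families = families, nDecoys = nDecoys,
                            nGenomes = nGenomes, seed = seed + 500L)
  panel <- buildMarkerPanel(families, identity = identity,
                            nRandom = nRandom, seed = seed + 1000L)
  search <- searchGenomes(panel, set$proteomes, thresholds)
  sp <- collapseToSpecies(search$presence, rule = collapseRule)
  calls <- callPathways(sp, scheme = scheme)
  tab <- tabulateCooccurrence(calls)

  truth <- set$truth[order(set$truth$species_id), , drop = FALSE]
  spo <- sp[match(truth$species_id, sp$species_id), , drop = FALSE]
  genes <- markerPanel()
  agree <- vapply(genes, function(g) sum(spo[[g]] == truth[[g]]),
                  numeric(1))
  gene_accuracy <- sum(agree) / (nrow(truth) * length(genes))

  list(table = tab, calls = calls, species_presence = sp, truth = truth,
       gene_accuracy = gene_accuracy, hits = search$hits, panel = panel)
}
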