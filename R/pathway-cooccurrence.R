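#' Pathway scheme: marker gene panels and the presence rule
#'
#' Groups the 13 markers into pathway variants: classical naphthoquinone
#' biosynthesis (menB, menC, menF), the futalosine route (mqnA, mqnC, mqnD),
#' ubiquinone biosynthesis (ubiA, ubiC, ubiG), NDH-1 subunits (nuoA, nuoE,
#' nuoJ) and NDH-2 (ndh). A pathway variant is called present when its gene
#' set satisfies the presence rule: `"all"` (default, all representative
#' genes present) or `at_least_k` with `k` via the `k` argument.
#'
#' @param presenceRule `"all"` or `"at_least_k"`.
#' @param k Minimum number of genes when `presenceRule = "at_least_k"`.
#' @return Object of class `pathwayScheme`.
#' @export
pathwayScheme <- function(presenceRule = c("all", "at_least_k"), k = 2) {
  presenceRule <- match.arg(presenceRule)
  if (presenceRule == "at_least_k" && (k < 1 || k > 3))
    stop("k must be between 1 and 3")
  structure(list(
    classical_NQ = c("menB", "menC", "menF"),
    futalosine_NQ = c("mqnA", "mqnC", "mqnD"),
    UQ = c("ubiA", "ubiC", "ubiG"),
    NDH1 = c("nuoA", "nuoE", "nuoJ"),
    NDH2 = "ndh",
    presence_rule = presenceRule,
    k = as.integer(k)
  ), class = "pathwayScheme")
}

#' Call pathway presence per species
#'
#' Applies the presence rule to each pathway's gene set and derives the
#' composite flags and categories: `nq` is true when either the classical
#' or the futalosine route is present; the quinone category is one of
#' NQ-only / UQ-only / both / neither, and likewise for dehydrogenases.
#'
#' @param presence data.frame with a `species_id` column and one logical
#'   column per marker gene (e.g. from [collapseToSpecies()]), or a single
#'   named logical vector covering the panel.
#' @param scheme A [pathwayScheme()].
#' @return data.frame with one row per species: species_id, nq_classical,
#'   nq_futalosine, nq, uq, ndh1, ndh2, quinone_category, dh_category.
#' @examples
#' pres <- setNames(markerPanel() %in% c("mqnA", "mqnC", "mqnD", "ndh"),
#'                  markerPanel())
#' callPathways(pres)
#' @export
callPathways <- function(presence, scheme = pathwayScheme()) {
  if (is.logical(presence) && !is.null(names(presence)))
    presence <- cbind(data.frame(species_id = "species1",
                                 stringsAsFactors = FALSE),
                      as.data.frame(as.list(presence)))
  missing <- setdiff(markerPanel(), names(presence))
  if (length(missing))
    stop("presence table lacks marker column(s): ",
         paste(missing, collapse = ", "))
  n <- nrow(presence)
  mat <- sapply(markerPanel(), function(g) as.logical(presence[[g]]))
  if (n == 1L) mat <- matrix(mat, nrow = 1, dimnames = list(NULL, markerPanel()))
  flag <- function(genes) {
    cnt <- rowSums(mat[, genes, drop = FALSE])
    need <- if (scheme$presence_rule == "all") length(genes)
            else min(scheme$k, length(genes))
    cnt >= need
  }
  out <- data.frame(
    species_id = if ("species_id" %in% names(presence)) presence$species_id
                 else sprintf("species%d", seq_len(n)),
    stringsAsFactors = FALSE)
  out$nq_classical <- flag(scheme$classical_NQ)
  out$nq_futalosine <- flag(scheme$futalosine_NQ)
  out$nq <- out$nq_classical | out$nq_futalosine
  out$uq <- flag(scheme$UQ)
  out$ndh1 <- flag(scheme$NDH1)
  out$ndh2 <- flag(scheme$NDH2)
  out$quinone_category <- ifelse(out$nq & out$uq, "both",
    ifelse(out$nq, "NQ-only", ifelse(out$uq, "UQ-only", "neither")))
  out$dh_category <- ifelse(out$ndh1 & out$ndh2, "both",
    ifelse(out$ndh1, "NDH1-only", ifelse(out$ndh2, "NDH2-only", "neither")))
  out
}

QUINONE_LEVELS <- c("NQ-only", "UQ-only", "both", "neither")
DH_LEVELS <- c("NDH1-only", "NDH2-only", "both", "neither")

#' Tabulate quinone-by-dehydrogenase co-occurrence
#'
#' Counts every species exactly once in a 4 x 4 quinone-category by
#' dehydrogenase-category table and reports the headline fractions:
#' `frac_nq_with_ndh2`, the fraction of NQ-pathway species that also carry
#' NDH-2 (exclusively or together with NDH-1), and `frac_ndh2_with_uq`, the
#' fraction of species in which NDH-2 coexists with UQ. The denominator of
#' the latter is configurable (`"all"` species by default; `"ndh2"` or
#' `"uq"` are reported side by side in any case).
#'
#' @param calls data.frame from [callPathways()].
#' @param uqDenominator `"all"`, `"ndh2"` or `"uq"`.
#' @return Object of class `cooccurrenceTable`: list with `counts` (4 x 4
#'   matrix), `n_species`, `frac_nq_with_ndh2`, `frac_ndh2_with_uq`,
#'   `frac_ndh2_with_uq_by` (all three denominators) and `uq_denominator`.
#'   Fractions with an empty denominator are `NA`.
#' @export
tabulateCooccurrence <- function(calls, uqDenominator = c("all", "ndh2", "uq")) {
  uqDenominator <- match.arg(uqDenominator)
  if (!is.data.frame(calls) || nrow(calls) == 0L)
    stop("need at least one pathway call")
  counts <- table(factor(calls$quinone_category, levels = QUINONE_LEVELS),
                  factor(calls$dh_category, levels = DH_LEVELS))
  counts <- unclass(as.matrix(counts))
  names(dimnames(counts)) <- c("quinone", "dehydrogenase")
  n <- nrow(calls)
  n_nq <- sum(calls$nq)
  n_nq_ndh2 <- sum(calls$nq & calls$ndh2)
  n_ndh2 <- sum(calls$ndh2)
  n_uq <- sum(calls$uq)
  n_ndh2_uq <- sum(calls$ndh2 & calls$uq)
  frac_nq_with_ndh2 <- if (n_nq > 0) n_nq_ndh2 / n_nq else NA_real_
  by <- c(all = n_ndh2_uq / n,
          ndh2 = if (n_ndh2 > 0) n_ndh2_uq / n_ndh2 else NA_real_,
          uq = if (n_uq > 0) n_ndh2_uq / n_uq else NA_real_)
  structure(list(counts = counts, n_species = n,
                 frac_nq_with_ndh2 = frac_nq_with_ndh2,
                 frac_ndh2_with_uq = by[[uqDenominator]],
                 frac_ndh2_with_uq_by = by,
                 n_nq = n_nq, uq_denominator = uqDenominator),
            class = "cooccurrenceTable")
}

#' @export
print.cooccurrenceTable <- function(x, ...) {
  cat(sprintf("Co-occurrence across %d species\n", x$n_species))
  print(x$counts)
  if (is.na(x$frac_nq_with_ndh2))
    cat("NQ species with NDH-2: NA (no NQ species)\n")
  else
    cat(sprintf("NQ species with NDH-2: %.1f%% (of %d NQ species)\n",
                100 * x$frac_nq_with_ndh2, x$n_nq))
  cat(sprintf("NDH-2 coexisting with UQ: %.1f%% (denominator: %s)\n",
              100 * x$frac_ndh2_with_uq, x$uq_denominator))
  invisible(x)
}

#' Recompute co-occurrence statistics from a per-genome search sheet
#'
#' Accepts either layout of a per-genome search-result table:
#' \describe{
#'   \item{wide presence}{columns `genome_id`, `species_id` and one
#'     logical/0-1 column per marker gene;}
#'   \item{long scored hits}{columns `genome_id`, `species_id`, `gene`,
#'     `bit_score`, `evalue` — filtering with `thresholds` is applied
#'     first.}
#' }
#' The table is collapsed to species level, pathway calls are made and the
#' co-occurrence table is tabulated, reporting the rule configuration used.
#'
#' @param sheet data.frame, or path to a CSV/TSV file.
#' @param scheme A [pathwayScheme()].
#' @param thresholds [geneThresholds()], used only for the long layout.
#' @param collapseRule Passed to [collapseToSpecies()].
#' @param uqDenominator Passed to [tabulateCooccurrence()].
#' @return List with `table` (the `cooccurrenceTable`), `calls`,
#'   `species_presence` and `config` (rules used).
#' @export
recomputeFromSheet <- function(sheet, scheme = pathwayScheme(),
                               thresholds = geneThresholds(),
                               collapseRule = "any",
                               uqDenominator = "all") {
  if (is.character(sheet) && length(sheet) == 1L) {
    sep <- if (grepl("\\.csv$", sheet, ignore.case = TRUE)) "," else "\t"
    sheet <- utils::read.table(sheet, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE)
  }
  cols <- names(sheet)
  if (!all(c("genome_id", "species_id") %in% cols))
    stop("unrecognised sheet layout: need 'genome_id' and 'species_id'; ",
         "found columns: ", paste(cols, collapse = ", "))
  wide <- all(markerPanel() %in% cols)
  long <- all(c("gene", "bit_score", "evalue") %in% cols)
  if (!wide && !long)
    stop("unrecognised sheet layout: need either the 13 marker columns ",
         "(wide presence) or gene/bit_score/evalue (long hits); found: ",
         paste(cols, collapse = ", "))
  if (wide) {
    presence <- sheet[, c("genome_id", "species_id", markerPanel())]
    for (g in markerPanel()) presence[[g]] <- as.logical(presence[[g]])
  } else {
    keep <- sheet$gene %in% markerPanel() &
      sheet$evalue <= thresholds$evalue_by_gene[sheet$gene] &
      sheet$bit_score >= thresholds$min_bit_score
    filt <- sheet[keep, , drop = FALSE]
    genomes <- unique(sheet[, c("genome_id", "species_id")])
    presence <- genomes
    for (g in markerPanel())
      presence[[g]] <- genomes$genome_id %in%
        filt$genome_id[filt$gene == g]
  }
  sp <- collapseToSpecies(presence, rule = collapseRule)
  calls <- callPathways(sp, scheme = scheme)
  tab <- tabulateCooccurrence(calls, uqDenominator = uqDenominator)
  list(table = tab, calls = calls, species_presence = sp,
       config = list(presence_rule = scheme$presence_rule,
                     collapse_rule = collapseRule,
                     uq_denominator = uqDenominator))
}

#' Sweep rule configurations for the headline statistics
#'
#' Recomputes the co-occurrence table under every combination of presence
#' rule (`all`, `at_least_2`), collapse rule (`any`, `majority`, `all`) and
#' denominator choice for the NDH-2-with-UQ fraction, reporting the
#' headline fractions for each; used to identify which configuration
#' matches externally reported values.
#'
#' @inheritParams recomputeFromSheet
#' @return data.frame with one row per configuration.
#' @export
ruleSensitivitySweep <- function(sheet, thresholds = geneThresholds()) {
  grid <- expand.grid(presence_rule = c("all", "at_least_2"),
                      collapse_rule = c("any", "majority", "all"),
                      uq_denominator = c("all", "ndh2", "uq"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sch <- if (grid$presence_rule[i] == "all") pathwayScheme("all") else
      pathwayScheme("at_least_k", k = 2)
    r <- recomputeFromSheet(sheet, scheme = sch, thresholds = thresholds,
                            collapseRule = grid$collapse_rule[i],
                            uqDenominator = grid$uq_denominator[i])
    data.frame(grid[i, , drop = FALSE],
               n_species = r$table$n_species,
               frac_nq_with_ndh2 = r$table$frac_nq_with_ndh2,
               frac_ndh2_with_uq = r$table$frac_ndh2_with_uq,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}
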