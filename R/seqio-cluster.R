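#' Read and write protein FASTA
#'
#' Thin wrappers around Biostrings keeping the package's header dialect
#' (`>genomeID|speciesID|label`) intact.
#'
#' @param file Path to a (plain-text) FASTA file.
#' @return `readFastaAA()` returns an `AAStringSet`.
#' @export
readFastaAA <- function(file) {
  Biostrings::readAAStringSet(file)
}

#' @rdname readFastaAA
#' @param x `AAStringSet` (gapped or ungapped).
#' @export
writeFastaAA <- function(x, file) {
  Biostrings::writeXStringSet(x, filepath = file)
  invisible(file)
}

#' Read a Stockholm alignment
#'
#' Minimal Stockholm 1.0 reader: sequence lines are concatenated across
#' blocks, markup (`#=GF`, `#=GC`, ...) is skipped, and `.` gaps are
#' normalised to `-`. Column structure is preserved.
#'
#' @param file Path to a Stockholm file.
#' @return Gapped `AAStringSet` (equal widths).
#' @export
readStockholm <- function(file) {
  lines <- readLines(file)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
    stop("not a Stockholm file (missing '# STOCKHOLM' header)")
  seqs <- list()
  for (ln in lines[-1]) {
    if (grepl("^//", ln)) break
    if (ln == "" || grepl("^#", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) next
    id <- parts[1]
    seqs[[id]] <- paste0(if (is.null(seqs[[id]])) "" else seqs[[id]], parts[2])
  }
  if (!length(seqs)) stop("no sequences found in Stockholm file")
  out <- toupper(gsub("\\.", "-", unlist(seqs)))
  if (length(unique(nchar(out))) != 1L)
    stop("Stockholm alignment rows have unequal widths")
  Biostrings::AAStringSet(out)
}

#' Pairwise sequence identity for clustering
#'
#' Fraction of identical aligned residue pairs in one optimal global
#' alignment (BLOSUM62, affine gaps), divided by the length of the shorter
#' sequence (the CD-HIT convention). Symmetric in its arguments.
#'
#' @param a,b Protein sequences (character or `AAString`).
#' @param substitutionMatrix Name of the scoring matrix (default
#'   `"BLOSUM62"`).
#' @param gapOpening,gapExtension Affine gap penalties (defaults 11 and 1).
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwiseIdentity("AAAA", "AAAT")  # 0.75
#' @export
pairwiseIdentity <- function(a, b, substitutionMatrix = "BLOSUM62",
                             gapOpening = 11, gapExtension = 1) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension,
    type = "global")
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Greedy identity-threshold clustering
#'
#' De-redundifies a sequence set the way seed sets are thinned before
#' profile building: sequences are visited longest first (ties broken by id,
#' ascending) and each joins the first existing representative it matches at
#' `identity >= threshold`, otherwise it founds a new cluster. Every
#' representative therefore has identity below the threshold to all earlier
#' representatives.
#'
#' @param seqs Named `AAStringSet` or named character vector (unique ids).
#' @param threshold Identity threshold in `(0, 1]` (0.5 removes redundancy
#'   at 50% identity).
#' @param ... Passed to [pairwiseIdentity()].
#' @return A [SeqClustering-class]: representatives plus member assignments.
#' @export
clusterAtIdentity <- function(seqs, threshold = 0.5, ...) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (length(seqs) < 1L) stop("need at least one sequence")
  ids <- names(seqs)
  if (is.null(ids) || any(ids == "") || anyDuplicated(ids))
    stop("sequences must carry unique non-empty ids")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  ord <- order(-nchar(seqs), ids)
  rep_ids <- character(0)
  assignment <- setNames(character(length(seqs)), ids)
  for (i in ord) {
    id <- ids[i]
    placed <- FALSE
    for (r in rep_ids) {
      if (pairwiseIdentity(seqs[[i]], seqs[[r]], ...) >= threshold) {
        assignment[id] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_ids <- c(rep_ids, id)
      assignment[id] <- id
    }
  }
  methods::new("SeqClustering",
               representatives = rep_ids,
               assignment = assignment,
               threshold = threshold)
}

#' SeqClustering: result of greedy identity clustering
#'
#' @slot representatives Character vector of representative ids, in founding
#'   order.
#' @slot assignment Named character vector mapping every input id to its
#'   representative id.
#' @slot threshold The identity threshold used.
#' @seealso [clusterAtIdentity()]
#' @export
setClass("SeqClustering",
  representation(representatives = "character",
                 assignment = "character",
                 threshold = "numeric"))

setValidity("SeqClustering", function(object) {
  msgs <- character()
  if (!all(object@representatives %in% object@assignment))
    msgs <- c(msgs, "every representative must be assigned to itself")
  if (!all(object@assignment %in% object@representatives))
    msgs <- c(msgs, "every member must map to a representative")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SeqClustering Cluster membership as a list of id vectors,
#'   one per representative.
#' @param x A `SeqClustering`.
#' @export
clusterMembers <- function(x) {
  split(names(x@assignment),
        factor(x@assignment, levels = x@representatives))
}

#' @describeIn SeqClustering Representative ids.
#' @export
clusterRepresentatives <- function(x) x@representatives

setMethod("show", "SeqClustering", function(object) {
  cat(sprintf("SeqClustering: %d sequences in %d clusters (threshold %.2f)\n",
              length(object@assignment), length(object@representatives),
              object@threshold))
  invisible(NULL)
})
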