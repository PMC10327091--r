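#' Taxonomic groups prevalent in temperate coastal bloom communities
#'
#' The classes and divisions commonly configured for 18S-based assignment
#' of 3-20 um plankton fractions. \code{assignContigTaxon} defaults to the
#' groups present in the supplied reference databases (so synthetic taxa
#' work unchanged); pass this list to reproduce the field-standard grouping
#' on real references.
#' @return character vector of group names
#' @export
defaultTaxonGroups <- function()
  c("Bacillariophyta", "Prymnesiophyceae", "Chrysophyceae", "MAST-3",
    "Katablepharidaceae", "Pseudofungi", "Lobosa", "Ciliphora",
    "Dinoflagellata", "Cercozoa")

#' Assign a taxonomic group to contigs by thresholded best-hit 18S homology
#'
#' Each contig of at least \code{minLen} nt is searched against every 18S
#' reference database; per database only the single top-bitscore hit passing
#' the identity / E-value / length gates is kept. If all kept hits agree on
#' one group the contig gets that group; hits spanning two or more groups
#' make it "nonspecific"; a kept hit whose group is outside the configured
#' group list yields "other_eukaryote"; no passing hit (or a sub-length
#' contig) yields "unassigned". Setting \code{allHits = TRUE} applies the
#' multi-group rule to all passing hits rather than per-database best hits.
#'
#' @param contigs DNAStringSet (mcols$cell gives the cell of origin) or a
#'   single character string
#' @param refDbs list of DNAStringSets, each with \code{mcols()$group}
#' @param groups configured group list; hits outside it become
#'   "other_eukaryote" (default: all groups present in the databases)
#' @param minIdentity,maxEvalue,minLen gates (defaults 99, 1e-10, 100)
#' @param allHits apply the conflict rule to all passing hits
#' @return data.frame: cell, contig_id, group, best_identity, best_bitscore
#' @export
assignContigTaxon <- function(contigs, refDbs, groups = NULL,
                              minIdentity = 99, maxEvalue = 1e-10,
                              minLen = 100L, allHits = FALSE) {
  if (is.character(contigs)) {
    nm <- if (!is.null(names(contigs))) names(contigs) else
      paste0("contig", seq_along(contigs))
    contigs <- DNAStringSet(setNames(contigs, nm))
  }
  if (!length(refDbs) || !sum(lengths(refDbs)))
    stop("empty reference databases")
  if (is.null(groups))
    groups <- unique(unlist(lapply(refDbs, function(d) mcols(d)$group)))
  cells <- if (!is.null(mcols(contigs)$cell)) mcols(contigs)$cell else
    rep(NA_character_, length(contigs))
  out <- data.frame(
    cell = cells, contig_id = names(contigs),
    group = "unassigned", best_identity = NA_real_,
    best_bitscore = NA_real_, stringsAsFactors = FALSE)
  long <- which(width(contigs) >= minLen)
  if (!length(long)) return(out)
  qseqs <- setNames(as.character(contigs[long]), names(contigs)[long])
  kept <- list()
  for (db in refDbs) {
    hits <- .searchNucleotideBatch(qseqs, db, minIdentity, maxEvalue, minLen)
    if (!nrow(hits)) next
    if (!allHits) hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
    kept[[length(kept) + 1L]] <- hits
  }
  if (!length(kept)) return(out)
  hits <- do.call(rbind, kept)
  for (q in unique(hits$query_id)) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    grp <- unique(h$group_label)
    i <- match(q, out$contig_id)
    out$best_identity[i] <- max(h$identity)
    out$best_bitscore[i] <- max(h$bit_score)
    out$group[i] <- if (length(grp) > 1L) "nonspecific"
      else if (!grp %in% groups) "other_eukaryote" else grp
  }
  out
}

#' Cell-level taxonomy from contig calls with conservative conflict omission
#'
#' Nonspecific and unassigned contigs are ignored. A cell whose remaining
#' contigs name exactly one group gets that group ("other_eukaryote" counts
#' as a group); cells with no informative contig are "unassigned"; cells
#' whose specific contigs span two or more groups are conservatively
#' "omitted". A cell-level group call therefore never contradicts any of
#' its specific contig calls.
#'
#' @param contigCalls data.frame from \code{\link{assignContigTaxon}}
#'   (column \code{cell} identifies the cell)
#' @param cellBarcodes cells to report (default: those present)
#' @return data.frame: barcode, group, n_supporting_contigs
#' @export
assignCellTaxon <- function(contigCalls, cellBarcodes = NULL) {
  if (is.null(cellBarcodes)) cellBarcodes <- unique(contigCalls$cell)
  specific <- contigCalls[!contigCalls$group %in% c("nonspecific", "unassigned"), ,
                      drop = FALSE]
  res <- lapply(cellBarcodes, function(bc) {
    g <- specific$group[specific$cell == bc]
    ug <- unique(g)
    grp <- if (length(ug) == 0L) "unassigned"
      else if (length(ug) == 1L) ug else "omitted"
    data.frame(barcode = bc, group = grp,
               n_supporting_contigs = length(g), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Identify a pooled subpopulation at relaxed identity
#'
#' Pools the reads of a set of cells (for example all infected cells of a
#' rare class from one sample), assembles them jointly, and aligns the
#' resulting contigs against a reference database at a relaxed identity
#' gate (default 90\%). Reports per reference species the best identity and
#' the number of supporting contigs, ranked by identity.
#'
#' @param cellBarcodes barcodes of the pooled cells (>= 1)
#' @param reads a \linkS4class{ReadPairSet}
#' @param refDb DNAStringSet with \code{mcols()$group}
#' @param minIdentity,maxEvalue,minLen gates (defaults 90, 1e-10, 100)
#' @param minOverlap assembly overlap (default 21)
#' @return data.frame: subject_id, group, best_identity, best_bitscore,
#'   n_contigs, ranked by identity (then bitscore) descending
#' @export
identifyPooledSubpopulation <- function(cellBarcodes, reads, refDb,
                                        minIdentity = 90, maxEvalue = 1e-10,
                                        minLen = 100L, minOverlap = 21L) {
  if (length(cellBarcodes) == 0L) stop("empty cell set")
  pooled <- reads[barcodes(reads) %in% cellBarcodes]
  trimmed <- trimReads(pooled)
  contigs <- greedyAssemble(cdnaSeqs(trimmed), minOverlap, barcode = "pooled")
  contigs <- contigs[width(contigs) >= minLen]
  empty <- data.frame(subject_id = character(0), group = character(0),
                      best_identity = numeric(0), best_bitscore = numeric(0),
                      n_contigs = integer(0), stringsAsFactors = FALSE)
  if (!length(contigs)) {
    warning("no contigs of length >= ", minLen, " from pooled assembly")
    return(empty)
  }
  hits <- .searchNucleotideBatch(
    setNames(as.character(contigs), names(contigs)), refDb,
    minIdentity, maxEvalue, minLen)
  if (!nrow(hits)) return(empty)
  agg <- do.call(rbind, lapply(split(hits, hits$subject_id), function(h)
    data.frame(subject_id = h$subject_id[1L], group = h$group_label[1L],
               best_identity = max(h$identity),
               best_bitscore = max(h$bit_score),
               n_contigs = length(unique(h$query_id)),
               stringsAsFactors = FALSE)))
  agg <- agg[order(-agg$best_identity, -agg$best_bitscore, agg$subject_id), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}
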