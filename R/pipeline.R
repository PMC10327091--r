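#' Run the full infected-cell detection and host-virus pairing pipeline
#'
#' screen -> assemble -> assign -> pair: counts viral marker UMIs per cell,
#' calls highly infected cells, profiles their viral reads by family,
#' assembles the highly infected cells' reads into contigs, assigns host
#' taxonomy by best-hit 18S homology with conflict omission, and builds the
#' host-virus pair table (optionally excluding the dominant family's
#' cells).
#'
#' @param reads a \linkS4class{ReadPairSet}
#' @param refs a \linkS4class{ReferenceSet}
#' @param dominantFamily family excluded from the pair table (NULL: none)
#' @param minAAScore translated-search threshold (default 60)
#' @param groups configured taxonomic group list (default: the reference
#'   taxa)
#' @return list(viralTable, calls, profileCounts, profiles, contigs,
#'   contigCalls, taxonomy, pairs, summary)
#' @export
runPairingPipeline <- function(reads, refs, dominantFamily = NULL,
                               minAAScore = 60L, groups = NULL) {
  trimmed <- trimReads(reads)
  viralTable <- countViralUMIs(trimmed, refs, minAAScore = minAAScore)
  calls <- callHighlyInfected(viralTable)
  hi <- calls$barcode[calls$highly_infected]
  prof <- viralReadProfiles(reads, viralProteins(refs),
                            minAAScore = minAAScore, cellBarcodes = hi)
  contigs <- assembleCells(reads, cellBarcodes = hi)
  contigCalls <- assignContigTaxon(contigs, refDbList(refs), groups = groups)
  taxonomy <- assignCellTaxon(contigCalls, cellBarcodes = hi)
  pt <- buildPairTable(calls, prof$counts, prof$profiles, taxonomy,
                       dominantFamily = dominantFamily)
  list(viralTable = viralTable, calls = calls,
       profileCounts = prof$counts, profiles = prof$profiles,
       contigs = contigs, contigCalls = contigCalls, taxonomy = taxonomy,
       pairs = pt$pairs, summary = pt$summary)
}
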