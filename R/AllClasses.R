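#' Paired droplet reads
#'
#' Container for barcode/UMI/cDNA read triplets from paired FASTQ input
#' (R1 carries the 16-nt cell barcode followed by a 12-nt UMI; R2 carries
#' the cDNA). Fresh reads are 60 nt; poly-A trimming may shorten the cDNA
#' (never below 30 nt, shorter reads are dropped).
#'
#' @slot barcode character, 16-nt cell barcodes
#' @slot umi character, 12-nt unique molecular identifiers
#' @slot cdna character, cDNA sequences over ACGTN
#' @slot readId character, unique read identifiers
#' @export
setClass("ReadPairSet", representation(
  barcode = "character", umi = "character",
  cdna = "character", readId = "character"
))

setValidity("ReadPairSet", function(object) {
  n <- length(object@barcode)
  if (length(object@umi) != n || length(object@cdna) != n ||
      length(object@readId) != n)
    return("slots must have equal length")
  if (n == 0L) return(TRUE)
  if (any(nchar(object@barcode) != 16L)) return("barcodes must be 16 nt")
  if (any(nchar(object@umi) != 12L)) return("UMIs must be 12 nt")
  nc <- nchar(object@cdna)
  if (any(nc < 1L | nc > 60L)) return("cDNA must be 1-60 nt")
  if (any(grepl("[^ACGTN]", object@cdna))) return("cDNA must be over ACGTN")
  TRUE
})

#' Construct a ReadPairSet
#' @param barcode,umi,cdna,readId character vectors of equal length
#' @return a \linkS4class{ReadPairSet}
#' @export
ReadPairSet <- function(barcode = character(), umi = character(),
                        cdna = character(), readId = character()) {
  new("ReadPairSet", barcode = as.character(barcode), umi = as.character(umi),
      cdna = as.character(cdna), readId = as.character(readId))
}

#' @describeIn ReadPairSet number of read pairs
#' @param x a ReadPairSet
#' @export
setMethod("length", "ReadPairSet", function(x) length(x@barcode))

#' @export
setMethod("[", "ReadPairSet", function(x, i, j, ..., drop = TRUE) {
  new("ReadPairSet", barcode = x@barcode[i], umi = x@umi[i],
      cdna = x@cdna[i], readId = x@readId[i])
})

setMethod("show", "ReadPairSet", function(object) {
  cat("ReadPairSet with", length(object), "read pairs,",
      length(unique(object@barcode)), "barcodes\n")
})

#' Labelled reference sequence collections
#'
#' Holds the four reference sets the pipeline aligns against: host 18S rRNA
#' analogs (grouped by taxon and source database), host mRNA transcripts,
#' viral marker genes (nucleotide) and their translated proteins. Viral
#' records carry gene name, virus family and virus id in \code{mcols}.
#'
#' @slot host18S DNAStringSet with mcols \code{group}, \code{db}
#' @slot hostMRNA DNAStringSet with mcols \code{taxon}
#' @slot viralGenes DNAStringSet with mcols \code{family}, \code{gene},
#'   \code{virus_id}
#' @slot viralProteins AAStringSet parallel to \code{viralGenes}
#' @export
setClass("ReferenceSet", representation(
  host18S = "DNAStringSet", hostMRNA = "DNAStringSet",
  viralGenes = "DNAStringSet", viralProteins = "AAStringSet"
))

setValidity("ReferenceSet", function(object) {
  if (!identical(names(object@viralGenes), names(object@viralProteins)))
    return("viralGenes and viralProteins must be parallel")
  for (sl in c("host18S", "hostMRNA", "viralGenes")) {
    nm <- names(slot(object, sl))
    if (length(nm) && anyDuplicated(nm)) return(paste("duplicate ids in", sl))
  }
  if (length(object@host18S) && is.null(mcols(object@host18S)$group))
    return("host18S must carry mcols$group")
  if (length(object@viralGenes) && is.null(mcols(object@viralGenes)$family))
    return("viralGenes must carry mcols$family")
  TRUE
})

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet:",
      length(object@host18S), "18S analogs (",
      length(unique(mcols(object@host18S)$group)), "taxa ),",
      length(object@hostMRNA), "host mRNAs,",
      length(object@viralGenes), "viral marker genes (",
      length(unique(mcols(object@viralGenes)$family)), "families )\n")
})

#' Sparse per-cell UMI count table
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"counts"}
#' (genes x cells, sparse, non-negative integers) and a \code{source} tag per
#' gene (\code{"viral-marker"}, \code{"host"} or \code{"custom"}).
#'
#' @export
setClass("CellUMITable", contains = "SummarizedExperiment")

#' Construct a CellUMITable
#' @param counts sparse or dense genes x cells matrix of non-negative counts
#'   with unique dimnames
#' @param geneSource character vector per gene: "viral-marker", "host" or
#'   "custom"
#' @return a \linkS4class{CellUMITable}
#' @export
CellUMITable <- function(counts, geneSource = rep("custom", nrow(counts))) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(source = as.character(geneSource))
  )
  new("CellUMITable", se)
}

setValidity("CellUMITable", function(object) {
  m <- assay(object, "counts")
  if (any(m@x < 0)) return("counts must be non-negative")
  if (anyDuplicated(colnames(m))) return("duplicate barcodes")
  if (anyDuplicated(rownames(m))) return("duplicate genes")
  src <- rowData(object)$source
  if (is.null(src)) return("gene source tag missing")
  if (!all(src %in% c("viral-marker", "host", "custom")))
    return("gene source must be viral-marker, host or custom")
  TRUE
})

#' Planted simulation ground truth
#'
#' Per-cell record of the synthetic community (taxon, infecting family if
#' any, doublet status, number of viral molecules) and, in time-series mode,
#' the per-day community composition.
#'
#' @slot cells data.frame with columns barcode, taxon, taxon2, infected,
#'   family, doublet, true_viral_umis
#' @slot days data.frame with columns day, taxon, cells (may be empty)
#' @export
setClass("GroundTruth", representation(cells = "data.frame", days = "data.frame"))

setValidity("GroundTruth", function(object) {
  cl <- object@cells
  if (nrow(cl)) {
    need <- c("barcode", "taxon", "taxon2", "infected", "family", "doublet",
              "true_viral_umis")
    if (!all(need %in% names(cl))) return("missing ground-truth columns")
    if (anyDuplicated(cl$barcode)) return("barcodes must be unique")
    if (any(cl$infected & is.na(cl$family)))
      return("infected cells must carry a family")
    if (any(cl$doublet & is.na(cl$taxon2)))
      return("doublet cells must carry two taxa")
  }
  TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@cells), "cells,",
      sum(object@cells$infected), "infected,",
      sum(object@cells$doublet), "doublets\n")
})

#' Two-dimensional community embedding
#'
#' @slot barcodes character, cell barcodes
#' @slot coords numeric matrix, n x 2 embedding coordinates
#' @slot taxonLabels character per cell (NA where unassigned)
#' @slot infectedFlags logical per cell (>= 10 viral UMIs)
#' @export
setClass("EmbeddingResult", representation(
  barcodes = "character", coords = "matrix",
  taxonLabels = "character", infectedFlags = "logical"
))

setValidity("EmbeddingResult", function(object) {
  n <- length(object@barcodes)
  if (nrow(object@coords) != n || ncol(object@coords) != 2L)
    return("coords must be n x 2")
  if (any(!is.finite(object@coords))) return("coords must be finite")
  if (length(object@taxonLabels) != n || length(object@infectedFlags) != n)
    return("labels/flags length mismatch")
  TRUE
})

setMethod("show", "EmbeddingResult", function(object) {
  cat("EmbeddingResult:", length(object@barcodes), "cells,",
      sum(object@infectedFlags, na.rm = TRUE), "infected (>=10 viral UMIs)\n")
})

#' Synthetic community configuration
#'
#' Study conditions for the generator: community composition with one
#' dominant bloomer and a rare class, planted infections per (taxon, family)
#' with their expression levels, ambient viral background, doublet rate and
#' sequencing depth. One integer seed fully determines all generator output.
#'
#' @slot taxonNames character
#' @slot taxonCellFractions numeric simplex weights (sum to 1)
#' @slot dominantTaxon character scalar
#' @slot familyNames character, viral family labels
#' @slot markerGenesPerFamily integer >= 4
#' @slot infectionTable data.frame: taxon, family, frac_infected,
#'   expr_fraction
#' @slot ambientViralRate numeric, per-read ambient probability in
#'   uninfected cells
#' @slot doubletRate numeric fraction of cells
#' @slot nCells integer
#' @slot readsPerCell numeric c(meanlog, sdlog) of the log-normal depth
#' @slot seed integer
#' @export
setClass("CommunityConfig", representation(
  taxonNames = "character", taxonCellFractions = "numeric",
  dominantTaxon = "character", familyNames = "character",
  markerGenesPerFamily = "integer", infectionTable = "data.frame",
  ambientViralRate = "numeric", doubletRate = "numeric",
  nCells = "integer", readsPerCell = "numeric", seed = "integer"
))

setValidity("CommunityConfig", function(object) {
  f <- object@taxonCellFractions
  if (length(f) != length(object@taxonNames))
    return("one cell fraction per taxon required")
  if (any(f < 0 | f > 1)) return("fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9) return("cell fractions must sum to 1")
  if (!object@dominantTaxon %in% object@taxonNames)
    return("dominant taxon must be one of the taxa")
  if (object@markerGenesPerFamily < 4L)
    return("at least 4 marker genes per family required")
  it <- object@infectionTable
  if (nrow(it)) {
    if (!all(c("taxon", "family", "frac_infected", "expr_fraction") %in%
             names(it))) return("malformed infection table")
    if (!all(it$taxon %in% object@taxonNames)) return("unknown taxon in infection table")
    if (!all(it$family %in% object@familyNames)) return("unknown family in infection table")
    if (any(it$frac_infected < 0 | it$frac_infected > 1 |
            it$expr_fraction < 0 | it$expr_fraction > 1))
      return("infection fractions must lie in [0, 1]")
  }
  if (object@ambientViralRate < 0 || object@ambientViralRate > 1 ||
      object@doubletRate < 0 || object@doubletRate > 1)
    return("rates must lie in [0, 1]")
  if (object@nCells < 0L) return("nCells must be >= 0")
  TRUE
})

setMethod("show", "CommunityConfig", function(object) {
  cat("CommunityConfig:", length(object@taxonNames), "taxa,",
      length(object@familyNames), "viral families,",
      object@nCells, "cells, seed", object@seed, "\n")
})
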