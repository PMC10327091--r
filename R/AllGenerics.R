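#' @name virolink-accessors
#' @title Accessors for virolink classes
#' @param x an object
#' @description Slot accessors for the package's S4 containers.
NULL

#' @rdname virolink-accessors
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))
#' @rdname virolink-accessors
#' @export
setGeneric("umis", function(x) standardGeneric("umis"))
#' @rdname virolink-accessors
#' @export
setGeneric("cdnaSeqs", function(x) standardGeneric("cdnaSeqs"))
#' @rdname virolink-accessors
#' @export
setGeneric("readIds", function(x) standardGeneric("readIds"))
#' @rdname virolink-accessors
#' @export
setGeneric("umiCounts", function(x) standardGeneric("umiCounts"))
#' @rdname virolink-accessors
#' @export
setGeneric("geneSource", function(x) standardGeneric("geneSource"))
#' @rdname virolink-accessors
#' @export
setGeneric("totalUMIs", function(x) standardGeneric("totalUMIs"))
#' @rdname virolink-accessors
#' @export
setGeneric("viralUMIs", function(x) standardGeneric("viralUMIs"))
#' @rdname virolink-accessors
#' @export
setGeneric("host18S", function(x) standardGeneric("host18S"))
#' @rdname virolink-accessors
#' @export
setGeneric("hostMRNA", function(x) standardGeneric("hostMRNA"))
#' @rdname virolink-accessors
#' @export
setGeneric("viralGenes", function(x) standardGeneric("viralGenes"))
#' @rdname virolink-accessors
#' @export
setGeneric("viralProteins", function(x) standardGeneric("viralProteins"))
#' @rdname virolink-accessors
#' @export
setGeneric("truthCells", function(x) standardGeneric("truthCells"))
#' @rdname virolink-accessors
#' @export
setGeneric("truthDays", function(x) standardGeneric("truthDays"))
#' @rdname virolink-accessors
#' @export
setGeneric("embeddingCoords", function(x) standardGeneric("embeddingCoords"))
#' @rdname virolink-accessors
#' @export
setGeneric("taxonLabels", function(x) standardGeneric("taxonLabels"))
#' @rdname virolink-accessors
#' @export
setGeneric("infectedFlags", function(x) standardGeneric("infectedFlags"))

#' @rdname virolink-accessors
#' @export
setMethod("barcodes", "ReadPairSet", function(x) x@barcode)
#' @rdname virolink-accessors
#' @export
setMethod("umis", "ReadPairSet", function(x) x@umi)
#' @rdname virolink-accessors
#' @export
setMethod("cdnaSeqs", "ReadPairSet", function(x) x@cdna)
#' @rdname virolink-accessors
#' @export
setMethod("readIds", "ReadPairSet", function(x) x@readId)

#' @rdname virolink-accessors
#' @export
setMethod("barcodes", "CellUMITable", function(x) colnames(x))
#' @rdname virolink-accessors
#' @export
setMethod("umiCounts", "CellUMITable", function(x) assay(x, "counts"))
#' @rdname virolink-accessors
#' @export
setMethod("geneSource", "CellUMITable",
          function(x) setNames(rowData(x)$source, rownames(x)))
#' @rdname virolink-accessors
#' @export
setMethod("totalUMIs", "CellUMITable",
          function(x) setNames(Matrix::colSums(assay(x, "counts")), colnames(x)))
#' @rdname virolink-accessors
#' @export
setMethod("viralUMIs", "CellUMITable", function(x) {
  m <- assay(x, "counts")[rowData(x)$source == "viral-marker", , drop = FALSE]
  setNames(Matrix::colSums(m), colnames(x))
})

#' @rdname virolink-accessors
#' @export
setMethod("host18S", "ReferenceSet", function(x) x@host18S)
#' @rdname virolink-accessors
#' @export
setMethod("hostMRNA", "ReferenceSet", function(x) x@hostMRNA)
#' @rdname virolink-accessors
#' @export
setMethod("viralGenes", "ReferenceSet", function(x) x@viralGenes)
#' @rdname virolink-accessors
#' @export
setMethod("viralProteins", "ReferenceSet", function(x) x@viralProteins)

#' @rdname virolink-accessors
#' @export
setMethod("truthCells", "GroundTruth", function(x) x@cells)
#' @rdname virolink-accessors
#' @export
setMethod("truthDays", "GroundTruth", function(x) x@days)

#' @rdname virolink-accessors
#' @export
setMethod("barcodes", "EmbeddingResult", function(x) x@barcodes)
#' @rdname virolink-accessors
#' @export
setMethod("embeddingCoords", "EmbeddingResult", function(x) x@coords)
#' @rdname virolink-accessors
#' @export
setMethod("taxonLabels", "EmbeddingResult", function(x) x@taxonLabels)
#' @rdname virolink-accessors
#' @export
setMethod("infectedFlags", "EmbeddingResult", function(x) x@infectedFlags)
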