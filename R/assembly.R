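#' Pool reads by cell barcode
#'
#' @param reads a \linkS4class{ReadPairSet}
#' @param barcode a single 16-nt barcode
#' @return the reads carrying exactly that barcode, input order preserved
#' @export
poolReadsByBarcode <- function(reads, barcode) {
  reads[barcodes(reads) == barcode]
}

#' Trim poly-A tails and drop short reads
#'
#' Removes from the 3' end of each cDNA a trailing adenosine run of total
#' length >= 10, allowing one embedded non-A interruption. 5' A-runs are
#' untouched. Reads shorter than 30 nt after trimming are dropped.
#'
#' @param reads a \linkS4class{ReadPairSet}
#' @param minRun minimum tail length to trim (default 10)
#' @param minLen minimum surviving read length (default 30)
#' @return the trimmed \linkS4class{ReadPairSet}
#' @export
trimReads <- function(reads, minRun = 10L, minLen = 30L) {
  trimmed <- .trim_polya_cpp(cdnaSeqs(reads), as.integer(minRun))
  keep <- nchar(trimmed) >= minLen
  new("ReadPairSet", barcode = barcodes(reads)[keep],
      umi = umis(reads)[keep], cdna = trimmed[keep],
      readId = readIds(reads)[keep])
}

#' Greedy suffix-prefix assembly of short reads
#'
#' Iteratively merges the pair of sequences with the longest exact
#' suffix-prefix overlap of at least \code{minOverlap} nt, considering both
#' orientations of every sequence; ties pick the lexicographically smallest
#' merged sequence, which makes the output independent of input order.
#' Contigs are reported in canonical orientation (lexicographic minimum of
#' the sequence and its reverse complement), sorted by decreasing length.
#' In the error-free no-indel regime every constituent read is an exact
#' substring of its contig.
#'
#' @param sequences character vector of reads, or a
#'   \linkS4class{ReadPairSet}
#' @param minOverlap minimum exact overlap (default 21, echoing the smaller
#'   assembly k-mer used on real data)
#' @param minContigLen shortest contig reported (default 60)
#' @param barcode contig id prefix (default "cell")
#' @return a \code{DNAStringSet} of contigs; \code{mcols} carries
#'   \code{n_reads} and \code{cell}; \code{metadata()$unplaced_reads}
#'   counts reads in sub-length fragments, so that
#'   \code{sum(n_reads) + unplaced_reads} equals the input read count
#' @export
greedyAssemble <- function(sequences, minOverlap = 21L, minContigLen = 60L,
                           barcode = "cell") {
  if (is(sequences, "ReadPairSet")) sequences <- cdnaSeqs(sequences)
  res <- .greedy_assemble_cpp(as.character(sequences),
                              as.integer(minOverlap),
                              as.integer(minContigLen))
  contigs <- DNAStringSet(res$sequence)
  if (length(contigs))
    names(contigs) <- paste0(barcode, "_c", seq_along(contigs))
  mcols(contigs) <- DataFrame(
    cell = rep(barcode, length(contigs)),
    n_reads = res$n_reads,
    description = metaDescription(cell = rep(barcode, length(contigs)),
                                  n_reads = res$n_reads))
  metadata(contigs)$unplaced_reads <- res$unplaced_reads
  contigs
}

#' Per-cell pooling, trimming and assembly
#'
#' Runs \code{\link{poolReadsByBarcode}}, \code{\link{trimReads}} and
#' \code{\link{greedyAssemble}} for each requested barcode and concatenates
#' the per-cell contigs.
#'
#' @param reads a \linkS4class{ReadPairSet}
#' @param cellBarcodes barcodes to assemble (default: all present)
#' @param minOverlap,minContigLen passed to \code{\link{greedyAssemble}}
#' @return a combined contig \code{DNAStringSet} with per-cell metadata
#' @export
assembleCells <- function(reads, cellBarcodes = NULL, minOverlap = 21L,
                          minContigLen = 60L) {
  if (is.null(cellBarcodes)) cellBarcodes <- unique(barcodes(reads))
  trimmed <- trimReads(reads)
  idx <- split(seq_along(trimmed@barcode), trimmed@barcode)
  out <- vector("list", length(cellBarcodes))
  unplaced <- 0
  for (k in seq_along(cellBarcodes)) {
    bc <- cellBarcodes[k]
    sel <- idx[[bc]]
    cs <- greedyAssemble(trimmed@cdna[sel], minOverlap, minContigLen,
                         barcode = bc)
    unplaced <- unplaced + metadata(cs)$unplaced_reads
    out[[k]] <- cs
  }
  combined <- if (length(out)) do.call(c, out) else DNAStringSet()
  metadata(combined)$unplaced_reads <- unplaced
  combined
}
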