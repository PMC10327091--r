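#' Read paired barcode/cDNA FASTQ files
#'
#' R1 entries must be exactly 28 nt (16-nt cell barcode + 12-nt UMI); R2
#' carries the 60-nt cDNA. Files must have equal record counts and matching
#' read ids (first whitespace-separated token, ignoring a trailing /1 or /2).
#' Order is preserved.
#'
#' @param pathR1,pathR2 FASTQ paths
#' @return a \linkS4class{ReadPairSet}
#' @export
readPairedFastq <- function(pathR1, pathR2) {
  r1 <- Biostrings::readBStringSet(pathR1, format = "fastq")
  r2 <- Biostrings::readBStringSet(pathR2, format = "fastq")
  if (length(r1) != length(r2))
    stop("R1 and R2 record counts differ (", length(r1), " vs ", length(r2), ")")
  id1 <- sub("/[12]$", "", sub("\\s.*$", "", names(r1)))
  id2 <- sub("/[12]$", "", sub("\\s.*$", "", names(r2)))
  bad <- which(id1 != id2)
  if (length(bad))
    stop("read id mismatch at record ", bad[1L], ": ", id1[bad[1L]],
         " vs ", id2[bad[1L]])
  s1 <- toupper(as.character(r1))
  badlen <- which(nchar(s1) != 28L)
  if (length(badlen))
    stop("R1 read ", id1[badlen[1L]], " is ", nchar(s1)[badlen[1L]],
         " nt; expected 28 (16 barcode + 12 UMI)")
  s2 <- toupper(as.character(r2))
  badlen2 <- which(nchar(s2) != 60L)
  if (length(badlen2))
    stop("R2 read ", id2[badlen2[1L]], " is ", nchar(s2)[badlen2[1L]],
         " nt; expected 60")
  ReadPairSet(barcode = substr(s1, 1L, 16L), umi = substr(s1, 17L, 28L),
              cdna = s2, readId = id1)
}

#' Write a ReadPairSet as paired FASTQ
#'
#' Constant quality strings are emitted (the simulator models no sequencing
#' error), so output is byte-identical across runs with the same input.
#'
#' @param reads a \linkS4class{ReadPairSet} of untrimmed (60 nt) reads
#' @param pathR1,pathR2 output FASTQ paths
#' @export
writePairedFastq <- function(reads, pathR1, pathR2) {
  r1seq <- paste0(barcodes(reads), umis(reads))
  .writeFastq(readIds(reads), r1seq, pathR1)
  .writeFastq(readIds(reads), cdnaSeqs(reads), pathR2)
  invisible(c(pathR1, pathR2))
}

.writeFastq <- function(ids, seqs, path) {
  qual <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
}
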