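#' Write a CellUMITable as MatrixMarket triplets plus annotation files
#'
#' Emits \code{matrix.mtx} (1-based sparse triplets, genes x cells),
#' \code{features.tsv} (gene id, source tag) and \code{barcodes.tsv}, the
#' common droplet-RNA-seq interchange layout. \code{readUMIMatrix} inverts
#' it exactly.
#'
#' @param table a \linkS4class{CellUMITable}
#' @param dir output directory (created if needed)
#' @export
writeUMIMatrix <- function(table, dir) {
  m <- umiCounts(table)
  if (any(m@x < 0)) stop("negative counts")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  genes <- if (is.null(rownames(m))) character(0) else rownames(m)
  write.table(
    data.frame(gene = genes, source = rowData(table)$source),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  bcs <- if (is.null(colnames(m))) character(0) else colnames(m)
  writeLines(bcs, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname writeUMIMatrix
#' @return \code{readUMIMatrix}: the \linkS4class{CellUMITable} stored in
#'   \code{dir}
#' @export
readUMIMatrix <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  fpath <- file.path(dir, "features.tsv")
  feat <- if (file.size(fpath) > 0)
    read.table(fpath, sep = "\t", header = FALSE, colClasses = "character")
  else data.frame(V1 = character(0), V2 = character(0))
  bc <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(feat) != nrow(m) || length(bc) != ncol(m))
    stop("matrix dimensions disagree with features/barcodes files")
  dimnames(m) <- list(feat[[1L]], bc)
  CellUMITable(m, geneSource = feat[[2L]])
}
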