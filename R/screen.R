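#' Count viral marker-gene UMIs per cell
#'
#' Assigns each read to a viral marker gene and collapses reads sharing
#' (barcode, gene, UMI) to a single molecule. The default assignment is the
#' six-frame translated best hit against the family-labelled protein
#' database; a read whose best score is shared by two genes is left
#' unassigned (unique-mapping semantics). The alternative
#' \code{mode = "nucleotide"} requires exact full-length containment of the
#' read (either strand) in a unique marker gene.
#'
#' @param reads a \linkS4class{ReadPairSet} (poly-A trimmed)
#' @param refs a \linkS4class{ReferenceSet} (viral genes/proteins are used)
#' @param mode "translated" (default) or "nucleotide"
#' @param minAAScore minimum BLOSUM62 score for translated assignment
#' @return a \linkS4class{CellUMITable} over all barcodes in \code{reads}
#'   (columns) and all marker genes (rows, source "viral-marker");
#'   \code{metadata()$n_unassigned_reads} counts reads without a unique
#'   gene assignment
#' @export
countViralUMIs <- function(reads, refs, mode = c("translated", "nucleotide"),
                           minAAScore = 60L) {
  mode <- match.arg(mode)
  genes <- names(viralGenes(refs))
  bcs <- unique(barcodes(reads))
  cdna <- cdnaSeqs(reads)
  if (mode == "translated") {
    h <- .translatedBatch(cdna, viralProteins(refs), minAAScore)
    assigned <- !is.na(h$subject) & !h$tie
    geneIdx <- h$subject
  } else {
    h <- .assign_reads_nt_cpp(cdna, as.character(viralGenes(refs)), 1L, -2L, 22L)
    perfect <- !is.na(h$score) & h$score == nchar(cdna)
    assigned <- perfect & !h$tie
    geneIdx <- h$ref
  }
  keep <- which(assigned)
  .buildUMITable(
    barcode = barcodes(reads)[keep], gene = genes[geneIdx[keep]],
    umi = umis(reads)[keep], geneLevels = genes, barcodeLevels = bcs,
    source = rep("viral-marker", length(genes)),
    nUnassigned = length(cdna) - length(keep))
}

.buildUMITable <- function(barcode, gene, umi, geneLevels, barcodeLevels,
                           source, nUnassigned = 0L) {
  key <- paste(barcode, gene, umi, sep = "\r")
  first <- !duplicated(key)
  gi <- match(gene[first], geneLevels)
  bi <- match(barcode[first], barcodeLevels)
  m <- sparseMatrix(i = gi, j = bi, x = rep(1, length(gi)),
                    dims = c(length(geneLevels), length(barcodeLevels)),
                    dimnames = list(geneLevels, barcodeLevels))
  tab <- CellUMITable(m, geneSource = source)
  metadata(tab)$n_unassigned_reads <- nUnassigned
  tab
}

#' Remove zero-UMI cells and the extreme 1\% tails of library size
#'
#' Cells with zero total UMIs are dropped; then cells whose totals lie at or
#' below the 1st percentile, or at or beyond the 99th percentile, of the
#' remaining totals are removed (nearest-rank percentiles, boundaries
#' inclusive). When more than 2\% of cells tie exactly at a cut value, only
#' cells strictly beyond the boundary are removed, so degenerate tables
#' (e.g. all totals equal) lose nothing beyond their zero cells. This is a
#' one-shot filter applied once before downstream analysis.
#'
#' @param table a \linkS4class{CellUMITable}
#' @return the filtered \linkS4class{CellUMITable}
#' @export
qcFilterCells <- function(table) {
  tot <- totalUMIs(table)
  if (length(tot) == 0L) stop("empty table")
  keep <- tot > 0
  tot <- tot[keep]
  n <- length(tot)
  if (n >= 1L) {
    s <- sort(tot)
    p1 <- s[max(1L, ceiling(0.01 * n))]
    p99 <- s[max(1L, ceiling(0.99 * n))]
    lowStrict <- sum(tot == p1) > 0.02 * n
    highStrict <- sum(tot == p99) > 0.02 * n
    drop <- (if (lowStrict) tot < p1 else tot <= p1) |
      (if (highStrict) tot > p99 else tot >= p99)
    keep[keep] <- !drop
  }
  if (sum(keep) < 3L) stop("fewer than 3 cells remain after QC")
  out <- table[, keep]
  methods::as(out, "CellUMITable")
}

#' Call highly infected cells
#'
#' A cell is called highly infected when all three criteria hold on its
#' viral marker-gene UMIs: more than one viral gene expressed (>= 1 UMI in
#' each of >= 2 genes), at least one gene with a UMI count greater than one,
#' and a total of at least 10 viral UMIs.
#'
#' @param table a \linkS4class{CellUMITable} (viral-marker rows are used)
#' @return data.frame: barcode, n_viral_genes_expressed, max_gene_umis,
#'   total_viral_umis, highly_infected
#' @export
callHighlyInfected <- function(table) {
  m <- umiCounts(table)[geneSource(table) == "viral-marker", , drop = FALSE]
  m <- as.matrix(m)
  nGenes <- colSums(m >= 1)
  maxG <- if (nrow(m)) apply(m, 2L, max) else rep(0, ncol(m))
  tot <- colSums(m)
  data.frame(
    barcode = colnames(m),
    n_viral_genes_expressed = as.integer(nGenes),
    max_gene_umis = as.integer(maxG),
    total_viral_umis = as.integer(tot),
    highly_infected = nGenes > 1 & maxG > 1 & tot >= 10,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Partition highly infected cells by their dominant-family status
#'
#' Splits the highly infected cells into those whose best-matching (argmax)
#' virus family is the designated dominant family and the rest, mirroring
#' the exclusion of the bloomer's own virus before rare-pair analysis. The
#' two sets always partition the highly infected set.
#'
#' @param calls output of \code{\link{callHighlyInfected}}
#' @param profiles profile data.frame with columns barcode, argmax_family
#'   (see \code{\link{viralReadProfiles}})
#' @param dominantFamily family label
#' @return list(dominant, other): barcode vectors
#' @export
partitionByDominantVirus <- function(calls, profiles, dominantFamily) {
  hi <- calls$barcode[calls$highly_infected]
  am <- profiles$argmax_family[match(hi, profiles$barcode)]
  dom <- hi[!is.na(am) & am == dominantFamily]
  list(dominant = dom, other = setdiff(hi, dom))
}
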