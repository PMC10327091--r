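#' Fraction of positions inside low-complexity repeats
#'
#' Positions inside homopolymer runs of >= 5 nt or perfect dinucleotide
#' tandems of >= 8 nt are flagged; the score is the flagged fraction of the
#' sequence. Used to drop repetitive sequences when curating the host-virus
#' reference.
#'
#' @param seq nucleotide string
#' @return numeric in [0, 1]
#' @export
repeatFraction <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  if (n == 0L) return(0)
  flag <- logical(n)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$lengths >= 5L)) flag[starts[k]:ends[k]] <- TRUE
  # dinucleotide tandems: runs of s[i] == s[i-2] spanning >= 8 nt
  if (n >= 8L) {
    same2 <- c(FALSE, FALSE, v[-(1:2)] == v[seq_len(n - 2L)])
    r2 <- rle(same2)
    e2 <- cumsum(r2$lengths); s2 <- e2 - r2$lengths + 1L
    for (k in which(r2$values & r2$lengths >= 6L))
      flag[(s2[k] - 2L):e2[k]] <- TRUE
  }
  mean(flag)
}

#' Curate the combined host-virus transcript reference
#'
#' Labels each infected-cell contig as viral (translated best hit in the
#' viral protein database) or host, merges in supplied known gene sets
#' (e.g. the dominant bloomer's transcripts and its virus's CDSs), removes
#' sequences whose repeat fraction is at least \code{repeatThreshold}, and
#' collapses duplicates (exact, or >= 99\% identity containment of the
#' shorter in the longer) keeping the longer sequence.
#'
#' @param contigs DNAStringSet of infected-cell contigs
#' @param knownGenes optional DNAStringSet with \code{mcols()$source}
#'   ("host" or "viral")
#' @param proteinDb AAStringSet used to label contigs as viral
#' @param minAAScore translated-search threshold (default 60)
#' @param repeatThreshold removal threshold on \code{repeatFraction}
#'   (default 0.5)
#' @param dupIdentity containment identity for deduplication (default 99)
#' @return DNAStringSet with \code{mcols()$source}
#' @export
buildHostVirusReference <- function(contigs, knownGenes = NULL, proteinDb,
                                    minAAScore = 60L, repeatThreshold = 0.5,
                                    dupIdentity = 99) {
  src <- rep("host", length(contigs))
  if (length(contigs)) {
    h <- .translatedBatch(as.character(contigs), proteinDb, minAAScore)
    src[!is.na(h$subject)] <- "viral"
  }
  seqs <- as.character(contigs)
  nms <- names(contigs)
  if (!is.null(knownGenes) && length(knownGenes)) {
    ks <- mcols(knownGenes)$source
    if (is.null(ks)) stop("knownGenes must carry mcols$source")
    seqs <- c(seqs, as.character(knownGenes))
    nms <- c(nms, names(knownGenes))
    src <- c(src, ks)
  }
  rf <- vapply(seqs, repeatFraction, 0)
  keep <- rf < repeatThreshold
  seqs <- seqs[keep]; nms <- nms[keep]; src <- src[keep]
  # dedup: longest first; drop later sequences contained at >= dupIdentity
  ord <- order(-nchar(seqs), seqs)
  kept <- integer(0)
  for (i in ord) {
    dup <- FALSE
    if (length(kept)) {
      hits <- .search_nt_batch_cpp(seqs[i], seqs[kept], 1L, -2L, 22L)
      if (nrow(hits)) {
        ident <- 100 * hits$matches / hits$aln_len
        if (any(ident >= dupIdentity & hits$aln_len >= 0.99 * nchar(seqs[i])))
          dup <- TRUE
      }
    }
    if (!dup) kept <- c(kept, i)
  }
  kept <- sort(kept)
  if (!length(kept)) stop("reference curation removed every sequence")
  out <- DNAStringSet(setNames(seqs[kept], nms[kept]))
  mcols(out) <- DataFrame(source = src[kept])
  out
}

#' Quantify all cells against the combined host-virus reference
#'
#' Same assignment and UMI-collapse semantics as marker-gene counting, but
#' against the curated reference: a read is assigned to the reference
#' sequence with the unique best ungapped alignment (both strands); reads
#' tied between references are unassigned; reads sharing (barcode, gene,
#' UMI) collapse to one molecule.
#'
#' @param reads a \linkS4class{ReadPairSet}
#' @param reference DNAStringSet with \code{mcols()$source} ("host" /
#'   "viral")
#' @param minScore minimum raw alignment score (default 30)
#' @return a \linkS4class{CellUMITable}; viral reference sequences carry
#'   source "viral-marker"
#' @export
quantifyCells <- function(reads, reference, minScore = 30L) {
  if (!length(reference)) stop("empty reference")
  h <- .assign_reads_nt_cpp(cdnaSeqs(reads), as.character(reference),
                            1L, -2L, as.integer(minScore))
  assigned <- which(!is.na(h$ref) & !h$tie)
  srcTag <- ifelse(mcols(reference)$source == "viral", "viral-marker", "host")
  .buildUMITable(
    barcode = barcodes(reads)[assigned],
    gene = names(reference)[h$ref[assigned]],
    umi = umis(reads)[assigned],
    geneLevels = names(reference),
    barcodeLevels = unique(barcodes(reads)),
    source = srcTag,
    nUnassigned = length(reads) - length(assigned))
}

#' Normalize, reduce and embed the community in two dimensions
#'
#' Applies the cell-level QC filter, drops genes present in fewer than two
#' cells, normalizes each cell to the median library size, takes the square
#' root, projects onto principal components by exact SVD, and embeds with
#' UMAP (neighborhood parameters as given; single-threaded with a fixed
#' seed, so coordinates are reproducible bit-for-bit).
#'
#' @param table a \linkS4class{CellUMITable}
#' @param nPCs number of principal components (default 50)
#' @param nNeighbors,minDist,spread UMAP parameters (defaults 7, 0.4, 2)
#' @param seed integer seed for the embedding
#' @param qc apply \code{\link{qcFilterCells}} first (default TRUE)
#' @param taxonomy optional data.frame(barcode, group) to label cells
#' @return an \linkS4class{EmbeddingResult} (infected flags all FALSE until
#'   \code{\link{overlayInfection}} is applied)
#' @export
normalizeAndEmbed <- function(table, nPCs = 50L, nNeighbors = 7L,
                              minDist = 0.4, spread = 2, seed = 1L,
                              qc = TRUE, taxonomy = NULL) {
  if (qc) table <- qcFilterCells(table)
  m <- umiCounts(table)
  m <- m[Matrix::rowSums(m > 0) >= 2L, , drop = FALSE]
  n <- ncol(m)
  if (n < nNeighbors + 1L)
    stop("need at least nNeighbors + 1 = ", nNeighbors + 1L, " cells, have ", n)
  tot <- Matrix::colSums(m)
  med <- stats::median(tot)
  norm <- m %*% Matrix::Diagonal(x = med / tot)
  sq <- sqrt(norm)
  x <- Matrix::t(sq)
  k <- min(nPCs, n - 1L, nrow(m))
  pcs <- prcomp(as.matrix(x), center = TRUE, rank. = k)$x
  set.seed(seed)
  coords <- uwot::umap(pcs, n_neighbors = nNeighbors, min_dist = minDist,
                       spread = spread, n_threads = 1, n_sgd_threads = 0)
  labels <- rep(NA_character_, n)
  if (!is.null(taxonomy))
    labels <- taxonomy$group[match(colnames(m), taxonomy$barcode)]
  new("EmbeddingResult", barcodes = colnames(m),
      coords = unname(coords),
      taxonLabels = as.character(labels),
      infectedFlags = rep(FALSE, n))
}

#' Overlay infection status on an embedding
#'
#' Flags cells expressing at least 10 viral UMIs as infected.
#'
#' @param embedding an \linkS4class{EmbeddingResult}
#' @param viralTable a \linkS4class{CellUMITable} covering the embedded
#'   barcodes
#' @param minViralUMIs flag threshold (default 10)
#' @return the updated \linkS4class{EmbeddingResult}
#' @export
overlayInfection <- function(embedding, viralTable, minViralUMIs = 10L) {
  vt <- viralUMIs(viralTable)
  missing <- setdiff(barcodes(embedding), names(vt))
  if (length(missing))
    stop("barcode mismatch: ", missing[1L], " absent from the viral table")
  embedding@infectedFlags <- unname(vt[barcodes(embedding)] >= minViralUMIs)
  methods::validObject(embedding)
  embedding
}
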