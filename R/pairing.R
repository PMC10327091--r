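#' Profile each cell's viral reads by virus family
#'
#' Every read is compared to the family-labelled protein database by
#' six-frame translated best-hit search; the best match contributes one
#' read to its family's count (reads, not UMIs, are the pairing currency —
#' infection calling uses UMIs). Unmatched reads are excluded from the
#' total. Fractions are counts over the total; the argmax family breaks
#' ties lexicographically.
#'
#' @param reads a \linkS4class{ReadPairSet}
#' @param proteinDb AAStringSet with \code{mcols()$family}
#' @param minAAScore minimum BLOSUM62 score (default 60)
#' @param cellBarcodes restrict to these cells (default: all)
#' @return list(counts = data.frame(barcode, family, reads, fraction),
#'   profiles = data.frame(barcode, total_viral_reads, argmax_family))
#' @export
viralReadProfiles <- function(reads, proteinDb, minAAScore = 60L,
                              cellBarcodes = NULL) {
  if (!is.null(cellBarcodes))
    reads <- reads[barcodes(reads) %in% cellBarcodes]
  bcs <- if (!is.null(cellBarcodes)) cellBarcodes else
    unique(barcodes(reads))
  fams <- mcols(proteinDb)$family
  h <- .translatedBatch(cdnaSeqs(reads), proteinDb, minAAScore)
  hit <- !is.na(h$subject)
  df <- data.frame(barcode = barcodes(reads)[hit],
                   family = fams[h$subject[hit]], stringsAsFactors = FALSE)
  if (nrow(df)) {
    counts <- as.data.frame(table(barcode = df$barcode, family = df$family),
                            stringsAsFactors = FALSE)
    names(counts)[3L] <- "reads"
    counts <- counts[counts$reads > 0, , drop = FALSE]
    tot <- tapply(counts$reads, counts$barcode, sum)
    counts$fraction <- counts$reads / as.numeric(tot[counts$barcode])
    counts <- counts[order(counts$barcode, counts$family), , drop = FALSE]
    rownames(counts) <- NULL
  } else {
    counts <- data.frame(barcode = character(0), family = character(0),
                         reads = integer(0), fraction = numeric(0),
                         stringsAsFactors = FALSE)
  }
  profiles <- data.frame(barcode = bcs,
                         total_viral_reads = 0L,
                         argmax_family = NA_character_,
                         stringsAsFactors = FALSE)
  if (nrow(counts)) {
    for (i in seq_len(nrow(profiles))) {
      cc <- counts[counts$barcode == profiles$barcode[i], , drop = FALSE]
      if (!nrow(cc)) next
      profiles$total_viral_reads[i] <- sum(cc$reads)
      best <- cc$family[order(-cc$reads, cc$family)][1L]
      profiles$argmax_family[i] <- best
    }
  }
  list(counts = counts, profiles = profiles)
}

#' Classify a cell's host-virus links
#'
#' A cell yields links only if its host call is a real taxonomic group (not
#' omitted / unassigned / nonspecific) and its maximum per-family read
#' count is at least 10. One link is reported per family holding at least
#' 10\% of the cell's viral reads; a link is "unambiguous" when its family
#' holds at least 90\% of the viral reads, otherwise "ambiguous". All
#' boundaries are inclusive and evaluated in integer arithmetic.
#'
#' @param familyCounts data.frame(family, reads) for one cell
#' @param hostGroup the cell's host group call
#' @param barcode the cell barcode
#' @param minReads eligibility threshold on the max family count (10)
#' @param minFraction display threshold (0.10)
#' @param unambiguousFraction link-class threshold (0.90)
#' @return data.frame: barcode, host_group, family, reads, fraction,
#'   link_class (possibly 0 rows)
#' @export
classifyLinks <- function(familyCounts, hostGroup, barcode = NA_character_,
                          minReads = 10L, minFraction = 0.10,
                          unambiguousFraction = 0.90) {
  empty <- data.frame(barcode = character(0), host_group = character(0),
                      family = character(0), reads = integer(0),
                      fraction = numeric(0), link_class = character(0),
                      stringsAsFactors = FALSE)
  if (is.na(hostGroup) ||
      hostGroup %in% c("omitted", "unassigned", "nonspecific")) return(empty)
  if (!nrow(familyCounts)) return(empty)
  total <- sum(familyCounts$reads)
  if (max(familyCounts$reads) < minReads) return(empty)
  # integer-exact fraction gates: reads/total >= p  <=>  reads*q >= total*p*q
  keep <- familyCounts$reads * 100 >= total * (minFraction * 100)
  fc <- familyCounts[keep, , drop = FALSE]
  unamb <- fc$reads * 100 >= total * (unambiguousFraction * 100)
  out <- data.frame(barcode = barcode, host_group = hostGroup,
                    family = fc$family, reads = as.integer(fc$reads),
                    fraction = fc$reads / total,
                    link_class = ifelse(unamb, "unambiguous", "ambiguous"),
                    stringsAsFactors = FALSE)
  out[order(out$family), , drop = FALSE]
}

#' Build the host-virus pair table
#'
#' Takes highly infected cells, removes cells whose argmax family is the
#' designated dominant family (so the bloomer's own virus does not mask
#' rarer pairs), classifies each remaining cell's links, and summarises
#' cells per (host group, family) and link class.
#'
#' @param calls output of \code{\link{callHighlyInfected}}
#' @param profileCounts,profiles the two components of
#'   \code{\link{viralReadProfiles}}
#' @param taxonomy output of \code{\link{assignCellTaxon}}
#' @param dominantFamily family to exclude, or NULL to keep all
#' @param ... thresholds passed to \code{\link{classifyLinks}}
#' @return list(pairs = per-cell link table ordered by host group, family,
#'   barcode; summary = data.frame(host_group, family, n_cells,
#'   n_unambiguous, n_ambiguous))
#' @export
buildPairTable <- function(calls, profileCounts, profiles, taxonomy,
                           dominantFamily = NULL, ...) {
  hi <- calls$barcode[calls$highly_infected]
  if (!is.null(dominantFamily)) {
    am <- profiles$argmax_family[match(hi, profiles$barcode)]
    hi <- hi[is.na(am) | am != dominantFamily]
  }
  rows <- lapply(hi, function(bc) {
    grp <- taxonomy$group[match(bc, taxonomy$barcode)]
    if (length(grp) == 0L || is.na(grp)) grp <- "unassigned"
    classifyLinks(profileCounts[profileCounts$barcode == bc,
                                c("family", "reads"), drop = FALSE],
                  grp, bc, ...)
  })
  pairs <- do.call(rbind, c(rows, list(classifyLinks(
    data.frame(family = character(0), reads = integer(0)), NA_character_))))
  pairs <- pairs[order(pairs$host_group, pairs$family, pairs$barcode), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  if (nrow(pairs)) {
    sp <- split(pairs, paste(pairs$host_group, pairs$family, sep = "\r"))
    summary <- do.call(rbind, lapply(sp, function(p) data.frame(
      host_group = p$host_group[1L], family = p$family[1L],
      n_cells = length(unique(p$barcode)),
      n_unambiguous = sum(p$link_class == "unambiguous"),
      n_ambiguous = sum(p$link_class == "ambiguous"),
      stringsAsFactors = FALSE)))
    summary <- summary[order(summary$host_group, summary$family), ,
                       drop = FALSE]
    rownames(summary) <- NULL
  } else {
    summary <- data.frame(host_group = character(0), family = character(0),
                          n_cells = integer(0), n_unambiguous = integer(0),
                          n_ambiguous = integer(0), stringsAsFactors = FALSE)
  }
  list(pairs = pairs, summary = summary)
}

#' Summed viral gene expression across cells
#'
#' Per viral gene: total UMIs over the listed cells and the log2(x + 1)
#' display transform, sorted by expression (descending, ties by gene name).
#'
#' @param table a \linkS4class{CellUMITable}
#' @param cellBarcodes cells to sum over (default: all)
#' @param geneSet genes to report (default: all viral-marker genes)
#' @return data.frame: gene, total_umis, log2_expression
#' @export
viralGeneExpression <- function(table, cellBarcodes = NULL, geneSet = NULL) {
  m <- umiCounts(table)
  if (is.null(geneSet)) geneSet <- rownames(m)[geneSource(table) == "viral-marker"]
  if (is.null(cellBarcodes)) cellBarcodes <- colnames(m)
  m <- m[rownames(m) %in% geneSet, colnames(m) %in% cellBarcodes, drop = FALSE]
  tot <- Matrix::rowSums(m)
  out <- data.frame(gene = rownames(m), total_umis = as.numeric(tot),
                    log2_expression = log2(tot + 1),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total_umis, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
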