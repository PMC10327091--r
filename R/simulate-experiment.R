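.uniqueRandomSeqs <- function(n, len) {
  if (n == 0L) return(character(0))
  out <- vapply(seq_len(n), function(i) .randomSeq(len), "")
  while (anyDuplicated(out)) {
    d <- which(duplicated(out))
    out[d] <- vapply(d, function(i) .randomSeq(len), "")
  }
  out
}

# encode per-barcode molecule counters as 12-nt UMIs (base-4 digits -> ACGT);
# distinct molecules get distinct UMIs by construction
.encodeUMI <- function(ints) {
  m <- matrix("", nrow = length(ints), ncol = 12L)
  x <- ints - 1L
  for (d in 12:1) { m[, d] <- .BASES[(x %% 4L) + 1L]; x <- x %/% 4L }
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate a barcoded droplet experiment with planted infections
#'
#' Each cell draws a log-normal number of reads. An infected cell spends its
#' configured viral expression fraction on reads drawn uniformly from its
#' family's marker genes; every cell spends a fixed 2\% on its own 18S
#' analog (the rRNA carry-through the taxonomy step relies on) and the
#' remainder on its taxon's mRNA transcripts. Uninfected cells additionally
#' receive ambient viral reads (free virions / ingestion) at the configured
#' per-read rate, drawn from a random family. Every read is an exact 60-mer
#' substring of its source transcript at a uniform start; every molecule of
#' a barcode gets a distinct UMI. Doublet barcodes merge the reads of the
#' cell with a second, uninfected cell of a different taxon.
#'
#' Cell counts per taxon and infected-cell counts per infection-table row
#' are apportioned deterministically (largest remainder) from the configured
#' fractions, so rare classes are represented exactly as configured.
#'
#' @param refs a \linkS4class{ReferenceSet} from \code{simulateReferences}
#' @param config a \linkS4class{CommunityConfig}
#' @param markerGeneWeights optional named numeric vector of relative
#'   expression weights per marker gene name (e.g.
#'   \code{c(HSP70 = 5, HSP90 = 5)}); unlisted genes get weight 1. Within a
#'   family, an infected cell's viral reads are drawn from its marker genes
#'   with these weights (default: uniform)
#' @return list(reads = \linkS4class{ReadPairSet},
#'   truth = \linkS4class{GroundTruth})
#' @export
simulateExperiment <- function(refs, config, markerGeneWeights = NULL) {
  stopifnot(is(refs, "ReferenceSet"), is(config, "CommunityConfig"))
  set.seed(config@seed + 1L)
  n <- config@nCells
  emptyTruth <- data.frame(
    barcode = character(0), taxon = character(0), taxon2 = character(0),
    infected = logical(0), family = character(0), doublet = logical(0),
    true_viral_umis = integer(0), stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(reads = ReadPairSet(),
                truth = new("GroundTruth", cells = emptyTruth,
                            days = data.frame())))
  taxa <- config@taxonNames
  cellTaxon <- rep(taxa, .largestRemainder(n, config@taxonCellFractions))
  bcs <- .uniqueRandomSeqs(n, 16L)

  # source pools (transcripts < 60 nt cannot yield a read)
  s18 <- host18S(refs)
  seq18S <- setNames(as.character(s18[mcols(s18)$db == unique(mcols(s18)$db)[1L]]),
                     mcols(s18)$group[mcols(s18)$db == unique(mcols(s18)$db)[1L]])
  mr <- hostMRNA(refs)
  short <- width(mr) < 60L
  if (any(short)) {
    warning(sum(short), " transcript(s) shorter than 60 nt excluded from sampling")
    mr <- mr[!short]
  }
  mrnaByTaxon <- split(as.character(mr), mcols(mr)$taxon)
  vg <- viralGenes(refs)
  vshort <- width(vg) < 60L
  if (any(vshort)) {
    warning(sum(vshort), " viral gene(s) shorter than 60 nt excluded from sampling")
    vg <- vg[!vshort]
  }
  vgSeqs <- setNames(as.character(vg), mcols(vg)$gene)
  genesByFamily <- split(vgSeqs, mcols(vg)$family)
  fams <- names(genesByFamily)
  weightsByFamily <- lapply(genesByFamily, function(g) {
    w <- rep(1, length(g))
    if (!is.null(markerGeneWeights)) {
      hit <- names(g) %in% names(markerGeneWeights)
      w[hit] <- markerGeneWeights[names(g)[hit]]
    }
    w / sum(w)
  })

  # planted infections: deterministic counts per infection-table row
  infFamily <- rep(NA_character_, n)
  infExpr <- rep(NA_real_, n)
  it <- config@infectionTable
  for (t in unique(it$taxon)) {
    rows <- which(it$taxon == t)
    cellsT <- which(cellTaxon == t)
    if (!length(cellsT)) next
    fr <- it$frac_infected[rows]
    if (sum(fr) > 1 + 1e-9)
      stop("infected fractions for taxon ", t, " exceed 1")
    cnts <- .largestRemainder(length(cellsT),
                              c(fr, max(0, 1 - sum(fr))))[seq_along(rows)]
    pick <- if (length(cellsT) > 1L) sample(cellsT) else cellsT
    at <- 0L
    for (k in seq_along(rows)) {
      if (cnts[k] == 0L) next
      sel <- pick[(at + 1L):(at + cnts[k])]
      infFamily[sel] <- it$family[rows[k]]
      infExpr[sel] <- it$expr_fraction[rows[k]]
      at <- at + cnts[k]
    }
  }

  # doublets: partner of a different taxon, uninfected
  nD <- as.integer(round(config@doubletRate * n))
  doubletIdx <- if (nD > 0L) sort(sample.int(n, nD)) else integer(0)
  partnerTaxon <- rep(NA_character_, n)
  for (i in doubletIdx) {
    others <- setdiff(taxa, cellTaxon[i])
    w <- config@taxonCellFractions[match(others, taxa)]
    partnerTaxon[i] <- if (length(others) == 1L) others else
      sample(others, 1L, prob = w)
  }

  ml <- config@readsPerCell[1L]; sl <- config@readsPerCell[2L]
  nReads <- pmax(1L, as.integer(round(rlnorm(n, ml, sl))))
  nReadsPartner <- ifelse(!is.na(partnerTaxon),
                          pmax(1L, as.integer(round(rlnorm(n, ml, sl)))), 0L)

  drawComponent <- function(taxon, family, expr, nr) {
    u <- runif(nr)
    isViral <- if (!is.na(family)) u < expr else u < config@ambientViralRate
    p18 <- if (!is.na(family)) expr + 0.02 else config@ambientViralRate + 0.02
    is18S <- !isViral & u < p18
    src <- character(nr)
    nv <- sum(isViral)
    if (nv) {
      if (!is.na(family)) {
        src[isViral] <- sample(genesByFamily[[family]], nv, replace = TRUE,
                               prob = weightsByFamily[[family]])
      } else {
        af <- sample(fams, nv, replace = TRUE)
        src[isViral] <- vapply(af, function(f)
          sample(genesByFamily[[f]], 1L), "")
      }
    }
    src[is18S] <- seq18S[[taxon]]
    nm <- !isViral & !is18S
    if (any(nm)) src[nm] <- sample(mrnaByTaxon[[taxon]], sum(nm), replace = TRUE)
    start <- 1L + floor(runif(nr) * (nchar(src) - 59L))
    list(cdna = substring(src, start, start + 59L), viral = isViral)
  }

  cdnaL <- vector("list", n); bcL <- vector("list", n)
  umiL <- vector("list", n); idL <- vector("list", n)
  trueViral <- integer(n)
  for (i in seq_len(n)) {
    comp <- drawComponent(cellTaxon[i], infFamily[i], infExpr[i], nReads[i])
    cdna <- comp$cdna; nViral <- sum(comp$viral)
    if (!is.na(partnerTaxon[i])) {
      comp2 <- drawComponent(partnerTaxon[i], NA_character_, NA_real_,
                             nReadsPartner[i])
      cdna <- c(cdna, comp2$cdna)
      nViral <- nViral + sum(comp2$viral)
    }
    tot <- length(cdna)
    cdnaL[[i]] <- cdna
    bcL[[i]] <- rep(bcs[i], tot)
    umiL[[i]] <- .encodeUMI(seq_len(tot))
    idL[[i]] <- paste0("r", i, "_", seq_len(tot))
    trueViral[i] <- nViral
  }

  reads <- ReadPairSet(barcode = unlist(bcL), umi = unlist(umiL),
                       cdna = unlist(cdnaL), readId = unlist(idL))
  truth <- data.frame(
    barcode = bcs, taxon = cellTaxon, taxon2 = partnerTaxon,
    infected = !is.na(infFamily), family = infFamily,
    doublet = !is.na(partnerTaxon), true_viral_umis = trueViral,
    stringsAsFactors = FALSE)
  list(reads = reads,
       truth = new("GroundTruth", cells = truth, days = data.frame()))
}
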