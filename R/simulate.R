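#' Default synthetic community configuration
#'
#' The defaults emulate the structure of a late-stage induced coccolithophore
#' bloom: one dominant bloomer (about half the cells), several mid-abundance
#' protist classes and one rare class at 0.4\% of cells; four giant-virus
#' families of which one (the coccolithovirus analog) dominates infections;
#' per-family marker gene panels that include PolB/MCP/TopoII analogs plus
#' chaperone analogs (HSP70/HSP90/DnaJ); and a rare-class infection at 86\%
#' of its cells. Sequencing depth is log-normal around 2000 reads per cell.
#' All fractions are treated as exact design conditions (see the methods
#' vignette); one integer seed fully determines every generator output.
#'
#' @param taxonNames,taxonCellFractions community composition (must sum to 1)
#' @param dominantTaxon the bloomer
#' @param familyNames viral family labels; the first is the dominant family
#' @param markerGenesPerFamily marker genes per family (>= 4)
#' @param infectionTable data.frame(taxon, family, frac_infected,
#'   expr_fraction)
#' @param ambientViralRate per-read probability of an ambient/ingestion
#'   viral read in uninfected cells
#' @param doubletRate fraction of barcodes carrying two cells
#' @param nCells number of cell barcodes
#' @param readsPerCell c(meanlog, sdlog) of log-normal reads per cell
#' @param seed integer seed
#' @return a \linkS4class{CommunityConfig}
#' @export
communityConfig <- function(
    taxonNames = c("Prymnesiophyceae", "Chrysophyceae", "Dinoflagellata",
                   "Cercozoa", "MAST-3", "Katablepharidaceae"),
    taxonCellFractions = c(0.491, 0.20, 0.15, 0.10, 0.055, 0.004),
    dominantTaxon = taxonNames[1L],
    familyNames = c("Coccolithovirus", "Mesomimiviridae", "IM_07", "IM_09"),
    markerGenesPerFamily = 6L,
    infectionTable = data.frame(
      taxon = c("Prymnesiophyceae", "Chrysophyceae", "Dinoflagellata",
                "Katablepharidaceae"),
      family = c("Coccolithovirus", "Mesomimiviridae", "IM_09", "IM_07"),
      frac_infected = c(0.5, 0.2, 0.1, 0.86),
      expr_fraction = c(0.20, 0.15, 0.10, 0.20),
      stringsAsFactors = FALSE),
    ambientViralRate = 0.002, doubletRate = 0.01, nCells = 500L,
    readsPerCell = c(meanlog = log(2000), sdlog = 0.25), seed = 1L) {
  new("CommunityConfig",
      taxonNames = taxonNames,
      taxonCellFractions = as.numeric(taxonCellFractions),
      dominantTaxon = dominantTaxon,
      familyNames = familyNames,
      markerGenesPerFamily = as.integer(markerGenesPerFamily),
      infectionTable = infectionTable,
      ambientViralRate = ambientViralRate, doubletRate = doubletRate,
      nCells = as.integer(nCells), readsPerCell = as.numeric(readsPerCell),
      seed = as.integer(seed))
}

.BASES <- c("A", "C", "G", "T")
.MARKER_NAMES <- c("PolB", "MCP", "TopoII", "HSP70", "HSP90", "DNAJ")
.SENSE_CODONS <- local({
  b <- c("T", "C", "A", "G")
  aas <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]
  cods <- character(64); k <- 0L
  for (x in b) for (y in b) for (z in b) { k <- k + 1L; cods[k] <- paste0(x, y, z) }
  cods[aas != "*"]
})

.randomSeq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

# per-site substitution at `rate` from `seq` (no indels)
.mutateSeq <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit)) {
    cur <- match(v[hit], .BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    v[hit] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  paste(v, collapse = "")
}

# deterministic apportionment of n into counts proportional to `fracs`
.largestRemainder <- function(n, fracs) {
  raw <- n * fracs
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate the synthetic reference sets
#'
#' Per taxon: two 18S rRNA analog variants (1800 nt, >= 99\% identical within
#' a taxon, < 90\% between taxa by construction, checked) split across two
#' reference databases, plus 20 mRNA transcripts (300-2000 nt). Per viral
#' family: \code{markerGenesPerFamily} marker genes built from sense codons
#' (no in-frame stops) together with their frame-0 translations; families
#' are mutually unrelated so between-family protein identity is far below
#' 60\% (checked). Sequence divergence is per-site substitution from shared
#' ancestors; no indels, which keeps the ungapped aligner exact.
#'
#' @param config a \linkS4class{CommunityConfig}
#' @return a \linkS4class{ReferenceSet}
#' @export
simulateReferences <- function(config) {
  stopifnot(is(config, "CommunityConfig"))
  set.seed(config@seed)
  taxa <- config@taxonNames
  ancestor <- .randomSeq(1800L)
  masters <- vapply(taxa, function(t) .mutateSeq(ancestor, 0.15), "")
  # identity bands
  for (i in seq_along(taxa)) for (j in seq_len(i - 1L)) {
    if (fullLengthIdentity(masters[i], masters[j]) >= 90)
      stop("between-taxon 18S identity >= 90%; request fewer taxa ",
           "or rerun with another seed")
  }
  v1 <- vapply(masters, function(m) .mutateSeq(m, 0.003), "")
  v2 <- vapply(masters, function(m) .mutateSeq(m, 0.003), "")
  host18S <- DNAStringSet(setNames(c(v1, v2), c(
    paste0(taxa, "|18S_v1"), paste0(taxa, "|18S_v2"))))
  mcols(host18S) <- DataFrame(
    group = rep(taxa, 2L),
    db = rep(c("pr2like", "metapr2like"), each = length(taxa)),
    description = metaDescription(group = rep(taxa, 2L),
                                  db = rep(c("pr2like", "metapr2like"),
                                           each = length(taxa))))

  nM <- 20L
  mrnaSeqs <- character(0); mrnaTaxon <- character(0); mrnaNames <- character(0)
  for (t in taxa) {
    lens <- sample(300:2000, nM, replace = TRUE)
    mrnaSeqs <- c(mrnaSeqs, vapply(lens, .randomSeq, ""))
    mrnaTaxon <- c(mrnaTaxon, rep(t, nM))
    mrnaNames <- c(mrnaNames, paste0(t, "|mRNA", seq_len(nM)))
  }
  hostMRNA <- DNAStringSet(setNames(mrnaSeqs, mrnaNames))
  mcols(hostMRNA) <- DataFrame(taxon = mrnaTaxon,
                               description = metaDescription(taxon = mrnaTaxon))

  fams <- config@familyNames
  nG <- config@markerGenesPerFamily
  geneNames <- c(.MARKER_NAMES, paste0("gene", seq_len(max(0L, nG - 6L)) + 6L))[seq_len(nG)]
  gSeqs <- character(0); gFam <- character(0); gGene <- character(0)
  for (f in fams) for (g in geneNames) {
    nAA <- sample(200:500, 1L)
    gSeqs <- c(gSeqs, paste(sample(.SENSE_CODONS, nAA, replace = TRUE),
                            collapse = ""))
    gFam <- c(gFam, f); gGene <- c(gGene, g)
  }
  gNames <- paste0(gFam, "_", gGene)
  viralGenes <- DNAStringSet(setNames(gSeqs, gNames))
  virusIds <- paste0("GVMAG-", gFam)
  mcols(viralGenes) <- DataFrame(
    family = gFam, gene = gGene, virus_id = virusIds,
    description = metaDescription(family = gFam, gene = gGene,
                                  virus_id = virusIds))
  prots <- .translate_cpp(gSeqs, 0L)
  viralProteins <- AAStringSet(setNames(prots, gNames))
  mcols(viralProteins) <- mcols(viralGenes)
  # between-family protein identity band
  for (g in geneNames) {
    idx <- which(gGene == g)
    for (i in idx) for (j in idx) if (i < j) {
      if (fullLengthIdentity(prots[i], prots[j]) >= 60)
        stop("between-family protein identity >= 60%; rerun with another seed")
    }
  }
  new("ReferenceSet", host18S = host18S, hostMRNA = hostMRNA,
      viralGenes = viralGenes, viralProteins = viralProteins)
}

#' Write / read a ReferenceSet as four FASTA files
#'
#' Labels (group, db, taxon, family, gene, virus_id) are carried as
#' key=value tokens in the descriptions, so the set round-trips through
#' \code{\link{readFasta}} unchanged.
#'
#' @param refs a \linkS4class{ReferenceSet}
#' @param dir directory (created if needed)
#' @export
writeReferenceSet <- function(refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFasta(host18S(refs), file.path(dir, "host18S.fasta"))
  writeFasta(hostMRNA(refs), file.path(dir, "host_mrna.fasta"))
  writeFasta(viralGenes(refs), file.path(dir, "viral_genes.fasta"))
  writeFasta(viralProteins(refs), file.path(dir, "viral_proteins.fasta"))
  invisible(dir)
}

#' @rdname writeReferenceSet
#' @return \code{readReferenceSet}: the \linkS4class{ReferenceSet}
#' @export
readReferenceSet <- function(dir) {
  s18 <- readFasta(file.path(dir, "host18S.fasta"), type = "dna")
  mr <- readFasta(file.path(dir, "host_mrna.fasta"), type = "dna")
  vg <- readFasta(file.path(dir, "viral_genes.fasta"), type = "dna")
  vp <- readFasta(file.path(dir, "viral_proteins.fasta"), type = "aa")
  new("ReferenceSet", host18S = s18, hostMRNA = mr, viralGenes = vg,
      viralProteins = vp)
}

# split the two-database 18S reference into the list form host assignment takes
#' @rdname simulateReferences
#' @param refs a ReferenceSet
#' @return \code{refDbList}: named list of per-database DNAStringSets
#' @export
refDbList <- function(refs) {
  s <- host18S(refs)
  lapply(split(seq_along(s), mcols(s)$db), function(i) s[i])
}
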