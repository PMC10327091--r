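test_that("reads sharing barcode, gene and UMI collapse to one molecule", {
  fx <- smallFixture()
  gene <- as.character(viralGenes(fx$refs)[[1]])
  gname <- names(viralGenes(fx$refs))[1]
  cdna <- rep(substr(gene, 10, 69), 5)
  umi <- c("AAAAAAAAAAAA", "AAAAAAAAAAAA", "CCCCCCCCCCCC",
           "CCCCCCCCCCCC", "GGGGGGGGGGGG")
  reads <- readSet(cdna, umi = umi)
  tab <- countViralUMIs(reads, fx$refs)
  expect_equal(sum(umiCounts(tab)[gname, ]), 3)
})

test_that("a read matching two genes at the same score is unassigned", {
  fx <- smallFixture()
  vg <- viralGenes(fx$refs)
  dupSeq <- as.character(vg[[1]])
  genes <- Biostrings::DNAStringSet(c(copyA = dupSeq, copyB = dupSeq))
  mcols(genes) <- S4Vectors::DataFrame(
    family = c("F1", "F2"), gene = c("PolB", "PolB"),
    virus_id = c("vA", "vB"))
  prots <- Biostrings::AAStringSet(setNames(
    as.character(Biostrings::translate(genes)), names(genes)))
  mcols(prots) <- mcols(genes)
  refs2 <- new("ReferenceSet", host18S = host18S(fx$refs),
               hostMRNA = hostMRNA(fx$refs), viralGenes = genes,
               viralProteins = prots)
  reads <- readSet(substr(dupSeq, 1, 60))
  tab <- countViralUMIs(reads, refs2)
  expect_equal(sum(umiCounts(tab)), 0)
  expect_equal(S4Vectors::metadata(tab)$n_unassigned_reads, 1L)
})

test_that("QC removes zero cells plus the nearest-rank 1% tails", {
  set.seed(41)
  totals <- c(0, sample(1000:5000, 99))  # 100 cells, one empty, distinct totals
  m <- Matrix::Matrix(matrix(totals, nrow = 1), sparse = TRUE)
  rownames(m) <- "g1"
  colnames(m) <- paste0("c", seq_along(totals))
  tab <- CellUMITable(m, "host")
  out <- qcFilterCells(tab)
  kept <- totalUMIs(out)
  expect_equal(length(kept), 97L)  # 0-cell + lowest + highest removed
  expect_false(min(totals[totals > 0]) %in% kept)
  expect_false(max(totals) %in% kept)
})

test_that("QC tie rule: equal totals beyond 2% are not cut", {
  m <- Matrix::Matrix(matrix(c(0, rep(50, 99)), nrow = 1), sparse = TRUE)
  rownames(m) <- "g1"; colnames(m) <- paste0("c", 1:100)
  out <- qcFilterCells(CellUMITable(m, "host"))
  expect_equal(length(totalUMIs(out)), 99L)  # only the zero cell dropped
})

test_that("QC re-run leaves a small filtered table unchanged", {
  set.seed(42)
  totals <- sample(100:900, 45)
  m <- Matrix::Matrix(matrix(totals, nrow = 1), sparse = TRUE)
  rownames(m) <- "g1"; colnames(m) <- paste0("c", 1:45)
  once <- qcFilterCells(CellUMITable(m, "host"))
  twice <- qcFilterCells(once)
  expect_identical(totalUMIs(twice), totalUMIs(once))
})

test_that("the three infection criteria gate exactly at their boundaries", {
  mk <- function(counts) {
    m <- matrix(0, nrow = 10, ncol = 1,
                dimnames = list(paste0("vg", 1:10), "cell1"))
    m[seq_along(counts), 1] <- counts
    callHighlyInfected(umiTable(m))
  }
  expect_true(mk(c(9, 1))$highly_infected)       # 2 genes, max 9, total 10
  expect_false(mk(c(12))$highly_infected)        # one gene only
  expect_false(mk(rep(1, 10))$highly_infected)   # no gene > 1
  expect_false(mk(c(8, 1))$highly_infected)      # total 9 < 10
  expect_true(mk(c(8, 2))$highly_infected)       # total 10 flips the call
})

test_that("adding viral UMIs never flips a highly-infected call off", {
  set.seed(43)
  for (i in 1:50) {
    counts <- rpois(6, 2)
    m <- matrix(counts, ncol = 1, dimnames = list(paste0("g", 1:6), "c"))
    before <- callHighlyInfected(umiTable(m))$highly_infected
    j <- sample(6, 1)
    m[j, 1] <- m[j, 1] + sample(1:10, 1)
    after <- callHighlyInfected(umiTable(m))$highly_infected
    expect_false(before && !after)
  }
})

test_that("exact-containment counting agrees with translated counting noise-free", {
  fx <- smallFixture()
  tr <- truthCells(fx$sim$truth)
  reads <- trimReads(fx$sim$reads[1:20000])
  t1 <- countViralUMIs(reads, fx$refs, mode = "translated")
  t2 <- countViralUMIs(reads, fx$refs, mode = "nucleotide")
  expect_equal(as.matrix(umiCounts(t1)), as.matrix(umiCounts(t2)))
})

test_that("dominant vs other infections split in the planted proportions", {
  # ~754:218 structure scaled down: dominant family infects ~77.6% of
  # infected cells
  cfg <- communityConfig(
    taxonNames = c("Bloomer", "Rare"), taxonCellFractions = c(0.8, 0.2),
    dominantTaxon = "Bloomer",
    familyNames = c("Coccolithovirus", "IM_07"),
    infectionTable = data.frame(
      taxon = c("Bloomer", "Rare"), family = c("Coccolithovirus", "IM_07"),
      frac_infected = c(0.6, 0.7), expr_fraction = c(0.2, 0.2),
      stringsAsFactors = FALSE),
    ambientViralRate = 0, doubletRate = 0, nCells = 300L,
    readsPerCell = c(meanlog = log(400), sdlog = 0.2), seed = 44L)
  refs <- simulateReferences(cfg)
  sim <- simulateExperiment(refs, cfg)
  tr <- truthCells(sim$truth)
  tab <- countViralUMIs(trimReads(sim$reads), refs)
  calls <- callHighlyInfected(tab)
  hi <- calls$barcode[calls$highly_infected]
  prof <- viralReadProfiles(sim$reads, viralProteins(refs), cellBarcodes = hi)
  p <- partitionByDominantVirus(calls, prof$profiles, "Coccolithovirus")
  expect_equal(length(p$dominant) + length(p$other), length(hi))
  # planted proportion: 144 dominant vs 42 other infected cells
  plantedFrac <- sum(tr$infected & tr$family == "Coccolithovirus") /
    sum(tr$infected)
  gotFrac <- length(p$dominant) / length(hi)
  se <- sqrt(plantedFrac * (1 - plantedFrac) / length(hi))
  expect_lt(abs(gotFrac - plantedFrac), 3 * se + 0.02)
})

test_that("stop-codon-dense reads yield no translated hit", {
  fx <- smallFixture()
  stops <- strrep("TAA", 20)  # frame +1 is all stops; others are poly-N
  expect_null(searchTranslated(stops, viralProteins(fx$refs)))
  expect_null(searchTranslated("TAGTGATAGTGATAGTGATAGTGATAGTGA",
                               viralProteins(fx$refs)))
})

test_that("dominant-family partition always covers the highly infected set", {
  calls <- data.frame(
    barcode = paste0("b", 1:30),
    n_viral_genes_expressed = 3L, max_gene_umis = 5L, total_viral_umis = 20L,
    highly_infected = TRUE, stringsAsFactors = FALSE)
  profiles <- data.frame(
    barcode = paste0("b", 1:30),
    argmax_family = c(rep("EhV", 22), rep("IM_07", 8)),
    stringsAsFactors = FALSE)
  p <- partitionByDominantVirus(calls, profiles, "EhV")
  expect_length(p$dominant, 22)
  expect_length(p$other, 8)
  expect_setequal(c(p$dominant, p$other), calls$barcode)

  none <- partitionByDominantVirus(calls, profiles, "absent_family")
  expect_length(none$dominant, 0)
  expect_length(none$other, 30)
})
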