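test_that("repeat scoring flags low-complexity sequences for removal", {
  expect_gte(repeatFraction(strrep("AT", 100)), 0.5)
  expect_gte(repeatFraction(strrep("A", 64)), 0.5)
  set.seed(81)
  expect_lt(repeatFraction(randSeq(500)), 0.3)
})

test_that("reference curation removes repeats and collapses duplicates", {
  fx <- smallFixture()
  set.seed(82)
  good <- randSeq(300)
  contigs <- Biostrings::DNAStringSet(c(
    a = good, b = good,                   # exact duplicates
    r = strrep("AT", 100),                # pure dinucleotide repeat
    v = substr(as.character(viralGenes(fx$refs))[1], 1, 240)))
  ref <- buildHostVirusReference(contigs, proteinDb = viralProteins(fx$refs))
  expect_equal(sum(as.character(ref) == good), 1L)
  expect_false(strrep("AT", 100) %in% as.character(ref))
  expect_identical(unname(mcols(ref)$source[as.character(ref) != good]),
                   "viral")
  # containment at >= 99% also collapses
  contigs2 <- Biostrings::DNAStringSet(c(long = good,
                                         short = substr(good, 50, 250)))
  ref2 <- buildHostVirusReference(contigs2, proteinDb = viralProteins(fx$refs))
  expect_equal(length(ref2), 1L)
  expect_equal(unname(nchar(as.character(ref2)[1])), 300L)
})

test_that("curated reference covers every planted infected taxon", {
  fx <- smallFixture()
  tr <- truthCells(fx$sim$truth)
  hi <- tr$barcode[tr$infected]
  contigs <- assembleCells(fx$sim$reads, cellBarcodes = hi)
  contigs <- contigs[Biostrings::width(contigs) >= 100]
  ref <- buildHostVirusReference(contigs, proteinDb = viralProteins(fx$refs))
  cellOf <- sub("_c\\d+$", "", names(ref))
  taxaCovered <- unique(tr$taxon[match(cellOf, tr$barcode)])
  expect_true(all(unique(tr$taxon[tr$infected]) %in% taxaCovered))
})

test_that("library-size normalization makes proportional cells identical", {
  m <- matrix(c(2, 4, 6, 0,
                1, 2, 3, 0,
                5, 0, 1, 2), nrow = 4,
              dimnames = list(paste0("g", 1:4), c("c1", "c2", "c3")))
  tab <- umiTable(m, source = rep("host", 4))
  # the normalized matrix: recompute the documented transform
  mm <- umiCounts(tab)
  mm <- mm[Matrix::rowSums(mm > 0) >= 2, ]
  tot <- Matrix::colSums(mm)
  norm <- as.matrix(mm %*% Matrix::Diagonal(x = median(tot) / tot))
  expect_equal(norm[, 1], norm[, 2])              # proportional cells agree
  expect_true(all(abs(colSums(norm) - median(tot)) < 1e-9))
})

test_that("genes present in fewer than two cells are dropped", {
  m <- matrix(c(1, 0, 0,
                2, 3, 0,
                1, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("solo", "duo", "trio"), c("c1", "c2", "c3")))
  tab <- umiTable(m, source = rep("host", 3))
  mm <- umiCounts(tab)
  kept <- rownames(mm)[Matrix::rowSums(mm > 0) >= 2]
  expect_setequal(kept, c("duo", "trio"))
})

test_that("embedding is deterministic under a fixed seed", {
  set.seed(83)
  m <- matrix(rpois(40 * 30, 3), nrow = 40,
              dimnames = list(paste0("g", 1:40), NULL))
  colnames(m) <- vapply(1:30, function(i) randSeq(16), "")
  tab <- umiTable(m, source = rep("host", 40))
  e1 <- normalizeAndEmbed(tab, nPCs = 10, seed = 5, qc = FALSE)
  e2 <- normalizeAndEmbed(tab, nPCs = 10, seed = 5, qc = FALSE)
  expect_identical(embeddingCoords(e1), embeddingCoords(e2))
})

test_that("taxa with disjoint gene usage separate in the embedding", {
  set.seed(84)
  nPer <- 25
  gsA <- matrix(rpois(nPer * 30, 5), nrow = 30)
  gsB <- matrix(rpois(nPer * 30, 5), nrow = 30)
  m <- rbind(cbind(gsA, matrix(0, 30, nPer)),
             cbind(matrix(0, 30, nPer), gsB))
  rownames(m) <- paste0("g", 1:60)
  colnames(m) <- vapply(1:(2 * nPer), function(i) randSeq(16), "")
  labels <- rep(c("A", "B"), each = nPer)
  tab <- umiTable(m, source = rep("host", 60))
  emb <- normalizeAndEmbed(tab, nPCs = 10, seed = 7, qc = FALSE)
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             dist(embeddingCoords(emb)))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  # 1-NN label agreement
  d <- as.matrix(dist(embeddingCoords(emb)))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  expect_gte(mean(labels[nn] == labels), 0.95)
})

test_that("infection overlay applies the 10-UMI boundary exactly", {
  set.seed(85)
  bcs <- vapply(1:10, function(i) randSeq(16), "")
  host <- matrix(rpois(200, 6), nrow = 20)
  viral <- matrix(0, nrow = 2, ncol = 10)
  viral[1, 1] <- 10; viral[1, 2] <- 9
  m <- rbind(host, viral)
  rownames(m) <- c(paste0("h", 1:20), "v1", "v2")
  colnames(m) <- bcs
  tab <- umiTable(m, source = c(rep("host", 20), rep("viral-marker", 2)))
  emb <- normalizeAndEmbed(tab, nPCs = 5, seed = 2, qc = FALSE)
  emb <- overlayInfection(emb, tab)
  flags <- setNames(infectedFlags(emb), barcodes(emb))
  expect_true(flags[[bcs[1]]])
  expect_false(flags[[bcs[2]]])

  # zero viral rows: all false
  tabH <- umiTable(host, source = rep("host", 20))
  colnames(host) <- bcs
  tabH <- umiTable(host, source = rep("host", 20))
  embH <- overlayInfection(normalizeAndEmbed(tabH, nPCs = 5, seed = 2,
                                             qc = FALSE), tabH)
  expect_false(any(infectedFlags(embH)))

  # barcode mismatch errors
  other <- umiTable(matrix(1, 1, 1,
                           dimnames = list("v", randSeq(16))),
                    source = "viral-marker")
  expect_error(overlayInfection(emb, other), "mismatch")
})

test_that("overlay flags match simulator truth in the noise-free regime", {
  fx <- smallFixture()
  tr <- truthCells(fx$sim$truth)
  tab <- countViralUMIs(trimReads(fx$sim$reads), fx$refs)
  flags <- viralUMIs(tab)[tr$barcode] >= 10
  expect_identical(unname(flags), tr$true_viral_umis >= 10)
})
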