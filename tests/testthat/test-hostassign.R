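test_that("contigs from pure cells are assigned their own taxon", {
  fx <- smallFixture()
  tr <- truthCells(fx$sim$truth)
  bc <- tr$barcode[which(tr$taxon == "Prymnesiophyceae")[1]]
  s18 <- as.character(host18S(fx$refs))[1]  # Prymnesiophyceae v1
  # fabricate an assembled 18S fragment for that cell
  contig <- Biostrings::DNAStringSet(setNames(substr(s18, 200, 500),
                                              paste0(bc, "_c1")))
  mcols(contig) <- S4Vectors::DataFrame(cell = bc)
  calls <- assignContigTaxon(contig, refDbList(fx$refs))
  expect_identical(calls$group, "Prymnesiophyceae")
  expect_gte(calls$best_identity, 99)
})

test_that("conflicting per-database best hits make a contig nonspecific", {
  set.seed(61)
  s <- randSeq(400)
  dbA <- Biostrings::DNAStringSet(c(refA = s))
  mcols(dbA) <- S4Vectors::DataFrame(group = "GroupA")
  dbB <- Biostrings::DNAStringSet(c(refB = s))
  mcols(dbB) <- S4Vectors::DataFrame(group = "GroupB")
  calls <- assignContigTaxon(substr(s, 1, 200), list(dbA, dbB),
                             groups = c("GroupA", "GroupB"))
  expect_identical(calls$group, "nonspecific")
})

test_that("identity and length gates leave distant contigs unassigned", {
  set.seed(62)
  fx <- smallFixture()
  db <- refDbList(fx$refs)
  ref1 <- as.character(host18S(fx$refs))[1]
  qv <- strsplit(substr(ref1, 1, 400), "")[[1]]
  pos <- sample(400, 20)  # 95% identity
  qv[pos] <- vapply(qv[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  q95 <- paste(qv, collapse = "")
  expect_identical(assignContigTaxon(q95, db)$group, "unassigned")
  # lowering the gate assigns it (threshold monotonicity)
  expect_identical(assignContigTaxon(q95, db, minIdentity = 90)$group,
                   "Prymnesiophyceae")
  # sub-length contigs are never searched
  expect_identical(assignContigTaxon(substr(ref1, 1, 80), db)$group,
                   "unassigned")
})

test_that("hits outside the configured group list become other_eukaryote", {
  fx <- smallFixture()
  db <- refDbList(fx$refs)
  contig <- substr(as.character(host18S(fx$refs))[1], 1, 300)
  calls <- assignContigTaxon(contig, db, groups = c("Chrysophyceae"))
  expect_identical(calls$group, "other_eukaryote")
})

test_that("cell-level calls follow the conservative conflict rules", {
  cc <- data.frame(
    cell = c("c1", "c1", "c1", "c2", "c2", "c3", "c3", "c4"),
    contig_id = paste0("k", 1:8),
    group = c("A", "A", "nonspecific", "A", "B",
              "other_eukaryote", "other_eukaryote", "unassigned"),
    best_identity = 99.5, best_bitscore = 300,
    stringsAsFactors = FALSE)
  tx <- assignCellTaxon(cc, cellBarcodes = c("c1", "c2", "c3", "c4"))
  expect_identical(tx$group, c("A", "omitted", "other_eukaryote", "unassigned"))
  # conservatism: a group call never contradicts a specific contig call
  expect_true(all(tx$group[1] %in% cc$group[cc$cell == "c1"]))
})

test_that("pooled subpopulation assembly identifies the rare host at high identity", {
  fx <- smallFixture()
  tr <- truthCells(fx$sim$truth)
  inf <- tr$barcode[tr$infected & tr$taxon == "Prymnesiophyceae"]
  db <- refDbList(fx$refs)[[1]]
  ranked <- identifyPooledSubpopulation(inf, fx$sim$reads, db)
  expect_gt(nrow(ranked), 0)
  expect_identical(ranked$group[1], "Prymnesiophyceae")
  expect_gte(ranked$best_identity[1], 99)

  # two-taxon pooling surfaces both, each from its own contigs
  inf2 <- tr$barcode[tr$infected & tr$taxon %in%
                       c("Prymnesiophyceae", "Chrysophyceae")]
  ranked2 <- identifyPooledSubpopulation(inf2, fx$sim$reads, db)
  expect_setequal(intersect(c("Prymnesiophyceae", "Chrysophyceae"),
                            ranked2$group),
                  c("Prymnesiophyceae", "Chrysophyceae"))

  expect_error(identifyPooledSubpopulation(character(0), fx$sim$reads, db),
               "empty")
})

test_that("noise-free singlets are never omitted; planted doublets are", {
  cfg <- communityConfig(
    taxonNames = c("TaxA", "TaxB", "TaxC"),
    taxonCellFractions = c(0.5, 0.3, 0.2), dominantTaxon = "TaxA",
    infectionTable = data.frame(taxon = character(0), family = character(0),
                                frac_infected = numeric(0),
                                expr_fraction = numeric(0)),
    ambientViralRate = 0, doubletRate = 0.1, nCells = 30L,
    readsPerCell = c(meanlog = log(4000), sdlog = 0.1), seed = 13L)
  refs <- simulateReferences(cfg)
  sim <- simulateExperiment(refs, cfg)
  tr <- truthCells(sim$truth)
  contigs <- assembleCells(sim$reads)
  cc <- assignContigTaxon(contigs, refDbList(refs))
  tx <- assignCellTaxon(cc, cellBarcodes = tr$barcode)
  omitted <- tx$barcode[tx$group == "omitted"]
  expect_setequal(omitted, tr$barcode[tr$doublet])
  # and cell-level groups match truth for assigned singlets
  singles <- tx[tx$barcode %in% tr$barcode[!tr$doublet] &
                  !tx$group %in% c("unassigned", "omitted"), ]
  expect_identical(singles$group,
                   tr$taxon[match(singles$barcode, tr$barcode)])
})
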