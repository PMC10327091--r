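test_that("one seed reproduces references and reads bit-exactly", {
  cfg <- smallConfig(seed = 42L)
  r1 <- simulateReferences(cfg)
  r2 <- simulateReferences(cfg)
  expect_identical(as.character(host18S(r1)), as.character(host18S(r2)))
  expect_identical(as.character(viralGenes(r1)), as.character(viralGenes(r2)))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeFasta(host18S(r1), f1); writeFasta(host18S(r2), f2)
  expect_identical(readLines(f1), readLines(f2))

  cfg2 <- smallConfig(seed = 42L, nCells = 20L)
  s1 <- simulateExperiment(r1, cfg2)
  s2 <- simulateExperiment(r2, cfg2)
  expect_identical(cdnaSeqs(s1$reads), cdnaSeqs(s2$reads))
  expect_identical(truthCells(s1$truth), truthCells(s2$truth))
})

test_that("reference identity bands hold: >=99% within taxa, <90% between", {
  fx <- smallFixture()
  s18 <- host18S(fx$refs)
  grp <- mcols(s18)$group
  seqs <- as.character(s18)
  for (i in seq_along(seqs)) for (j in seq_len(i - 1L)) {
    id <- fullLengthIdentity(seqs[i], seqs[j])
    if (grp[i] == grp[j]) expect_gte(id, 99) else expect_lt(id, 90)
  }
  # and the in-repo aligner agrees for one between-taxon pair: whatever the
  # best local alignment is, its identity sits far below every gate
  a <- which(grp == grp[1]); b <- which(grp != grp[1])[1]
  h <- alignUngapped(seqs[a[1]], seqs[b])
  if (!is.null(h)) expect_lt(h$identity, 90)
})

test_that("viral proteins are the frame-0 translations of their genes", {
  fx <- smallFixture()
  vg <- viralGenes(fx$refs)
  vp <- viralProteins(fx$refs)
  indep <- suppressWarnings(
    Biostrings::translate(vg, no.init.codon = TRUE))  # independent translator
  expect_identical(as.character(indep), as.character(vp))
  # between-family protein identity stays far below 60%
  fam <- mcols(vp)$family
  g <- mcols(vp)$gene
  idx <- which(g == g[1])
  for (i in idx) for (j in idx) if (i < j && fam[i] != fam[j])
    expect_lt(fullLengthIdentity(as.character(vp[[i]]),
                                 as.character(vp[[j]])), 60)
})

test_that("a planted infection at 50% expression yields ~50 viral UMIs of 100 reads,
           recovered exactly by UMI counting", {
  cfg <- communityConfig(
    taxonNames = "Solo", taxonCellFractions = 1, dominantTaxon = "Solo",
    infectionTable = data.frame(taxon = "Solo", family = "IM_07",
                                frac_infected = 1, expr_fraction = 0.5,
                                stringsAsFactors = FALSE),
    ambientViralRate = 0, doubletRate = 0, nCells = 5L,
    readsPerCell = c(meanlog = log(100), sdlog = 0), seed = 9L)
  refs <- simulateReferences(cfg)
  sim <- simulateExperiment(refs, cfg)
  tr <- truthCells(sim$truth)
  expect_true(all(abs(tr$true_viral_umis - 50) < 25))  # binomial around 50
  tab <- countViralUMIs(trimReads(sim$reads), refs)
  expect_identical(unname(viralUMIs(tab)[tr$barcode]),
                   as.numeric(tr$true_viral_umis))
})

test_that("degenerate community sizes behave", {
  cfg <- smallConfig(nCells = 0L)
  refs <- simulateReferences(cfg)
  sim <- simulateExperiment(refs, cfg)
  expect_length(sim$reads, 0)
  expect_equal(nrow(truthCells(sim$truth)), 0L)
})

test_that("rare-class composition is apportioned exactly", {
  cfg <- communityConfig(nCells = 5000L, seed = 3L)
  refs <- smallFixture()$refs
  sim <- simulateExperiment(refs, cfg)
  tab <- table(truthCells(sim$truth)$taxon)
  expect_equal(as.integer(tab[["Katablepharidaceae"]]), 20L)  # 0.4% of 5000
})

test_that("time-series tables follow the configured trajectory structure", {
  cfg <- smallConfig(seed = 5L)
  taxa <- cfg@taxonNames
  traj <- as.data.frame(matrix(rep(c(0.5, 0.2, 0.15, 0.1, 0.03, 0.02), 3),
                               nrow = 3, byrow = TRUE))
  names(traj) <- taxa
  traj$infected_fraction <- c(0, 0, 0)
  ts <- simulateTimeseries(cfg, days = 1:3, trajectory = traj,
                           focalTaxon = "Katablepharidaceae",
                           focalFamily = "IM_07", nASV = 2000L,
                           metazoanFraction = 0.5)
  ra <- relativeAbundance(ts$asv)
  sums <- tapply(ra$fraction, ra$day, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(ts$infected_fraction == 0))
  expect_error(
    simulateTimeseries(cfg, days = 1:4, trajectory = traj,
                       focalTaxon = "Katablepharidaceae",
                       focalFamily = "IM_07"),
    "disagree")
})

test_that("simulated reads are exact substrings of reference transcripts", {
  fx <- smallFixture()
  set.seed(12)
  pool <- c(as.character(host18S(fx$refs)), as.character(hostMRNA(fx$refs)),
            as.character(viralGenes(fx$refs)))
  some <- sample(length(fx$sim$reads), 50)
  for (i in some) {
    rd <- cdnaSeqs(fx$sim$reads)[i]
    expect_true(any(vapply(pool, function(s) grepl(rd, s, fixed = TRUE),
                           TRUE)))
  }
})
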