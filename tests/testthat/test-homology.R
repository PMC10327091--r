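test_that("exact substrings align at 100% identity on the + strand", {
  set.seed(31)
  s <- randSeq(400)
  q <- substr(s, 101, 200)
  h <- alignUngapped(q, s)
  expect_equal(h$identity, 100.0)
  expect_gte(h$aln_len, 100)
  expect_identical(h$strand, "+")
  expect_equal(h$s_start, 100)

  hr <- alignUngapped(revcompChr(q), s)
  expect_equal(hr$raw_score, h$raw_score)
  expect_identical(hr$strand, "-")
})

test_that("empty sequences and sub-threshold scores return no hit", {
  expect_null(alignUngapped("", "ACGT"))
  set.seed(32)
  expect_null(alignUngapped(randSeq(15), randSeq(15)))  # max score < 22
})

test_that("Karlin-Altschul forms are closed-form and monotone", {
  sc <- ntScoringScheme()
  expect_equal(bitScore(0, sc), -log(0.46) / log(2))
  b <- bitScore(50, sc)
  expect_equal(eValue(b, 100, 2e6), 2 * eValue(b, 100, 1e6))
  # a 100-nt perfect match passes the 1e-10 gate against a 1-Mb database
  expect_lt(eValue(bitScore(100, sc), 100, 1e6), 1e-10)
  # monotonicity
  expect_true(all(diff(bitScore(1:50, sc)) > 0))
  expect_true(all(diff(eValue(bitScore(1:50, sc), 100, 1e6)) < 0))
})

test_that("seed-and-extend equals the brute-force diagonal scan", {
  set.seed(33)
  for (i in 1:200) {
    s <- randSeq(200)
    if (i %% 2 == 0) {
      q <- randSeq(40)
    } else {
      # plant a (possibly mutated, possibly reverse-complemented) substring
      at <- sample(1:160, 1)
      q <- substr(s, at, at + 39)
      qv <- strsplit(q, "")[[1]]
      nmut <- sample(0:2, 1)
      if (nmut > 0) {
        pos <- sample(40, nmut)
        qv[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
      }
      q <- paste(qv, collapse = "")
      if (runif(1) < 0.5) q <- revcompChr(q)
    }
    got <- alignUngapped(q, s)
    want <- bruteForceAlign(q, s)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$raw_score, want$score)
      expect_equal(got$q_start, want$q_start)
      expect_equal(got$q_end, want$q_end)
      expect_equal(got$s_start, want$s_start)
      expect_equal(got$s_end, want$s_end)
      expect_identical(got$strand, want$strand)
    }
  }
})

test_that("strand symmetry: reverse-complementing the query flips the strand only", {
  set.seed(34)
  for (i in 1:25) {
    s <- randSeq(300)
    at <- sample(1:240, 1)
    q <- substr(s, at, at + 59)
    h1 <- alignUngapped(q, s)
    h2 <- alignUngapped(revcompChr(q), s)
    expect_equal(h1$raw_score, h2$raw_score)
    expect_setequal(c(h1$strand, h2$strand), c("-", "+"))
  }
})

test_that("gated nucleotide search keeps one best hit per subject and honors gates", {
  fx <- smallFixture()
  db <- host18S(fx$refs)
  ref1 <- as.character(db[[1]])
  hits <- searchNucleotide(ref1, db[1], minIdentity = 99)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 100.0)

  # a 95%-identity query fails the 99 gate but passes at 90
  set.seed(35)
  qv <- strsplit(ref1, "")[[1]]
  pos <- sample(length(qv), round(0.05 * length(qv)))
  qv[pos] <- vapply(qv[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  q95 <- paste(qv, collapse = "")
  expect_equal(nrow(searchNucleotide(q95, db[1], minIdentity = 99)), 0L)
  relaxed <- searchNucleotide(q95, db[1], minIdentity = 90)
  expect_equal(nrow(relaxed), 1L)

  # gate soundness: no returned hit violates its thresholds
  all18S <- searchNucleotide(ref1, db, minIdentity = 99, maxEvalue = 1e-10,
                             minLen = 100)
  expect_true(all(all18S$identity >= 99))
  expect_true(all(all18S$e_value <= 1e-10))
  expect_true(all(all18S$aln_len >= 100))
  expect_true(all(diff(all18S$bit_score) <= 0))  # sorted by bit score
})

test_that("translated search finds the source protein in the correct frame", {
  fx <- smallFixture()
  pdb <- viralProteins(fx$refs)
  gene <- as.character(viralGenes(fx$refs)[[1]])
  gname <- names(viralGenes(fx$refs))[1]

  read <- substr(gene, 1, 60)  # in frame 0 -> label +1
  h <- searchTranslated(read, pdb)
  expect_identical(h$subject_id, gname)
  expect_equal(h$frame, 1)
  expect_equal(h$identity, 100.0)

  hr <- searchTranslated(revcompChr(read), pdb)
  expect_identical(hr$subject_id, gname)
  expect_lt(hr$frame, 0)
})

test_that("host-derived reads essentially never hit the viral protein database", {
  fx <- smallFixture()
  pdb <- viralProteins(fx$refs)
  set.seed(36)
  mr <- as.character(hostMRNA(fx$refs))
  src <- sample(mr, 10000, replace = TRUE)
  at <- 1L + floor(runif(10000) * (nchar(src) - 59L))
  hostReads <- substring(src, at, at + 59L)
  h <- virolink:::.translatedBatch(hostReads, pdb, 60L)
  falseRate <- mean(!is.na(h$subject))
  expect_lt(falseRate, 0.01)
  # and a single host read returns NULL at the default threshold
  expect_null(searchTranslated(hostReads[which(is.na(h$subject))[1]], pdb))
})
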