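randSeq <- function(n, alphabet = c("A", "C", "G", "T"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# small noise-free community shared across tests (built once per run)
.fixtures <- new.env()

smallConfig <- function(seed = 7L, nCells = 60L, ...)
  communityConfig(nCells = nCells, seed = seed,
                  readsPerCell = c(meanlog = log(800), sdlog = 0.2),
                  ambientViralRate = 0, doubletRate = 0, ...)

smallFixture <- function() {
  if (is.null(.fixtures$sim)) {
    cfg <- smallConfig()
    refs <- simulateReferences(cfg)
    .fixtures$cfg <- cfg
    .fixtures$refs <- refs
    .fixtures$sim <- simulateExperiment(refs, cfg)
  }
  list(cfg = .fixtures$cfg, refs = .fixtures$refs, sim = .fixtures$sim)
}

# dense counts -> CellUMITable with auto names
umiTable <- function(m, source = rep("viral-marker", nrow(m))) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- vapply(seq_len(ncol(m)), function(i) randSeq(16), "")
  CellUMITable(m, geneSource = source)
}

# minimal ReadPairSet around given cDNA sequences
readSet <- function(cdna, barcode = NULL, umi = NULL) {
  n <- length(cdna)
  if (is.null(barcode)) barcode <- rep(strrep("A", 16), n)
  if (is.null(umi)) umi <- vapply(seq_len(n), function(i) randSeq(12), "")
  ReadPairSet(barcode = barcode, umi = umi, cdna = cdna,
              readId = paste0("r", seq_len(n)))
}
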