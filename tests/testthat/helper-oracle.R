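# Independent brute-force oracle for ungapped local alignment: scans every
# diagonal of both strands and keeps the maximal-subarray interval, with the
# same tie rules the package documents (score desc, lower s_start, + strand,
# lower q_start; within a diagonal earliest start then earliest end).
revcompChr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

bruteForceAlign <- function(query, subject, match = 1, mismatch = -2,
                            minScore = 22) {
  best <- NULL
  betterThan <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$score != b$score) return(a$score > b$score)
    if (a$s_start != b$s_start) return(a$s_start < b$s_start)
    if (a$strand != b$strand) return(a$strand == "+")
    a$q_start < b$q_start
  }
  sv <- strsplit(subject, "")[[1]]
  ns <- length(sv)
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcompChr(query)
    qv <- strsplit(q, "")[[1]]
    nq <- length(qv)
    for (d in (-(nq - 1L)):(ns - 1L)) {
      lo <- max(0L, -d)
      hi <- min(nq, ns - d)
      if (hi <= lo) next
      i <- lo:(hi - 1L)
      sc <- ifelse(qv[i + 1L] != "N" & sv[i + d + 1L] != "N" &
                     qv[i + 1L] == sv[i + d + 1L], match, mismatch)
      cur <- 0; curStart <- lo; bsc <- -Inf; bs <- NA; be <- NA
      for (k in seq_along(sc)) {
        cur <- cur + sc[k]
        if (cur > bsc) { bsc <- cur; bs <- curStart; be <- i[k] + 1L }
        if (cur < 0) { cur <- 0; curStart <- i[k] + 1L }
      }
      cand <- list(score = bsc, q_start = bs, q_end = be,
                   s_start = bs + d, s_end = be + d, strand = strand)
      if (betterThan(cand, best)) best <- cand
    }
  }
  if (is.null(best) || best$score < minScore) return(NULL)
  best
}
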