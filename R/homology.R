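#' Alignment scoring schemes
#'
#' Match/mismatch scores with the Karlin-Altschul parameters lambda and K
#' used to convert raw ungapped scores to bit scores and E-values. The
#' nucleotide defaults (+1/-2, lambda 1.28, K 0.46) and the protein defaults
#' (BLOSUM62, lambda 0.267, K 0.041) are the standard published values for
#' these schemes.
#'
#' @slot match positive match score (ignored for protein scoring)
#' @slot mismatch negative mismatch score (ignored for protein scoring)
#' @slot lambda Karlin-Altschul lambda (> 0)
#' @slot k Karlin-Altschul K (0 < K < 1)
#' @export
setClass("ScoringScheme", representation(
  match = "integer", mismatch = "integer", lambda = "numeric", k = "numeric"))

setValidity("ScoringScheme", function(object) {
  if (object@match <= 0L) return("match must be > 0")
  if (object@mismatch >= 0L) return("mismatch must be < 0")
  if (object@lambda <= 0) return("lambda must be > 0")
  if (object@k <= 0 || object@k >= 1) return("K must lie in (0, 1)")
  TRUE
})

#' @rdname ScoringScheme-class
#' @param match,mismatch,lambda,k scheme parameters
#' @return a \linkS4class{ScoringScheme}
#' @export
ntScoringScheme <- function(match = 1L, mismatch = -2L, lambda = 1.28, k = 0.46)
  new("ScoringScheme", match = as.integer(match),
      mismatch = as.integer(mismatch), lambda = lambda, k = k)

#' @rdname ScoringScheme-class
#' @export
aaScoringScheme <- function(lambda = 0.267, k = 0.041)
  new("ScoringScheme", match = 1L, mismatch = -1L, lambda = lambda, k = k)

#' Karlin-Altschul bit score and E-value
#'
#' \code{bitScore}: S' = (lambda * S - ln K) / ln 2.
#' \code{eValue}: E = m * n * 2^(-S'), linear in both search-space lengths.
#'
#' @param rawScore raw ungapped alignment score(s)
#' @param scheme a \linkS4class{ScoringScheme}
#' @return numeric
#' @export
bitScore <- function(rawScore, scheme = ntScoringScheme())
  (scheme@lambda * rawScore - log(scheme@k)) / log(2)

#' @rdname bitScore
#' @param bit bit score(s)
#' @param queryLen,dbLen search-space lengths (positive)
#' @export
eValue <- function(bit, queryLen, dbLen) {
  stopifnot(queryLen > 0, dbLen > 0)
  queryLen * dbLen * 2^(-bit)
}

#' Ungapped local nucleotide alignment
#'
#' Exact maximal-scoring ungapped local alignment of query against subject
#' over both strands: exact 11-mer seeds define candidate diagonals, each of
#' which is rescored exhaustively by a maximal-subarray pass, so the result
#' equals a brute-force scan over every seeded diagonal. N never matches.
#' Ties are broken by lower subject start, then + strand. Alignments scoring
#' below \code{minScore} (raw) are not reported.
#'
#' Coordinates are 0-based half-open; query coordinates refer to the
#' oriented query (the reverse complement when \code{strand == "-"}).
#'
#' @param query,subject nucleotide strings over ACGTN
#' @param scheme a \linkS4class{ScoringScheme}
#' @param minScore minimum raw score to report (default 22)
#' @return a list with raw_score, matches, aln_len, identity, q_start,
#'   q_end, s_start, s_end, strand, bit_score; or NULL if no alignment
#'   reaches \code{minScore}
#' @export
alignUngapped <- function(query, subject, scheme = ntScoringScheme(),
                          minScore = 22L) {
  if (!nzchar(query) || !nzchar(subject)) return(NULL)
  h <- .align_nt_cpp(as.character(query), as.character(subject),
                     scheme@match, scheme@mismatch, as.integer(minScore))
  if (!length(h)) return(NULL)
  h$identity <- round(100 * h$matches / h$aln_len, 1)
  h$bit_score <- bitScore(h$raw_score, scheme)
  h
}

#' Gated best-hit nucleotide search against a labelled database
#'
#' One best alignment per subject; a hit is kept only if it passes all three
#' gates (percent identity, E-value against the total database length, and
#' alignment length). Hits are sorted by bit score (descending), ties by
#' subject id.
#'
#' @param query nucleotide string
#' @param db DNAStringSet; \code{mcols(db)$group} supplies the group label
#' @param minIdentity,maxEvalue,minLen gate thresholds (defaults 99,
#'   1e-10, 100)
#' @param scheme a \linkS4class{ScoringScheme}
#' @return data.frame of passing hits (possibly 0 rows) with BLAST-tabular
#'   style columns
#' @export
searchNucleotide <- function(query, db, minIdentity = 99, maxEvalue = 1e-10,
                             minLen = 100L, scheme = ntScoringScheme()) {
  stopifnot(minIdentity >= 0, minIdentity <= 100, maxEvalue >= 0, minLen >= 1)
  hits <- .searchNucleotideBatch(setNames(as.character(query), "query"), db,
                                 minIdentity, maxEvalue, minLen, scheme)
  hits$query_id <- NULL
  hits
}

# batch form: one best gated hit per (query, subject)
.searchNucleotideBatch <- function(queries, db, minIdentity, maxEvalue,
                                   minLen, scheme = ntScoringScheme()) {
  empty <- data.frame(
    query_id = character(0), subject_id = character(0),
    group_label = character(0), identity = numeric(0), aln_len = integer(0),
    raw_score = numeric(0), bit_score = numeric(0), e_value = numeric(0),
    strand = character(0), q_start = integer(0), q_end = integer(0),
    s_start = integer(0), s_end = integer(0), stringsAsFactors = FALSE)
  if (length(db) == 0L || length(queries) == 0L) return(empty)
  df <- .search_nt_batch_cpp(as.character(queries), as.character(db),
                             scheme@match, scheme@mismatch, 22L)
  if (nrow(df) == 0L) return(empty)
  dbLen <- sum(width(db))
  groups <- mcols(db)$group
  out <- data.frame(
    query_id = names(queries)[df$query],
    subject_id = names(db)[df$subject],
    group_label = if (is.null(groups)) NA_character_ else groups[df$subject],
    identity = round(100 * df$matches / df$aln_len, 1),
    aln_len = df$aln_len,
    raw_score = df$raw_score,
    bit_score = bitScore(df$raw_score, scheme),
    strand = df$strand,
    q_start = df$q_start, q_end = df$q_end,
    s_start = df$s_start, s_end = df$s_end,
    stringsAsFactors = FALSE)
  out$e_value <- eValue(out$bit_score, nchar(queries)[df$query], dbLen)
  out <- out[out$identity >= minIdentity & out$e_value <= maxEvalue &
               out$aln_len >= minLen, , drop = FALSE]
  out <- out[order(out$query_id, -out$bit_score, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out[c("query_id", "subject_id", "group_label", "identity", "aln_len",
        "raw_score", "bit_score", "e_value", "strand", "q_start", "q_end",
        "s_start", "s_end")]
}

#' Six-frame translated best-hit search
#'
#' Translates the read in all six frames (standard code; stop codons break
#' alignments), seeds with exact 5-mer amino-acid matches and rescans each
#' seeded diagonal exhaustively under BLOSUM62. The single best hit is
#' returned; ties are broken by lexicographic subject id, then by frame in
#' the order +1, +2, +3, -1, -2, -3. Negative frames read the reverse
#' complement.
#'
#' @param read nucleotide string (any length)
#' @param proteinDb AAStringSet; \code{mcols} may carry \code{family} and
#'   \code{gene}
#' @param minAAScore minimum raw BLOSUM62 score. The default of 60 sits
#'   between the best scores random 60-mers reach against an unrelated
#'   protein database (at most the low 50s) and the worst-case score of a
#'   genuinely viral read (an exact 19-residue in-frame match scores at
#'   least 76), so host-derived reads essentially never pass while viral
#'   reads always do
#' @param scheme protein \linkS4class{ScoringScheme} for the bit score
#' @return a list (subject_id, group_label, raw_score, bit_score, frame,
#'   identity, aln_len, q_start, q_end, s_start, s_end, tie) or NULL
#' @export
searchTranslated <- function(read, proteinDb, minAAScore = 60L,
                             scheme = aaScoringScheme()) {
  h <- .translatedBatch(as.character(read), proteinDb, minAAScore)
  if (is.na(h$subject[1L])) return(NULL)
  fam <- mcols(proteinDb)$family
  list(subject_id = names(proteinDb)[h$subject[1L]],
       group_label = if (is.null(fam)) NA_character_ else fam[h$subject[1L]],
       raw_score = h$raw_score[1L],
       bit_score = bitScore(h$raw_score[1L], scheme),
       frame = h$frame[1L],
       identity = round(100 * h$matches[1L] / h$aln_len[1L], 1),
       aln_len = h$aln_len[1L],
       q_start = h$q_start[1L], q_end = h$q_end[1L],
       s_start = h$s_start[1L], s_end = h$s_end[1L],
       tie = h$tie[1L])
}

.translatedBatch <- function(reads, proteinDb, minAAScore) {
  lex <- match(names(proteinDb), sort(names(proteinDb)))
  .translated_best_hits_cpp(reads, as.character(proteinDb), lex,
                            as.integer(minAAScore))
}

#' Full-length ungapped pairwise identity
#'
#' Position-by-position identity of two equal-length (or truncated to the
#' shorter) sequences, as a percentage. Used for reference-set identity-band
#' checks.
#' @param a,b sequences
#' @return numeric percent identity
#' @export
fullLengthIdentity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  av <- utf8ToInt(substr(a, 1, n))
  bv <- utf8ToInt(substr(b, 1, n))
  100 * mean(av == bv)
}
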