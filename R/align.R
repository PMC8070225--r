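## Self-contained Smith-Waterman-Gotoh local aligner for generating homology
## hits in tests and demos without an external BLAST/DIAMOND. Scores use
## BLOSUM62 with affine gaps; E-values come from a fixed Karlin-Altschul
## approximation and are documented as approximate.

## BLOSUM62 (half-bit units, standard NCBI table), 20 residues + X.
.blosum62 <- local({
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V","X")
  v <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,-1,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,-1,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,-1,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-2,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,-1,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,-1,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,-1,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,-1,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,-1,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,-1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,-1,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,-1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2, 0,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,-2,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,-1,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4,-1,
     0,-1,-1,-1,-2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-2, 0, 0,-2,-1,-1,-1)
  matrix(v, 21L, 21L, byrow = TRUE, dimnames = list(aa, aa))
})

#' The built-in BLOSUM62 substitution matrix
#'
#' Standard NCBI BLOSUM62 scores (half-bit units) over the 20 amino acids
#' plus \code{X}.
#'
#' @return 21 x 21 integer matrix with residue dimnames
#' @export
blosum62Matrix <- function() .blosum62

#' Toy Smith-Waterman local alignment
#'
#' Optimal local alignment (Smith-Waterman with Gotoh affine gaps) of two
#' amino-acid sequences. A gap of length L costs
#' \code{gap_open + L * gap_extend}. The raw score is converted to a bit
#' score and E-value with fixed Karlin-Altschul parameters
#' (\code{E = K * m * n * exp(-lambda * raw)}) — a documented approximation
#' good enough for generating self-consistent test hits, not a BLAST
#' replacement. Percent identity is computed over the alignment columns and
#' the coverages over the aligned spans, matching the similarity-hit
#' contract.
#'
#' @param seq_a,seq_b amino-acid strings (query, subject); must be non-empty
#' @param submat substitution matrix (default [blosum62Matrix()]); unknown
#'   residues fall back to \code{X}
#' @param gap_open,gap_extend affine gap parameters (defaults 10 and 0.5,
#'   subtracted)
#' @param lambda,K Karlin-Altschul parameters (defaults 0.267, 0.041)
#' @return a one-row similarity-hit data.frame (same columns as
#'   [readSimilarityTable()]), or \code{NULL} when no positive-scoring local
#'   alignment exists
#' @examples
#' toyLocalAlign("MKVLAW", "MKVLAW")$pct_identity   # 100
#' @export
toyLocalAlign <- function(seq_a, seq_b, submat = blosum62Matrix(),
                          gap_open = 10, gap_extend = 0.5,
                          lambda = 0.267, K = 0.041) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  a <- strsplit(toupper(seq_a), "")[[1L]]
  b <- strsplit(toupper(seq_b), "")[[1L]]
  a[!a %in% rownames(submat)] <- "X"
  b[!b %in% rownames(submat)] <- "X"
  m <- length(a); n <- length(b)

  NEG <- -Inf
  H <- matrix(0, m + 1L, n + 1L)          # best ending in match/mismatch or 0
  E <- matrix(NEG, m + 1L, n + 1L)        # gap in query (consume subject)
  Fm <- matrix(NEG, m + 1L, n + 1L)       # gap in subject (consume query)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(m)) {
    si <- submat[a[i], ]
    for (j in seq_len(n)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - gap_open - gap_extend,
                               E[i + 1L, j] - gap_extend)
      Fm[i + 1L, j + 1L] <- max(H[i, j + 1L] - gap_open - gap_extend,
                                Fm[i, j + 1L] - gap_extend)
      dg <- H[i, j] + si[b[j]]
      h <- max(0, dg, E[i + 1L, j + 1L], Fm[i + 1L, j + 1L])
      H[i + 1L, j + 1L] <- h
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  if (best <= 0) return(NULL)

  ## traceback from (bi, bj); states: H (aligned column), E (gap in query),
  ## F (gap in subject)
  eps <- 1e-9
  i <- bi; j <- bj; state <- "H"
  matches <- 0L; ali_len <- 0L; gapopen <- 0L
  q_end <- bi; s_end <- bj
  repeat {
    if (state == "H") {
      v <- H[i + 1L, j + 1L]
      if (v <= eps) break
      if (i > 0L && j > 0L &&
          abs(v - (H[i, j] + submat[a[i], b[j]])) < eps) {
        ali_len <- ali_len + 1L
        if (a[i] == b[j]) matches <- matches + 1L
        i <- i - 1L; j <- j - 1L
      } else if (abs(v - E[i + 1L, j + 1L]) < eps) {
        state <- "E"
      } else {
        state <- "F"
      }
    } else if (state == "E") {
      ali_len <- ali_len + 1L
      opened <- abs(E[i + 1L, j + 1L] -
                    (H[i + 1L, j] - gap_open - gap_extend)) < eps
      j <- j - 1L
      if (opened) { gapopen <- gapopen + 1L; state <- "H" }
    } else {
      ali_len <- ali_len + 1L
      opened <- abs(Fm[i + 1L, j + 1L] -
                    (H[i, j + 1L] - gap_open - gap_extend)) < eps
      i <- i - 1L
      if (opened) { gapopen <- gapopen + 1L; state <- "H" }
    }
  }
  q_start <- i; s_start <- j        # 0-based half-open span starts

  raw <- best
  bit <- (lambda * raw - log(K)) / log(2)
  evalue <- K * m * n * exp(-lambda * raw)
  data.frame(query_id = "query", subject_id = "subject",
             pct_identity = 100 * matches / ali_len,
             ali_len = ali_len, mismatch = ali_len - matches,
             gapopen = gapopen,
             q_start = q_start, q_end = q_end,
             s_start = s_start, s_end = s_end,
             evalue = evalue, bitscore = bit,
             q_len = m, s_len = n,
             q_cov = 100 * (q_end - q_start) / m,
             s_cov = 100 * (s_end - s_start) / n,
             raw_score = raw)
}
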